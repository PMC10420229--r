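test_that("z-transform standardizes columns and drops constants", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize_descriptors(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))
  expect_equal(unname(standardize_descriptors(z)), unname(z), tolerance = 1e-12)

  expect_warning(z2 <- standardize_descriptors(cbind(m, k = rep(7, 3))),
                 "constant")
  expect_identical(colnames(z2), c("a", "b"))
  expect_error(standardize_descriptors(cbind(k = rep(7, 3))), "degenerate")
})

test_that("k-means recovers planted blobs and honors its invariants", {
  sim <- simulate_descriptors(sizes = c(20L, 20L, 20L), p = 10L,
                              separation = 10, seed = 2)
  cr <- kmeans_cluster(sim$values, k = 3, seed = 2)
  expect_equal(label_agreement(sim$labels, cr$labels), 1.0)
  expect_equal(sum(cr$sizes), 60L)

  cr1 <- kmeans_cluster(sim$values, k = 1, seed = 2)
  expect_equal(cr1$within_ss, sum(scale(sim$values, scale = FALSE)^2))

  crn <- kmeans_cluster(sim$values[1:5, ], k = 5, seed = 2)
  expect_equal(crn$within_ss, 0)
  expect_error(kmeans_cluster(sim$values[1:3, ], k = 4, seed = 2), "k must")

  # within-SS is non-increasing in k for best-of-restarts solutions
  wss <- vapply(1:5, function(k)
    kmeans_cluster(sim$values, k, seed = 2)$within_ss, numeric(1))
  expect_true(all(diff(wss) <= 1e-8))

  # determinism given the seed
  cr_again <- kmeans_cluster(sim$values, k = 3, seed = 2)
  expect_identical(cr$labels, cr_again$labels)
})

test_that("PCA decomposes variance on the correlation convention", {
  set.seed(9)
  x <- rnorm(50)
  m <- cbind(a = x, b = 2 * x, c = -3 * x)  # perfectly collinear
  z <- standardize_descriptors(m)
  p <- pca_descriptors(z, 1)
  expect_equal(p$explained_variance_ratio[1], 1.0)

  big <- standardize_descriptors(matrix(rnorm(2000 * 5), 2000,
                                        dimnames = list(NULL, paste0("d", 1:5))))
  pb <- pca_descriptors(big, 5)
  expect_equal(unname(pb$explained_variance_ratio), rep(0.2, 5),
               tolerance = 0.12)
  expect_equal(sum(pb$explained_variance_ratio), 1, tolerance = 1e-10)
  expect_equal(crossprod(pb$loadings), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # standardized data: total variance equals the number of descriptors
  expect_equal(sum(apply(big, 2, var)), 5)

  expect_error(pca_descriptors(big, 9), "n_components")
})

test_that("cluster profiles decompose the grand mean", {
  sim <- simulate_descriptors(sizes = c(30L, 15L, 15L), p = 8L,
                              separation = 12, seed = 4)
  z <- standardize_descriptors(sim$values)
  cr <- kmeans_cluster(z, 3, seed = 4)
  prof <- cluster_profile(cr, z)
  # size-weighted average of cluster means recovers the zero grand mean
  wavg <- colSums(prof$profile * cr$sizes) / sum(cr$sizes)
  expect_lt(max(abs(wavg)), 1e-10)
  expect_equal(unname(prof$profile), unname(cr$centroids), tolerance = 1e-8)
  expect_identical(names(prof$argmax), colnames(z))

  one <- kmeans_cluster(z, 1, seed = 4)
  expect_lt(max(abs(cluster_profile(one, z)$profile)), 1e-12)
})

test_that("SVM regression recovers a noiseless linear response", {
  set.seed(21)
  dm <- matrix(rnorm(80 * 5), 80, dimnames = list(sprintf("c%02d", 1:80),
                                                  paste0("D", 1:5)))
  y <- 2 * dm[, "D1"] - 1
  rep <- svm_regress(dm, y, selected = "D1", seed = 1)
  expect_gte(rep$r2_test, 0.99)
  expect_equal(rep$n_test, 12L)
  expect_identical(rep$selected_descriptors, "D1")
})

test_that("SVM metrics are deterministic and row-order invariant", {
  set.seed(22)
  dm <- matrix(rnorm(40 * 4), 40, dimnames = list(sprintf("c%02d", 1:40),
                                                  paste0("D", 1:4)))
  y <- dm[, 1] + rnorm(40, 0, 0.3)
  r1 <- svm_regress(dm, y, seed = 3)
  r2 <- svm_regress(dm, y, seed = 3)
  expect_identical(r1$r2_test, r2$r2_test)
  expect_identical(r1$best_hyperparameters, r2$best_hyperparameters)

  perm <- sample(40)
  r3 <- svm_regress(dm[perm, ], y[perm], seed = 99,
                    test_index = r1$test_compounds)
  expect_equal(r3$r2_test, r1$r2_test, tolerance = 1e-8)
  expect_equal(r3$rmse_test, r1$rmse_test, tolerance = 1e-8)
  expect_identical(sort(r3$test_compounds), sort(r1$test_compounds))

  expect_error(svm_regress(dm[1:10, ], y[1:10], seed = 1), "insufficient")
  expect_error(svm_regress(dm, y, selected = "nope", seed = 1), "unknown descriptor")
})

test_that("the open descriptor panel covers the bundled compounds", {
  dm <- compute_descriptors(experimental_compounds())
  expect_equal(nrow(dm), 63L)
  expect_gte(ncol(dm), 20L)
  expect_false(anyNA(dm))
  expect_equal(unname(dm["Phenol", "n_heavy"]), 7)
  expect_equal(unname(dm["Caffeine", "n_N"]), 4)
  expect_gt(dm["Butylbenzene", "logP_crippen"], dm["Hydroquinone", "logP_crippen"])
})
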