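test_that("generators are pure functions of their seed", {
  expect_identical(simulate_partition_truth(20, seed = 8),
                   simulate_partition_truth(20, seed = 8))
  truth <- simulate_partition_truth(10, seed = 8)
  expect_identical(suppressWarnings(simulate_retention(truth, seed = 8)),
                   suppressWarnings(simulate_retention(truth, seed = 8)))
  plant <- data.frame(micelle = "SC", solvent = "s", slope = 0.5, intercept = 1)
  expect_identical(simulate_solvation(truth, plant, seed = 8),
                   simulate_solvation(truth, plant, seed = 8))
  expect_identical(simulate_descriptors(seed = 8), simulate_descriptors(seed = 8))
  # the global RNG stream is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_partition_truth(5, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("partition truth spans the requested range", {
  truth <- simulate_partition_truth(500, seed = 1)
  expect_true(all(truth >= 0.19 & truth <= 3.71))
  expect_identical(dim(simulate_partition_truth(0, seed = 1)), c(0L, 3L))
})

test_that("noiseless retention records invert exactly; noisy ones are unbiased", {
  truth <- simulate_partition_truth(63, seed = 3)
  rec0 <- simulate_retention(truth, noise_sd = 0, seed = 3)
  conv0 <- convert_retention_table(rec0)
  expect_equal(conv0$logp[rownames(truth), colnames(truth)], truth,
               tolerance = 1e-10)

  # near the EOF marker (k -> 0) time noise maps to heavy-tailed logP error;
  # unbiasedness is asserted on the informative part of the range
  informative <- truth >= 1
  stats_by_reps <- vapply(c(1L, 3L, 9L), function(nr) {
    per_seed <- vapply(1:20, function(s) {
      conv <- suppressWarnings(convert_retention_table(
        simulate_retention(truth, noise_sd = 0.05, n_replicates = nr,
                           seed = s)))
      err <- conv$logp[rownames(truth), colnames(truth)] - truth
      c(mae = mean(abs(err)), bias = mean(err[informative]))
    }, numeric(2))
    rowMeans(per_seed)
  }, numeric(2))
  expect_true(all(diff(stats_by_reps["mae", ]) < 0))  # more replicates, less error
  expect_lt(abs(stats_by_reps["bias", 2]), 0.05)      # recovery is unbiased
})

test_that("extreme partitioning hugs the micellar marker with a clipping warning", {
  truth <- matrix(8, 1, 1, dimnames = list("cpd001", "SC"))
  expect_warning(rec <- simulate_retention(truth, noise_sd = 0.05, seed = 1),
                 "clipped")
  expect_true(all(rec$t_r < 10 & rec$t_r > 9.9))
})

test_that("solvation panels carry the planted linear calibration", {
  truth <- simulate_partition_truth(63, seed = 6)
  plant <- data.frame(micelle = "SC", solvent = "propan-1-ol",
                      slope = 0.47, intercept = 0.55)
  dg0 <- simulate_solvation(truth, plant, residual_sd = 0, seed = 6)
  m0 <- fit_calibration(logp_matrix(dg0)[, "propan-1-ol/water"], truth[, "SC"])
  expect_equal(m0$slope, 0.47, tolerance = 1e-8)
  expect_equal(m0$intercept, 0.55, tolerance = 1e-8)
  expect_gt(m0$r2, 1 - 1e-10)

  hits <- vapply(1:500, function(s) {
    dg <- simulate_solvation(truth, plant, residual_sd = 0.5, seed = s)
    m <- fit_calibration(logp_matrix(dg)[, "propan-1-ol/water"], truth[, "SC"])
    abs(m$slope - 0.47) <= 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(simulate_solvation(truth, transform(plant, slope = 0)),
               "nonzero")
})

test_that("planted descriptor blobs are recovered at high separation only", {
  sim <- simulate_descriptors(sizes = c(45L, 13L, 5L), p = 85L,
                              separation = 10, seed = 9)
  expect_identical(dim(sim$values), c(63L, 85L))
  cr <- kmeans_cluster(standardize_descriptors(sim$values), k = 3, seed = 9)
  expect_identical(sort(cr$sizes, decreasing = TRUE), c(45L, 13L, 5L))
  expect_equal(label_agreement(sim$labels, cr$labels), 1.0)

  flat <- simulate_descriptors(sizes = c(45L, 13L, 5L), p = 85L,
                               separation = 0, seed = 9)
  crf <- kmeans_cluster(standardize_descriptors(flat$values), k = 3, seed = 9)
  agree <- e1071::classAgreement(table(flat$labels, crf$labels))
  expect_lt(abs(agree$crand), 0.2)  # no better than chance
})
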