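test_that("correlation matrices respect affine invariance and support masks", {
  set.seed(3)
  x <- rnorm(20)
  tab <- cbind(a = x, b = 2 * x + 1, c = -x, d = rnorm(20))
  rownames(tab) <- paste0("c", 1:20)
  cm <- correlation_matrix(tab)
  expect_equal(unname(diag(cm$r)), rep(1, 4))
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "c"], -1)
  expect_true(all(abs(cm$r) <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(cm$r, t(cm$r))

  # cells with fewer complete pairs than min_pairs are masked
  tab2 <- tab
  tab2[1:18, "d"] <- NA
  cm2 <- correlation_matrix(tab2, min_pairs = 3)
  expect_true(is.na(cm2$r["a", "d"]))
  expect_equal(cm2$n_pairs["a", "d"], 2L)

  tab3 <- cbind(tab, e = rep(1, 20))
  expect_warning(cm3 <- correlation_matrix(tab3), "zero-variance")
  expect_true(all(is.na(cm3$r["e", ])))
})

test_that("correlation on the bundled table matches a textbook Pearson oracle", {
  tab <- experimental_logp_table()
  cm <- correlation_matrix(tab, min_pairs = 2)
  for (i in colnames(tab)) for (j in colnames(tab)) {
    expect_equal(cm$r[i, j], pearson_oracle(tab[, i], tab[, j]),
                 tolerance = 1e-12)
  }
})

test_that("surrogate ranking orders solvents by correlation with ties alphabetical", {
  r <- matrix(c(1, 0.9, 0.5,
                0.9, 1, 0.2,
                0.5, 0.2, 1), 3, byrow = TRUE,
              dimnames = list(c("SC", "a/water", "b/water"),
                              c("SC", "a/water", "b/water")))
  cm <- structure(list(labels = rownames(r), r = r,
                       n_pairs = matrix(10L, 3, 3, dimnames = dimnames(r))),
                  class = "correlation_matrix")
  expect_identical(rank_surrogates(cm, "SC")$solvent, c("a/water", "b/water"))

  r_tie <- r; r_tie["SC", c("a/water", "b/water")] <- 0.7
  cm$r <- r_tie
  expect_identical(rank_surrogates(cm, "SC")$solvent, c("a/water", "b/water"))
  expect_error(rank_surrogates(cm, "XX"), "unknown")
})

test_that("the aromatic-N/urea filter partitions compounds with recorded reasons", {
  cs <- experimental_compounds()
  fr <- nset_filter(cs)
  expect_setequal(c(fr$retained$name, fr$excluded$name), cs$name)
  expect_length(intersect(fr$retained$name, fr$excluded$name), 0L)
  expect_match(fr$reasons[["Pyrimidine"]], "aromatic nitrogen")
  expect_match(fr$reasons[["Phenylurea"]], "urea")
  expect_true(all(c("Aniline", "Benzamide", "Ethylbenzene") %in% fr$retained$name))

  # idempotence: filtering the retained set removes nothing further
  fr2 <- nset_filter(fr$retained)
  expect_identical(fr2$retained$name, fr$retained$name)
  expect_equal(nrow(fr2$excluded), 0L)
})

test_that("linear calibrations reproduce exact and degenerate fits", {
  x <- 1:10
  m <- fit_calibration(x, 0.5 * x + 1)
  expect_equal(m$slope, 0.5)
  expect_equal(m$intercept, 1.0)
  expect_equal(m$r2, 1.0)
  expect_equal(m$mae, 0, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(m$mse))

  const <- fit_calibration(x, rep(2, 10))
  expect_equal(const$slope, 0)
  expect_equal(const$r2, 0)

  # three collinear points: closed-form two-point slope
  m3 <- fit_calibration(c(0, 1, 2), c(1, 3, 5))
  expect_equal(m3$slope, (5 - 1) / (2 - 0))

  expect_error(fit_calibration(1:2, 1:2), "insufficient")
  expect_error(fit_calibration(rep(1, 5), 1:5), "zero variance")

  # missing pairs are listwise-deleted
  xm <- c(1:8, NA, 10); ym <- 0.5 * (1:10) + 1; ym[3] <- NA
  expect_equal(fit_calibration(xm, ym)$n, 8L)
})

test_that("MAE of a Gaussian-residual fit converges to sigma*sqrt(2/pi)", {
  set.seed(11)
  n <- 10000
  x <- runif(n, -1, 6)
  y <- 0.47 * x + 0.55 + rnorm(n, 0, 0.5)
  m <- fit_calibration(x, y)
  expect_equal(m$mae, 0.5 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("prediction and micelle comparison follow the fitted line", {
  sc <- reference_calibration_model("SC", "propan-1-ol")
  expect_equal(sc$slope, 0.47)
  expect_equal(predict_micellar_logp(sc, 3.0), 1.96)
  expect_equal(predict_micellar_logp(sc, 0), sc$intercept)
  expect_equal(predict(sc, 3.0), 1.96)

  models <- list(sc,
                 reference_calibration_model("LPFOS", "propan-1-ol"),
                 reference_calibration_model("HTAB", "propan-1-ol"))
  # at a hydrophilic x = 0 the HTAB intercept dominates
  expect_identical(best_micelle_system(models, 0), "HTAB")

  ref <- reference_calibrations()
  expect_equal(nrow(ref), 12L)
  expect_equal(sum(ref$n_set_excluded), 3L)
})

test_that("planted-surrogate synthesis is recovered through the full chain", {
  truth <- simulate_partition_truth(63, seed = 5)
  plant <- data.frame(micelle = "SC",
                      solvent = c("propan-1-ol", "octanol"),
                      slope = c(0.47, 0.47), intercept = c(0.55, 0.55),
                      residual_sd = c(0.05, 1.5))
  wins <- 0L
  for (s in 1:50) {
    dg <- simulate_solvation(truth, plant, seed = s)
    cm <- correlation_matrix(truth, logp_matrix(dg), min_pairs = 3)
    top <- rank_surrogates(cm, "SC")$solvent[1]
    wins <- wins + (top == "propan-1-ol/water")
  }
  expect_gte(wins / 50, 0.95)
})
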