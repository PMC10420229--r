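# Synthetic-data generators emulating the statistical structure the
# analysis assumes: true micellar logP tables, noisy MEKC retention
# records, solvation-energy panels with planted linear calibrations, and
# descriptor matrices with planted cluster structure. Every generator is a
# pure function of its (parameters, seed): repeated calls are bit-identical.

#' Simulate a ground-truth micellar partition table
#'
#' Draws one true micelle-water logP per (compound, system), uniformly over
#' `logp_range`. The default range [0.19, 3.71] spans the observed extremes
#' of the bundled experimental table.
#'
#' @param n_compounds Number of synthetic compounds.
#' @param systems Micellar system labels (columns).
#' @param logp_range Interval the true logP values are drawn from.
#' @param seed Integer RNG seed.
#' @return Numeric matrix (compounds x systems).
#' @export
simulate_partition_truth <- function(n_compounds,
                                     systems = c("SC", "LPFOS", "HTAB"),
                                     logp_range = c(0.19, 3.71), seed = 1L) {
  stopifnot(n_compounds >= 0L, length(logp_range) == 2L,
            logp_range[1L] <= logp_range[2L])
  vals <- with_seed(seed,
    runif(n_compounds * length(systems), logp_range[1L], logp_range[2L]))
  matrix(vals, nrow = n_compounds, ncol = length(systems),
         dimnames = list(sprintf("cpd%03d", seq_len(n_compounds)), systems))
}

#' Simulate replicate MEKC retention records
#'
#' Pushes a true partition table through the inverse retention model
#' (logP -> retention factor -> migration time) and adds Gaussian
#' measurement noise on the time axis, emitting `n_replicates` records per
#' (compound, system) — noise enters in the measurement domain, where the
#' retention model is nonlinear. Times falling outside the open interval
#' `(t_0, t_m)` are clipped just inside it with a warning (a very
#' micelle-bound analyte hugs the micellar marker).
#'
#' @param truth Numeric matrix of true logP values (compounds x systems).
#' @param registry Micelle registry resolving the column labels.
#' @param t_0,t_m EOF and micellar marker times (min).
#' @param noise_sd Gaussian noise standard deviation on migration times
#'   (min).
#' @param n_replicates Records per (compound, system).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `compound`, `system`, `replicate`,
#'   `t_r`, `t_0`, `t_m`, suitable for [convert_retention_table()].
#' @export
simulate_retention <- function(truth, registry = micelle_registry(),
                               t_0 = 2, t_m = 10, noise_sd = 0.05,
                               n_replicates = 3L, seed = 1L) {
  stopifnot(is.matrix(truth), t_0 > 0, t_m > t_0, noise_sd >= 0,
            n_replicates >= 1L)
  unknown <- setdiff(colnames(truth), names(registry))
  if (length(unknown)) {
    stop("systems not in registry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cells <- expand.grid(compound = rownames(truth), system = colnames(truth),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$logp <- truth[cbind(cells$compound, cells$system)]
  cells <- cells[!is.na(cells$logp), , drop = FALSE]
  t_true <- numeric(nrow(cells))
  for (s in unique(cells$system)) {
    idx <- cells$system == s
    k <- retention_factor_from_logp(cells$logp[idx], registry[[s]])
    t_true[idx] <- retention_time_from_factor(k, t_0, t_m)
  }
  rec <- data.frame(
    compound = rep(cells$compound, each = n_replicates),
    system = rep(cells$system, each = n_replicates),
    replicate = rep.int(seq_len(n_replicates), nrow(cells)),
    t_r = rep(t_true, each = n_replicates),
    t_0 = t_0, t_m = t_m, stringsAsFactors = FALSE)
  if (noise_sd > 0) {
    rec$t_r <- rec$t_r + with_seed(seed, rnorm(nrow(rec), 0, noise_sd))
  }
  margin <- 1e-9 * (t_m - t_0)
  clipped <- rec$t_r <= t_0 | rec$t_r >= t_m
  if (any(clipped)) {
    warning(sum(clipped), " simulated time(s) clipped into (t_0, t_m)",
            call. = FALSE)
    rec$t_r <- pmin(pmax(rec$t_r, t_0 + margin), t_m - margin)
  }
  rec
}

#' Simulate a solvation-energy panel with planted linear calibrations
#'
#' For each calibration row (micelle, solvent, slope, intercept), generates
#' solvent/water logP values consistent with the planted linear relation
#' `y_micelle = slope * x_solvent + intercept` plus Gaussian residuals on
#' `x`, then converts them to a solvation-free-energy table: a random water
#' column and, per solvent, `dG_solv = dG_wat + ddG` with
#' `ddG = -x * RT ln 10`. Fitting [fit_calibration()] on
#' `logp_matrix(result)` against `truth` recovers the planted coefficients
#' up to sampling error (exactly at `residual_sd = 0`).
#'
#' @param truth True micellar logP matrix (compounds x systems).
#' @param calibration Data frame with columns `micelle`, `solvent`,
#'   `slope`, `intercept`, and optionally `residual_sd` (overriding the
#'   global `residual_sd` per row). Slopes must be nonzero, solvents
#'   unique.
#' @param residual_sd Gaussian residual standard deviation on the solvent
#'   logP scale.
#' @param temperature Temperature (K) for the energy conversion.
#' @param dg_wat_range Interval (kcal/mol) the water solvation energies are
#'   drawn from.
#' @param seed Integer RNG seed.
#' @return Numeric matrix (compounds x solvents) of solvation free energies
#'   in kcal/mol, including a `water` column.
#' @export
simulate_solvation <- function(truth, calibration, residual_sd = 0.5,
                               temperature = 298.15,
                               dg_wat_range = c(-15, -2), seed = 1L) {
  stopifnot(is.matrix(truth), is.data.frame(calibration),
            all(c("micelle", "solvent", "slope", "intercept") %in%
                  names(calibration)),
            residual_sd >= 0)
  if (any(calibration$slope == 0)) stop("planted slopes must be nonzero",
                                        call. = FALSE)
  if (anyDuplicated(calibration$solvent)) {
    stop("solvent names in calibration must be unique", call. = FALSE)
  }
  unknown <- setdiff(calibration$micelle, colnames(truth))
  if (length(unknown)) {
    stop("calibration references unknown micelle(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(truth)
  sds <- calibration$residual_sd %||% rep(residual_sd, nrow(calibration))
  sds[is.na(sds)] <- residual_sd
  with_seed(seed, {
    dg_wat <- runif(n, dg_wat_range[1L], dg_wat_range[2L])
    dg <- matrix(NA_real_, n, nrow(calibration) + 1L,
                 dimnames = list(rownames(truth),
                                 c("water", calibration$solvent)))
    dg[, "water"] <- dg_wat
    for (j in seq_len(nrow(calibration))) {
      y <- truth[, calibration$micelle[j]]
      x <- (y - calibration$intercept[j]) / calibration$slope[j] +
        rnorm(n, 0, sds[j])
      dg[, calibration$solvent[j]] <- dg_wat +
        (-x * rt_ln10(temperature))
    }
    dg
  })
}

#' Simulate a descriptor matrix with planted cluster structure
#'
#' Draws isotropic Gaussian blobs (unit within-cluster standard deviation
#' per dimension) around centers placed at pairwise Euclidean distance
#' `separation`, then shuffles row order. The default sizes (45, 13, 5)
#' mirror the three-group structure of the bundled 63-compound dataset.
#'
#' @param sizes Integer vector of cluster sizes.
#' @param p Number of descriptor dimensions.
#' @param separation Pairwise distance between cluster centers, in units of
#'   the within-cluster standard deviation; 0 plants no structure.
#' @param seed Integer RNG seed.
#' @param shuffle Shuffle row order (labels stay aligned).
#' @return List with `values` (n x p matrix) and `labels` (integer vector
#'   of planted cluster memberships, aligned with rows).
#' @export
simulate_descriptors <- function(sizes = c(45L, 13L, 5L), p = 85L,
                                 separation = 10, seed = 1L, shuffle = TRUE) {
  stopifnot(all(sizes >= 1L), p >= length(sizes), separation >= 0)
  k <- length(sizes); n <- sum(sizes)
  with_seed(seed, {
    # random orthonormal directions; centers at separation/sqrt(2) along each
    # give exact pairwise center distance = separation
    q <- qr.Q(qr(matrix(rnorm(p * k), p, k)))
    centers <- t(q) * separation / sqrt(2)
    labels <- rep.int(seq_len(k), sizes)
    values <- centers[labels, , drop = FALSE] + matrix(rnorm(n * p), n, p)
    if (shuffle) {
      ord <- sample.int(n)
      values <- values[ord, , drop = FALSE]
      labels <- labels[ord]
    }
    dimnames(values) <- list(sprintf("cpd%03d", seq_len(n)),
                             sprintf("D%03d", seq_len(p)))
    list(values = values, labels = labels)
  })
}
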