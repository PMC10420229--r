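# Surrogate-solvent identification: pairwise Pearson correlation of logP
# columns, the aromatic-nitrogen / urea exclusion filter, and micelle-vs-
# solvent linear calibrations with error metrics.

#' Pairwise Pearson correlation of partition-table columns
#'
#' Computes the Pearson correlation between every pair of logP columns
#' across one or more partition tables sharing a compound index, on
#' pairwise-complete observations. Cells supported by fewer than
#' `min_pairs` complete pairs are reported missing, as are pairs involving
#' a zero-variance column (with a warning). Column order follows the input
#' tables, so passing the experimental table first keeps the micellar
#' columns first.
#'
#' @param ... One or more numeric matrices with identical compound row
#'   names (e.g. [experimental_logp_table()] and a [logp_matrix()]).
#' @param min_pairs Minimum number of complete pairs for a reported
#'   coefficient (>= 2).
#' @return An object of class `correlation_matrix`: list with `labels`,
#'   symmetric matrix `r`, and integer matrix `n_pairs`.
#' @export
correlation_matrix <- function(..., min_pairs = 3L) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1L]]) && !is.matrix(tables[[1L]])) {
    tables <- tables[[1L]]
  }
  stopifnot(length(tables) >= 1L, min_pairs >= 2L)
  ref <- rownames(tables[[1L]])
  for (tab in tables) {
    stopifnot(is.matrix(tab), is.numeric(tab))
    if (!identical(sort(rownames(tab)), sort(ref))) {
      stop("all tables must share the same compound index", call. = FALSE)
    }
  }
  m <- do.call(cbind, lapply(tables, function(tab) tab[ref, , drop = FALSE]))
  if (anyDuplicated(colnames(m))) {
    stop("duplicate column labels across tables", call. = FALSE)
  }
  zero_var <- apply(m, 2L, function(x) {
    x <- x[!is.na(x)]
    length(x) >= 2L && var(x) == 0
  })
  if (any(zero_var)) {
    warning("zero-variance column(s): ",
            paste(colnames(m)[zero_var], collapse = ", "),
            "; their correlations are reported missing", call. = FALSE)
  }
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  n_pairs <- crossprod(!is.na(m))
  r[n_pairs < min_pairs] <- NA_real_
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  structure(list(labels = colnames(m), r = r,
                 n_pairs = matrix(as.integer(n_pairs), nrow(n_pairs),
                                  dimnames = dimnames(n_pairs))),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<correlation_matrix> %d columns (min n_pairs = %d)\n",
              length(x$labels), min(x$n_pairs)))
  print(round(x$r, digits))
  invisible(x)
}

#' Rank candidate surrogate solvents for a micelle
#'
#' Orders the non-micellar columns of a [correlation_matrix()] by
#' descending Pearson correlation with the chosen micellar column; ties are
#' broken alphabetically. Columns without a reported coefficient are
#' dropped.
#'
#' @param cm A `correlation_matrix`.
#' @param micelle Label of the micellar column, e.g. `"logP_SC"`.
#' @param exclude Labels that are not surrogate candidates (default: every
#'   label not containing `"/"`, i.e. the experimental micellar columns,
#'   following the `"<solvent>/water"` naming of [logp_matrix()]).
#' @return Data frame with columns `solvent` and `r`, best surrogate first.
#' @export
rank_surrogates <- function(cm, micelle, exclude = NULL) {
  stopifnot(inherits(cm, "correlation_matrix"))
  if (!micelle %in% cm$labels) {
    stop("unknown column label: ", micelle, call. = FALSE)
  }
  if (is.null(exclude)) exclude <- cm$labels[!grepl("/", cm$labels, fixed = TRUE)]
  candidates <- setdiff(cm$labels, union(micelle, exclude))
  if (!length(candidates)) stop("no surrogate candidate columns", call. = FALSE)
  rv <- cm$r[micelle, candidates]
  keep <- !is.na(rv)
  candidates <- candidates[keep]; rv <- rv[keep]
  ord <- order(-rv, candidates)
  data.frame(solvent = candidates[ord], r = unname(rv[ord]),
             stringsAsFactors = FALSE)
}

#' Exclude aromatic-ring-nitrogen and urea compounds (the "N set")
#'
#' Partitions a compound set into retained and excluded subsets. A compound
#' is excluded iff it contains a nitrogen atom inside an aromatic ring
#' (SMARTS `[n]`, under OpenBabel aromaticity perception) or the urea
#' (carbamide) substructure (SMARTS `[NX3][CX3](=O)[NX3]`). These compounds
#' partition anomalously in HTAB micelles; amides with a single flanking
#' nitrogen (benzamide, acetanilide) and anilines are retained.
#'
#' @param compounds A `compound_set` data frame (columns `name`, `smiles`),
#'   e.g. from [load_compound_table()].
#' @param patterns Named character vector of SMARTS patterns; matching any
#'   pattern excludes the compound, and the matched names are recorded as
#'   reasons.
#' @return An object of class `nset_filter`: list with `retained` and
#'   `excluded` (both `compound_set`) and `reasons`, a character vector
#'   named by compound ("" for retained ones).
#' @examples
#' \donttest{
#' fr <- nset_filter(experimental_compounds())
#' nrow(fr$excluded)
#' }
#' @export
nset_filter <- function(compounds,
                        patterns = c("aromatic nitrogen" = "[n]",
                                     "urea group" = "[NX3][CX3](=O)[NX3]")) {
  stopifnot(is.data.frame(compounds), all(c("name", "smiles") %in% names(compounds)),
            length(patterns) >= 1L, !is.null(names(patterns)))
  sdf <- parse_compounds(compounds$smiles, compounds$name)
  hits <- vapply(patterns, function(p) {
    ChemmineR::smartsSearchOB(sdf, p, uniqueMatches = FALSE) > 0L
  }, logical(nrow(compounds)))
  hits <- matrix(hits, nrow = nrow(compounds),
                 dimnames = list(compounds$name, names(patterns)))
  reasons <- apply(hits, 1L, function(h) paste(names(patterns)[h], collapse = "; "))
  excluded <- rowSums(hits) > 0L
  out <- list(
    retained = compounds[!excluded, , drop = FALSE],
    excluded = compounds[excluded, , drop = FALSE],
    reasons = reasons
  )
  class(out$retained) <- class(out$excluded) <- c("compound_set", "data.frame")
  structure(out, class = "nset_filter")
}

#' @export
print.nset_filter <- function(x, ...) {
  cat(sprintf("<nset_filter> %d retained, %d excluded\n",
              nrow(x$retained), nrow(x$excluded)))
  if (nrow(x$excluded)) {
    r <- x$reasons[x$excluded$name]
    for (nm in names(r)) cat(sprintf("  - %s: %s\n", nm, r[[nm]]))
  }
  invisible(x)
}

#' Linear calibration of micellar logP against a surrogate-solvent logP
#'
#' Ordinary least squares of experimental micellar logP (`y`) on computed
#' solvent/water logP (`x`) after listwise deletion of incomplete pairs.
#' Reports slope, intercept, the squared Pearson correlation as R-squared,
#' and MAE/MSE/RMSE of the fit residuals, plus a 95 percent confidence
#' interval for the slope.
#'
#' @param x Numeric vector of predictor logP values.
#' @param y Numeric vector of micellar logP values, same length.
#' @param micelle,solvent Optional labels stored with the model.
#' @return An object of class `calibration_model`.
#' @examples
#' m <- fit_calibration(1:10, 0.5 * (1:10) + 1)
#' m$slope
#' @export
fit_calibration <- function(x, y, micelle = NA_character_, solvent = NA_character_) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    stop("insufficient data: need >= 3 complete (x, y) pairs, have ", n,
         call. = FALSE)
  }
  if (var(x) == 0) stop("degenerate fit: zero variance in x", call. = FALSE)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2L]); intercept <- unname(coef(fit)[1L])
  slope_se <- suppressWarnings(summary(fit))$coefficients[2L, 2L]
  resid <- unname(fit$residuals)
  r <- suppressWarnings(cor(x, y))
  crit <- qt(0.975, df = n - 2L)
  structure(list(
    micelle = micelle, solvent = solvent,
    slope = slope, intercept = intercept,
    r2 = if (is.na(r)) 0 else r^2,
    mae = mean(abs(resid)), mse = mean(resid^2), rmse = sqrt(mean(resid^2)),
    n = n, slope_se = slope_se,
    slope_ci = c(lower = slope - crit * slope_se,
                 upper = slope + crit * slope_se)
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  lab <- if (!is.na(x$micelle)) sprintf(" %s ~ %s", x$micelle, x$solvent) else ""
  cat(sprintf("<calibration_model>%s: y = %.3fx + %.3f (R2 = %.3f, MAE = %.3f, n = %d)\n",
              lab, x$slope, x$intercept, x$r2, x$mae, x$n))
  invisible(x)
}

#' Predict micellar logP from a calibration model
#'
#' @param model A `calibration_model`.
#' @param x Solvent/water logP value(s).
#' @return Predicted micellar logP, `slope * x + intercept`.
#' @export
predict_micellar_logp <- function(model, x) {
  stopifnot(inherits(model, "calibration_model"))
  model$slope * x + model$intercept
}

#' @export
predict.calibration_model <- function(object, newdata, ...) {
  predict_micellar_logp(object, newdata)
}

#' Pick the micelle with the highest predicted logP
#'
#' Compares calibration models for several micellar systems at one
#' solvent/water logP value and returns the system whose predicted micellar
#' logP is largest, i.e. the micelle expected to carry the compound best.
#'
#' @param models List of `calibration_model` objects with `micelle` labels.
#' @param x A single solvent/water logP value.
#' @return Name of the winning micellar system.
#' @export
best_micelle_system <- function(models, x) {
  stopifnot(length(x) == 1L, length(models) >= 1L)
  preds <- vapply(models, predict_micellar_logp, numeric(1L), x = x)
  labels <- vapply(models, function(m) m$micelle, character(1L))
  labels[which.max(preds)]
}

#' Fit all micelle-vs-solvent calibrations
#'
#' Fits [fit_calibration()] for every (micellar column, solvent column)
#' pair of an experimental and a computed partition table sharing the
#' compound index, listwise-deleting missing pairs per fit.
#'
#' @param experimental Compounds x micelles logP matrix.
#' @param computed Compounds x solvent/water logP matrix.
#' @param min_n Pairs with fewer complete observations are skipped.
#' @return Data frame with one row per fitted pair: micelle, solvent,
#'   slope, intercept, r2, mae, mse, rmse, n.
#' @export
calibration_table <- function(experimental, computed, min_n = 3L) {
  stopifnot(is.matrix(experimental), is.matrix(computed))
  shared <- intersect(rownames(experimental), rownames(computed))
  if (!length(shared)) stop("no shared compounds", call. = FALSE)
  rows <- list()
  for (mic in colnames(experimental)) {
    for (solv in colnames(computed)) {
      y <- experimental[shared, mic]; x <- computed[shared, solv]
      if (sum(complete.cases(x, y)) < min_n) next
      m <- fit_calibration(x, y, micelle = mic, solvent = solv)
      rows[[length(rows) + 1L]] <- data.frame(
        micelle = mic, solvent = solv, slope = m$slope,
        intercept = m$intercept, r2 = m$r2, mae = m$mae, mse = m$mse,
        rmse = m$rmse, n = m$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Reference surrogate-solvent calibrations
#'
#' The bundled reference linear calibrations relating computed alcohol/water
#' logP values (B3LYP/SMD solvation energies) to experimental micellar logP
#' in SC, LPFOS, and HTAB, including the HTAB refits after N-set exclusion.
#' These coefficients are shipped as reference data, not recomputed: the
#' underlying quantum-chemistry energies are not redistributable.
#'
#' @return Data frame with columns `micelle`, `solvent`, `n_set_excluded`,
#'   `slope`, `intercept`, `r2`, `mae`.
#' @export
reference_calibrations <- function() {
  read.csv(extdata_path("micelle_surrogate_calibrations.csv"),
           stringsAsFactors = FALSE)
}

#' Reference calibration as a model object
#'
#' Convenience wrapper turning one row of [reference_calibrations()] into a
#' `calibration_model` usable with [predict_micellar_logp()].
#'
#' @param micelle,solvent Row selector.
#' @param n_set_excluded Whether to use the N-set-excluded refit.
#' @return A `calibration_model` (error metrics beyond r2/mae are `NA`).
#' @export
reference_calibration_model <- function(micelle, solvent,
                                        n_set_excluded = FALSE) {
  ref <- reference_calibrations()
  row <- ref[ref$micelle == micelle & ref$solvent == solvent &
               ref$n_set_excluded == n_set_excluded, ]
  if (nrow(row) != 1L) {
    stop("no reference calibration for ", micelle, " ~ ", solvent, call. = FALSE)
  }
  structure(list(micelle = row$micelle, solvent = row$solvent,
                 slope = row$slope, intercept = row$intercept, r2 = row$r2,
                 mae = row$mae, mse = NA_real_, rmse = NA_real_,
                 n = NA_integer_, slope_se = NA_real_,
                 slope_ci = c(lower = NA_real_, upper = NA_real_)),
            class = "calibration_model")
}
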