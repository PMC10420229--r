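# MEKC retention model: migration times -> retention factor -> micelle-water
# partition coefficient, in both directions.
#
# Forward relations:
#   k = (t_R - t_0) / (t_0 (1 - t_R / t_m))
#   k = P phi / (1 - phi),   phi = v (C_T - CMC)
# so logP = log10(k) + log10((1 - phi) / phi).

#' Retention factor from migration times
#'
#' Computes the MEKC retention factor
#' \eqn{k = (t_R - t_0) / [t_0 (1 - t_R/t_m)]} from the analyte migration
#' time `t_r` and the electro-osmotic-flow and micellar marker times `t_0`
#' and `t_m` (methanol and phenyl-undecyl ketone in the bundled dataset).
#' `t_r = t_0` gives `k = 0` (unretained analyte); `t_r` must stay strictly
#' below `t_m`, where `k` diverges.
#'
#' @param t_r Analyte retention time (min). Vectorized; `t_0`/`t_m` recycle.
#' @param t_0 EOF marker time (min), > 0.
#' @param t_m Micellar marker time (min), > `t_0`.
#' @return Dimensionless retention factor(s), >= 0.
#' @examples
#' retention_factor(4, 2, 10)  # 1.6667
#' @export
retention_factor <- function(t_r, t_0, t_m) {
  n <- max(length(t_r), length(t_0), length(t_m))
  t_r <- rep_len(t_r, n); t_0 <- rep_len(t_0, n); t_m <- rep_len(t_m, n)
  if (any(!is.finite(t_0) | t_0 <= 0)) {
    stop("t_0 must be positive and finite", call. = FALSE)
  }
  if (any(t_m <= t_0)) stop("need t_m > t_0", call. = FALSE)
  if (any(t_r < t_0)) {
    stop("t_r < t_0: analyte cannot precede the EOF marker", call. = FALSE)
  }
  if (any(t_r >= t_m)) {
    stop("t_r >= t_m: analyte co-elutes with or after the micellar marker",
         call. = FALSE)
  }
  (t_r - t_0) / (t_0 * (1 - t_r / t_m))
}

#' Analyte migration time from a retention factor
#'
#' Inverse of [retention_factor()]:
#' \eqn{t_R = t_0 (1 + k) / (1 + k\, t_0/t_m)}, used by the synthetic
#' retention generator. Satisfies `t_0 <= t_r < t_m`, approaching `t_m`
#' from below as `k` grows.
#'
#' @param k Retention factor(s), >= 0.
#' @inheritParams retention_factor
#' @return Migration time(s) in the units of `t_0`/`t_m`.
#' @export
retention_time_from_factor <- function(k, t_0, t_m) {
  if (any(!is.finite(k) | k < 0)) stop("k must be finite and >= 0", call. = FALSE)
  if (any(t_0 <= 0) || any(t_m <= t_0)) stop("need 0 < t_0 < t_m", call. = FALSE)
  t_0 * (1 + k) / (1 + k * t_0 / t_m)
}

#' Micelle-water logP from a retention factor
#'
#' Applies the phase-ratio relation \eqn{k = P \phi / (1 - \phi)} with
#' \eqn{\phi = \upsilon (C_T - CMC)}, i.e.
#' \eqn{\log P = \log_{10} k + \log_{10}[(1-\phi)/\phi]}.
#'
#' @param k Retention factor(s), > 0.
#' @param sys A [micelle_system()].
#' @return log10 micelle-water partition coefficient(s).
#' @examples
#' logp_from_retention(39.85, micelle_registry()$SC)
#' @export
logp_from_retention <- function(k, sys) {
  phi <- phase_ratio(sys)
  if (any(!is.finite(k) | k <= 0)) {
    stop("k must be positive to define a finite logP", call. = FALSE)
  }
  log10(k) + log10((1 - phi) / phi)
}

#' Retention factor implied by a micelle-water logP
#'
#' Exact inverse of [logp_from_retention()]:
#' \eqn{k = 10^{\log P} \phi / (1 - \phi)}.
#'
#' @param logp log10 partition coefficient(s).
#' @param sys A [micelle_system()].
#' @return Retention factor(s), > 0.
#' @export
retention_factor_from_logp <- function(logp, sys) {
  phi <- phase_ratio(sys)
  if (any(!is.finite(logp))) stop("logp must be finite", call. = FALSE)
  10^logp * phi / (1 - phi)
}

#' Convert retention records to a partition table
#'
#' Converts a long table of MEKC retention records into a compounds x
#' systems matrix of micelle-water logP values. Replicates of the same
#' (compound, system) pair are averaged on the logP scale and their
#' standard deviation reported. Records at the domain boundary (`t_r = t_0`,
#' giving `k = 0`, or `t_r >= t_m`) cannot yield a finite logP; they are
#' dropped with a warning, and a pair with no usable replicate is reported
#' missing.
#'
#' @param records Data frame with columns `compound`, `system`, `t_r`,
#'   `t_0`, `t_m` (one row per replicate injection).
#' @param registry Named list of [micelle_system()] objects; every value of
#'   `records$system` must be present.
#' @return A list of class `partition_conversion` with matrices `logp`
#'   (replicate means), `sd` (replicate standard deviations; `NA` for a
#'   single replicate), and `n` (usable replicate counts). Rows follow
#'   first appearance in `records`; columns follow registry order.
#' @export
convert_retention_table <- function(records, registry = micelle_registry()) {
  required <- c("compound", "system", "t_r", "t_0", "t_m")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("retention records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(records$system), names(registry))
  if (length(unknown)) {
    stop("unknown micellar system(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  compounds <- unique(records$compound)
  systems <- intersect(names(registry), unique(records$system))

  usable <- records$t_0 > 0 & records$t_r > records$t_0 & records$t_r < records$t_m
  n_bad <- sum(!usable)
  if (n_bad > 0) {
    warning(n_bad, " retention record(s) at or outside the (t_0, t_m) domain",
            " were dropped (no finite logP)", call. = FALSE)
  }

  logp_rec <- rep(NA_real_, nrow(records))
  for (s in systems) {
    idx <- which(usable & records$system == s)
    if (!length(idx)) next
    k <- retention_factor(records$t_r[idx], records$t_0[idx], records$t_m[idx])
    logp_rec[idx] <- logp_from_retention(k, registry[[s]])
  }

  dims <- list(compounds, systems)
  mean_m <- matrix(NA_real_, length(compounds), length(systems), dimnames = dims)
  sd_m <- mean_m
  n_m <- matrix(0L, length(compounds), length(systems), dimnames = dims)
  grp <- interaction(factor(records$compound, compounds),
                     factor(records$system, systems), drop = FALSE)
  for (cell in split(which(usable), grp[usable])) {
    if (!length(cell)) next
    i <- records$compound[cell[1L]]; j <- records$system[cell[1L]]
    v <- logp_rec[cell]
    mean_m[i, j] <- mean(v)
    sd_m[i, j] <- if (length(v) > 1L) sd(v) else NA_real_
    n_m[i, j] <- length(v)
  }
  structure(list(logp = mean_m, sd = sd_m, n = n_m),
            class = "partition_conversion")
}

#' @export
print.partition_conversion <- function(x, ...) {
  cat(sprintf("<partition_conversion> %d compounds x %d systems (%d missing cells)\n",
              nrow(x$logp), ncol(x$logp), sum(is.na(x$logp))))
  invisible(x)
}
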