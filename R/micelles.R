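#' Define a micellar pseudo-stationary phase
#'
#' A micellar system is described by the surfactant constants that enter the
#' MEKC phase-ratio relation: the total surfactant concentration `c_total`,
#' the critical micellar concentration `cmc` (only surfactant above the CMC
#' forms micelles), and the partial molar volume `molar_volume` of the
#' micellized surfactant. The phase ratio is
#' \eqn{\phi = \upsilon (C_T - CMC)}, the volume fraction of the micellar
#' pseudo-phase, and must lie strictly inside (0, 1).
#'
#' @param name System label, e.g. `"SC"`.
#' @param c_total Total surfactant concentration (mol/L, or mmol/L when
#'   `units = "millimolar"`).
#' @param cmc Critical micellar concentration, same units as `c_total`.
#' @param molar_volume Partial molar volume of micellized surfactant (L/mol).
#' @param units Concentration units of `c_total` and `cmc`; concentrations
#'   are stored in mol/L.
#' @return An object of class `micelle_system`.
#' @examples
#' sc <- micelle_system("SC", c_total = 0.080, cmc = 0.0124, molar_volume = 0.317)
#' phase_ratio(sc)
#' @seealso [micelle_registry()], [phase_ratio()]
#' @export
micelle_system <- function(name, c_total, cmc, molar_volume,
                           units = c("molar", "millimolar")) {
  units <- match.arg(units)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (units == "millimolar") {
    c_total <- c_total / 1000
    cmc <- cmc / 1000
  }
  if (!is.finite(c_total) || !is.finite(cmc) || !is.finite(molar_volume)) {
    stop("micelle system '", name, "': constants must be finite", call. = FALSE)
  }
  if (cmc < 0 || c_total <= cmc) {
    stop("micelle system '", name, "': need c_total > cmc >= 0", call. = FALSE)
  }
  phi <- molar_volume * (c_total - cmc)
  if (phi <= 0 || phi >= 1) {
    stop("micelle system '", name, "': phase ratio ", signif(phi, 6),
         " outside (0, 1)", call. = FALSE)
  }
  structure(
    list(name = name, c_total = c_total, cmc = cmc,
         molar_volume = molar_volume),
    class = "micelle_system"
  )
}

#' @export
print.micelle_system <- function(x, ...) {
  cat(sprintf(
    "<micelle_system> %s: C_T = %g M, CMC = %g M, v = %g L/mol (phi = %.6g)\n",
    x$name, x$c_total, x$cmc, x$molar_volume, phase_ratio(x)))
  invisible(x)
}

#' Phase ratio of a micellar system
#'
#' @param sys A [micelle_system()].
#' @return The micellar phase ratio \eqn{\phi = \upsilon (C_T - CMC)}
#'   (dimensionless volume fraction).
#' @export
phase_ratio <- function(sys) {
  stopifnot(inherits(sys, "micelle_system"))
  sys$molar_volume * (sys$c_total - sys$cmc)
}

#' Registry of micellar systems
#'
#' Returns the three buffered micellar systems of the bundled experimental
#' dataset (pH 7, 20 mM phosphate, 25 degrees C): 80 mM sodium cholate (SC,
#' CMC 12.4 mM, v = 0.317 L/mol), 40 mM lithium perfluorooctanesulfonate
#' (LPFOS, CMC 3.27 mM, v = 0.285 L/mol), and 20 mM
#' hexadecyltrimethylammonium bromide (HTAB, CMC 0.34 mM, v = 0.324 L/mol).
#'
#' @param extra Optional list of additional [micelle_system()] objects,
#'   appended to (or overriding, by name) the default three.
#' @return A named list of `micelle_system` objects.
#' @examples
#' reg <- micelle_registry()
#' reg$SC$cmc
#' @export
micelle_registry <- function(extra = NULL) {
  reg <- list(
    SC    = micelle_system("SC",    c_total = 0.080, cmc = 0.01240, molar_volume = 0.317),
    LPFOS = micelle_system("LPFOS", c_total = 0.040, cmc = 0.00327, molar_volume = 0.285),
    HTAB  = micelle_system("HTAB",  c_total = 0.020, cmc = 0.00034, molar_volume = 0.324)
  )
  if (!is.null(extra)) {
    stopifnot(is.list(extra))
    for (sys in extra) {
      stopifnot(inherits(sys, "micelle_system"))
      reg[[sys$name]] <- sys
    }
  }
  reg
}
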