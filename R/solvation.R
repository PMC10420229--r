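# Solvation free energies -> solvent/water partition coefficients.
#
# The transfer free energy of a solute from water into a bulk solvent is
#   ddG = dG_solv - dG_wat            (kcal/mol)
# and the corresponding partition coefficient
#   logP = -ddG / (R T ln 10),
# with R = 1.98720e-3 kcal/(mol K). At T = 298.15 K, RT ln10 = 1.36425
# kcal/mol, so -1.36425 kcal/mol of transfer free energy is one log unit in
# favor of the solvent.

#' Molar gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.98720e-3

# RT ln 10 in kcal/mol.
rt_ln10 <- function(temperature = 298.15, r_gas = R_KCAL) {
  stopifnot(temperature > 0, r_gas > 0)
  r_gas * temperature * log(10)
}

#' Water-to-solvent transfer free energy
#'
#' @param dg_solv Solvation free energy in the bulk solvent (kcal/mol).
#' @param dg_wat Solvation free energy in water (kcal/mol).
#' @return `dg_solv - dg_wat` (kcal/mol); `NA` propagates.
#' @export
transfer_energy <- function(dg_solv, dg_wat) {
  dg_solv - dg_wat
}

#' Solvent/water logP from a transfer free energy
#'
#' @param ddg Transfer free energy (kcal/mol), negative when the solvent is
#'   preferred over water.
#' @param temperature Temperature in K.
#' @param r_gas Molar gas constant in kcal/(mol K).
#' @return Dimensionless log10 partition coefficient; linear in `ddg`.
#' @examples
#' logp_from_transfer(-1.36425)  # 1 log unit at 298.15 K
#' @export
logp_from_transfer <- function(ddg, temperature = 298.15, r_gas = R_KCAL) {
  -ddg / rt_ln10(temperature, r_gas)
}

#' Read a wide solvation-free-energy table
#'
#' First CSV column is the compound name; every other column is one solvent
#' (a `water` column must be present exactly once). Energies are kcal/mol by
#' default; `units = "kJ"` divides by 4.184 on input.
#'
#' @param path CSV path.
#' @param units Input energy units.
#' @return Numeric matrix (compounds x solvents) in kcal/mol.
#' @export
read_solvation_table <- function(path, units = c("kcal", "kJ")) {
  units <- match.arg(units)
  tab <- load_partition_table(path)  # same wide-CSV grammar, NA for missing
  check_water_column(colnames(tab))
  if (units == "kJ") tab <- tab / 4.184
  tab
}

check_water_column <- function(solvents) {
  n_water <- sum(tolower(solvents) == "water")
  if (n_water != 1L) {
    stop("solvation table must contain exactly one 'water' column (found ",
         n_water, ")", call. = FALSE)
  }
  invisible(solvents[tolower(solvents) == "water"])
}

#' Solvent/water logP matrix from a solvation table
#'
#' Subtracts the water column from every other solvent column and converts
#' the transfer free energies to log10 partition coefficients. Output
#' columns are named `"<solvent>/water"`; an entry is missing wherever
#' either free energy is missing.
#'
#' @param tab Numeric matrix (compounds x solvents, kcal/mol) containing a
#'   `water` column, e.g. from [read_solvation_table()].
#' @param temperature Temperature in K.
#' @param r_gas Molar gas constant in kcal/(mol K).
#' @return Numeric matrix (compounds x solvent/water pairs) of logP values.
#' @export
logp_matrix <- function(tab, temperature = 298.15, r_gas = R_KCAL) {
  stopifnot(is.matrix(tab), is.numeric(tab))
  water <- check_water_column(colnames(tab))
  solvents <- setdiff(colnames(tab), water)
  if (!length(solvents)) {
    stop("solvation table has no non-water solvent column", call. = FALSE)
  }
  out <- sapply(solvents, function(s) {
    logp_from_transfer(transfer_energy(tab[, s], tab[, water]),
                       temperature, r_gas)
  })
  out <- matrix(out, nrow = nrow(tab),
                dimnames = list(rownames(tab), paste0(solvents, "/water")))
  out
}
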