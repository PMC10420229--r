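# Partition tables: compounds x systems logP matrices with explicit missing
# values, stored as RFC-4180 CSV with "-" (or empty) marking missing cells.

#' Load a partition table
#'
#' Reads a CSV whose first column holds compound names and whose remaining
#' columns hold log10 partition coefficients, one column per micellar system
#' or solvent/water pair. Cells containing `"-"` or nothing are loaded as
#' `NA` (missing, never imputed); any other non-numeric cell is an error
#' reporting its coordinates.
#'
#' @param path Path to a CSV file.
#' @param missing_markers Character values interpreted as missing.
#' @return A numeric matrix (compounds x systems) with compound row names;
#'   missing entries are `NA`.
#' @examples
#' tab <- experimental_logp_table()
#' tab["Butylbenzene", ]
#' @export
load_partition_table <- function(path, missing_markers = c("-", "")) {
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = "character"),
    error = function(e) stop("cannot read partition table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2L) {
    stop("partition table '", path,
         "' needs a compound column plus at least one system column",
         call. = FALSE)
  }
  compounds <- trimws(df[[1L]])
  if (anyDuplicated(compounds)) {
    stop("duplicate compound name(s) in partition table: ",
         paste(unique(compounds[duplicated(compounds)]), collapse = ", "),
         call. = FALSE)
  }
  systems <- names(df)[-1L]
  values <- matrix(NA_real_, nrow(df), length(systems),
                   dimnames = list(compounds, systems))
  for (j in seq_along(systems)) {
    cell <- trimws(df[[j + 1L]])
    is_missing <- cell %in% missing_markers | is.na(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_missing & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf(
        "partition table '%s': cell (%s, %s) = '%s' is neither numeric nor a missing marker",
        path, compounds[i], systems[j], cell[i]), call. = FALSE)
    }
    values[, j] <- ifelse(is_missing, NA_real_, num)
  }
  values
}

#' Write a partition table
#'
#' Inverse of [load_partition_table()]: numeric cells are written with
#' shortest round-trip representation, missing cells as `missing_marker`,
#' so that load-write-load reproduces all values bit-exactly.
#'
#' @param tab Numeric matrix with compound row names.
#' @param path Output CSV path.
#' @param missing_marker String written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_partition_table <- function(tab, path, missing_marker = "-") {
  stopifnot(is.matrix(tab), is.numeric(tab), !is.null(rownames(tab)),
            !is.null(colnames(tab)))
  df <- data.frame(compound = rownames(tab), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in colnames(tab)) {
    cell <- as.character(tab[, j])  # shortest round-trip doubles (R >= 4.3)
    cell[is.na(tab[, j])] <- missing_marker
    df[[j]] <- cell
  }
  write.csv(df, path, row.names = FALSE, quote = 1L)
  invisible(path)
}

#' Bundled experimental micellar partition table
#'
#' The experimental micelle-water log10 partition coefficients of 63
#' compounds in SC, HTAB, and LPFOS micelles, determined from MEKC retention
#' factors (80 mM SC / 20 mM HTAB / 40 mM LPFOS in 20 mM phosphate buffer,
#' pH 7, 25 degrees C). Five compounds lack an HTAB value; those cells are
#' `NA`.
#'
#' @return A 63 x 3 numeric matrix with columns `logP_SC`, `logP_HTAB`,
#'   `logP_LPFOS`.
#' @export
experimental_logp_table <- function() {
  load_partition_table(extdata_path("micellar_logp_experimental.csv"))
}
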