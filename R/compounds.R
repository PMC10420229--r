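# Compound tables: loading, SMILES validation, bundled fixtures.

# Parse a vector of SMILES into an SDFset, identifying offending rows on
# failure. OpenBabel reports parse problems on stderr; we convert them into
# row-level validation errors.
parse_compounds <- function(smiles, names) {
  stopifnot(length(smiles) == length(names))
  res <- try(suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, names))),
             silent = TRUE)
  # a failed parse either errors or silently drops molecules from the set
  if (!inherits(res, "try-error") && length(res) == length(smiles) &&
      all(ChemmineR::validSDF(res))) {
    return(res)
  }
  bad <- vapply(smiles, function(s) {
    one <- try(suppressWarnings(ChemmineR::smiles2sdf(s)), silent = TRUE)
    inherits(one, "try-error") || length(one) != 1L ||
      !all(ChemmineR::validSDF(one))
  }, logical(1))
  stop("unparsable SMILES for compound(s): ",
       paste(sprintf("'%s' (row %d)", names[bad], which(bad)), collapse = ", "),
       call. = FALSE)
}

#' Load and validate a compound table
#'
#' Reads a CSV with columns `name` and `smiles` (plus an optional free-text
#' `tags` column), validates that names are unique (case-insensitively) and
#' that every SMILES parses to a valid molecule, and returns the table in
#' file order.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of class `compound_set` with columns `name`,
#'   `smiles`, and `tags`, in input-file order.
#' @examples
#' cs <- experimental_compounds()
#' nrow(cs)
#' @export
load_compound_table <- function(path) {
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot read compound table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  required <- c("name", "smiles")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("compound table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) stop("compound table '", path, "' has no rows", call. = FALSE)
  dup <- duplicated(tolower(df$name))
  if (any(dup)) {
    stop("duplicate compound name(s): ",
         paste(unique(df$name[dup]), collapse = ", "), call. = FALSE)
  }
  parse_compounds(df$smiles, df$name)  # errors name the offending rows
  if (is.null(df$tags)) df$tags <- ""
  out <- df[, c("name", "smiles", "tags")]
  class(out) <- c("compound_set", "data.frame")
  out
}

#' Bundled structures for the 63 experimental compounds
#'
#' SMILES for the compounds of the bundled experimental partition table,
#' curated by name from the primary literature on each structure. Tags give
#' a coarse chemical class (pesticide, hormone, phenol, ...).
#'
#' @return A `compound_set` data frame (see [load_compound_table()]).
#' @export
experimental_compounds <- function() {
  load_compound_table(extdata_path("compound_smiles.csv"))
}
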