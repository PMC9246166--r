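#' Coerce and validate a sample-by-compound concentration matrix
#'
#' The concentration container used by every downstream stage is a plain
#' numeric matrix (rows = soil samples, columns = the 16 priority PAHs in
#' catalog order, units ng g\eqn{^{-1}}) with row names as sample ids.  An
#' optional logical attribute \code{"below_mdl"} of the same shape marks
#' cells that were substituted at the detection limit.
#'
#' @param x numeric matrix or data.frame with the 16 compound abbreviations
#'   as column names (any order; reordered to catalog order).
#' @param catalog a \code{pah_catalog}; defines the canonical column order.
#' @return Validated numeric matrix, columns in catalog order.
#' @export
as_concentration_matrix <- function(x, catalog = default_catalog()) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("'x' must be a matrix or data.frame")
  missing_cols <- setdiff(catalog$abbreviation, colnames(x))
  if (length(missing_cols)) {
    stop("missing compound column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- x[, catalog$abbreviation, drop = FALSE]
  storage.mode(x) <- "double"
  if (nrow(x) < 1L) stop("concentration matrix needs at least one sample")
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid concentration at row %s, column %s (%s)",
                 bad[1L, 1L], bad[1L, 2L], colnames(x)[bad[1L, 2L]]))
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  x
}

#' Read a concentration table from CSV
#'
#' Expects a header row naming the 16 compound abbreviations (an optional
#' \code{sample_id} column supplies row names) and one row per soil sample.
#' Columns may appear in any order; they are reordered to catalog order.
#' Negative or non-numeric cells are rejected with the offending position.
#'
#' @inheritParams as_concentration_matrix
#' @param path CSV path (UTF-8, comma-separated, decimal point).
#' @return Concentration matrix, ng g\eqn{^{-1}} (see
#'   [as_concentration_matrix()]).
#' @export
read_concentration_table <- function(path, catalog = default_catalog()) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- if ("sample_id" %in% names(tab)) {
    as.character(tab[["sample_id"]])
  } else {
    paste0("sample_", seq_len(nrow(tab)))
  }
  tab <- tab[, setdiff(names(tab), "sample_id"), drop = FALSE]
  missing_cols <- setdiff(catalog$abbreviation, names(tab))
  if (length(missing_cols)) {
    stop("concentration CSV is missing compound column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, catalog$abbreviation, drop = FALSE]
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      stop("non-numeric value in column ", names(tab)[j])
    }
  }
  m <- as.matrix(tab)
  rownames(m) <- ids
  as_concentration_matrix(m, catalog)
}

#' Write a concentration matrix to CSV
#'
#' Inverse of [read_concentration_table()]; writes a \code{sample_id} column
#' followed by the 16 compound columns in catalog order.
#'
#' @param x concentration matrix.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_concentration_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Substitute censored values at half the detection limit
#'
#' Standard receptor-model pre-treatment: concentrations below the method
#' detection limit (MDL) are replaced by MDL/2 and flagged; values at or
#' above the MDL pass through unchanged.  Flags are stored in the
#' \code{"below_mdl"} attribute and respected by [build_uncertainty()].
#'
#' @param x concentration matrix (ng g\eqn{^{-1}}).
#' @param catalog a \code{pah_catalog} supplying per-compound MDLs.
#' @return Concentration matrix with substituted values and a logical
#'   \code{"below_mdl"} attribute.
#' @export
substitute_below_mdl <- function(x, catalog = default_catalog()) {
  x <- as_concentration_matrix(x, catalog)
  mdl <- matrix(catalog$mdl, nrow = nrow(x), ncol = 16L, byrow = TRUE)
  flag <- x < mdl
  x[flag] <- mdl[flag] / 2
  dimnames(flag) <- dimnames(x)
  attr(x, "below_mdl") <- flag
  x
}
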