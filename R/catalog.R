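#' Compound catalog for the 16 US-EPA priority PAHs
#'
#' Builds the canonical compound table used throughout the package: the 16
#' priority polycyclic aromatic hydrocarbons in their conventional order, with
#' ring counts, toxic equivalency factors (TEFs, Nisbet & LaGoy scheme,
#' benzo[a]pyrene = 1), and per-compound method detection limits (MDL) and
#' error fractions used by the PMF uncertainty model.
#'
#' @param mdl numeric; default method detection limit, ng g\eqn{^{-1}}.
#'   Either length 1 (recycled) or length 16 in catalog order.
#' @param error_fraction numeric; default relative measurement uncertainty
#'   (dimensionless), length 1 or 16.
#'
#' @return A data.frame of class \code{pah_catalog} with columns
#'   \code{name}, \code{abbreviation}, \code{ring_count}, \code{tef},
#'   \code{mdl}, \code{error_fraction}; exactly 16 rows.
#' @examples
#' cat16 <- default_catalog()
#' cat16$abbreviation
#' @export
default_catalog <- function(mdl = 1.0, error_fraction = 0.1) {
  out <- data.frame(
    name = c("naphthalene", "acenaphthylene", "acenaphthene", "fluorene",
             "phenanthrene", "anthracene", "fluoranthene", "pyrene",
             "benz[a]anthracene", "chrysene", "benzo[b]fluoranthene",
             "benzo[k]fluoranthene", "benzo[a]pyrene",
             "indeno[1,2,3-cd]pyrene", "dibenzo[a,h]anthracene",
             "benzo[g,h,i]perylene"),
    abbreviation = c("Naph", "Acy", "Ace", "Flu", "Phe", "Ant", "Flt", "Pyr",
                     "BaA", "Chr", "BbF", "BkF", "BaP", "IND", "DBahA",
                     "BghiP"),
    ring_count = c(2L, 3L, 3L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 5L, 5L, 5L, 6L,
                   5L, 6L),
    tef = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.01, 0.001, 0.001, 0.1,
            0.01, 0.1, 0.1, 1, 0.1, 1, 0.01),
    stringsAsFactors = FALSE
  )
  out$mdl <- rep_len(as.numeric(mdl), 16L)
  out$error_fraction <- rep_len(as.numeric(error_fraction), 16L)
  class(out) <- c("pah_catalog", "data.frame")
  validate_catalog(out)
}

#' Read a compound catalog from CSV
#'
#' Reads per-compound overrides (TEF, MDL, error fraction) keyed by
#' abbreviation and merges them onto the default catalog.  Compounds absent
#' from the file keep their defaults.
#'
#' @param path path to a CSV with column \code{abbreviation} and any of
#'   \code{tef}, \code{mdl}, \code{error_fraction}.
#' @return A \code{pah_catalog} data.frame (see [default_catalog()]).
#' @export
read_catalog <- function(path) {
  stopifnot(file.exists(path))
  ov <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"abbreviation" %in% names(ov)) {
    stop("catalog CSV must have an 'abbreviation' column")
  }
  unknown <- setdiff(ov$abbreviation, default_catalog()$abbreviation)
  if (length(unknown)) {
    stop("unknown compound abbreviations: ", paste(unknown, collapse = ", "))
  }
  cat16 <- default_catalog()
  idx <- match(ov$abbreviation, cat16$abbreviation)
  for (col in intersect(c("tef", "mdl", "error_fraction"), names(ov))) {
    cat16[[col]][idx] <- as.numeric(ov[[col]])
  }
  validate_catalog(cat16)
}

validate_catalog <- function(catalog) {
  stopifnot(
    nrow(catalog) == 16L,
    !anyDuplicated(catalog$abbreviation),
    all(catalog$tef > 0),
    all(catalog$ring_count %in% 2:6),
    all(is.finite(catalog$mdl)), all(catalog$mdl > 0),
    all(is.finite(catalog$error_fraction)), all(catalog$error_fraction > 0)
  )
  catalog
}

# Low-molecular-weight (2-3 ring) abbreviations; LMW dominance flags
# petrogenic origin, HMW (4-6 ring) dominance pyrogenic origin.
lmw_abbreviations <- function(catalog = default_catalog()) {
  catalog$abbreviation[catalog$ring_count <= 3L]
}

hmw_abbreviations <- function(catalog = default_catalog()) {
  catalog$abbreviation[catalog$ring_count >= 4L]
}
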