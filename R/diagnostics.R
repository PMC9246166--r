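#' Isomer diagnostic ratios
#'
#' The three ratio definitions used for fast source screening of soil PAHs,
#' each of the form numerator / (numerator + partner) so values fall in
#' [0, 1]:
#' \describe{
#'   \item{\code{"BaA/(BaA+Chr)"}}{< 0.2 petroleum; 0.2-0.35 mixed
#'     petroleum/combustion; > 0.35 wood/coal combustion.}
#'   \item{\code{"Flt/(Flt+Pyr)"}}{< 0.4 petroleum; 0.4-0.5 petroleum
#'     combustion; > 0.5 biomass/coal combustion.}
#'   \item{\code{"Ant/(Ant+Phe)"}}{< 0.1 petrogenic; >= 0.1 combustion.}
#' }
#' Boundary values fall in the middle/mixed class where one exists,
#' otherwise in the lower class.
#'
#' @return Character vector of the ratio identifiers.
#' @export
diagnostic_ratio_ids <- function() {
  c("BaA/(BaA+Chr)", "Flt/(Flt+Pyr)", "Ant/(Ant+Phe)")
}

ratio_components <- function(ratio_id) {
  switch(ratio_id,
         "BaA/(BaA+Chr)" = c("BaA", "Chr"),
         "Flt/(Flt+Pyr)" = c("Flt", "Pyr"),
         "Ant/(Ant+Phe)" = c("Ant", "Phe"),
         stop("unknown ratio id: ", ratio_id))
}

#' Compute a diagnostic ratio for one sample
#'
#' @param sample named numeric vector of the 16 compound concentrations
#'   (names must include the two constituents), ng g\eqn{^{-1}}.
#' @param ratio_id one of [diagnostic_ratio_ids()].
#' @return Ratio in [0, 1], or \code{NA_real_} when both constituents are 0
#'   (undefined ratio; such samples are excluded from classification).
#' @examples
#' compute_ratio(c(Ant = 1, Phe = 9), "Ant/(Ant+Phe)")
#' @export
compute_ratio <- function(sample, ratio_id) {
  comp <- ratio_components(ratio_id)
  num <- sample[[comp[1L]]]
  partner <- sample[[comp[2L]]]
  if (!is.finite(num) || !is.finite(partner) || num < 0 || partner < 0) {
    stop("constituent concentrations must be finite and non-negative")
  }
  if (num + partner == 0) return(NA_real_)
  num / (num + partner)
}

#' Classify a diagnostic-ratio value into a source label
#'
#' @param ratio_id one of [diagnostic_ratio_ids()].
#' @param value ratio value in [0, 1].
#' @return Source label (character).
#' @examples
#' classify_ratio("Flt/(Flt+Pyr)", 0.6)
#' @export
classify_ratio <- function(ratio_id, value) {
  if (!is.finite(value) || value < 0 || value > 1) {
    stop("'value' must lie in [0, 1]")
  }
  switch(ratio_id,
         "BaA/(BaA+Chr)" = if (value < 0.2) "petroleum"
           else if (value <= 0.35) "mixed petroleum/combustion"
           else "wood/coal combustion",
         "Flt/(Flt+Pyr)" = if (value < 0.4) "petroleum"
           else if (value <= 0.5) "petroleum combustion"
           else "biomass/coal combustion",
         "Ant/(Ant+Phe)" = if (value < 0.1) "petrogenic" else "combustion",
         stop("unknown ratio id: ", ratio_id))
}

combustion_labels <- function() {
  c("wood/coal combustion", "petroleum combustion",
    "biomass/coal combustion", "combustion")
}

#' Ratio cross-plot table for a concentration matrix
#'
#' One record per sample with all three diagnostic ratios and their source
#' labels, the tabular form behind the usual isomer-ratio cross plots
#' (Flt/(Flt+Pyr) against Ant/(Ant+Phe) and against BaA/(BaA+Chr)).
#' Samples with an undefined (0/0) ratio get \code{NA} for that ratio and
#' label and are reported in the \code{"excluded"} attribute.
#'
#' @param x concentration matrix (see [as_concentration_matrix()]).
#' @return data.frame with columns \code{sample_id}, one ratio and one label
#'   column per diagnostic ratio.
#' @export
ratio_crossplot_table <- function(x) {
  if (!is.null(dim(x)) && nrow(x) == 0L) {
    out <- data.frame(sample_id = character(0), stringsAsFactors = FALSE)
    attr(out, "excluded") <- character(0)
    return(out)
  }
  x <- as_concentration_matrix(x)
  ids <- diagnostic_ratio_ids()
  out <- data.frame(sample_id = rownames(x), stringsAsFactors = FALSE)
  excluded <- character(0)
  for (rid in ids) {
    vals <- apply(x, 1L, compute_ratio, ratio_id = rid)
    labs <- rep(NA_character_, length(vals))
    ok <- !is.na(vals)
    labs[ok] <- vapply(vals[ok], classify_ratio, character(1),
                       ratio_id = rid)
    excluded <- union(excluded, rownames(x)[!ok])
    key <- gsub("[^A-Za-z]+", "_", rid)
    out[[paste0("ratio_", key)]] <- unname(vals)
    out[[paste0("label_", key)]] <- labs
  }
  attr(out, "excluded") <- excluded
  out
}
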