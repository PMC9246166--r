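#' Load the bundled literature study table
#'
#' Returns the package's compiled summary of soil-PAH burdens in urban,
#' suburban and rural soils of a large northern-Chinese conurbation:
#' 41 study records, each with a land-use type, a total concentration of the
#' 16 priority PAHs (ng g\eqn{^{-1}}), a benzo[a]pyrene-equivalent toxicity
#' (BaPeq, ng g\eqn{^{-1}}) and the contamination label printed in the source
#' compilation.  The table is integrity-checked on load: 41 rows split
#' 11 urban / 11 suburban / 19 rural, positive totals, non-negative BaPeq.
#'
#' @return A data.frame with columns \code{land_use} (factor: urban,
#'   suburban, rural), \code{description}, \code{total_pahs}, \code{bapeq},
#'   \code{sampling_depth}, \code{contamination_level} (ordered factor, see
#'   [contamination_levels()]) and \code{reference}.
#' @examples
#' tab <- load_study_table()
#' table(tab$land_use)
#' @export
load_study_table <- function() {
  path <- system.file("extdata", "table1.csv", package = "pmfteq",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("land_use", "description", "total_pahs", "bapeq",
              "sampling_depth", "contamination_level", "reference")
  if (!all(needed %in% names(tab))) {
    stop("study table fixture is corrupted: missing columns ",
         paste(setdiff(needed, names(tab)), collapse = ", "))
  }
  bad <- which(!is.finite(tab$total_pahs) | tab$total_pahs <= 0 |
                 !is.finite(tab$bapeq) | tab$bapeq < 0 |
                 !tab$land_use %in% c("urban", "suburban", "rural"))
  if (length(bad)) {
    stop("study table fixture is corrupted at row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(tab$description[bad], collapse = "; "))
  }
  counts <- table(tab$land_use)
  if (nrow(tab) != 41L || counts[["urban"]] != 11L ||
      counts[["suburban"]] != 11L || counts[["rural"]] != 19L) {
    stop("study table fixture is corrupted: expected 41 records ",
         "(11 urban, 11 suburban, 19 rural)")
  }
  tab$land_use <- factor(tab$land_use,
                         levels = c("urban", "suburban", "rural"))
  lab <- printed_label_to_level(tab$contamination_level)
  if (anyNA(lab)) {
    stop("study table fixture is corrupted: unknown contamination label in ",
         "row(s) ", paste(which(is.na(lab)), collapse = ", "))
  }
  tab$contamination_level <- lab
  tab
}

#' Contamination severity levels
#'
#' The four-level ordinal scale used to grade total soil PAH burdens.
#'
#' @return Character vector of the level names in increasing severity.
#' @export
contamination_levels <- function() {
  c("not_contaminated", "weakly_contaminated", "contaminated",
    "heavily_contaminated")
}

printed_label_to_level <- function(x) {
  map <- c("Not contaminated" = "not_contaminated",
           "Weakly contaminated" = "weakly_contaminated",
           "Contaminated" = "contaminated",
           "Heavily contaminated" = "heavily_contaminated")
  factor(unname(map[x]), levels = contamination_levels(), ordered = TRUE)
}

#' Classify a total PAH concentration into a contamination level
#'
#' Grades total 16-PAH concentrations on the four-level scale used for
#' surface soils: below 200 ng g\eqn{^{-1}} not contaminated, 200-600 weakly
#' contaminated, 600-1000 contaminated, above 1000 heavily contaminated.
#' Because the published class limits share their endpoints, the boundary
#' convention here is the unique one consistent with all 41 printed study
#' labels: [0, 200), [200, 600), [600, 1000], (1000, Inf).
#'
#' @param total numeric vector of total PAH concentrations, ng g\eqn{^{-1}};
#'   must be finite and non-negative.
#' @return Ordered factor over [contamination_levels()].
#' @examples
#' classify_contamination(c(142, 602.5, 1989))
#' @export
classify_contamination <- function(total) {
  if (any(!is.finite(total)) || any(total < 0)) {
    stop("'total' must be finite and non-negative")
  }
  lev <- contamination_levels()
  out <- ifelse(total < 200, lev[1L],
                ifelse(total < 600, lev[2L],
                       ifelse(total <= 1000, lev[3L], lev[4L])))
  factor(out, levels = lev, ordered = TRUE)
}

#' Summary statistic of a study-table field within a record subset
#'
#' @param records data.frame of study records (as from [load_study_table()],
#'   possibly subset).
#' @param field one of \code{"total_pahs"}, \code{"bapeq"}.
#' @param stat one of \code{"mean"}, \code{"median"}, \code{"min"},
#'   \code{"max"}.
#' @return The statistic, ng g\eqn{^{-1}} (full precision; round only for
#'   display).
#' @examples
#' tab <- load_study_table()
#' summarize_group(tab[tab$land_use == "urban", ], "bapeq", "mean")
#' @export
summarize_group <- function(records,
                            field = c("total_pahs", "bapeq"),
                            stat = c("mean", "median", "min", "max")) {
  field <- match.arg(field)
  stat <- match.arg(stat)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("'records' must be a non-empty data.frame of study records")
  }
  x <- records[[field]]
  switch(stat,
         mean = mean(x),
         median = stats::median(x),
         min = min(x),
         max = max(x))
}

#' Count study records by computed contamination level
#'
#' Levels are recomputed from the totals via [classify_contamination()],
#' never read from the printed labels, so the counts double as a consistency
#' check on the classification rule.
#'
#' @param records data.frame of study records with a \code{total_pahs}
#'   column.
#' @return Named integer vector over all four levels (zero-filled).
#' @export
count_by_level <- function(records) {
  lev <- contamination_levels()
  if (is.null(records) || nrow(records) == 0L) {
    return(stats::setNames(integer(length(lev)), lev))
  }
  cl <- classify_contamination(records$total_pahs)
  tab <- table(cl)
  stats::setNames(as.integer(tab[lev]), lev)
}
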