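#' Benzo[a]pyrene-equivalent toxicity of a sample
#'
#' Toxicity-weighted total concentration
#' \eqn{BaP_{TEQ} = \sum_i TEF_i \, c_i}, with the toxic equivalency
#' factors of the compound catalog (benzo[a]pyrene and
#' dibenz[a,h]anthracene 1, most 2-4 ring compounds 0.001).
#'
#' @param sample numeric vector of the 16 compound concentrations in
#'   catalog order (ng g\eqn{^{-1}}), or a concentration matrix (one value
#'   per row is returned).
#' @param catalog a \code{pah_catalog} supplying the TEFs.
#' @return BaP-equivalent concentration(s), ng g\eqn{^{-1}}.
#' @examples
#' v <- setNames(numeric(16), default_catalog()$abbreviation)
#' v["BaP"] <- 10; v["BaA"] <- 10; v["Naph"] <- 100
#' bap_teq(v)  # 11.1
#' @export
bap_teq <- function(sample, catalog = default_catalog()) {
  if (is.matrix(sample)) {
    x <- as_concentration_matrix(sample, catalog)
    return(as.numeric(x %*% catalog$tef))
  }
  if (length(sample) != 16L) {
    stop("expected 16 concentrations, got ", length(sample))
  }
  if (!is.null(names(sample))) {
    missing_cmp <- setdiff(catalog$abbreviation, names(sample))
    if (length(missing_cmp)) {
      stop("missing compound(s): ", paste(missing_cmp, collapse = ", "))
    }
    sample <- sample[catalog$abbreviation]
  }
  if (any(!is.finite(sample)) || any(sample < 0)) {
    stop("concentrations must be finite and non-negative")
  }
  sum(catalog$tef * sample)
}

#' Apportion BaP-equivalent toxicity to PMF sources
#'
#' Distributes each sample's toxicity over the fitted sources: the
#' species-level contribution of source p in sample k is
#' \eqn{(PAH_i)_{kp} = S_{kp} f_{ip}}, its toxicity
#' \eqn{(BaP_{TEQ})_{kp} = \sum_i TEF_i (PAH_i)_{kp}}, and each source's
#' share is its summed toxicity over the grand total.  Shares are computed
#' on the model reconstruction (S f), not on the raw observations, so they
#' sum to exactly 100% per sample and overall.
#'
#' @param normalized a \code{pmf_normalized} model (see
#'   [normalize_profiles()]); factor labels from [label_sources()] are used
#'   as column names when present.
#' @param catalog a \code{pah_catalog} supplying the TEFs.
#' @return Object of class \code{teq_apportionment}: list with \code{teq}
#'   (samples x sources matrix of (BaP_TEQ)_kp, ng g\eqn{^{-1}}),
#'   \code{share} (per-source percentages summing to 100),
#'   \code{profile_teq_per_unit} (TEQ per unit source mass, i.e.
#'   \eqn{\sum_i TEF_i f_{ip}}) and \code{sources}.
#' @export
apportion_teq <- function(normalized, catalog = default_catalog()) {
  stopifnot(inherits(normalized, "pmf_normalized"))
  f <- normalized$f
  stopifnot(identical(colnames(f), catalog$abbreviation))
  unit_teq <- as.numeric(f %*% catalog$tef)  # TEQ per ng of source mass
  teq <- sweep(normalized$S, 2L, unit_teq, `*`)
  sources <- if (!is.null(normalized$labels)) {
    as.character(normalized$labels)
  } else {
    colnames(normalized$S)
  }
  colnames(teq) <- sources
  share <- 100 * colSums(teq) / sum(teq)
  structure(list(teq = teq, share = share,
                 profile_teq_per_unit = stats::setNames(unit_teq, sources),
                 sources = sources),
            class = "teq_apportionment")
}

#' Source shares of carcinogenic potency, optionally by group
#'
#' Summarizes a toxicity apportionment as per-source percentages of the
#' total BaP-equivalent burden, overall or within groups (e.g. land-use
#' types).  Percentages sum to 100 within each group.
#'
#' @param apportionment a \code{teq_apportionment}.
#' @param groups optional factor/character vector, one entry per sample.
#' @return data.frame with columns \code{group}, \code{source},
#'   \code{percent}.
#' @export
teq_source_share_report <- function(apportionment, groups = NULL) {
  stopifnot(inherits(apportionment, "teq_apportionment"))
  teq <- apportionment$teq
  if (is.null(groups)) groups <- rep("all", nrow(teq))
  stopifnot(length(groups) == nrow(teq))
  out <- do.call(rbind, lapply(unique(groups), function(gr) {
    tot <- colSums(teq[groups == gr, , drop = FALSE])
    data.frame(group = gr, source = colnames(teq),
               percent = 100 * tot / sum(tot), row.names = NULL)
  }))
  out
}
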