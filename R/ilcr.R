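#' Exposure parameters for the adult ILCR model
#'
#' Returns the adult exposure constants of the incremental lifetime cancer
#' risk (ILCR) model, with USEPA-style defaults: body weight BW 62 kg,
#' exposure frequency EF 180 d y\eqn{^{-1}}, exposure duration ED 24 y, soil
#' ingestion rate IR_ingestion 100 mg d\eqn{^{-1}}, inhalation rate
#' IR_inhalation 20 m\eqn{^3} d\eqn{^{-1}}, skin surface area SA 5700
#' cm\eqn{^2}, adherence factor AF 0.07 mg cm\eqn{^{-2}}, averaging time AT
#' 25550 d, dermal absorption ABS 0.13, particle emission factor PEF
#' 1.36e9 m\eqn{^3} kg\eqn{^{-1}}, and cancer slope factors (mg
#' kg\eqn{^{-1}} d\eqn{^{-1}})\eqn{^{-1}} of 3.85 (inhalation), 7.3
#' (ingestion) and 25 (dermal).
#'
#' @param ... named overrides of individual defaults.
#' @return Named list of class \code{exposure_params}; all entries strictly
#'   positive.
#' @examples
#' exposure_params(BW = 70)
#' @export
exposure_params <- function(...) {
  defaults <- list(
    BW = 62, EF = 180, ED = 24,
    IR_inhalation = 20, IR_ingestion = 100,
    SA = 5700, AF = 0.07, AT = 25550, ABS = 0.13, PEF = 1.36e9,
    CSF_inhalation = 3.85, CSF_ingestion = 7.3, CSF_dermal = 25
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown exposure parameter(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  bad <- vapply(defaults, function(v) !is.numeric(v) || !is.finite(v) ||
                  v <= 0, logical(1))
  if (any(bad)) {
    stop("exposure parameters must be positive and finite: ",
         paste(names(defaults)[bad], collapse = ", "))
  }
  structure(defaults, class = "exposure_params")
}

#' Three-pathway incremental lifetime cancer risk
#'
#' Deterministic adult ILCR from a BaP-equivalent soil concentration via
#' accidental soil ingestion, dermal contact and particulate inhalation,
#' with the total as their sum.  The slope-factor body-weight adjustment is
#' the standard USEPA cube-root scaling \eqn{(BW/70)^{1/3}} (published
#' renderings of these formulas often typeset it as a literal "BW/70^3" or
#' "BW/703", which is dimensionally unsupportable).  The concentration is
#' converted from ng g\eqn{^{-1}} to mg kg\eqn{^{-1}} internally and the
#' 1e6 factor converts mg of ingested/adhered soil to kg, so all pathway
#' doses are mg kg\eqn{^{-1}} d\eqn{^{-1}}:
#' \deqn{ILCR_{ing} = C \cdot CSF_{ing} (BW/70)^{1/3} \cdot
#'   IR_{ing} \, EF \, ED / (BW \cdot AT \cdot 10^6)}
#' \deqn{ILCR_{derm} = C \cdot CSF_{derm} (BW/70)^{1/3} \cdot
#'   SA \, AF \, ABS \, EF \, ED / (BW \cdot AT \cdot 10^6)}
#' \deqn{ILCR_{inh} = C \cdot CSF_{inh} (BW/70)^{1/3} \cdot
#'   IR_{inh} \, EF \, ED / (BW \cdot AT \cdot PEF)}
#' Every pathway is exactly linear in C.
#'
#' @param C BaP-equivalent soil concentration(s), ng g\eqn{^{-1}};
#'   non-negative.
#' @param params an \code{exposure_params} list.
#' @return data.frame with one row per concentration: \code{C},
#'   \code{ingestion}, \code{dermal}, \code{inhalation}, \code{total}
#'   (dimensionless lifetime probabilities).
#' @examples
#' ilcr_pathways(121.6)
#' @export
ilcr_pathways <- function(C, params = exposure_params()) {
  if (any(!is.finite(C)) || any(C < 0)) {
    stop("'C' must be finite and non-negative")
  }
  stopifnot(inherits(params, "exposure_params"))
  c_mgkg <- C * 1e-3                    # ng/g -> mg/kg soil
  bw_adj <- (params$BW / 70)^(1 / 3)
  time_term <- params$EF * params$ED / (params$BW * params$AT)
  ing <- c_mgkg * params$CSF_ingestion * bw_adj *
    params$IR_ingestion * time_term / 1e6
  derm <- c_mgkg * params$CSF_dermal * bw_adj *
    params$SA * params$AF * params$ABS * time_term / 1e6
  inh <- c_mgkg * params$CSF_inhalation * bw_adj *
    params$IR_inhalation * time_term / params$PEF
  data.frame(C = C, ingestion = ing, dermal = derm, inhalation = inh,
             total = ing + derm + inh)
}

#' Classify an ILCR value
#'
#' USEPA-style risk bands: below 1e-6 is the safe level, 1e-6 to 1e-4 a low
#' risk level, above 1e-4 marginal safety.
#'
#' @param ilcr non-negative risk value(s).
#' @return Ordered factor with levels \code{safe}, \code{low_risk},
#'   \code{marginal_safety}.
#' @examples
#' risk_category(c(5e-7, 9.6e-6, 2e-4))
#' @export
risk_category <- function(ilcr) {
  if (any(!is.finite(ilcr)) || any(ilcr < 0)) {
    stop("'ilcr' must be finite and non-negative")
  }
  lev <- c("safe", "low_risk", "marginal_safety")
  out <- ifelse(ilcr < 1e-6, lev[1L],
                ifelse(ilcr <= 1e-4, lev[2L], lev[3L]))
  factor(out, levels = lev, ordered = TRUE)
}

# Classical two-parameter Pareto: density, cdf, quantiles, draws.
# Scale (minimum) fixed at the sample minimum; shape fitted by its
# closed-form maximum-likelihood estimate.
dpareto <- function(x, shape, scale) {
  ifelse(x < scale, 0, shape * scale^shape / x^(shape + 1))
}
ppareto <- function(q, shape, scale) {
  ifelse(q < scale, 0, 1 - (scale / q)^shape)
}
qpareto <- function(p, shape, scale) scale * (1 - p)^(-1 / shape)
rpareto <- function(n, shape, scale) qpareto(stats::runif(n), shape, scale)

# Anderson-Darling statistic of a sample against a fitted CDF.
ad_statistic <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  z <- pmin(pmax(cdf(x), 1e-12), 1 - 1e-12)
  -n - mean((2 * seq_len(n) - 1) * (log(z) + log(1 - rev(z))))
}

#' Select the best-fitting concentration distribution
#'
#' Fits each candidate family to strictly positive values by maximum
#' likelihood (log-normal, gamma, Weibull and normal via
#' \pkg{fitdistrplus}; the classical two-parameter Pareto by its closed
#' form, scale fixed at the sample minimum) and selects the family with the
#' smallest Anderson-Darling statistic; ties go to the family with fewer
#' parameters.
#'
#' @param values numeric vector, at least 5 strictly positive values.
#' @param candidates subset of
#'   \code{c("lognormal", "gamma", "pareto", "normal", "weibull")}.
#' @return Object of class \code{fitted_distribution}: list with
#'   \code{family}, \code{parameters}, \code{gof} (the AD statistic),
#'   \code{all_fits} (family, parameters and AD for every candidate),
#'   \code{n}, plus quantile/random closures \code{qfun}, \code{rfun} for
#'   the winner.
#' @examples
#' tab <- load_study_table()
#' fit_best_distribution(tab$bapeq[tab$land_use == "urban"])
#' @export
fit_best_distribution <- function(values,
                                  candidates = c("lognormal", "gamma",
                                                 "pareto", "normal",
                                                 "weibull")) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  if (length(values) < 5L || any(!is.finite(values)) || any(values <= 0)) {
    stop("need at least 5 finite, strictly positive values")
  }
  if (stats::sd(values) == 0) {
    stop("fit undefined: values are constant")
  }
  fit_one <- function(family) {
    if (family == "pareto") {
      scale <- min(values)
      shape <- length(values) / sum(log(values / scale))
      pars <- c(shape = shape, scale = scale)
      list(family = family, parameters = pars, n_par = 2L,
           cdf = function(q) ppareto(q, pars["shape"], pars["scale"]),
           qfun = function(p) qpareto(p, pars["shape"], pars["scale"]),
           rfun = function(n) rpareto(n, pars["shape"], pars["scale"]))
    } else {
      dist <- switch(family, lognormal = "lnorm", gamma = "gamma",
                     normal = "norm", weibull = "weibull")
      fd <- fitdistrplus::fitdist(values, dist, method = "mle")
      pars <- fd$estimate
      pf <- get(paste0("p", dist), mode = "function")
      qf <- get(paste0("q", dist), mode = "function")
      rf <- get(paste0("r", dist), mode = "function")
      list(family = family, parameters = pars, n_par = length(pars),
           cdf = function(q) do.call(pf, c(list(q), as.list(pars))),
           qfun = function(p) do.call(qf, c(list(p), as.list(pars))),
           rfun = function(n) do.call(rf, c(list(n), as.list(pars))))
    }
  }
  fits <- lapply(candidates, function(fam) {
    f <- tryCatch(fit_one(fam), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    f$ad <- ad_statistic(values, f$cdf)
    f
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$ad), fits)
  if (!length(fits)) stop("no candidate family could be fitted")
  ads <- vapply(fits, function(f) f$ad, numeric(1))
  npars <- vapply(fits, function(f) f$n_par, integer(1))
  best <- fits[[order(ads, npars)[1L]]]
  structure(list(
    family = best$family,
    parameters = best$parameters,
    gof = best$ad,
    all_fits = data.frame(
      family = vapply(fits, function(f) f$family, character(1)),
      ad = ads,
      row.names = NULL),
    n = length(values),
    qfun = best$qfun,
    rfun = best$rfun
  ), class = "fitted_distribution")
}

#' @export
print.fitted_distribution <- function(x, ...) {
  cat("Best-fit distribution:", x$family, "(AD =",
      format(x$gof, digits = 4), ")\n")
  print(x$parameters)
  invisible(x)
}

#' Monte Carlo propagation of concentration uncertainty through the ILCR
#'
#' Draws concentrations from a fitted distribution (or a degenerate point
#' mass), truncates negatives at zero, evaluates the three-pathway ILCR for
#' each draw, and summarizes the resulting risk distribution; the 95th
#' percentile serves as the conventional high-end risk estimate.
#'
#' @param distribution a \code{fitted_distribution}, or a single number for
#'   a point mass at that concentration.
#' @param params an \code{exposure_params} list.
#' @param n_iter number of draws (at least 1000).
#' @param seed integer seed; draws are reproducible given the seed.
#' @param probs percentile grid to report.
#' @return Object of class \code{ilcr_mc}: list with \code{family},
#'   \code{n_iter}, \code{seed}, \code{percentiles} (data.frame of
#'   probability, concentration and per-pathway/total ILCR),
#'   \code{p95_total}, \code{category} (risk band of the 95th percentile)
#'   and \code{mean_total}.
#' @export
monte_carlo_ilcr <- function(distribution, params = exposure_params(),
                             n_iter = 10000L, seed = 1L,
                             probs = c(0.05, 0.25, 0.5, 0.75, 0.9, 0.95,
                                       0.99)) {
  if (n_iter < 1000L) stop("'n_iter' must be at least 1000")
  if (is.numeric(distribution) && length(distribution) == 1L) {
    draws <- rep(as.numeric(distribution), n_iter)
    family <- "point_mass"
  } else {
    stopifnot(inherits(distribution, "fitted_distribution"))
    draws <- with_preserved_seed(seed, distribution$rfun(n_iter))
    family <- distribution$family
  }
  draws <- pmax(draws, 0)
  risks <- ilcr_pathways(draws, params)
  qs <- apply(risks, 2L, stats::quantile, probs = probs, names = FALSE)
  percentiles <- data.frame(prob = probs, qs, row.names = NULL)
  p95 <- stats::quantile(risks$total, 0.95, names = FALSE)
  structure(list(
    family = family,
    n_iter = n_iter,
    seed = seed,
    percentiles = percentiles,
    p95_total = p95,
    category = risk_category(p95),
    mean_total = mean(risks$total)
  ), class = "ilcr_mc")
}

#' @export
print.ilcr_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo ILCR (%s, %d draws): 95th percentile %.3g (%s)\n",
              x$family, x$n_iter, x$p95_total, as.character(x$category)))
  invisible(x)
}
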