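#' Pipeline configuration
#'
#' Validated, fully serializable settings for [run_pipeline()].  Two modes
#' are supported: \code{"study_table"} runs the stages available for the
#' bundled literature table (contamination classification, group summaries,
#' distribution fitting and Monte Carlo ILCR; the table carries no
#' per-compound data, so compound-level stages do not apply), and
#' \code{"profile"} runs the full chain (diagnostic ratios, PCA/MLR, PMF
#' factor scan, toxicity apportionment, ILCR) on a sample-by-compound
#' matrix, either read from a CSV or simulated.
#'
#' @param mode \code{"study_table"} or \code{"profile"}.
#' @param input optional concentration CSV path (profile mode); when NULL a
#'   synthetic dataset of \code{n_synthetic} samples is simulated.
#' @param n_synthetic number of simulated samples when \code{input} is NULL.
#' @param mdl,error_fraction catalog-wide uncertainty defaults.
#' @param p_min,p_max PMF factor-count scan range.
#' @param n_starts,tol,max_iter PMF solver settings.
#' @param n_iter Monte Carlo draw count.
#' @param exposure named list of exposure-parameter overrides.
#' @param seed top-level seed for every stochastic stage.
#' @param outdir output directory for stage files; NULL disables writing.
#' @return Named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(mode = c("study_table", "profile"),
                            input = NULL, n_synthetic = 50L,
                            mdl = 1.0, error_fraction = 0.1,
                            p_min = 3L, p_max = 8L, n_starts = 10L,
                            tol = 1e-8, max_iter = 5000L,
                            n_iter = 10000L, exposure = list(),
                            seed = 1L, outdir = NULL) {
  mode <- match.arg(mode)
  if (!is.null(input) && !file.exists(input)) {
    stop("input file does not exist: ", input)
  }
  if (p_min < 1L || p_max < p_min || p_max > 16L) {
    stop("need 1 <= p_min <= p_max <= 16")
  }
  if (mode == "profile" && is.null(input) && n_synthetic < 4L) {
    stop("'n_synthetic' must be at least the number of simulated sources")
  }
  stopifnot(mdl > 0, error_fraction > 0, n_starts >= 1L, n_iter >= 1000L)
  do.call(exposure_params, exposure)  # validate overrides early
  structure(list(mode = mode, input = input, n_synthetic = n_synthetic,
                 mdl = mdl, error_fraction = error_fraction,
                 p_min = p_min, p_max = p_max, n_starts = n_starts,
                 tol = tol, max_iter = max_iter, n_iter = n_iter,
                 exposure = exposure, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the end-to-end analysis
#'
#' Executes the configured stages in order and (optionally) writes every
#' stage table plus a machine-readable JSON summary to
#' \code{config$outdir}.  Identical configurations and seeds yield
#' identical outputs.
#'
#' @param config a \code{pipeline_config}.
#' @return The summary as a nested list (invisibly written as
#'   \code{summary.json} when an output directory is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  params <- do.call(exposure_params, config$exposure)
  summary <- list(mode = config$mode, seed = config$seed)
  if (config$mode == "study_table") {
    summary <- c(summary, study_table_stages(config, params, outdir))
  } else {
    summary <- c(summary, profile_stages(config, params, outdir))
  }
  if (!is.null(outdir)) {
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(summary)
}

study_table_stages <- function(config, params, outdir) {
  tab <- load_study_table()
  groups <- lapply(split(tab, tab$land_use), function(rec) {
    counts <- count_by_level(rec)
    fit <- fit_best_distribution(rec$bapeq)
    mc <- monte_carlo_ilcr(fit, params, n_iter = config$n_iter,
                           seed = config$seed)
    list(
      n_studies = nrow(rec),
      total_pahs = list(mean = summarize_group(rec, "total_pahs", "mean"),
                        median = summarize_group(rec, "total_pahs", "median"),
                        min = summarize_group(rec, "total_pahs", "min"),
                        max = summarize_group(rec, "total_pahs", "max")),
      bapeq_mean = summarize_group(rec, "bapeq", "mean"),
      contamination_counts = as.list(counts),
      n_contaminated_or_heavier = unname(counts["contaminated"] +
                                           counts["heavily_contaminated"]),
      bapeq_distribution = list(family = fit$family,
                                parameters = as.list(fit$parameters),
                                ad = fit$gof),
      ilcr_p95 = mc$p95_total,
      risk_category = as.character(mc$category)
    )
  })
  if (!is.null(outdir)) {
    cls <- data.frame(tab, computed_level =
                        classify_contamination(tab$total_pahs))
    utils::write.csv(cls, file.path(outdir, "classification.csv"),
                     row.names = FALSE)
  }
  list(land_use = groups)
}

profile_stages <- function(config, params, outdir) {
  catalog <- default_catalog(mdl = config$mdl,
                             error_fraction = config$error_fraction)
  if (is.null(config$input)) {
    sim <- simulate_dataset(config$n_synthetic, seed = config$seed)
    x <- sim$x
  } else {
    x <- read_concentration_table(config$input, catalog)
  }
  x <- substitute_below_mdl(x, catalog)

  crossplot <- ratio_crossplot_table(x)
  pca <- run_pca(x)
  mlr <- apportion_mlr(pca, rowSums(x))
  u <- build_uncertainty(x, catalog)
  scan <- scan_factors(x, u, p_min = config$p_min, p_max = config$p_max,
                       seed = config$seed, n_starts = config$n_starts,
                       tol = config$tol, max_iter = config$max_iter)
  p_use <- if (is.na(scan$recommended_p)) {
    scan$table$p[which.max(scan$table$r_squared)]
  } else {
    scan$recommended_p
  }
  model <- scan$models[[as.character(p_use)]]
  normalized <- normalize_profiles(model)
  labels <- label_sources(normalized)
  normalized$labels <- labels
  contrib_pct <- stats::setNames(source_contribution_percent(normalized),
                                 labels)
  teq <- apportion_teq(normalized, catalog)
  sample_teq <- bap_teq(unclass_matrix(x), catalog)
  risk <- NULL
  if (sum(sample_teq > 0) >= 5L && stats::sd(sample_teq) > 0) {
    fit <- fit_best_distribution(sample_teq[sample_teq > 0])
    mc <- monte_carlo_ilcr(fit, params, n_iter = config$n_iter,
                           seed = config$seed)
    risk <- list(family = fit$family, ilcr_p95 = mc$p95_total,
                 risk_category = as.character(mc$category))
  }
  if (!is.null(outdir)) {
    utils::write.csv(crossplot, file.path(outdir, "diagnostic_ratios.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(compound = rownames(pca$loadings),
                                pca$loadings),
                     file.path(outdir, "pca_loadings.csv"),
                     row.names = FALSE)
    utils::write.csv(scan$table, file.path(outdir, "pmf_scan.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(source = labels, normalized$f),
                     file.path(outdir, "pmf_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(sample_id = rownames(normalized$S),
                                normalized$S),
                     file.path(outdir, "pmf_contributions.csv"),
                     row.names = FALSE)
    utils::write.csv(teq_source_share_report(teq),
                     file.path(outdir, "teq_shares.csv"),
                     row.names = FALSE)
  }
  list(
    n_samples = nrow(x),
    pca = list(n_retained = pca$n_retained,
               cumulative_variance =
                 pca$cumulative_variance[pca$n_retained],
               mlr_contributions = as.list(mlr$contributions)),
    pmf = list(scan = scan$table, recommended_p = p_use,
               Q = model$Q, r_squared = model$r_squared,
               labels = as.character(labels),
               contribution_percent = as.list(contrib_pct)),
    teq_share_percent = as.list(teq$share),
    risk = risk
  )
}

# Strip attributes (e.g. below_mdl flags) that confuse downstream matrix ops.
unclass_matrix <- function(x) {
  attr(x, "below_mdl") <- NULL
  x
}
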