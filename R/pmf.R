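#' Equation-based measurement uncertainty matrix
#'
#' Builds the per-cell uncertainty u_ij that weights the PMF objective:
#' below or at the method detection limit the uncertainty is 5/6 of the MDL;
#' above it, \eqn{u_{ij} = \sqrt{(EF_j x_{ij})^2 + MDL_j^2}} where EF_j is
#' the compound's error fraction (relative measurement uncertainty).
#'
#' @param x concentration matrix (ng g\eqn{^{-1}}).
#' @param catalog a \code{pah_catalog} supplying per-compound \code{mdl}
#'   (must be strictly positive) and \code{error_fraction}.
#' @return Numeric matrix of uncertainties, same shape and units as
#'   \code{x}, all entries strictly positive.
#' @examples
#' build_uncertainty(matrix(30, 1, 16,
#'   dimnames = list("s1", default_catalog()$abbreviation)))
#' @export
build_uncertainty <- function(x, catalog = default_catalog()) {
  x <- as_concentration_matrix(x, catalog)
  if (any(catalog$mdl <= 0)) stop("all MDLs must be strictly positive")
  mdl <- matrix(catalog$mdl, nrow(x), 16L, byrow = TRUE)
  ef <- matrix(catalog$error_fraction, nrow(x), 16L, byrow = TRUE)
  u <- sqrt((ef * x)^2 + mdl^2)
  low <- x <= mdl
  u[low] <- 5 / 6 * mdl[low]
  dimnames(u) <- dimnames(x)
  u
}

#' Fit an uncertainty-weighted positive matrix factorization
#'
#' Decomposes a non-negative concentration matrix X (n samples x m
#' compounds) as X = G F + E with G (n x p) and F (p x m) non-negative,
#' minimizing the weighted least-squares objective
#' \eqn{Q = \sum_{ij} (e_{ij}/u_{ij})^2}.  The solver uses multiplicative
#' updates for weighted non-negative factorization (weights
#' \eqn{1/u_{ij}^2}), which keep both factors non-negative and never
#' increase Q; the best of \code{n_starts} seeded random initializations is
#' returned, so results are reproducible for a fixed seed.
#'
#' @param x concentration matrix (ng g\eqn{^{-1}}).
#' @param u uncertainty matrix from [build_uncertainty()]; all entries
#'   must be positive.
#' @param p number of factors (sources); 1 <= p <= min(n, m).
#' @param n_starts number of random initializations.
#' @param seed top-level seed, expanded deterministically into one sub-seed
#'   per start.
#' @param tol convergence tolerance on the relative change of Q between
#'   iterations.
#' @param max_iter iteration cap per start; hitting it flags the start as
#'   unconverged (a warning, not an error).
#' @param polish_sweeps number of alternating weighted nonnegative
#'   least-squares sweeps applied to the winning start.  Multiplicative
#'   updates approach active-set boundaries (exact zeros in G or F) only
#'   asymptotically; each polish sweep solves the per-row and per-column
#'   weighted NNLS subproblems exactly, so Q keeps its monotone descent and
#'   reaches the local optimum at machine precision.  Set to 0 to disable.
#' @return Object of class \code{pmf_model}: list with \code{p}, \code{G},
#'   \code{F}, \code{residual} (X - GF), \code{Q}, \code{r_squared} (squared
#'   Pearson correlation of all observed vs reconstructed cells),
#'   \code{q_trace} (per-iteration Q of the winning start), \code{log}
#'   (per-start seed, iterations, Q, convergence flag), \code{converged},
#'   and the inputs \code{x}, \code{u}.
#' @export
fit_pmf <- function(x, u, p, n_starts = 20L, seed = 1L, tol = 1e-8,
                    max_iter = 5000L, polish_sweeps = 50L) {
  x <- as_concentration_matrix(x)
  stopifnot(identical(dim(u), dim(x)), all(is.finite(u)), all(u > 0))
  n <- nrow(x)
  m <- ncol(x)
  if (p < 1L || p > min(n, m)) {
    stop("'p' must satisfy 1 <= p <= min(n, m) = ", min(n, m))
  }
  if (all(x == 0)) {
    warning("degenerate input: X is identically zero; returning the ",
            "trivial all-zero model (Q = 0)")
    g0 <- matrix(0, n, p, dimnames = list(rownames(x), paste0("F", 1:p)))
    f0 <- matrix(0, p, m, dimnames = list(paste0("F", 1:p), colnames(x)))
    return(structure(list(p = p, G = g0, F = f0, residual = x, Q = 0,
                          r_squared = NA_real_, q_trace = 0,
                          log = data.frame(), converged = TRUE,
                          x = x, u = u), class = "pmf_model"))
  }
  w <- 1 / u^2
  wx <- w * x
  # absolute stopping floor: a statistically adequate fit has Q ~ n*m, so
  # anything this far below is an (essentially) exact reconstruction
  q_floor <- 1e-9 * n * m
  scale0 <- mean(rowSums(x)) / p
  seeds <- expand_seeds(seed, n_starts)
  best <- NULL
  log <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fit <- with_preserved_seed(seeds[s], {
      g <- matrix(stats::runif(n * p, 0.1, 1) * scale0, n, p)
      f <- matrix(stats::runif(p * m, 0.1, 1), p, m)
      f <- f / rowSums(f)
      q_trace <- numeric(0)
      q_prev <- Inf
      converged <- FALSE
      iter <- 0L
      eps <- .Machine$double.eps
      while (iter < max_iter) {
        iter <- iter + 1L
        gf <- g %*% f
        g <- g * (wx %*% t(f)) / ((w * gf) %*% t(f) + eps)
        gf <- g %*% f
        f <- f * (t(g) %*% wx) / (t(g) %*% (w * gf) + eps)
        q <- sum(w * (x - g %*% f)^2)
        q_trace <- c(q_trace, q)
        if (q <= q_floor ||
            (is.finite(q_prev) && abs(q_prev - q) <= tol * max(q_prev, eps))) {
          converged <- TRUE
          break
        }
        q_prev <- q
      }
      list(g = g, f = f, q = q, q_trace = q_trace, iter = iter,
           converged = converged)
    })
    log[[s]] <- data.frame(start = s, seed = seeds[s],
                           iterations = fit$iter, Q = fit$q,
                           converged = fit$converged)
    if (is.null(best) || fit$q < best$q) best <- fit
  }
  log <- do.call(rbind, log)
  if (polish_sweeps > 0L) {
    best <- anls_polish(x, u, w, wx, best, sweeps = polish_sweeps, tol = tol)
  }
  if (!best$converged) {
    warning("PMF did not converge within ", max_iter,
            " iterations for the best start; results may be improvable")
  }
  dimnames(best$g) <- list(rownames(x), paste0("F", seq_len(p)))
  dimnames(best$f) <- list(paste0("F", seq_len(p)), colnames(x))
  recon <- best$g %*% best$f
  structure(list(
    p = p, G = best$g, F = best$f,
    residual = x - recon,
    Q = best$q,
    r_squared = stats::cor(as.numeric(x), as.numeric(recon))^2,
    q_trace = best$q_trace,
    log = log,
    converged = best$converged,
    x = x, u = u
  ), class = "pmf_model")
}

# Alternating exact weighted-NNLS sweeps (block coordinate descent on Q):
# each sweep solves every row of G and every column of F at its weighted
# nonnegative least-squares optimum, so Q is non-increasing sweep to sweep.
anls_polish <- function(x, u, w, wx, fit, sweeps, tol) {
  g <- fit$g
  f <- fit$f
  q_prev <- fit$q
  eps <- .Machine$double.eps
  q_floor <- 1e-9 * length(x)
  for (s in seq_len(sweeps)) {
    for (i in seq_len(nrow(x))) {
      a <- t(f) / u[i, ]
      g[i, ] <- pracma::lsqnonneg(a, x[i, ] / u[i, ])$x
    }
    for (j in seq_len(ncol(x))) {
      a <- g / u[, j]
      f[, j] <- pracma::lsqnonneg(a, x[, j] / u[, j])$x
    }
    q <- sum(w * (x - g %*% f)^2)
    fit$q_trace <- c(fit$q_trace, q)
    if (q <= q_floor || abs(q_prev - q) <= tol * max(q_prev, eps)) {
      fit$converged <- TRUE
      q_prev <- q
      break
    }
    q_prev <- q
  }
  fit$g <- g
  fit$f <- f
  fit$q <- q_prev
  fit
}

#' @export
print.pmf_model <- function(x, ...) {
  cat(sprintf("PMF model: %d factors, %d samples x %d compounds\n",
              x$p, nrow(x$G), ncol(x$F)))
  cat(sprintf("Q = %.6g, R^2 = %.4f, converged: %s\n",
              x$Q, x$r_squared, x$converged))
  invisible(x)
}

#' Scan candidate factor counts
#'
#' Fits the PMF at each factor count in \code{p_min:p_max} and tabulates Q,
#' Q over its expected value (the residual degrees of freedom
#' nm - p(n+m), the usual receptor-model yardstick for an adequate fit),
#' and the pooled-cell R^2.  The recommended count is the smallest p whose
#' R^2 reaches \code{r2_threshold} and for which adding one more factor
#' improves the fit by less than \code{q_improvement} (relative).  The
#' improvement is measured on Q/Q_expected rather than raw Q: every extra
#' factor absorbs noise worth roughly (n+m)/dof of Q even past the true
#' factor count, so raw-Q improvements never level off at moderate sample
#' sizes, while the dof-normalized ratio flattens as soon as the factors
#' stop capturing structure.  The largest scanned p trivially satisfies the
#' improvement condition.
#'
#' @inheritParams fit_pmf
#' @param p_min,p_max factor-count range to scan (defaults 3 to 8).
#' @param r2_threshold minimum pooled R^2 (default 0.91).
#' @param q_improvement relative Q gain below which an extra factor is not
#'   considered worthwhile (default 0.10).
#' @param ... passed on to [fit_pmf()] (\code{n_starts}, \code{tol},
#'   \code{max_iter}).
#' @return List with \code{table} (one row per p: \code{p}, \code{Q},
#'   \code{Q_over_Qexpected}, \code{r_squared}), \code{recommended_p}
#'   (NA if no p qualifies) and \code{models} (the fitted
#'   \code{pmf_model}s, named by p).
#' @export
scan_factors <- function(x, u, p_min = 3L, p_max = 8L, seed = 1L,
                         r2_threshold = 0.91, q_improvement = 0.10, ...) {
  x <- as_concentration_matrix(x)
  if (p_max > min(nrow(x), ncol(x))) {
    stop("'p_max' must not exceed min(n, m) = ", min(nrow(x), ncol(x)))
  }
  if (p_min < 1L || p_min > p_max) stop("need 1 <= p_min <= p_max")
  ps <- seq.int(p_min, p_max)
  seeds <- expand_seeds(seed, length(ps))
  models <- lapply(seq_along(ps), function(i) {
    fit_pmf(x, u, p = ps[i], seed = seeds[i], ...)
  })
  names(models) <- ps
  n <- nrow(x)
  m <- ncol(x)
  tab <- data.frame(
    p = ps,
    Q = vapply(models, function(mod) mod$Q, numeric(1)),
    Q_over_Qexpected = vapply(models, function(mod) {
      dof <- n * m - mod$p * (n + m)
      if (dof > 0) mod$Q / dof else NA_real_
    }, numeric(1)),
    r_squared = vapply(models, function(mod) mod$r_squared, numeric(1)),
    row.names = NULL
  )
  crit <- ifelse(is.na(tab$Q_over_Qexpected), tab$Q, tab$Q_over_Qexpected)
  gain <- c(ifelse(crit[-nrow(tab)] > 0,
                   (crit[-nrow(tab)] - crit[-1L]) / crit[-nrow(tab)],
                   0),
            0)
  ok <- tab$r_squared >= r2_threshold & gain < q_improvement
  recommended <- if (any(ok)) tab$p[which(ok)[1L]] else NA_integer_
  list(table = tab, recommended_p = recommended, models = models)
}

#' Normalize PMF factors into source profiles and mass contributions
#'
#' Rescales each factor profile to a fraction vector summing to 1 and folds
#' the scale into the contribution column, so the rescaled pair (S, f)
#' reproduces G F exactly and S_kp reads directly as the total PAH mass
#' (ng g\eqn{^{-1}}) attributed to source p in sample k.  All-zero factors
#' are dropped with a warning.
#'
#' @param model a fitted \code{pmf_model}.
#' @return Object of class \code{pmf_normalized}: list with \code{S}
#'   (n x p contributions, ng g\eqn{^{-1}}), \code{f} (p x m profile
#'   fractions, rows summing to 1), \code{labels} (NULL until
#'   [label_sources()] is applied) and \code{p}.
#' @export
normalize_profiles <- function(model) {
  stopifnot(inherits(model, "pmf_model"))
  s_row <- rowSums(model$F)
  keep <- s_row > 0
  if (!all(keep)) {
    warning("dropping all-zero factor(s): ",
            paste(rownames(model$F)[!keep], collapse = ", "))
  }
  f <- model$F[keep, , drop = FALSE] / s_row[keep]
  s <- sweep(model$G[, keep, drop = FALSE], 2L, s_row[keep], `*`)
  structure(list(S = s, f = f, labels = NULL, p = sum(keep)),
            class = "pmf_normalized")
}

#' Label PMF factors against reference source signatures
#'
#' Assigns each normalized factor profile the reference source with the
#' highest cosine similarity, greedily and injectively while reference
#' candidates remain (ties broken towards the factor carrying more summed
#' mass on the candidate's marker compounds, i.e. the larger dot product).
#' Factors whose best similarity falls below \code{min_similarity} are
#' flagged low-confidence.
#'
#' @param normalized a \code{pmf_normalized} model.
#' @param marker_library reference profile matrix (candidates x 16), e.g.
#'   [make_source_profiles()].
#' @param min_similarity confidence floor on the cosine similarity.
#' @return Character vector of labels, one per factor, with attributes
#'   \code{similarity} (numeric) and \code{low_confidence} (logical).
#' @export
label_sources <- function(normalized, marker_library = make_source_profiles(),
                          min_similarity = 0.5) {
  stopifnot(inherits(normalized, "pmf_normalized"))
  f <- normalized$f
  sim <- matrix(NA_real_, nrow(f), nrow(marker_library),
                dimnames = list(rownames(f), rownames(marker_library)))
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(nrow(marker_library))) {
      sim[i, j] <- cosine_similarity(f[i, ], marker_library[j, ])
    }
  }
  labels <- rep(NA_character_, nrow(f))
  best_sim <- rep(NA_real_, nrow(f))
  avail <- rep(TRUE, nrow(marker_library))
  todo <- rep(TRUE, nrow(f))
  while (any(todo)) {
    cand <- sim
    cand[!todo, ] <- -Inf
    if (any(avail)) cand[, !avail] <- -Inf
    idx <- which(cand == max(cand), arr.ind = TRUE)
    if (nrow(idx) > 1L) {
      # tie-break: the factor with the larger mass on the candidate profile
      dots <- apply(idx, 1L, function(ij) sum(f[ij[1L], ] *
                                                marker_library[ij[2L], ]))
      idx <- idx[which.max(dots), , drop = FALSE]
    }
    i <- idx[1L, 1L]
    j <- idx[1L, 2L]
    labels[i] <- rownames(marker_library)[j]
    best_sim[i] <- sim[i, j]
    todo[i] <- FALSE
    avail[j] <- FALSE
    if (!any(avail)) avail[] <- TRUE  # more factors than candidates: reuse
  }
  structure(labels,
            similarity = best_sim,
            low_confidence = best_sim < min_similarity)
}

#' Per-source contribution percentages
#'
#' Share of the total reconstructed PAH mass attributed to each source:
#' \eqn{100 \sum_k S_{kp} / \sum_{k,p} S_{kp}}.
#'
#' @param normalized a \code{pmf_normalized} model.
#' @return Named numeric vector of percentages summing to 100.
#' @export
source_contribution_percent <- function(normalized) {
  stopifnot(inherits(normalized, "pmf_normalized"))
  tot <- colSums(normalized$S)
  100 * tot / sum(tot)
}

# Best one-to-one matching (by mean cosine similarity) between estimated and
# true profile rows; used by recovery experiments.  Enumerates permutations,
# so only suitable for small factor counts.
match_profiles <- function(est, truth) {
  p <- nrow(truth)
  stopifnot(nrow(est) == p)
  perms <- permutations_of(p)
  best <- NULL
  for (pi in seq_len(nrow(perms))) {
    perm <- perms[pi, ]
    sims <- vapply(seq_len(p), function(k) {
      cosine_similarity(est[perm[k], ], truth[k, ])
    }, numeric(1))
    if (is.null(best) || mean(sims) > best$mean_cosine) {
      best <- list(permutation = perm, cosines = sims,
                   mean_cosine = mean(sims))
    }
  }
  best
}

permutations_of <- function(p) {
  if (p == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(p - 1L)
  out <- matrix(0L, 0L, p)
  for (k in seq_len(p)) {
    out <- rbind(out, cbind(k, sub + (sub >= k)))
  }
  unname(out)
}
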