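# Brute-force objective oracle: plain double loop over cells, independent of
# the solver's vectorized Q computation.
oracle_q <- function(x, g, f, u) {
  recon <- g %*% f
  q <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      q <- q + ((x[i, j] - recon[i, j]) / u[i, j])^2
    }
  }
  q
}

# Noise-free two-source dataset built for exact identifiability: profiles
# with disjoint supports (HMW-only vehicular vs LMW-only petrogenic) and a
# few pure "anchor" samples per source, the classical separability condition
# under which the non-negative factorization is unique up to permutation
# and scale.
make_anchored_dataset <- function(seed = 7, n_mixed = 16) {
  prof <- make_source_profiles(1)[c("vehicular_emission", "petrogenic"), ]
  lmw <- c("Naph", "Acy", "Ace", "Flu", "Phe", "Ant")
  prof["vehicular_emission", lmw] <- 0
  prof["petrogenic", setdiff(colnames(prof), lmw)] <- 0
  prof <- prof / rowSums(prof)
  g <- pmfteq:::with_preserved_seed(seed, {
    rbind(
      cbind(rlnorm(n_mixed, log(250), 0.8), rlnorm(n_mixed, log(250), 0.8)),
      cbind(rlnorm(2, log(400), 0.3), 0),
      cbind(0, rlnorm(2, log(400), 0.3))
    )
  })
  x <- g %*% prof
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  list(x = as_concentration_matrix(x), g = g, profiles = prof)
}

# One full 4-source recovery replicate at the generator's calibrated
# defaults; returns profile cosines (best permutation) and the signed
# mass-share errors in percentage points.
recovery_replicate <- function(sim_seed, fit_seed, n = 50, n_starts = 8,
                               max_iter = 2500) {
  sim <- simulate_dataset(n = n, seed = sim_seed)
  u <- build_uncertainty(sim$x)
  fit <- suppressWarnings(fit_pmf(sim$x, u, p = 4, n_starts = n_starts,
                                  seed = fit_seed, max_iter = max_iter))
  norm <- normalize_profiles(fit)
  m <- pmfteq:::match_profiles(norm$f, sim$truth$profiles)
  est_share <- source_contribution_percent(norm)[m$permutation]
  true_share <- 100 * colSums(sim$truth$g) / sum(sim$truth$g)
  teq <- apportion_teq(norm)
  true_teq <- colSums(sim$truth$g *
                        matrix(as.numeric(sim$truth$profiles %*%
                                            default_catalog()$tef),
                               nrow(sim$truth$g), 4, byrow = TRUE))
  list(model = fit, normalized = norm, sim = sim,
       cosines = m$cosines, permutation = m$permutation,
       share_error = unname(est_share - true_share),
       teq_share_error = unname(teq$share[m$permutation] -
                                  100 * true_teq / sum(true_teq)))
}

# A minimal hand-built normalized model for unit tests of downstream stages.
toy_normalized <- function(S, f) {
  colnames(f) <- default_catalog()$abbreviation
  structure(list(S = S, f = f, labels = NULL, p = nrow(f)),
            class = "pmf_normalized")
}
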