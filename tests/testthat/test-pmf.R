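test_that("uncertainty matrix follows the two-branch equation", {
  catal <- default_catalog(mdl = 6, error_fraction = 0.1)
  x <- matrix(2, 1, 16, dimnames = list("s1", catal$abbreviation))
  expect_equal(unname(build_uncertainty(x, catal))[1, ],
               rep(5, 16))  # (5/6) * 6

  catal2 <- default_catalog(mdl = 4, error_fraction = 0.1)
  x2 <- matrix(30, 1, 16, dimnames = list("s1", catal2$abbreviation))
  expect_equal(unname(build_uncertainty(x2, catal2))[1, ],
               rep(5, 16))  # sqrt(3^2 + 4^2)

  # the boundary concentration x == MDL uses the detection-limit branch
  x3 <- matrix(4, 1, 16, dimnames = list("s1", catal2$abbreviation))
  expect_equal(unname(build_uncertainty(x3, catal2))[1, ],
               rep(5 / 6 * 4, 16))

  bad <- default_catalog()
  bad$mdl[3] <- 0
  expect_error(build_uncertainty(x, bad), "strictly positive")
})

test_that("Q matches the brute-force double-loop oracle", {
  sim <- simulate_dataset(n = 15, seed = 6)
  u <- build_uncertainty(sim$x)
  fit <- suppressWarnings(fit_pmf(sim$x, u, p = 3, n_starts = 3, seed = 2,
                                  max_iter = 800))
  expect_equal(fit$Q, oracle_q(unclass(sim$x), fit$G, fit$F, u),
               tolerance = 1e-8)
  # the stored residual is consistent with the stored factors
  expect_equal(fit$residual, unclass(sim$x) - fit$G %*% fit$F,
               tolerance = 1e-10)
})

test_that("noise-free separable data is recovered exactly", {
  ds <- make_anchored_dataset(seed = 7)
  u <- matrix(1, nrow(ds$x), 16)
  fit <- fit_pmf(ds$x, u, p = 2, n_starts = 5, seed = 3, tol = 1e-9,
                 max_iter = 3000, polish_sweeps = 400)
  expect_lte(fit$Q, 1e-6 * length(ds$x))
  m <- pmfteq:::match_profiles(normalize_profiles(fit)$f, ds$profiles)
  expect_gte(min(m$cosines), 0.999)
})

test_that("rank-1 non-negative data is reconstructed exactly at p = 1", {
  catal <- default_catalog()
  g <- rlnorm(10, 5, 1)
  f <- make_source_profiles(4)["coal_combustion", ]
  x <- as_concentration_matrix(
    `rownames<-`(g %*% t(f), paste0("s", 1:10)))
  u <- matrix(1, 10, 16)
  fit <- fit_pmf(x, u, p = 1, n_starts = 3, seed = 5, max_iter = 2000)
  expect_lte(fit$Q, 1e-6 * length(x))
})

test_that("objective is monotone non-increasing along the trace", {
  sim <- simulate_dataset(n = 20, seed = 9)
  u <- build_uncertainty(sim$x)
  fit <- suppressWarnings(fit_pmf(sim$x, u, p = 4, n_starts = 2, seed = 4,
                                  max_iter = 600))
  qt <- fit$q_trace
  expect_true(all(diff(qt) <= 1e-9 * pmax(qt[-length(qt)], 1)))
})

test_that("degenerate and invalid inputs are signalled", {
  catal <- default_catalog()
  x0 <- matrix(0, 4, 16, dimnames = list(paste0("s", 1:4),
                                         catal$abbreviation))
  u <- matrix(1, 4, 16)
  expect_warning(fit <- fit_pmf(x0, u, p = 2, n_starts = 1, seed = 1),
                 "identically zero")
  expect_equal(fit$Q, 0)
  expect_true(all(fit$G == 0))

  x <- matrix(1, 4, 16, dimnames = dimnames(x0))
  expect_error(fit_pmf(x, u, p = 5, n_starts = 1, seed = 1), "min\\(n, m\\)")
})

test_that("fits are deterministic in the seed and permutation invariant", {
  sim <- simulate_dataset(n = 15, seed = 13)
  u <- build_uncertainty(sim$x)
  a <- suppressWarnings(fit_pmf(sim$x, u, p = 3, n_starts = 2, seed = 7,
                                max_iter = 500))
  b <- suppressWarnings(fit_pmf(sim$x, u, p = 3, n_starts = 2, seed = 7,
                                max_iter = 500))
  expect_identical(a$G, b$G)
  expect_identical(a$Q, b$Q)

  perm <- c(3, 1, 2)
  recon <- a$G[, perm] %*% a$F[perm, ]
  expect_equal(recon, a$G %*% a$F, tolerance = 1e-12)
  expect_equal(oracle_q(unclass(sim$x), a$G[, perm], a$F[perm, ], u), a$Q,
               tolerance = 1e-10)
})

test_that("joint rescaling of X and U leaves Q invariant and scales GF", {
  sim <- simulate_dataset(n = 12, seed = 17)
  u <- build_uncertainty(sim$x)
  a <- suppressWarnings(fit_pmf(sim$x, u, p = 2, n_starts = 2, seed = 11,
                                max_iter = 800))
  xs <- as_concentration_matrix(unclass(sim$x) * 10)
  b <- suppressWarnings(fit_pmf(xs, u * 10, p = 2, n_starts = 2, seed = 11,
                                max_iter = 800))
  expect_equal(b$Q, a$Q, tolerance = 1e-6)
  expect_equal(b$G %*% b$F, 10 * (a$G %*% a$F), tolerance = 1e-6)
})

test_that("factor scan recommends the true source count on 4-source data", {
  sim <- simulate_dataset(n = 50, seed = 5)
  u <- build_uncertainty(sim$x)
  scan <- suppressWarnings(scan_factors(sim$x, u, seed = 1005, n_starts = 4,
                                        max_iter = 1500))
  expect_equal(scan$recommended_p, 4L)
  expect_equal(scan$table$p, 3:8)
  # capacity: fit quality does not deteriorate as p grows
  expect_true(all(diff(scan$table$r_squared) >= -0.01))
})

test_that("normalization preserves the reconstruction exactly", {
  sim <- simulate_dataset(n = 15, seed = 23)
  u <- build_uncertainty(sim$x)
  fit <- suppressWarnings(fit_pmf(sim$x, u, p = 3, n_starts = 2, seed = 3,
                                  max_iter = 500))
  norm <- normalize_profiles(fit)
  expect_equal(unname(rowSums(norm$f)), rep(1, 3), tolerance = 1e-9)
  expect_equal(norm$S %*% norm$f, fit$G %*% fit$F, tolerance = 1e-10)

  # all-zero factors are dropped with a warning
  fit$F[2, ] <- 0
  expect_warning(norm2 <- normalize_profiles(fit), "all-zero")
  expect_equal(norm2$p, 2L)
})

test_that("source labelling matches references and flags poor matches", {
  prof <- make_source_profiles(1)
  norm <- toy_normalized(S = matrix(1, 2, 4), f = prof)
  labels <- label_sources(norm, prof)
  expect_equal(as.character(labels), rownames(prof))
  expect_equal(attr(labels, "similarity"), rep(1, 4), tolerance = 1e-12)
  expect_false(any(attr(labels, "low_confidence")))

  # a factor orthogonal to every reference is flagged
  odd <- matrix(0, 1, 16)
  odd[1, 1] <- 1  # pure Naph
  refs <- prof
  refs[, 1] <- 0
  refs <- refs / rowSums(refs)
  norm2 <- toy_normalized(S = matrix(1, 2, 1), f = odd)
  lab2 <- label_sources(norm2, refs)
  expect_true(attr(lab2, "low_confidence")[1])
})

test_that("contribution percentages are symmetric and sum to 100", {
  norm <- toy_normalized(S = matrix(2.5, 4, 3),
                         f = matrix(1 / 16, 3, 16))
  pct <- source_contribution_percent(norm)
  expect_equal(unname(pct), rep(100 / 3, 3), tolerance = 1e-12)
  sim <- simulate_dataset(n = 15, seed = 29)
  u <- build_uncertainty(sim$x)
  fit <- suppressWarnings(fit_pmf(sim$x, u, p = 4, n_starts = 2, seed = 2,
                                  max_iter = 500))
  expect_equal(sum(source_contribution_percent(normalize_profiles(fit))),
               100, tolerance = 1e-6)
})

test_that("parameter recovery holds across seeded replicates", {
  reps <- lapply(1:3, function(r) {
    recovery_replicate(sim_seed = 100 + r, fit_seed = 200 + r,
                       n_starts = 5, max_iter = 1500)
  })
  mean_cos <- mean(vapply(reps, function(r) mean(r$cosines), numeric(1)))
  expect_gte(mean_cos, 0.95)
  # labels recovered for every factor in each replicate
  for (r in reps) {
    labs <- label_sources(r$normalized, r$sim$truth$profiles)
    expect_setequal(as.character(labs), rownames(r$sim$truth$profiles))
  }
})
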