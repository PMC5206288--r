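test_that("thermo_state stores beta = 1/(k_B T)", {
  st <- thermo_state(298)
  expect_equal(st$beta * 0.0019872041 * 298, 1, tolerance = 1e-9)
  expect_error(thermo_state(-1), "positive")
})

test_that("Zwanzig recovers trivial and Gaussian perturbations", {
  # identity and constant-shift perturbations are exact
  expect_equal(zwanzig_fep(c(0, 0, 0))$delta_g, 0)
  expect_equal(zwanzig_fep(rep(2.5, 10))$delta_g, 2.5)
  expect_equal(zwanzig_fep(rep(2.5, 10))$uncertainty, 0)

  # Gaussian dU: dG -> mu - beta sigma^2 / 2
  st <- thermo_state()
  mu <- 1.2; sig <- 0.8
  du <- with_seed(11, rnorm(1e6, mu, sig))
  est <- zwanzig_fep(du, st)
  expected <- mu - st$beta * sig^2 / 2
  expect_lt(abs(est$delta_g - expected), 3 * est$uncertainty)

  # numerically stable for very large energies (no Inf/NaN)
  big <- zwanzig_fep(c(1e4, 1e4 + 1, 1e4 + 2))
  expect_true(is.finite(big$delta_g))
  low <- zwanzig_fep(c(-1e4, -1e4 - 1))
  expect_true(is.finite(low$delta_g))

  expect_error(zwanzig_fep(numeric(0)), "no samples")
  expect_error(zwanzig_fep(c(1, NaN)), "finite")
})

test_that("Zwanzig obeys the Jensen bound dG <= mean(dU)", {
  for (s in 1:20) {
    du <- with_seed(s, rnorm(200, mean = runif(1, -3, 3),
                             sd = runif(1, 0.1, 2)))
    expect_lte(zwanzig_fep(du)$delta_g, mean(du) + 1e-12)
  }
})

test_that("MBAR: identical states give zero free-energy difference", {
  u <- with_seed(3, matrix(rnorm(200), nrow = 1))
  m <- reduced_potential_matrix(rbind(u, u), c(100, 100))
  fit <- mbar_free_energies(m)
  expect_equal(fit$delta_g[2], 0, tolerance = 1e-10)
})

test_that("MBAR recovers analytic harmonic free energies within 3 SE", {
  h <- make_harmonic_ensembles(c(1, 2.5, 6), n_per_state = 4000, seed = 7)
  fit <- mbar_free_energies(h$matrix)
  for (k in 2:3) {
    expect_lt(abs(fit$delta_g[k] - h$analytic_delta_g[k]),
              3 * fit$uncertainty[k])
  }
  expect_true(all(fit$uncertainty >= 0))
})

test_that("MBAR with two states equals the BAR bisection oracle", {
  h <- make_harmonic_ensembles(c(1, 4), n_per_state = 2000, seed = 5)
  fit <- mbar_free_energies(h$matrix, tol = 1e-12)
  u <- h$matrix$u
  idx0 <- 1:2000; idx1 <- 2001:4000
  w_f <- u[2, idx0] - u[1, idx0]
  w_r <- u[1, idx1] - u[2, idx1]
  bar_df <- bar_bisection_oracle(w_f, w_r)
  kT <- 1 / thermo_state()$beta
  expect_lt(abs(fit$delta_g[2] - bar_df * kT), 1e-6)
})

test_that("MBAR is invariant to a per-sample shift of the potentials", {
  h <- make_harmonic_ensembles(c(1, 3), n_per_state = 500, seed = 9)
  u <- h$matrix$u
  shift <- with_seed(10, rnorm(ncol(u)))
  u2 <- sweep(u, 2L, shift, "+")
  f1 <- mbar_free_energies(reduced_potential_matrix(u, h$matrix$n_k))
  f2 <- mbar_free_energies(reduced_potential_matrix(u2, h$matrix$n_k))
  expect_equal(f1$delta_g, f2$delta_g, tolerance = 1e-8)
})

test_that("MBAR without one state's samples degrades toward Zwanzig", {
  # samples only from state 1; the state-2 free energy must match the
  # one-sided exponential average on the same samples
  st <- thermo_state()
  h <- make_harmonic_ensembles(c(1, 2), n_per_state = 3000, seed = 13)
  u <- h$matrix$u[, 1:3000]
  fit <- mbar_free_energies(reduced_potential_matrix(u, c(3000, 0)))
  zw <- zwanzig_fep((u[2, ] - u[1, ]) / st$beta, st)
  expect_equal(fit$delta_g[2], zw$delta_g, tolerance = 1e-8)
})

test_that("MBAR input validation", {
  expect_error(mbar_free_energies(matrix(0, 1, 5), n_k = 5), "2 states")
  expect_error(reduced_potential_matrix(matrix(Inf, 2, 2), c(1, 1)),
               "finite")
  expect_error(reduced_potential_matrix(matrix(0, 2, 4), c(1, 1)),
               "sum")
  h <- make_harmonic_ensembles(c(1, 100), n_per_state = 10, seed = 2)
  expect_error(mbar_free_energies(h$matrix, max_iter = 1L),
               "did not converge")
})

test_that("two-run rule: mean, |g1-g2|/2 error, symmetry", {
  est <- run_pair_error(1.0, 2.0)
  expect_equal(est$delta_g, 1.5)
  expect_equal(est$uncertainty, 0.5)
  expect_equal(run_pair_error(-3, -3)$uncertainty, 0)
  expect_equal(run_pair_error(-3, -3)$delta_g, -3)
  a <- run_pair_error(0.7, -1.4); b <- run_pair_error(-1.4, 0.7)
  expect_equal(a$delta_g, b$delta_g)
  expect_equal(a$uncertainty, b$uncertainty)
  # err = 0 iff equal
  expect_gt(run_pair_error(1, 1 + 1e-9)$uncertainty, 0)
  expect_error(run_pair_error(Inf, 0), "finite")
})

test_that("statistical inefficiency: white noise, AR(1) and constants", {
  g_wn <- subsample_uncorrelated(with_seed(21, rnorm(1e5)))$g
  expect_lt(abs(g_wn - 1), 0.05)

  phi <- 0.9
  x <- with_seed(22, {
    e <- rnorm(1e5); out <- numeric(1e5); out[1] <- e[1]
    for (i in 2:1e5) out[i] <- phi * out[i - 1] + e[i]
    out
  })
  g_ar <- subsample_uncorrelated(x)$g
  expect_lt(abs(g_ar - 19) / 19, 0.15)

  cs <- subsample_uncorrelated(rep(3.2, 50))
  expect_equal(cs$g, 1)
  expect_equal(cs$indices, 1:50)

  s <- subsample_uncorrelated(x)
  expect_equal(s$stride, ceiling(s$g))
  expect_error(subsample_uncorrelated(1), "length")
})
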