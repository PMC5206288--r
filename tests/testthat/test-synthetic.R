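test_that("harmonic generator: analytic free energies and determinism", {
  st <- thermo_state()
  expect_equal(make_harmonic_ensembles(c(1, 1), 50, seed = 1)$analytic_delta_g,
               c(0, 0))
  h <- make_harmonic_ensembles(c(1, 4), 50, seed = 1)
  expect_equal(h$analytic_delta_g[2], log(4) / (2 * st$beta))

  a <- make_harmonic_ensembles(c(1, 2, 5), 100, seed = 42)
  b <- make_harmonic_ensembles(c(1, 2, 5), 100, seed = 42)
  expect_identical(a$matrix$u, b$matrix$u)
  c2 <- make_harmonic_ensembles(c(1, 2, 5), 100, seed = 43)
  expect_false(identical(a$matrix$u, c2$matrix$u))
  expect_error(make_harmonic_ensembles(c(1, -1), 10, seed = 1), "> 0")

  # generators restore the caller's RNG stream
  set.seed(123); x1 <- rnorm(1)
  set.seed(123); invisible(make_harmonic_ensembles(c(1, 2), 10, seed = 9))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("snapshot generator: solvent count matches an independent recount", {
  fx <- make_snapshot_fixture(n_frames = 15, n_solute_atoms = 3,
                              n_solvent = 150, box = c(40, 40, 40),
                              seed = 81)
  recount <- mean(vapply(fx$ensemble$frames, function(fr) {
    ctr <- colMeans(fr$solute)
    d <- sweep(fr$solvent, 2, ctr, "-")
    for (k in 1:3) d[, k] <- d[, k] - 40 * round(d[, k] / 40)
    sum(sqrt(rowSums(d^2)) < 12)
  }, numeric(1)))
  expect_equal(fx$n_s_avg, recount)
  expect_gt(fx$n_s_avg, 0)

  # density/box inconsistency is rejected
  expect_error(
    make_snapshot_fixture(n_solvent = 100, box = c(30, 30, 30),
                          solvent = lj_solvent(density = 0.05), seed = 1),
    "density/box")
})

test_that("zero-charge and zero-solvent fixtures give null corrections", {
  fx <- make_snapshot_fixture(n_frames = 8, n_solute_atoms = 4,
                              charges = rep(0, 4), seed = 82)
  expect_equal(func_correction(fx$ensemble, fx$topology)$delta_g, 0)

  fx0 <- make_snapshot_fixture(n_frames = 8, n_solute_atoms = 2,
                               n_solvent = 0, box = c(60, 60, 60),
                               seed = 83)
  est <- lj_long_range_correction(fx0$ensemble, fx0$topology, fx0$solvent,
                                  r_c_sim = 12)
  expect_equal(attr(est, "zwanzig_term"), 0)
})

test_that("species generator: noiseless recovery is exact", {
  ds <- make_species_dataset(n_molecules = 40, noise_sd = 0, seed = 91)
  out <- logd_from_species_table(ds$species)
  out <- out[match(ds$truth$molecule_id, out$molecule_id), ]
  expect_lt(max(abs(out$logd - ds$truth$logd_true)), 1e-10)
})

test_that("species generator: speciation weight -> 1 recovers pure logP", {
  # pKa_eff >> pH: the conjugate (acid) species takes all the weight
  ds <- make_species_dataset(n_molecules = 12, noise_sd = 0,
                             pka_mean = 25, pka_sd = 0.5, seed = 92)
  out <- logd_from_species_table(ds$species)
  out <- out[match(ds$truth$molecule_id, out$molecule_id), ]
  expect_lt(max(abs(out$logd - ds$truth$logp_con)), 1e-6)

  # pKa_eff << pH: all the weight moves to the dominant (base) species
  ds2 <- make_species_dataset(n_molecules = 12, noise_sd = 0,
                              pka_mean = -12, pka_sd = 0.5, seed = 92)
  out2 <- logd_from_species_table(ds2$species)
  out2 <- out2[match(ds2$truth$molecule_id, out2$molecule_id), ]
  expect_lt(max(abs(out2$logd - ds2$truth$logp_dom)), 1e-6)
})

test_that("species generator: noisy MUE matches the propagated closed form", {
  st <- thermo_state()
  noise_sd <- 0.5
  ds <- make_species_dataset(n_molecules = 100, noise_sd = noise_sd,
                             seed = 93)
  out <- logd_from_species_table(ds$species)
  out <- out[match(ds$truth$molecule_id, out$molecule_id), ]
  observed <- mue(out$logd, ds$truth$logd_true)

  # delta method: each species' transfer dG carries sd sqrt(2)*noise_sd,
  # i.e. per-species logP noise s; the logD noise combines the two terms
  # by their shares of the sum inside the log
  s <- sqrt(2) * noise_sd * st$beta / log(10)
  w_dom <- speciation_fraction(ds$truth$pka_eff, ds$truth$pH)
  t_con <- (1 - w_dom) * 10^ds$truth$logp_con
  t_dom <- w_dom * 10^ds$truth$logp_dom
  share_con <- t_con / (t_con + t_dom)
  share_dom <- 1 - share_con
  sd_logd <- s * sqrt(share_con^2 + share_dom^2)
  expected_mue <- mean(sqrt(2 / pi) * sd_logd)
  expect_lt(abs(observed - expected_mue) / expected_mue, 0.20)
})

test_that("end-to-end estimator error shrinks with more samples", {
  st <- thermo_state()
  k <- c(1, 2, 4, 8)
  errs <- vapply(c(200, 2000, 20000), function(n) {
    h <- make_harmonic_ensembles(k, n, seed = 17)
    fit <- mbar_free_energies(h$matrix)
    mue(fit$delta_g, h$analytic_delta_g)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
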