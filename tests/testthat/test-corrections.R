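test_that("Barker-Watts pair energy vanishes at and beyond the cutoff", {
  for (eps_rf in c(1, 2, 20, 82)) {
    expect_equal(bwrf_pair_energy(0.4, -0.3, 12, 12, eps_rf), 0)
    expect_equal(bwrf_pair_energy(0.4, -0.3, 15, 12, eps_rf), 0)
    # continuity: value just inside the cutoff tends to 0
    expect_lt(abs(bwrf_pair_energy(0.4, -0.3, 12 - 1e-7, 12, eps_rf)), 1e-4)
  }
  expect_equal(bwrf_pair_energy(0, 0.5, 5, 12, 82), 0)
  expect_error(bwrf_pair_energy(1, 1, -1, 12, 82), "r must be")
  # eps_rf = 1 reduces to truncated-shifted plain Coulomb at short range
  u <- bwrf_pair_energy(1, 1, 3, 1e6, 1)
  expect_equal(u, coulomb_pair_energy(1, 1, 3), tolerance = 1e-5)
})

test_that("functional-form correction: trivial cases", {
  fx <- make_snapshot_fixture(n_frames = 10, n_solute_atoms = 4, seed = 31)
  topo0 <- topology(charge = rep(0, 4),
                    epsilon = fx$topology$atoms$epsilon,
                    sigma = fx$topology$atoms$sigma,
                    bonds = cbind(1:3, 2:4))
  est <- func_correction(fx$ensemble, topo0, r_c = 12, eps_rf = 82)
  expect_equal(est$delta_g, 0)

  # rigid solute: Zwanzig of a constant is the constant
  one <- fx$ensemble$frames[[1]]
  rigid <- snapshot_ensemble(rep(list(one), 5), box = fx$ensemble$box)
  est_r <- func_correction(rigid, fx$topology, r_c = 12, eps_rf = 82)
  du <- brute_force_func_du(list(one), fx$topology$atoms$charge,
                            cbind(1:3, 2:4), 12, 82)
  expect_equal(est_r$delta_g, du[1], tolerance = 1e-10)
  expect_equal(est_r$uncertainty, 0)

  expect_error(snapshot_ensemble(list()), "zero frames")
})

test_that("functional-form correction matches the pairwise-sum oracle", {
  st <- thermo_state()
  fx <- make_snapshot_fixture(n_frames = 50, n_solute_atoms = 4,
                              jitter = 0.6, seed = 33)
  est <- func_correction(fx$ensemble, fx$topology, r_c = 12, eps_rf = 82,
                         state = st)
  du <- brute_force_func_du(fx$ensemble$frames, fx$topology$atoms$charge,
                            cbind(1:3, 2:4), 12, 82)
  oracle <- -log(mean(exp(-st$beta * du))) / st$beta
  expect_equal(est$delta_g, oracle, tolerance = 1e-8)
})

test_that("analytic LJ tail: trivial limits and quadrature oracle", {
  solv <- lj_solvent(epsilon = 0.25, sigma = 3.4, density = 0.007)
  topo <- topology(charge = 0, epsilon = 0.15, sigma = 3.2)
  expect_equal(lj_tail_analytic(topology(0, 0, 3), solv, 12), 0)

  # magnitude decays to zero as the cutoff grows, monotonically in the
  # attractive regime
  rcs <- c(10, 15, 20, 40, 80)
  vals <- vapply(rcs, function(rc) lj_tail_analytic(topo, solv, rc),
                 numeric(1))
  expect_true(all(diff(abs(vals)) < 0))
  expect_lt(abs(vals[length(vals)]), 1e-4)
  # negative once r_c exceeds sigma * 3^(1/6)
  for (rc in seq(4, 30, by = 2)) {
    expect_lt(lj_tail_analytic(topo, solv, rc), 0)
  }

  val <- lj_tail_analytic(topo, solv, 14)
  oracle <- quadrature_tail_oracle(sqrt(0.15 * 0.25), (3.2 + 3.4) / 2,
                                   0.007, 14)
  expect_equal(val, oracle, tolerance = 1e-6)

  # multi-atom solute: sum over all combination pairs
  topo2 <- topology(charge = c(0, 0), epsilon = c(0.1, 0.2),
                    sigma = c(3.0, 3.6), bonds = cbind(1, 2))
  val2 <- lj_tail_analytic(topo2, solv, 14)
  oracle2 <- quadrature_tail_oracle(sqrt(c(0.1, 0.2) * 0.25),
                                    (c(3.0, 3.6) + 3.4) / 2, 0.007, 14)
  expect_equal(val2, oracle2, tolerance = 1e-6)
})

test_that("LJ long-range correction: trivial cases", {
  fx <- make_snapshot_fixture(n_frames = 5, n_solute_atoms = 1,
                              n_solvent = 40, box = c(40, 40, 40),
                              seed = 41)
  # forced r_c_long == r_c_sim: the Zwanzig term is identically zero
  est <- lj_long_range_correction(fx$ensemble, fx$topology, fx$solvent,
                                  r_c_sim = 12, r_c_long = 12)
  expect_equal(attr(est, "zwanzig_term"), 0)
  expect_equal(est$delta_g,
               lj_tail_analytic(fx$topology, fx$solvent, 12))

  # no solvent and zero density: correction is exactly zero
  fx0 <- make_snapshot_fixture(n_frames = 5, n_solute_atoms = 1,
                               n_solvent = 0, box = c(60, 60, 60),
                               seed = 42)
  est0 <- lj_long_range_correction(fx0$ensemble, fx0$topology, fx0$solvent,
                                   r_c_sim = 12)
  expect_equal(est0$delta_g, 0)

  # box too small for the extended cutoff
  small <- make_snapshot_fixture(n_frames = 2, n_solute_atoms = 1,
                                 n_solvent = 10, box = c(20, 20, 20),
                                 seed = 43)
  expect_error(
    lj_long_range_correction(small$ensemble, small$topology,
                             small$solvent, r_c_sim = 12),
    "box too small")
})

test_that("LJ long-range Zwanzig term matches the double-loop oracle", {
  st <- thermo_state()
  fx <- make_snapshot_fixture(n_frames = 20, n_solute_atoms = 1,
                              n_solvent = 100, box = c(45, 45, 45),
                              seed = 44)
  est <- lj_long_range_correction(fx$ensemble, fx$topology, fx$solvent,
                                  r_c_sim = 12, state = st)
  r_c_long <- attr(est, "r_c_long")
  expect_equal(r_c_long, 0.95 * 45 / 2)
  du <- brute_force_ljlrc_du(fx$ensemble$frames, c(45, 45, 45),
                             fx$topology$atoms$epsilon,
                             fx$topology$atoms$sigma,
                             fx$solvent$epsilon, fx$solvent$sigma,
                             12, r_c_long)
  oracle <- -log(mean(exp(-st$beta * du))) / st$beta
  expect_equal(attr(est, "zwanzig_term"), oracle, tolerance = 1e-8)
})

test_that("summation-scheme correction: linearity, sign, spreadsheet", {
  w <- tip3p_solvent()
  # template quadrupole trace: 2 H at 0.9572 A from the origin-sited O
  expect_equal(w$gamma_s, 2 * 0.417 * 0.9572^2, tolerance = 1e-9)

  expect_equal(psum_correction(0, w, 12, 240), 0)
  v1 <- psum_correction(1, w, 12, 240)
  expect_equal(psum_correction(2, w, 12, 240), 2 * v1)
  expect_equal(psum_correction(-1, w, 12, 240), -v1)

  oracle <- psum_spreadsheet_oracle(-1, w$gamma_s, 12, 241.5,
                                    eps_bw = 82, eps0 = 78.3)
  expect_equal(psum_correction(-1, w, 12, 241.5), oracle,
               tolerance = 1e-6 * abs(oracle))

  # linear in gamma_s and in the bracket's n_s dependence
  w2 <- solvent_model(charge = w$charge * 2, xyz = w$xyz,
                      epsilon = w$epsilon, sigma = w$sigma,
                      density = w$density, eps_bw = w$eps_bw,
                      eps0_rel = w$eps0_rel)
  expect_equal(psum_correction(1, w2, 12, 240),
               2 * psum_correction(1, w, 12, 240))
  a <- psum_correction(1, w, 12, 0)
  b <- psum_correction(1, w, 12, 100)
  c2 <- psum_correction(1, w, 12, 200)
  expect_equal(c2 - b, b - a, tolerance = 1e-12)

  expect_error(psum_correction(1, w, -2, 10), "r_c")
  expect_error(psum_correction(1, w, 12, -1), "n_s_avg")
})

test_that("polarization pass-through forms the difference, never zero", {
  expect_equal(as.numeric(pol_correction(-5, -3)), -2)
  expect_equal(as.numeric(pol_correction(4.2, 4.2)), 0)
  expect_equal(as.numeric(pol_correction(-3, -5)),
               -as.numeric(pol_correction(-5, -3)))
  expect_error(pol_correction(NULL, 1), "required")
  expect_error(pol_correction(1), "required")
})

test_that("solvent model validates its stored quadrupole trace", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_error(solvent_model(c(-1, 1), xyz, c(0.1, 0), c(3, 1),
                             density = 0.01, gamma_s = 99),
               "gamma_s")
  m <- solvent_model(c(-1, 1), xyz, c(0.1, 0), c(3, 1), density = 0.01,
                     gamma_s = 1)
  expect_equal(m$gamma_s, 1)
})
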