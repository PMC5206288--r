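# Independent oracles, written without reference to the package internals.

# Bennett acceptance ratio for two states by root finding on the implicit
# equation. w_f = u1 - u0 at samples from state 0, w_r = u0 - u1 at samples
# from state 1 (dimensionless). Returns the dimensionless free-energy
# difference f1 - f0.
bar_bisection_oracle <- function(w_f, w_r, tol = 1e-12) {
  m <- log(length(w_f) / length(w_r))
  g <- function(df) {
    sum(1 / (1 + exp(m + w_f - df))) - sum(1 / (1 + exp(-m + w_r + df)))
  }
  stats::uniroot(g, lower = -200, upper = 200, tol = tol)$root
}

# plain-Coulomb / reaction-field intramolecular energies by an explicit
# double loop over frames and pairs (independent of the package's
# vectorized path). Exclusions and 1-4 scaling are recomputed here from
# the bond list.
brute_force_func_du <- function(frames, charge, bonds, r_c, eps_rf,
                                scale_14 = 1 / 1.2) {
  n <- length(charge)
  # bond-graph shortest paths by Floyd-Warshall
  d <- matrix(Inf, n, n); diag(d) <- 0
  if (!is.null(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      d[bonds[r, 1], bonds[r, 2]] <- 1
      d[bonds[r, 2], bonds[r, 1]] <- 1
    }
  }
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  kC <- 332.0637
  krf <- (eps_rf - 1) / ((2 * eps_rf + 1) * r_c^3)
  crf <- 3 * eps_rf / ((2 * eps_rf + 1) * r_c)
  vapply(frames, function(fr) {
    xyz <- fr$solute
    u_nc <- 0; u_sim <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sep <- d[i, j]
      sc <- if (sep <= 2) 0 else if (sep == 3) scale_14 else 1
      if (sc == 0) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      u_nc <- u_nc + sc * kC * charge[i] * charge[j] / r
      if (r < r_c) {
        u_sim <- u_sim + sc * kC * charge[i] * charge[j] *
          (1 / r + krf * r^2 - crf)
      }
    }
    u_nc - u_sim
  }, numeric(1))
}

# solute-solvent LJ energy differences by explicit double loop with
# minimum image (single-site solvent)
brute_force_ljlrc_du <- function(frames, box, eps_i, sig_i, eps_s, sig_s,
                                 r_c_sim, r_c_long) {
  u_at <- function(xyz_sol, xyz_solv, r_c) {
    tot <- 0
    for (a in seq_len(nrow(xyz_sol))) {
      for (b in seq_len(nrow(xyz_solv))) {
        dv <- xyz_solv[b, ] - xyz_sol[a, ]
        dv <- dv - box * round(dv / box)
        r <- sqrt(sum(dv^2))
        if (r < r_c) {
          e <- sqrt(eps_i[a] * eps_s)
          s <- (sig_i[a] + sig_s) / 2
          tot <- tot + 4 * e * ((s / r)^12 - (s / r)^6)
        }
      }
    }
    tot
  }
  vapply(frames, function(fr) {
    u_at(fr$solute, fr$solvent, r_c_long) - u_at(fr$solute, fr$solvent, r_c_sim)
  }, numeric(1))
}

# numeric radial quadrature of the dispersion tail for the same pair
# functional form the closed form integrates (u(r) = 2 eps [(s/r)^12 -
# (s/r)^6] over a uniform fluid of density rho)
quadrature_tail_oracle <- function(eps_ij, sig_ij, rho, r_c) {
  total <- 0
  for (k in seq_along(eps_ij)) {
    f <- function(r) {
      4 * pi * rho * r^2 * 2 * eps_ij[k] *
        ((sig_ij[k] / r)^12 - (sig_ij[k] / r)^6)
    }
    total <- total +
      stats::integrate(f, r_c, Inf, rel.tol = 1e-10)$value
  }
  total
}

# direct spreadsheet-style evaluation of the summation-scheme correction
psum_spreadsheet_oracle <- function(Q, gamma_s, r_c, n_s, eps_bw, eps0) {
  pref <- -(2 * pi / 3) * 332.0637 / eps0
  bracket <- (2 * (eps_bw + 1) / (2 * eps_bw + 1)) *
    n_s / ((4 / 3) * pi * r_c^3) + 3 / (2 * eps_bw + 1)
  pref * Q * gamma_s * bracket
}

# direct covariance-formula R^2
r2_formula_oracle <- function(pred, ref) {
  n <- length(pred)
  sxy <- sum((pred - mean(pred)) * (ref - mean(ref))) / (n - 1)
  sxy^2 / (stats::var(pred) * stats::var(ref))
}
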