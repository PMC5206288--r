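#' Barker-Watts reaction-field pair energy
#'
#' Electrostatic energy of a charge pair under an atom-based Barker-Watts
#' reaction field with cutoff `r_c` and continuum dielectric `eps_rf`:
#' u = C q1 q2 (1/r + k_rf r^2 - c_rf) for r <= r_c and 0 beyond, with
#' k_rf = (eps_rf - 1) / ((2 eps_rf + 1) r_c^3) and
#' c_rf = 3 eps_rf / ((2 eps_rf + 1) r_c), so the potential vanishes
#' continuously at the cutoff. C is the e^2/Angstrom -> kcal/mol factor.
#'
#' @param q1,q2 Charges (e).
#' @param r Separation(s), Angstrom (> 0); vectorized.
#' @param r_c Cutoff, Angstrom.
#' @param eps_rf Reaction-field dielectric constant (>= 1).
#' @return Energy in kcal/mol (vector of `length(r)`).
#' @export
bwrf_pair_energy <- function(q1, q2, r, r_c, eps_rf) {
  if (any(r <= 0)) stop("r must be > 0")
  if (r_c <= 0) stop("r_c must be > 0")
  k_rf <- (eps_rf - 1) / ((2 * eps_rf + 1) * r_c^3)
  c_rf <- 3 * eps_rf / ((2 * eps_rf + 1) * r_c)
  u <- alch_constants$coulomb * q1 * q2 * (1 / r + k_rf * r^2 - c_rf)
  u[r >= r_c] <- 0
  u
}

#' Plain Coulomb pair energy (no cutoff)
#'
#' @inheritParams bwrf_pair_energy
#' @return Energy in kcal/mol.
#' @export
coulomb_pair_energy <- function(q1, q2, r) {
  if (any(r <= 0)) stop("r must be > 0")
  alch_constants$coulomb * q1 * q2 / r
}

# Lennard-Jones pair energy, standard 4 eps convention.
lj_pair_energy <- function(eps, sig, r) {
  sr6 <- (sig / r)^6
  4 * eps * (sr6^2 - sr6)
}

# intramolecular electrostatic energy of one conformer under a pair
# potential function pot(q1, q2, r)
intramolecular_elec <- function(xyz, topo, pot) {
  p <- topo$pairs
  if (nrow(p) == 0L) return(0)
  d <- sqrt(rowSums((xyz[p$i, , drop = FALSE] - xyz[p$j, , drop = FALSE])^2))
  q <- topo$atoms$charge
  sum(p$coul_scale * pot(q[p$i], q[p$j], d))
}

#' Functional-form (cutoff-consistency) correction
#'
#' Free-energy correction that makes the intramolecular electrostatics of a
#' solute consistent between cutoff reaction-field solvated simulations and
#' no-cutoff Coulomb vacuum simulations. Evaluated by reprocessing solute
#' frames from the fully charged end state of the discharging leg:
#' dG = -beta^-1 ln < exp(-beta (U_nc - U_sim)) >, where U_nc uses plain
#' Coulomb and U_sim the Barker-Watts reaction-field form, both over the
#' same non-excluded intramolecular pairs and 1-4 scaling.
#'
#' @param ensemble A [snapshot_ensemble()] with solute frames.
#' @param topo The solute [topology()] (fully charged).
#' @param r_c Reaction-field cutoff, Angstrom.
#' @param eps_rf Reaction-field dielectric constant.
#' @param state A [thermo_state()].
#' @return A [free_energy_estimate()].
#' @export
func_correction <- function(ensemble, topo, r_c = alch_constants$cutoff_default,
                            eps_rf = alch_constants$eps_water_model,
                            state = thermo_state()) {
  if (!inherits(ensemble, "snapshot_ensemble")) stop("ensemble required")
  du <- vapply(ensemble$frames, function(fr) {
    xyz <- fr$solute
    u_nc <- intramolecular_elec(xyz, topo, coulomb_pair_energy)
    u_sim <- intramolecular_elec(
      xyz, topo, function(q1, q2, r) bwrf_pair_energy(q1, q2, r, r_c, eps_rf))
    u_nc - u_sim
  }, numeric(1))
  zwanzig_fep(du, state)
}

#' Analytic Lennard-Jones tail correction
#'
#' Closed-form solute-solvent dispersion energy beyond an extended cutoff,
#' assuming uniform solvent (g(r) = 1) and an infinitely large box:
#' U = 8 pi rho sum_i sum_j (eps_ij sigma_ij^12 / (9 r_c^9) -
#' eps_ij sigma_ij^6 / (3 r_c^3)), with Lorentz-Berthelot combination over
#' solute atoms i and solvent template sites j, and rho the solvent
#' molecule number density. The coefficients are used exactly as stated;
#' see the methods vignette for the pair-potential convention they imply.
#'
#' @param topo Solute [topology()].
#' @param solvent A [solvent_model()].
#' @param r_c_long Extended cutoff, Angstrom (> 0).
#' @return Energy in kcal/mol.
#' @export
lj_tail_analytic <- function(topo, solvent, r_c_long) {
  if (r_c_long <= 0) stop("r_c_long must be > 0")
  ei <- topo$atoms$epsilon; si <- topo$atoms$sigma
  ej <- solvent$epsilon;    sj <- solvent$sigma
  eps_ij <- sqrt(outer(ei, ej))
  sig_ij <- outer(si, sj, function(a, b) (a + b) / 2)
  8 * pi * solvent$density *
    sum(eps_ij * sig_ij^12 / (9 * r_c_long^9) -
        eps_ij * sig_ij^6 / (3 * r_c_long^3))
}

# solute-solvent LJ energy of one frame under a radial cutoff, orthorhombic
# minimum image; r < r_c included (r = r_c contributes zero-measure).
frame_lj_energy <- function(solute, solvent_xyz, eps_i, sig_i, eps_j, sig_j,
                            box, r_c) {
  if (is.null(solvent_xyz) || nrow(solvent_xyz) == 0L) return(0)
  total <- 0
  m <- nrow(solvent_xyz)
  for (a in seq_len(nrow(solute))) {
    d <- sweep(solvent_xyz, 2L, solute[a, ], "-")
    if (!is.null(box)) {
      for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
    r <- sqrt(rowSums(d^2))
    sel <- r < r_c
    if (any(sel)) {
      eps <- sqrt(eps_i[a] * eps_j[sel])
      sig <- (sig_i[a] + sig_j[sel]) / 2
      total <- total + sum(lj_pair_energy(eps, sig, r[sel]))
    }
  }
  total
}

# replicate the solvent template parameters over the solvent sites of a
# frame (sites are stored molecule-major)
solvent_site_params <- function(solvent, n_sites_total) {
  reps <- n_sites_total / solvent$n_sites
  if (reps != round(reps)) {
    stop("solvent site count is not a multiple of the template size")
  }
  list(eps = rep(solvent$epsilon, times = reps),
       sig = rep(solvent$sigma, times = reps))
}

#' Lennard-Jones long-range correction
#'
#' Dispersion correction obtained by re-evaluating the solute-solvent
#' Lennard-Jones energy of every frame at the simulation cutoff `r_c_sim`
#' and at an extended cutoff r_c_long = 0.95 min(Lx, Ly, Lz)/2 (minimum
#' image), applying the Zwanzig relation to the energy differences, and
#' adding the analytic tail [lj_tail_analytic()] beyond r_c_long.
#'
#' @param ensemble A [snapshot_ensemble()] whose frames carry solvent sites
#'   and whose box is recorded.
#' @param topo Solute [topology()].
#' @param solvent A [solvent_model()] (per-site LJ parameters and density).
#' @param r_c_sim Simulation cutoff, Angstrom.
#' @param state A [thermo_state()].
#' @param r_c_long Optional explicit extended cutoff (>= r_c_sim). When
#'   NULL (default) it is derived from the box; a derived value <=
#'   `r_c_sim` is an error ("box too small for extended cutoff").
#' @return A [free_energy_estimate()] whose `delta_g` includes the analytic
#'   tail; the Zwanzig and tail parts are attached as attributes
#'   `"zwanzig_term"` and `"tail_term"`.
#' @export
lj_long_range_correction <- function(ensemble, topo, solvent,
                                     r_c_sim = alch_constants$cutoff_default,
                                     state = thermo_state(),
                                     r_c_long = NULL) {
  state <- as_thermo_state(state)
  box <- ensemble$box
  if (is.null(r_c_long)) {
    if (is.null(box)) stop("box edges required to derive r_c_long")
    r_c_long <- alch_constants$rc_long_scale * min(box) / 2
    if (r_c_long <= r_c_sim) stop("box too small for extended cutoff")
  } else if (r_c_long < r_c_sim) {
    stop("box too small for extended cutoff")
  }
  ei <- topo$atoms$epsilon; si <- topo$atoms$sigma
  du <- vapply(ensemble$frames, function(fr) {
    if (is.null(fr$solvent) || nrow(fr$solvent) == 0L) return(0)
    sp <- solvent_site_params(solvent, nrow(fr$solvent))
    u_long <- frame_lj_energy(fr$solute, fr$solvent, ei, si, sp$eps, sp$sig,
                              box, r_c_long)
    u_sim <- frame_lj_energy(fr$solute, fr$solvent, ei, si, sp$eps, sp$sig,
                             box, r_c_sim)
    u_long - u_sim
  }, numeric(1))
  zw <- zwanzig_fep(du, state)
  tail <- lj_tail_analytic(topo, solvent, r_c_long)
  out <- free_energy_estimate(zw$delta_g + tail, zw$uncertainty, "zwanzig")
  attr(out, "zwanzig_term") <- zw$delta_g
  attr(out, "tail_term") <- tail
  attr(out, "r_c_long") <- r_c_long
  out
}

#' Summation-scheme correction for net-charged solutes
#'
#' Correction for the artefact of atom-based cutoff electrostatics acting
#' on a solute of net charge Q: an apparent solvation of anions and
#' de-solvation of cations. Evaluated as
#' dG = -(N_A / (6 eps0)) Q gamma_s ((2 (eps_bw + 1) / (2 eps_bw + 1)) *
#' <N_s(r_c)> / (4 pi r_c^3 / 3) + 3 / (2 eps_bw + 1)),
#' with gamma_s the solvent quadrupole trace (e A^2), <N_s(r_c)> the mean
#' number of solvent molecules within the cutoff and eps0 the experimental
#' relative permittivity of the solvent. The prefactor N_A/(6 eps_vac) in
#' e/Angstrom units equals (2 pi / 3) * 332.0637 kcal/mol; the bracket is
#' applied exactly as stated (see the methods vignette for the unit
#' bookkeeping of its two terms).
#'
#' @param Q_mol Solute net charge (e).
#' @param solvent A [solvent_model()] supplying gamma_s, eps_bw and
#'   eps0_rel.
#' @param r_c Cutoff, Angstrom (> 0).
#' @param n_s_avg Mean number of solvent molecules within r_c (>= 0).
#' @param eps_bw,eps0_rel Optional overrides of the solvent model values.
#' @return Energy in kcal/mol.
#' @export
psum_correction <- function(Q_mol, solvent, r_c, n_s_avg,
                            eps_bw = solvent$eps_bw,
                            eps0_rel = solvent$eps0_rel) {
  if (r_c <= 0) stop("r_c must be > 0")
  if (n_s_avg < 0) stop("n_s_avg must be >= 0")
  bracket <- (2 * (eps_bw + 1) / (2 * eps_bw + 1)) *
    n_s_avg / (4 * pi * r_c^3 / 3) + 3 / (2 * eps_bw + 1)
  -(2 * pi / 3) * alch_constants$coulomb / eps0_rel *
    Q_mol * solvent$gamma_s * bracket
}

#' Polarization / periodicity correction (pass-through)
#'
#' Difference between the electrostatic free energy under non-periodic
#' Coulomb conditions and under periodic reaction-field conditions, both
#' obtained from an external Poisson solver. This function only forms the
#' difference and records provenance; it never substitutes a silent zero
#' for a missing input.
#'
#' @param dg_np_coul Non-periodic Coulomb electrostatic free energy,
#'   kcal/mol.
#' @param dg_rf_coul Periodic reaction-field electrostatic free energy,
#'   kcal/mol.
#' @return Numeric correction in kcal/mol with attribute `"provenance"`.
#' @export
pol_correction <- function(dg_np_coul, dg_rf_coul) {
  if (missing(dg_np_coul) || missing(dg_rf_coul) ||
      is.null(dg_np_coul) || is.null(dg_rf_coul)) {
    stop("both Poisson-solver inputs are required; no silent zero")
  }
  if (!is.finite(dg_np_coul) || !is.finite(dg_rf_coul)) {
    stop("inputs must be finite")
  }
  out <- dg_np_coul - dg_rf_coul
  attr(out, "provenance") <- "external Poisson solver difference"
  out
}

#' Correction set for one molecule/phase
#'
#' Container for the post-processing correction terms of a solvated phase.
#' Absent terms stay NULL and are reported as absent rather than zero.
#'
#' @param dg_func Functional-form correction, kcal/mol (or
#'   [free_energy_estimate()]).
#' @param dg_ljlrc Lennard-Jones long-range correction.
#' @param dg_pol Polarization correction.
#' @param dg_psum Summation-scheme correction.
#' @return Object of class `correction_set`.
#' @export
correction_set <- function(dg_func = NULL, dg_ljlrc = NULL, dg_pol = NULL,
                           dg_psum = NULL) {
  wrap <- function(x) if (is.null(x)) NULL else as_fee(x)
  structure(list(dg_func = wrap(dg_func), dg_ljlrc = wrap(dg_ljlrc),
                 dg_pol = wrap(dg_pol), dg_psum = wrap(dg_psum)),
            class = "correction_set")
}

#' @export
print.correction_set <- function(x, ...) {
  for (nm in names(x)) {
    if (is.null(x[[nm]])) cat(sprintf("%-9s absent\n", nm))
    else cat(sprintf("%-9s %+.4f +/- %.4f kcal/mol\n", nm,
                     x[[nm]]$delta_g, x[[nm]]$uncertainty))
  }
  invisible(x)
}
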