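#' Harmonic-oscillator sampling fixture with analytic free energies
#'
#' Draws exact Boltzmann samples from K one-dimensional harmonic
#' oscillators U_k(x) = k_k x^2 / 2 (x ~ Normal(0, 1/(beta k_k))) and
#' builds the K x N reduced-potential matrix over the pooled samples. The
#' analytic free energies dG_k = (2 beta)^-1 ln(k_k / k_1) are returned for
#' oracle comparison. Deterministic for a fixed seed.
#'
#' @param spring_constants Vector of spring constants (kcal/mol/A^2, > 0),
#'   one per state.
#' @param n_per_state Samples drawn from each state.
#' @param state A [thermo_state()].
#' @param seed RNG seed.
#' @return A list with `matrix` (a [reduced_potential_matrix()]),
#'   `analytic_delta_g` (kcal/mol, relative to state 1) and `samples`.
#' @export
make_harmonic_ensembles <- function(spring_constants, n_per_state,
                                    state = thermo_state(), seed = 1L) {
  state <- as_thermo_state(state)
  k <- as.numeric(spring_constants)
  if (any(k <= 0)) stop("spring constants must be > 0")
  K <- length(k)
  b <- state$beta
  x <- with_seed(seed, {
    unlist(lapply(k, function(kk) {
      stats::rnorm(n_per_state, mean = 0, sd = sqrt(1 / (b * kk)))
    }))
  })
  # reduced potential of every sample under every state
  u <- outer(b * k / 2, x^2)
  list(
    matrix = reduced_potential_matrix(u, rep(n_per_state, K)),
    analytic_delta_g = log(k / k[1L]) / (2 * b),
    samples = x
  )
}

#' Synthetic snapshot ensemble for correction-term oracles
#'
#' Builds a reproducible ensemble of a small flexible solute in an
#' (optional) single-site Lennard-Jones solvent bath: solute conformers
#' are drawn by jittering a random compact template near the box center,
#' and solvent molecules are placed uniformly in the box. The mean number
#' of solvent molecules within `count_radius` of the solute geometric
#' center is re-counted from the generated frames and reported, for use by
#' the summation-scheme correction.
#'
#' @param n_frames Number of frames.
#' @param n_solute_atoms Number of solute atoms.
#' @param n_solvent Number of solvent molecules (single-site; 0 allowed).
#' @param box Length-3 box edges, Angstrom.
#' @param charges Optional per-atom solute charges; default random charges
#'   summing to `net_charge`.
#' @param net_charge Solute net charge used when drawing charges.
#' @param jitter Conformational jitter amplitude, Angstrom.
#' @param solvent A [solvent_model()]; default a one-site LJ fluid with the
#'   density implied by `n_solvent` and `box`.
#' @param bonds Solute bond list (default a linear chain).
#' @param count_radius Radius for the solvent count, Angstrom.
#' @param seed RNG seed.
#' @return A list with `ensemble` ([snapshot_ensemble()]), `topology`,
#'   `solvent` ([solvent_model()]), and `n_s_avg`.
#' @export
make_snapshot_fixture <- function(n_frames = 20L, n_solute_atoms = 4L,
                                  n_solvent = 0L, box = c(60, 60, 60),
                                  charges = NULL, net_charge = 0,
                                  jitter = 0.3, solvent = NULL,
                                  bonds = NULL, count_radius = 12,
                                  seed = 1L) {
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive edges")
  n_a <- n_solute_atoms
  if (is.null(bonds) && n_a > 1L) {
    bonds <- cbind(seq_len(n_a - 1L), 2:n_a)
  }
  density <- if (n_solvent > 0) n_solvent / prod(box) else 0
  if (is.null(solvent)) solvent <- lj_solvent(density = density)
  if (n_solvent > 0 && abs(solvent$density * prod(box) - n_solvent) > 0.5) {
    stop("density/box inconsistency: solvent model density does not match n_solvent in this box")
  }

  out <- with_seed(seed, {
    if (is.null(charges)) {
      q <- stats::runif(n_a, -0.5, 0.5)
      q <- q - mean(q) + net_charge / n_a
    } else {
      q <- charges
    }
    topo <- topology(
      charge = q,
      epsilon = stats::runif(n_a, 0.05, 0.25),
      sigma = stats::runif(n_a, 2.5, 3.8),
      bonds = bonds
    )
    template <- matrix(stats::rnorm(n_a * 3, sd = 1.2), ncol = 3L)
    center <- box / 2
    frames <- lapply(seq_len(n_frames), function(f) {
      sol <- template + matrix(stats::rnorm(n_a * 3, sd = jitter), ncol = 3L)
      sol <- sweep(sol, 2L, center - colMeans(sol), "+")
      solv <- NULL
      if (n_solvent > 0) {
        solv <- cbind(stats::runif(n_solvent, 0, box[1L]),
                      stats::runif(n_solvent, 0, box[2L]),
                      stats::runif(n_solvent, 0, box[3L]))
      }
      list(solute = sol, solvent = solv)
    })
    list(topo = topo, frames = frames)
  })

  ens <- snapshot_ensemble(out$frames, box = box)
  n_s_avg <- mean(vapply(out$frames, function(fr) {
    if (is.null(fr$solvent)) return(0)
    ctr <- colMeans(fr$solute)
    d <- sweep(fr$solvent, 2L, ctr, "-")
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    sum(sqrt(rowSums(d^2)) < count_radius)
  }, numeric(1)))

  list(ensemble = ens, topology = out$topo, solvent = solvent,
       n_s_avg = n_s_avg)
}

#' Synthetic species dataset with known ground-truth logD
#'
#' Draws, per molecule, a conjugate/dominant species pair with true
#' partition coefficients (log P values) and an effective pKa, computes the
#' true two-species logD, then emits the corresponding transfer free
#' energies with Gaussian noise of `noise_sd` added independently to every
#' per-phase free energy (so each transfer free energy carries noise of
#' sd sqrt(2) * noise_sd). The conjugate (neutral) species dominates the
#' partition by construction, mirroring the regime in which charged forms
#' hardly enter the organic phase.
#'
#' @param n_molecules Number of molecules (>= 1).
#' @param logp_con_mean,logp_con_sd Distribution of the conjugate-species
#'   true log P.
#' @param logp_gap_range The dominant-species log P is lower than the
#'   conjugate's by Uniform(min, max) of this range.
#' @param pka_mean,pka_sd Distribution of the effective pKa.
#' @param pH pH of the aqueous phase (default 7.4).
#' @param noise_sd Gaussian noise on each per-phase free energy, kcal/mol
#'   (>= 0).
#' @param state A [thermo_state()].
#' @param seed RNG seed.
#' @return A list with `species` (one row per species: molecule_id,
#'   species_id, role, f_dom, pH, pka_eff, dg_w, dg_cyc, dg_err) and
#'   `truth` (one row per molecule: true log P values, pKa_eff and
#'   logd_true).
#' @export
make_species_dataset <- function(n_molecules = 50L, logp_con_mean = 2,
                                 logp_con_sd = 1.5,
                                 logp_gap_range = c(3, 8),
                                 pka_mean = 7.4, pka_sd = 1.5, pH = 7.4,
                                 noise_sd = 0, state = thermo_state(),
                                 seed = 1L) {
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  state <- as_thermo_state(state)
  kT <- 1 / state$beta

  with_seed(seed, {
    logp_con <- stats::rnorm(n_molecules, logp_con_mean, logp_con_sd)
    logp_dom <- logp_con -
      stats::runif(n_molecules, logp_gap_range[1L], logp_gap_range[2L])
    pka_eff <- stats::rnorm(n_molecules, pka_mean, pka_sd)
    logd_true <- mapply(function(pc, pd, pk) {
      logd_two_species(10^pc, 10^pd, pk, pH)
    }, logp_con, logp_dom, pka_eff)
    f_dom <- speciation_fraction(pka_eff, pH)

    # transfer dG per species; split into arbitrary water and cyclohexane
    # legs, each of which receives independent noise
    dg_t_con <- -logp_con * LN10 * kT
    dg_t_dom <- -logp_dom * LN10 * kT
    dg_w_con <- stats::rnorm(n_molecules, -5, 2)
    dg_w_dom <- stats::rnorm(n_molecules, -5, 2)

    noisy <- function(x) x + stats::rnorm(length(x), 0, noise_sd)
    mk <- function(role, dg_w, dg_t) {
      data.frame(
        molecule_id = sprintf("mol%03d", seq_len(n_molecules)),
        species_id = sprintf("mol%03d_%s", seq_len(n_molecules), role),
        role = role,
        f_dom = f_dom, pH = pH, pka_eff = pka_eff,
        dg_w = noisy(dg_w), dg_cyc = noisy(dg_w + dg_t),
        dg_err = noise_sd,
        stringsAsFactors = FALSE
      )
    }
    species <- rbind(mk("conjugate", dg_w_con, dg_t_con),
                     mk("dominant", dg_w_dom, dg_t_dom))
    species <- species[order(species$molecule_id, species$role), ]
    rownames(species) <- NULL

    truth <- data.frame(
      molecule_id = sprintf("mol%03d", seq_len(n_molecules)),
      logp_con = logp_con, logp_dom = logp_dom,
      pka_eff = pka_eff, pH = pH, f_dom = f_dom,
      logd_true = logd_true,
      stringsAsFactors = FALSE
    )
    list(species = species, truth = truth)
  })
}

#' Two-species logD pipeline over a species table
#'
#' Runs the two-species model on a species table as produced by
#' [make_species_dataset()] or [read_species_table()]: per molecule, each
#' species' transfer free energy (dg_cyc - dg_w) is converted to a
#' partition coefficient and combined through the effective pKa.
#'
#' @param species Species data.frame (long format, roles "conjugate" and
#'   "dominant").
#' @param state A [thermo_state()].
#' @return A data.frame with one row per molecule: `molecule_id`, `logd`,
#'   `pka_eff`, `ph`.
#' @export
logd_from_species_table <- function(species, state = thermo_state()) {
  state <- as_thermo_state(state)
  split_list <- split(species, species$molecule_id)
  rows <- lapply(split_list, function(df) {
    con <- df[df$role == "conjugate", , drop = FALSE]
    dom <- df[df$role == "dominant", , drop = FALSE]
    if (nrow(con) != 1L || nrow(dom) != 1L) {
      stop(sprintf("molecule %s needs exactly one conjugate and one dominant species",
                   df$molecule_id[1L]))
    }
    pka <- resolve_pka_eff(
      pka_eff = if ("pka_eff" %in% names(dom)) dom$pka_eff else NULL,
      f_dom = if ("f_dom" %in% names(dom)) dom$f_dom else NULL,
      pH = dom$pH)
    p_con <- partition_from_transfer(con$dg_cyc - con$dg_w, state)
    p_dom <- partition_from_transfer(dom$dg_cyc - dom$dg_w, state)
    data.frame(molecule_id = df$molecule_id[1L],
               logd = logd_two_species(p_con, p_dom, pka, dom$pH),
               pka_eff = pka, ph = dom$pH, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
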