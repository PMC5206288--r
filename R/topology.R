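#' Solute topology
#'
#' Per-atom non-bonded parameters plus the intramolecular exclusion table
#' used by the cutoff-consistency correction. Exclusions follow the Amber
#' convention: 1-2 and 1-3 pairs are excluded, 1-4 electrostatics are
#' scaled by `scale_14` (default 1/1.2), all other pairs interact fully.
#'
#' @param charge Per-atom partial charges (elementary charges).
#' @param epsilon Per-atom Lennard-Jones well depths (kcal/mol, >= 0).
#' @param sigma Per-atom Lennard-Jones distances (Angstrom, > 0).
#' @param bonds Two-column matrix/data.frame of 1-based atom indices, one
#'   row per covalent bond, or NULL for an unbonded (all pairs interacting)
#'   topology.
#' @param scale_14 Electrostatic scale factor for 1-4 pairs.
#' @return Object of class `topology` with fields `atoms` (data.frame),
#'   `pairs` (data.frame `i`, `j`, `coul_scale` for all pairs with nonzero
#'   interaction), `net_charge` and `n_atoms`.
#' @export
topology <- function(charge, epsilon, sigma, bonds = NULL,
                     scale_14 = 1 / 1.2) {
  n <- length(charge)
  if (length(epsilon) != n || length(sigma) != n) {
    stop("charge, epsilon and sigma must have equal length")
  }
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  sep <- bond_separation(n, bonds)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pr[, 1L]; j <- pr[, 2L]
  s <- sep[cbind(i, j)]
  coul_scale <- ifelse(s <= 3, 0, ifelse(s == 4, scale_14, 1))
  keep <- coul_scale > 0
  structure(list(
    atoms = data.frame(charge = charge, epsilon = epsilon, sigma = sigma),
    pairs = data.frame(i = i[keep], j = j[keep],
                       coul_scale = coul_scale[keep]),
    net_charge = sum(charge),
    n_atoms = n
  ), class = "topology")
}

# shortest bond-path separation (in atoms, i.e. bonded neighbours are 2
# apart in the 1-2/1-3/1-4 naming); Inf where disconnected.
bond_separation <- function(n, bonds) {
  d <- matrix(Inf, n, n)
  diag(d) <- 1
  if (is.null(bonds) || NROW(bonds) == 0L) return(d)
  bonds <- as.matrix(bonds)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1L]; b <- bonds[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  for (start in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[start] <- 1
    frontier <- start
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (dist[w] > dist[v] + 1) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    d[start, ] <- dist
  }
  d
}

#' Solvent model
#'
#' A rigid solvent molecule template (site charges, positions relative to a
#' reference site, Lennard-Jones parameters) plus bulk properties. The
#' quadrupole-moment trace gamma_s = sum_i q_i |r_i|^2 (e Angstrom^2) is
#' computed from the template; positions should be expressed relative to
#' the molecular reference point used by the summation-scheme correction
#' (the oxygen for water-like models).
#'
#' @param charge Per-site charges (e).
#' @param xyz n x 3 matrix of site positions (Angstrom).
#' @param epsilon,sigma Per-site LJ parameters (kcal/mol, Angstrom).
#' @param density Bulk number density of solvent molecules (mol per
#'   Angstrom^3, i.e. molecules/A^3).
#' @param eps_bw Dielectric constant of the solvent model as used with the
#'   reaction field (82 for the water model).
#' @param eps0_rel Experimental relative permittivity of the solvent
#'   (enters the summation-scheme prefactor; 78.3 for water).
#' @param gamma_s Optional stored quadrupole trace; validated against the
#'   template to 1e-9 if supplied.
#' @return Object of class `solvent_model`.
#' @export
solvent_model <- function(charge, xyz, epsilon, sigma, density,
                          eps_bw = alch_constants$eps_water_model,
                          eps0_rel = alch_constants$eps_water_experimental,
                          gamma_s = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  n <- length(charge)
  if (nrow(xyz) != n || length(epsilon) != n || length(sigma) != n) {
    stop("template fields must all describe the same number of sites")
  }
  if (density < 0) stop("density must be >= 0")
  g <- sum(charge * rowSums(xyz^2))
  if (!is.null(gamma_s) && abs(gamma_s - g) > 1e-9) {
    stop(sprintf("stored gamma_s (%g) disagrees with template (%g)",
                 gamma_s, g))
  }
  structure(list(
    charge = charge, xyz = xyz, epsilon = epsilon, sigma = sigma,
    density = density, eps_bw = eps_bw, eps0_rel = eps0_rel,
    gamma_s = g, n_sites = n
  ), class = "solvent_model")
}

#' Single-site Lennard-Jones solvent
#'
#' Convenience constructor for an apolar one-site solvent model.
#'
#' @param epsilon,sigma LJ parameters of the site.
#' @param density Number density (molecules per Angstrom^3).
#' @param eps_bw,eps0_rel Dielectric constants (default 1: apolar).
#' @return A [solvent_model()].
#' @export
lj_solvent <- function(epsilon = 0.2, sigma = 3.5, density = 0.005,
                       eps_bw = 1, eps0_rel = 1) {
  solvent_model(charge = 0, xyz = matrix(0, 1, 3), epsilon = epsilon,
                sigma = sigma, density = density, eps_bw = eps_bw,
                eps0_rel = eps0_rel)
}

#' TIP3P-like water template
#'
#' Three-site water geometry (O at the origin, OH 0.9572 Angstrom, HOH
#' 104.52 degrees) with TIP3P charges and oxygen LJ parameters, for use in
#' the summation-scheme correction and related tests.
#'
#' @param density Number density in molecules per Angstrom^3 (default the
#'   ambient-water value 0.03342).
#' @return A [solvent_model()].
#' @export
tip3p_solvent <- function(density = 0.03342) {
  r_oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  xyz <- rbind(c(0, 0, 0),
               c(r_oh * sin(half),  r_oh * cos(half), 0),
               c(-r_oh * sin(half), r_oh * cos(half), 0))
  solvent_model(charge = c(-0.834, 0.417, 0.417), xyz = xyz,
                epsilon = c(0.1521, 0, 0), sigma = c(3.1507, 1, 1),
                density = density)
}

#' Snapshot ensemble
#'
#' A set of frames holding solute coordinates, optional solvent-site
#' coordinates and the (orthorhombic) box edges, as produced by
#' post-processable trajectories or by [make_snapshot_fixture()].
#'
#' @param frames List of frames; each frame is a list with `solute`
#'   (n_atoms x 3 matrix, Angstrom) and optionally `solvent` (m x 3 matrix
#'   of solvent sites).
#' @param box Length-3 vector of box edges (Angstrom), or NULL for
#'   non-periodic ensembles.
#' @return Object of class `snapshot_ensemble`.
#' @export
snapshot_ensemble <- function(frames, box = NULL) {
  if (length(frames) == 0L) stop("zero frames")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(box <= 0)) {
      stop("box must be three positive edge lengths")
    }
  }
  structure(list(frames = frames, box = box, n_frames = length(frames)),
            class = "snapshot_ensemble")
}
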