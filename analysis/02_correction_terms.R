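#!/usr/bin/env Rscript
# Correction-term survey on synthetic snapshot ensembles: the cutoff
# consistency (FUNC), LJ long-range (Zwanzig + analytic tail) and
# summation-scheme (PSUM) terms at the simulation conditions (12 A cutoff,
# eps_rf 82 in water, extended cutoff 0.95 min(L)/2).
# Writes results/correction_terms.csv.

suppressPackageStartupMessages(library(alchlogd))
dir.create("results", showWarnings = FALSE)
st <- thermo_state()

# flexible polar 4-atom solute, no solvent: FUNC term
fx <- make_snapshot_fixture(n_frames = 50, n_solute_atoms = 4,
                            jitter = 0.5, net_charge = 0, seed = 11)
func <- func_correction(fx$ensemble, fx$topology, r_c = 12, eps_rf = 82,
                        state = st)

# one-site solute in an LJ bath: long-range dispersion
fy <- make_snapshot_fixture(n_frames = 20, n_solute_atoms = 1,
                            n_solvent = 150, box = c(45, 45, 45), seed = 12)
ljlrc <- lj_long_range_correction(fy$ensemble, fy$topology, fy$solvent,
                                  r_c_sim = 12, state = st)

# summation-scheme correction for +/- 1 solutes in TIP3P-like water with
# the ambient-density solvent count at the 12 A cutoff
w <- tip3p_solvent()
n_s <- w$density * 4 / 3 * pi * 12^3
psum_pos <- psum_correction(+1, w, 12, n_s)
psum_neg <- psum_correction(-1, w, 12, n_s)

out <- data.frame(
  term = c("FUNC", "LJLRC_total", "LJLRC_zwanzig", "LJLRC_tail",
           "PSUM_cation", "PSUM_anion"),
  value_kcal_mol = c(func$delta_g, ljlrc$delta_g,
                     attr(ljlrc, "zwanzig_term"), attr(ljlrc, "tail_term"),
                     psum_pos, psum_neg),
  uncertainty = c(func$uncertainty, ljlrc$uncertainty, NA, NA, NA, NA))
write.csv(out, "results/correction_terms.csv", row.names = FALSE)
print(out, digits = 4, row.names = FALSE)
cat(sprintf("\nExtended cutoff used: %.3f A. The dispersion terms are\n",
            attr(ljlrc, "r_c_long")))
cat("negative (missing attraction beyond the cutoff); the summation-scheme\n")
cat("term is antisymmetric in the solute charge, de-solvating cations and\n")
cat("apparently solvating anions.\n")
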