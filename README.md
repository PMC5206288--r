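# alchlogd

Post-processing toolkit for alchemical solvation free-energy calculations
and water/cyclohexane distribution-coefficient (logD) prediction, written
for computational chemists benchmarking free-energy protocols on small
drug-like molecules.

Alchemical simulations give per-leg free energies (a *discharging* step
turning off partial charges, a *vanishing* step turning off Lennard-Jones
interactions, in solvent and in vacuum). Everything downstream of the
sampling lives here:

- **Estimators** — the Zwanzig relation
  (dG = −β⁻¹ ln⟨exp(−β ΔU)⟩, log-sum-exp stable), MBAR over multiple
  alchemical states with asymptotic uncertainties, autocorrelation
  subsampling, and the two-run error rule err(ΔG) = σ/√2.
- **Corrections** for simulations run with atom-based Barker–Watts
  reaction-field electrostatics (12 Å cutoff): intramolecular
  functional-form consistency (FUNC), Lennard-Jones long-range dispersion
  with analytic tail (LJLRC), the summation-scheme artefact for net-charged
  solutes (PSUM), and a strict pass-through for Poisson-solver polarization
  corrections (POL).
- **Models A–D** assembling solvation free energies (A: raw legs + FUNC;
  B: + LJLRC; C: + POL + PSUM; D: model C for charged species only), the
  transfer free energy ΔG(w→cyc) = ΔG(cyc) − ΔG(w) − ΔG(v→v), and
  logD = −β ΔG / ln 10.
- **Two-species speciation**: effective pKa from predicted dominant-species
  fractions, pKa_eff = pH − log10(f/(1−f)), and the pH-weighted two-species
  logD with its reduction to the common pKa-corrected logP.
- **Benchmark statistics**: MUE, R², MUD, and the 10 000-replicate
  parametric bootstrap reporting 95 % intervals as z− < μ < z+.
- **Synthetic data** with analytic ground truth (harmonic-oscillator
  ensembles, snapshot fixtures, species datasets) so the whole pipeline is
  testable without molecular-dynamics output, plus a packaged reference
  table of benchmark solvation free energies (Minnesota solvation set,
  13 water / 11 cyclohexane molecules, models A–D).

## Worked example

```r
library(alchlogd)

# assemble a hydration free energy under model A
legs <- solvation_legs(
  water  = list(elec = -10, vdw = -2),
  vacuum = list(elec = -8,  vdw = -1),
  water_corrections = correction_set(dg_func = 0.3))
solvation_free_energy(legs, "water", "A")
#> dG = -2.7000 +/- 0.0000 kcal/mol [assembled]

# a transfer free energy of -1.3637 kcal/mol is one logD unit at 298 K
logd_dominant(-1.3637)$logd
#> [1] 1.000102

# two-species logD: neutral acid (P = 100) with pKa_eff 6.4 at pH 7.4
logd_two_species(p_con = 100, p_dom = 1e-6, pka_eff = 6.4, pH = 7.4)
#> [1] 0.9586073   # = log10(100) - log10(11), the ionization penalty

# MBAR on an analytically solvable fixture
h <- make_harmonic_ensembles(c(1, 4), n_per_state = 5000, seed = 42)
mbar_free_energies(h$matrix)$delta_g[2]   # analytic value: 0.4105
#> [1] 0.4127
```

The numbered scripts under `analysis/` run the full studies and write
their tables to `results/`:

```sh
Rscript analysis/01_validate_estimators.R   # MBAR/Zwanzig vs closed forms
Rscript analysis/02_correction_terms.R      # FUNC/LJLRC/PSUM on fixtures
Rscript analysis/03_benchmark_metrics.R     # bootstrap MUE/R2 per model
Rscript analysis/04_two_species_recovery.R  # noise-recovery study
```

`analysis/03_benchmark_metrics.R` prints, per phase/model/subset, lines
such as

```
water        model A all      (n=13): MUE = 3.58 < 3.63 < 3.69
water        model D all      (n=13): MUE = 0.71 < 0.77 < 0.84
cyclohexane  model C all      (n=11): R2 = 0.37 < 0.44 < 0.50
```

i.e. the bootstrap mean with its 95 % percentile interval: hydration free
energies are accurate to ~0.6–0.8 kcal/mol for neutral molecules, the
ionic species are repaired by the finite-size charging corrections
(model C/D), and the same corrections *degrade* cyclohexane solvation —
the central benchmark finding this package reproduces.

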