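---
title: "Methods: free-energy post-processing and distribution-coefficient prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy post-processing and distribution-coefficient prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchlogd)
```

## The problem

The water/cyclohexane distribution coefficient of a drug-like molecule,

$$\log D = \log_{10}\frac{\sum_i [A_i]_{\mathrm{cyc}}}{\sum_i [A_i]_{\mathrm{w}}},$$

sums over every protonation and tautomeric state $A_i$, and is related to
solvation free energies through the transfer free energy
$\Delta G_{\mathrm{w\to cyc}} = \Delta G_{\mathrm{cyc}} - \Delta G_{\mathrm{w}}
- \Delta G_{\mathrm{v\to v}}$ and
$\log D = -\beta\,\Delta G_{\mathrm{w\to cyc}}/\ln 10$. This package
implements everything *after* the molecular-dynamics sampling: free-energy
estimation from alchemical samples, the cutoff/finite-size correction terms
needed when the simulations use Barker–Watts reaction-field (BWRF)
electrostatics, the assembly of solvation free energies under four
correction models (A–D), the dominant-species and two-species logD models,
and the bootstrap benchmark statistics. A synthetic-data module provides
analytically solvable fixtures so that every stage is testable without
simulation output.

Internally, energies are in kcal/mol, distances in Å, charges in elementary
charges; the default temperature is 298 K
($\beta = 1/k_BT$ with $k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$), and
the electrostatic conversion constant $e^2/(4\pi\varepsilon_0)$ is pinned at
332.0637 kcal mol$^{-1}$ Å $e^{-2}$ in `alch_constants`.

## Free-energy estimators

`zwanzig_fep()` implements one-sided exponential averaging,
$\Delta G = -\beta^{-1}\ln\langle e^{-\beta\Delta U}\rangle$, evaluated
through log-sum-exp so that arbitrarily large perturbation energies cannot
overflow; its uncertainty is the delta-method standard error of the
exponential average, which presumes uncorrelated samples.

`mbar_free_energies()` solves the multistate Bennett acceptance ratio
(MBAR) equations

$$f_i = -\ln\sum_{n=1}^{N}
\frac{e^{-u_i(x_n)}}{\sum_k N_k\, e^{f_k - u_k(x_n)}}$$

by direct self-consistent iteration on the dimensionless free energies.
The simulation literature does not pin an implementation contract, so one
is fixed here: convergence tolerance $10^{-8}$ (dimensionless), at most
10&nbsp;000 sweeps, error on non-convergence carrying the final residual.
Uncertainties come from the asymptotic covariance of the estimator,
computed from the $N\times K$ weight matrix in its SVD form with a
pseudo-inverse, so rank deficiency from strongly overlapping states is
handled gracefully. With two states MBAR is mathematically identical to
BAR; the test suite checks this against an independently coded BAR
bisection, and checks multi-state results against harmonic oscillators
where $\Delta G = (2\beta)^{-1}\ln(k_2/k_1)$ exactly.

`subsample_uncorrelated()` estimates the statistical inefficiency
$g = 1 + 2\sum_t (1 - t/N)\,C(t)$ with a triangle window, truncating the
sum at the first non-positive autocovariance. The estimator variant is a
package decision (the original analysis delegated to an external module
without specifying one); constant series are defined to have $g = 1$.
Retained indices are every $\lceil g\rceil$-th sample.

`run_pair_error()` implements the two-run rule: the estimate is the mean of
two independent repeats and the uncertainty $\sigma/\sqrt{2} =
|g_1-g_2|/2$ with $\sigma$ the $n-1$ sample standard deviation. Whether
run-averaging happens per leg (`combine_runs()`) or per assembled logD is
left as an explicit caller choice — the source protocol does not specify
it, and both entry points are provided.

## Correction terms

Simulations in the solvated phases use an atom-based BWRF with cutoff
$r_c = 12$ Å and dielectric 82 (water) or 1.0 (cyclohexane), while vacuum
legs use plain Coulomb electrostatics. Four post-processing corrections
reconcile this:

**FUNC** (`func_correction()`): intramolecular electrostatic consistency,
$\Delta G_{\mathrm{FUNC}} = -\beta^{-1}\ln\langle
e^{-\beta(U_{\mathrm{ic,nc}}-U_{\mathrm{ic,sim}})}\rangle$, evaluated over
solute frames from the fully charged end state. The BWRF constants are the
standard form $k_{rf} = (\varepsilon-1)/((2\varepsilon+1)r_c^3)$,
$c_{rf} = 3\varepsilon/((2\varepsilon+1)r_c)$, which vanishes continuously
at the cutoff (the source cites the original reaction-field reference
without printing the constants). Both potentials are restricted to
identical non-excluded pairs under the Amber convention — 1-2 and 1-3
excluded, 1-4 electrostatics scaled by 1/1.2 — chosen because the solutes
are GAFF-parametrized; only the functional-form difference survives.

**LJLRC** (`lj_long_range_correction()`): the solute–solvent dispersion
missed by the cutoff. Each frame's solute–solvent Lennard-Jones energy is
recomputed (orthorhombic minimum image, half-open cutoff) at $r_c$ and at
$r_{c,\mathrm{long}} = 0.95\min(L_x,L_y,L_z)/2$, the Zwanzig relation is
applied to the differences, and an analytic tail
(`lj_tail_analytic()`)

$$U_{\mathrm{LJ,ana}} = 8\pi\rho\sum_i\sum_j\left[
\frac{\epsilon_{ij}\sigma_{ij}^{12}}{9\,r_{c,\mathrm{long}}^{9}} -
\frac{\epsilon_{ij}\sigma_{ij}^{6}}{3\,r_{c,\mathrm{long}}^{3}}\right]$$

extends it to infinity under $g(r)=1$. The tail coefficients are used
exactly as stated in the source; note that integrating the textbook
$4\epsilon$ pair form over a uniform fluid would give twice this value
(the stated form corresponds to a $2\epsilon$ pair convention). This
possible factor-of-two ambiguity is not derivable from the source text
alone, so the printed form is kept and the quadrature oracle in the test
suite integrates the same functional form. The per-frame pair energies in
the Zwanzig term use the standard $4\epsilon$ convention. When
$r_{c,\mathrm{long}}$ is derived from the box and does not exceed the
simulation cutoff the function refuses ("box too small"); an explicitly
supplied equal cutoff is accepted and returns the tail alone.

**PSUM** (`psum_correction()`): the summation-scheme artefact of atom-based
cutoffs on net-charged solutes,

$$\Delta G_{\mathrm{PSUM}} = -\frac{N_A}{6\varepsilon_0}\,Q\,\gamma_s
\left[\frac{2(\varepsilon_{BW}+1)}{2\varepsilon_{BW}+1}\cdot
\frac{\langle N_s(r_c)\rangle}{\tfrac{4}{3}\pi r_c^3} +
\frac{3}{2\varepsilon_{BW}+1}\right].$$

Two unit decisions are documented here. First, $\gamma_s$ is the trace of
the solvent quadrupole tensor, $\sum_i q_i\,\mathbf r_i\!\cdot\!\mathbf
r_i$ (units e Å$^2$, computed from the solvent template and validated to
1e-9). Second, $\varepsilon_0$ is read as the experimental *relative*
permittivity of the solvent (78.3 for water), with the vacuum-permittivity
factor absorbed into the pinned conversion constant, so the prefactor
becomes $-(2\pi/3)\cdot 332.0637/\varepsilon_{0,\mathrm{rel}}$ in
e-Å-kcal/mol units. The bracket is applied exactly as stated even though
its second term is dimensionless while the first carries Å$^{-3}$; which
permittivity convention applies to the cyclohexane phase is genuinely
ambiguous, so `eps0_rel` is configurable per solvent model.
$\langle N_s(r_c)\rangle$ counts solvent molecules by their reference site
(water: oxygen) within $r_c$ of the solute's geometric center, averaged
over frames — the counting rule is a package decision.

**POL** (`pol_correction()`): periodicity/permittivity correction
$\Delta G_{\mathrm{NP}}^{\mathrm{Coul}} -
\Delta G_{\mathrm{RF}}^{\mathrm{Coul}}$. Both inputs come from external
Poisson solvers and are out of scope here; the function is a strict
pass-through that forms the difference, records provenance, and errors on
missing input rather than defaulting to zero.

## Models A–D and logD

`solvation_free_energy()` assembles, per phase,

- **A**: discharging + vanishing legs minus the vacuum legs, + FUNC;
- **B**: A + the phase's LJLRC (the source prints the model-B equation as a
  single-phase free energy containing the *difference* of both phases'
  LJLRC terms, which contradicts its own per-molecule table; assembling per
  phase reproduces exactly that printed difference at the transfer level,
  which is where the term is used);
- **C**: B + POL + PSUM;
- **D**: C for charged species, B for neutral ones.

Uncertainties propagate in quadrature assuming independent legs.
`transfer_free_energy()` subtracts the water from the cyclohexane value;
the vacuum interconversion term $\Delta G_{\mathrm{v\to v}}$ defaults to
absent and is explicitly flagged "neglected" (evaluating it rigorously with
a classical potential is problematic, and it was not evaluated in the
source protocol either). `logd_dominant()` applies
$-\beta/\ln 10$; $\ln 10 = 2.302585$ is used internally (printed sources
often round to 2.303).

## Two-species model

When a conjugate acid/base pair coexists at the experimental pH, the
dominant-species fraction $f$ from an external pKa predictor defines an
effective pKa, $\mathrm{pKa}^{\mathrm{eff}} = \mathrm{pH} -
\log_{10}(f/(1-f))$ (dominant form taken as the base; an orientation flag
handles acidic dominants symmetrically instead of silently flipping
signs). With per-species partition coefficients
$P = e^{-\beta\Delta G_{\mathrm{transfer}}}$,

$$\log D = \log_{10}\!\left[P_{\mathrm{con}}
\left(1+\tfrac{10^{-\mathrm{pKa^{eff}}}}{10^{-\mathrm{pH}}}\right)^{-1} +
P_{\mathrm{dom}}
\left(1+\tfrac{10^{-\mathrm{pH}}}{10^{-\mathrm{pKa^{eff}}}}\right)^{-1}
\right],$$

whose two weights are the speciation fractions and sum to one. When
$P_{\mathrm{con}} \gg P_{\mathrm{dom}}$ this reduces to the common pKa
correction `logd_pka_corrected()`; the divergence between the two grows as
the dominant species' contribution to the sum becomes comparable, which the
property tests quantify. Note the sign convention: with the conjugate as
the acid, $\mathrm{pKa} \gg \mathrm{pH}$ recovers
$\log_{10} P_{\mathrm{con}}$. An explicitly supplied
$\mathrm{pKa}^{\mathrm{eff}}$ takes precedence over a fraction-derived one,
with a warning when both are present and disagree by more than 0.01 units.
Only the two-species reduction is implemented; the general multi-species
sum is a documented generalisation left as future work. Selecting *which*
conjugate pair to model for multi-site molecules requires external pKa data
and is left to the input table.

## Benchmark statistics

`mue()`, `mud()` and `r_squared()` are the point metrics; $R^2$ defaults
to the squared Pearson correlation (sign-blind, documented), with the
regression-style $1-\mathrm{SS}_{\mathrm{res}}/\mathrm{SS}_{\mathrm{tot}}$
behind a flag, because the source usage is correlation-based but not
stated unambiguously. `bootstrap_metrics()` implements the parametric
bootstrap: every prediction is redrawn from
$\mathcal N(\hat y_i, \sigma_i)$, metrics are recomputed per replicate
(10&nbsp;000 by default), and the distribution is summarized by its mean
and empirical 2.5/97.5 percentiles, reported as $z^- < \mu < z^+$.
Only predictions are perturbed by default; whether the original protocol
also perturbed the experimental values is unspecified, so reference
perturbation is opt-in. Because $|x|$ of a normal variable is
folded-normal, the bootstrap mean MUE exceeds the deterministic MUE,
vanishing as $\sigma\to 0$ — a tested invariant. All reports are
bit-reproducible under a fixed seed, and every generator restores the
caller's RNG state (`with_seed()`).

`reproduce_table1()` runs this protocol over the packaged reference table
of 13 hydration (11 neutral + 2 ionic) and 11 cyclohexane solvation free
energies with per-value uncertainties, transcribed from the benchmark
against the Minnesota solvation set; the loader validates spot cells and
row counts before use, and synthesizes the cyclohexane model-D column from
model B (they coincide, as only neutral species occur there).

## Synthetic data: what it does and does not emulate

`make_harmonic_ensembles()` gives exact Boltzmann samples with closed-form
free energies — the gold standard for estimator validation, but with
perfect phase-space overlap structure unlike real decoupling legs.
`make_snapshot_fixture()` builds jittered solute conformers in a uniform
single-site LJ bath: adequate for exercising every pairwise-sum code path
(its defaults — 20–50 frames, a 4-atom solute, ~100–150 solvent sites in a
40–60 Å box — are sized so brute-force oracles are exact to 1e-8), but it
has no water structure, no realistic charge distributions, and no
force-field correlations. `make_species_dataset()` draws conjugate logP
around 2 ± 1.5 with the dominant (ionised) species 3–8 log units lower —
matching the observed regime where charged forms hardly partition into
cyclohexane — and effective pKa around pH 7.4 ± 1.5; Gaussian noise of
`noise_sd` on each per-phase free energy propagates to logD noise of
$\sqrt 2\,\beta\,\sigma/\ln 10$ per species. Passing tests on these
fixtures therefore demonstrate correctness of the estimators, corrections
and speciation algebra — not force-field accuracy on real molecules, which
is exactly the limitation the benchmark statistics quantify.

## Numerical choices and degenerate inputs

Log-sum-exp everywhere an exponential average appears; half-open cutoffs
($r < r_c$) with the BWRF form vanishing at $r_c$ by construction;
orthorhombic minimum image only; `MASS::ginv` pseudo-inverses for
covariance matrices; empty ensembles, zero-length sample sets, degenerate
speciation fractions ($f \in \{0,1\}$), missing POL inputs and duplicated
free-energy-table rows are all hard errors rather than silent defaults.
Problem sizes in the tests and analysis scripts (10⁴ samples per state for
estimator validation, 20–50-frame ensembles for correction oracles, 100
molecules for recovery studies, 10⁴ bootstrap replicates) were chosen as
the smallest sizes at which the analytic comparisons are statistically
clean.

## Known limitations

- MBAR uses plain self-consistent iteration; pathologically non-overlapping
  states converge slowly (they error out with the residual rather than
  returning a wrong answer).
- The LJLRC tail inherits the stated-coefficient ambiguity discussed above.
- The PSUM bracket mixes units as stated; absolute PSUM magnitudes should
  be interpreted with that caveat (its tested contracts are exact linearity
  in $Q$, $\gamma_s$ and the solvent-count term, and the zero for neutral
  solutes).
- Only two coexisting species per molecule; no tautomer enumeration, no
  pKa prediction — speciation fractions are inputs.
- No activity-coefficient corrections; concentrations stand in for
  activities throughout.
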