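# confex

Quantitative analysis of slow conformational exchange in globular
proteins, for structural biologists working with solution NMR and
molecular dynamics data.

The package targets the situation in which an engineered or mutated
protein shows a second population of peaks in its ¹H-¹⁵N HSQC spectrum
and the question is *which* slow process produces it: a genuine
side-chain conformational switch (e.g. a buried tryptophan flipping to a
solvent-exposed rotamer) or a weak monomer–dimer equilibrium. `confex`
implements the full quantitative chain used to make that call:

* **ZZ-exchange kinetics** — joint nonlinear fit of the four auto/cross
  peak intensity curves to the two-site longitudinal exchange model
  M(t) = exp(−Kt) M(0), K = [[R₁₁+k₁₂, −k₂₁], [−k₁₂, R₁₂+k₂₁]],
  yielding k₁₂, k₂₁ (`predict_zz`, `fit_zz`), with 2-D Gaussian peak-volume
  quantification (`quantify_peaks`).
* **Temperature analysis** — Arrhenius (Ea_app = −R·slope of ln k vs 1/T)
  and Eyring (ΔH‡, ΔS‡) fits, and classification of exchange behavior:
  Arrhenius only if Ea_app > 0 in both directions, plus a consistency
  check against a dimer-interface reporter residue
  (`fit_arrhenius`, `fit_eyring`, `classify_behavior`).
* **Dimerization** — Kd for 2M ⇌ M₂ (Kd = [M]²/[D]) from peak-volume
  titrations via the mass-action quadratic
  [M] = (−Kd + √(Kd² + 8·Kd·Ctot))/4 (`monomer_fraction`, `fit_kd`).
* **Shift classification** — combined displacement
  Δδ = √(Δδ_HN² + (Δδ_N/5)²) between major/minor peaks and grouping into
  no exchange / monomer-dimer exchange / Trp43 conformational exchange
  (`compute_delta_delta`, `classify_mode`).
* **Stability** — two-state sigmoid fits with linear baselines for
  chemical (Cm, m, ΔG_U = m·Cm) and thermal (Tm) denaturation, and
  destabilization ΔΔG between variants (`fit_chemical`, `fit_thermal`,
  `delta_delta_g`, `fluorescence_to_fraction`).
* **MD analysis** — χ1/χ2 dihedrals, rotamer-state assignment into the
  g+/g−/t × ±90° bins, dwell-filtered transition counting, a permutation
  test for concerted transitions between residues, and backbone RMSF
  after Kabsch superposition (`compute_dihedral`, `assign_rotamer_states`,
  `count_transitions`, `detect_concerted`, `compute_rmsf`).
* **Synthetic data** — seeded generators with known ground truth for every
  input above, including a dimer-coupled rate law that reproduces
  negative apparent activation energies, and a continuous-time Markov
  rotamer simulator with an exact jump log (`gen_*` functions).
* **Pipeline** — a per-variant orchestration layer driven by a YAML/JSON
  config, producing TSV/JSON reports (`run_pipeline`, `write_report`).

## Worked example

```r
library(confex)

# simulate a noisy ZZ-exchange dataset and refit it
truth <- zz_params(k_12 = 4, k_21 = 2, R1_1 = 1.3, R1_2 = 1.0,
                   I0_1 = 1, I0_2 = 0.5)
fit_zz(gen_zz_dataset(truth, noise_sd = 0.02, seed = 1))
#> ZZ-exchange fit (converged, rss = 0.009506, 8 mixing times)
#> Two-site exchange parameters:
#>   k_12 = 4.217 s^-1, k_21 = 1.994 s^-1
#>   ...

# the non-Arrhenius signature of exchange gated by an enthalpy-driven dimer
temps <- seq(282, 303, length.out = 6)
obs <- gen_rate_series("dimer_coupled",
                       list(k0 = 8, Ea_intrinsic = 9, Kd0 = 100e-6,
                            dH_assoc = 30, Ctot = 1e-3), temps)
fit_arrhenius(obs)
#> Arrhenius fit (W43e, 2->1): Ea_app = -2.95 +/- 0.38 kcal/mol (R^2 = 0.9370)

# dimerization constant from a four-point titration (5% volume noise)
fit_kd(gen_titration(116e-6, noise_sd = 0.05, seed = 3))
#> Dimer Kd = 0.0001103 M (se 4e-06 M, rss 0.000277, n = 4)

# stability: Cm and m give the unfolding free energy, differences give ddG
fit_chemical(gen_denaturation("chemical", list(Cm = 2.66, m = 1.616),
                              noise_sd = 0))
#> Chemical denaturation fit: Cm = 2.66 M, m = 1.62 kcal/(mol M), dG_U = 4.3 kcal/mol
delta_delta_g(2.7, 4.3)
#> [1] 1.6

# shift displacement classifies the exchange mode
classify_mode(shift_pair("W43e", 10.12, 129.5, 9.02, 127.3))
#> W43e: Trp43 conformational exchange (delta-delta = 1.18 ppm)
```

The recovered exchange rates (4.2 and 2.0 s⁻¹ against a truth of 4 and 2)
show the precision of the joint four-curve fit at 2% intensity noise. The
negative apparent activation energy (−2.95 kcal/mol) is the diagnostic
signature of exchange that is shut off by temperature-enhanced
dimerization; the underlying intrinsic barrier in the simulation is a
normal +9 kcal/mol. The Kd, ΔG_U and Δδ values illustrate the scales at
which these analyses operate (µM dissociation constants, a few kcal/mol of
stability, ppm-scale displacements).

A complete two-variant synthetic study ships with the package:

```r
cfg <- system.file("extdata", "example_config.yaml", package = "confex")
run_pipeline(cfg, out_dir = "report")
```

See `vignettes/conformational-exchange-methods.Rmd` for the models,
assumptions, defaults and numerical choices.

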