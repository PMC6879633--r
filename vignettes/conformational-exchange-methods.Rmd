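---
title: "Models and methods for quantifying slow conformational exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantifying slow conformational exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confex)
```

# Scope

`confex` quantifies slow (millisecond-to-second) conformational exchange in
small globular proteins from solution NMR observables and molecular dynamics
trajectories. The motivating system is an engineered protein G β1 domain in
which a buried tryptophan side chain (Trp43) switches between a core-buried
and a solvent-exposed rotamer, while the same protein also populates a weak
monomer–dimer equilibrium. The package's job is to separate those two
processes quantitatively: classify what kind of exchange a variant shows,
extract rate constants and activation parameters, estimate the dimerization
constant, measure the thermodynamic cost of the mutations, and count the
corresponding rotamer transitions in simulation data.

Every analysis stage has a matching synthetic-data generator with known
ground truth, so the whole pipeline is testable without any experimental
deposit.

# Two-site longitudinal (ZZ-) exchange

In a ZZ-exchange experiment, longitudinal magnetization prepared on the
major (1) or minor (2) state peak evolves during a mixing time and is read
out on both peaks, giving four curves: two auto peaks (AA, BB) and two
cross peaks (AB, BA). With exchange rates $k_{12}, k_{21}$ and longitudinal
relaxation rates $R_{1,1}, R_{1,2}$, the magnetization obeys
$\dot M = -K M$ with

$$K = \begin{pmatrix} R_{1,1} + k_{12} & -k_{21} \\ -k_{12} & R_{1,2} + k_{21} \end{pmatrix}.$$

`predict_zz()` evaluates $e^{-Kt}$ in closed form through the 2×2 Sylvester
(Lagrange) interpolation on the two eigenvalues
$\lambda_\pm = \tfrac12\left[(a_{11}+a_{22}) \pm \sqrt{(a_{11}-a_{22})^2 + 4k_{12}k_{21}}\right]$,
with a first-order fallback when the eigenvalue gap is below $10^{-10}$ of
the spectral scale (the formula degrades gracefully there; the fallback
avoids catastrophic cancellation). The test suite holds this closed form
against a generic numerical matrix exponential on a thousand random
parameter draws.

`fit_zz()` fits all four curves jointly — the model has six free parameters
($k_{12}, k_{21}, R_{1,1}, R_{1,2}, I_{0,1}, I_{0,2}$), and the individual
curves are badly under-determined on their own. All parameters are
positive by construction, so the optimizer works in log space; this also
avoids boundary-stuck fits at zero rates. Without a starting point a
deterministic 36-point multi-start grid ($k \in \{0.1, 1, 10\}$ s⁻¹ per
direction, $R_1 \in \{0.5, 2\}$ s⁻¹ per state, initial intensities from the
maxima of the auto-peak curves) is run and the lowest residual sum of
squares wins, ties resolved by grid order. The initial intensities are
deliberately *not* tied to the equilibrium constant: measured peak
intensities carry instrument and relaxation factors, so constraining
$I_{0,1}/I_{0,2}$ to the population ratio would import a systematic error.
Per-point uncertainties weight the residuals only when requested; the
default is unweighted.

Peak volumes enter through `quantify_peaks()`, which fits a sum of
axis-aligned 2-D Gaussians plus a flat per-cluster baseline to an intensity
patch and integrates analytically ($V = 2\pi A \sigma_x \sigma_y$). A flat
baseline is the smallest model that makes the volumes well-defined for
tightly clustered peaks; a planar baseline would add two parameters the
typical small cluster cannot support.

# Temperature dependence and exchange-mode classification

`fit_arrhenius()` is an ordinary least-squares line through
$(1/T, \ln k)$; the apparent activation energy is $-R \cdot$ slope with
$R = 1.9872 \times 10^{-3}$ kcal mol⁻¹ K⁻¹. `fit_eyring()` fits
$(1/T, \ln k/T)$ with transmission coefficient 1, reporting
$\Delta H^\ddagger$ (kcal/mol) and $\Delta S^\ddagger$ (cal mol⁻¹ K⁻¹).
The two agree through the textbook identity
$E_a = \Delta H^\ddagger + RT$, which the suite checks to 2% over windows
of up to 30 K. A series whose rates are numerically identical at every
temperature short-circuits to a slope of exactly zero: the floating-point
fit would otherwise return an $\pm\epsilon$-scale slope whose *sign* is
arbitrary, and sign matters below.

A probe's exchange is called **Arrhenius** only when the apparent
activation energy is strictly positive in *both* directions; zero or
negative in either direction is **non-Arrhenius**. A negative apparent
activation energy is a diagnostic of a composed process, not a
thermodynamic quantity. The mechanistic reading implemented in the
synthetic generator: if exchange happens only in the monomer and
dimerization is enthalpy-driven toward the dimer at high temperature
($\Delta H_{assoc} > 0$ in the van't Hoff law
$K_d(T) = K_{d,0}\, e^{\Delta H_{assoc}/R\,(1/T - 1/T_0)}$), the observed
rate $k_{obs}(T) = f_M(T)\, k_{intr}(T)$ can fall with temperature even
though the intrinsic barrier is normal. `gen_rate_series("dimer_coupled")`
composes exactly this law; with $\Delta H_{assoc} = 0$ it degenerates to a
constant multiple of the Arrhenius law, which the suite asserts.

When a dimer-interface reporter residue is available, the probe is also
checked for **reporter consistency**: both directional activation energies
must agree with the reporter's within twice the combined standard error.
The threshold of two combined standard errors is this package's choice of
"the same within error" — no numeric criterion exists in the source
literature. A probe that is Arrhenius but reporter-inconsistent is flagged
in the notes as sensing a process distinct from dimerization.

Exchange-mode classification from chemical shifts uses the combined
two-nucleus displacement
$\Delta\delta = \sqrt{(\Delta\delta_{HN})^2 + (\Delta\delta_N/5)^2}$
between linked major/minor peaks. Variants without minor peaks show no
exchange; among the rest, the default boundary of 0.6 ppm separates the
small displacements characteristic of dimerization (the dimer interface is
remote from the tryptophan, observed cluster ≈ 0.32–0.34 ppm) from the
large displacements of a genuine buried-to-exposed side-chain move
(observed cluster ≈ 0.94–1.32 ppm). The threshold sits in the gap between
those clusters and is configurable because it is an empirical separator,
not a physical constant. The same formula is applied to the tryptophan
indole NH pair even though the weighting was calibrated for backbone
amides; this mirrors practice for side-chain probes.

# Monomer–dimer equilibrium

For $2M \rightleftharpoons M_2$ with $K_d = [M]^2/[D]$ and total
concentration $C_{tot} = [M] + 2[D]$ in monomer equivalents, the physical
root is

$$[M] = \frac{-K_d + \sqrt{K_d^2 + 8 K_d C_{tot}}}{4}.$$

`fit_kd()` converts volumes to an observed monomer fraction
$f = V_M/(V_M + V_D)$ — the dimer peak is taken proportional to $2[D]$
because each dimer contributes two copies of the reporter residue — and
least-squares matches it to the model fraction over $\log K_d$ in
$[10^{-9}, 10^{-1}]$ M (positivity plus scale-invariance). A titration
whose observed fractions sit entirely above 0.98 or entirely below 0.02
carries no curvature information and is flagged unidentifiable rather
than fitted. A per-state
response-factor correction is exposed and defaults to 1; no correction for
exchange broadening is applied.

# Two-state stability fits

Both denaturation modes share one model: a two-state sigmoid flanked by
linear folded/unfolded baselines,
$y = (b_f + s_f x)(1 - p_U) + (b_u + s_u x)\, p_U$. Chemically,
$p_U = [1 + e^{m(C_m - D)/RT}]^{-1}$ at fixed $T = 298.15$ K — the linear
extrapolation model, under which $\Delta G_U = m \cdot C_m$. Thermally,
$p_U$ is the van't Hoff sigmoid in $1/T$ with a steepness enthalpy that is
fitted but not interpreted (melt reversibility and $\Delta C_p$ effects are
out of scope; only $T_m$ is reported). The linear extrapolation choice is
the standard two-state treatment and is internally consistent with the
reference free-energy values the worked examples use
(e.g. $1.616 \times 2.66 \approx 4.30$ kcal/mol).

Degenerate inputs fail loudly: constant or exactly linear responses raise
a "no transition" error before any optimizer runs, and a fitted midpoint
outside the measured range is an error rather than an extrapolation.
`fluorescence_to_fraction()` integrates emission spectra by the trapezoid
rule and normalizes between baselines fitted to the lowest- and
highest-denaturant points (two points per end by default); fractions may
exceed $[0, 1]$ slightly under noise and are not clamped.
`delta_delta_g()` is reference minus variant, so destabilization is
positive.

# Rotamer dynamics in trajectories

Dihedrals are computed with the standard atan2 construction on the two
bond-plane normals, wrapped to $[-180°, 180°)$; the suite checks sign
conventions against both a projection-based second implementation and
bio3d's torsion routine, plus rotation/translation invariance and mirror
antisymmetry.

Rotamer states use half-open bins: χ1 $[0°, 120°) \to g^+$,
$[-120°, 0°) \to g^-$, else $t$ (centered at 180°); χ2 $[0°, 180°) \to
+90$, else $-90$. Half-open boundaries are deterministic and tie-free, and
coincide with nearest-center assignment away from the edges; the boundary
angle $-120°$ belongs to $g^-$ by the same convention. The $g^+ = +60°$
naming is a recorded convention of this package — rotamer nomenclature is
not uniform across literatures.

`count_transitions()` counts label changes with an optional persistence
(dwell) filter: a change only counts when the new state survives at least
`min_dwell` frames. The default is 1 (no debouncing). The filter exists
because angular noise near a bin boundary manufactures spurious
back-and-forth flips: at 15° noise the raw count tracks the true jump
count within a few percent, while at 40° noise it overcounts severalfold
and a dwell of 5 frames recovers the truth to ~15%. Both the combined
χ1×χ2 count and the χ1-only count (the conventional definition of a
side-chain conformational transition) are available, since either reading
of "dihedral changes between bins" is defensible.

The synthetic generator behind these tests is a continuous-time Markov
chain over the six combined states, simulated exactly (Gillespie) and
sampled onto the frame grid; jumps flip one dihedral at a time by default,
the simplest mechanism consistent with the bin structure. The exact jump
log and true per-frame labels ride along as attributes, giving the
counting tests a brute-force oracle. Dwell times are exponential and the
empirical occupancies converge on the analytic stationary distribution;
both are asserted.

**Concerted motion.** The coupling statistic between two residues is the
number of B transitions within ±`window` frames of any A transition; its
null distribution comes from circular shifts of B's transition indicator
by uniform random offsets, which preserves B's count and clustering while
destroying alignment. $p = (1 + \#\{null \ge obs\})/(1 + n_{perm})$. This
procedure is this package's construction — the source analyses display
coupling qualitatively — and reports label it as a permutation test. Two
practical notes. First, permutation p-values are discrete: with few
transitions the statistic ties heavily and the test becomes conservative
(empirical false-positive rate at $\alpha = 0.05$ measured at ~0.015 with
~20 transitions per 1000-frame chain). The calibration check therefore
runs where the test has resolution — about 75 transitions per 1500-frame
chain, 199 permutations — and lands at 0.035. Second, a circular shift by
±`window` frames nearly preserves the observed alignment, so "perfect
synchrony implies the minimal p-value" holds exactly only at `window = 0`.

**RMSF.** `compute_rmsf()` discards the first third of frames by default
(mirroring the convention of analyzing the final two-thirds of production
runs), superposes frames onto their evolving mean (two Kabsch passes via
bio3d), and averages per-atom fluctuations over each residue's backbone
atoms (N, CA, C, O). For an ensemble built from independent isotropic
per-residue displacements of standard deviation σ per axis, the expected
RMSF is $\sigma\sqrt{3}$ — but superposition absorbs six rigid-body
degrees of freedom, shrinking the measured value by roughly
$\sqrt{1 - 2/R}$ for $R$ independently moving residues. The closed-form
check therefore uses 60 residues × 5000 frames, where the shrinkage is
~1.5% and the 5% tolerance is meaningful. RMSF is invariant to the input
reference frame and to per-frame rigid-body motion composed onto the
coordinates; both are asserted to 10⁻⁶ Å.

# Synthetic-data conditions

The generators' defaults are the package's statement of realistic study
conditions, fixed once:

| Quantity | Default | Basis |
|---|---|---|
| Mixing-time grid | 8 points, 0–0.4 s | typical ZZ-exchange sampling for s⁻¹-scale rates |
| Temperature grid | 278–303 K | the 5–30 °C experimental window |
| Reference temperature | 298.15 K | all rate laws and chemical fits |
| Titration | 20, 100, 500, 1000 µM | four-concentration design around a ~10⁻⁴ M Kd |
| Chemical grid | 12 points, 0–5 M | plate-based guanidinium series |
| Thermal grid | every 2 °C, 25–95 °C | CD melt sampling |
| Intensity noise | additive Gaussian, sd 0.02 | positive-and-negative integral noise |
| Volume/rate noise | multiplicative lognormal | keeps positive observables positive |
| Angular noise | wrapped Gaussian, 10° | within-rotamer libration |

Noise magnitudes are placeholders in the sense that no experimental values
are published for them; every one is a function argument. What the
generators deliberately do *not* emulate: spectral processing artifacts,
temperature-dependent relaxation, exchange broadening of peak volumes,
three-state unfolding, correlated (non-Markovian) rotamer dynamics, and
anisotropic or correlated backbone fluctuations. Passing tests therefore
demonstrate correctness of the estimators under their stated models, not
robustness to every pathology of real data.

# Numerical choices

* Nonlinear fits use Levenberg–Marquardt (`minpack.lm`) with `ftol` and
  `ptol` at 10⁻¹⁵ so that noiseless recovery tests can assert 10⁻⁶
  relative accuracy.
* Positive parameters (rates, relaxation, intensities, m-values, van't
  Hoff enthalpies) are log-transformed; standard errors return to the
  natural scale by the delta method.
* The Kd search is a 1-D golden-section/parabolic minimization over
  $\log K_d$; its standard error comes from the numerical curvature of the
  residual sum of squares.
* Ties in the ZZ multi-start are broken by grid order, making fits
  deterministic.
* Gas constant $1.987204 \times 10^{-3}$ kcal mol⁻¹ K⁻¹;
  $k_B/h = 2.0837 \times 10^{10}$ s⁻¹ K⁻¹.
* All generators accept an integer seed and restore the caller's RNG
  state; fixed seed implies bit-identical output.

# Worked example

```{r example}
truth <- zz_params(k_12 = 4, k_21 = 2, R1_1 = 1.3, R1_2 = 1.0,
                   I0_1 = 1, I0_2 = 0.5)
ds <- gen_zz_dataset(truth, noise_sd = 0.02, seed = 1)
fit <- fit_zz(ds)
fit$params

temps <- seq(282, 303, length.out = 6)
obs <- gen_rate_series("dimer_coupled",
                       list(k0 = 8, Ea_intrinsic = 9, Kd0 = 100e-6,
                            dH_assoc = 30, Ctot = 1e-3), temps)
fit_arrhenius(obs)
```

The pipeline ties the stages together from a config file; the bundled
two-variant synthetic configuration is the end-to-end smoke test:

```{r pipeline}
cfg <- system.file("extdata", "example_config.yaml", package = "confex")
run_pipeline(cfg)
```

# Known limitations

Only two-site exchange is modeled; three-site or hierarchical exchange is
out of scope, as are spectral processing, automatic peak picking, NOE
structure determination and the MD engine itself. The m-values implied by
$\Delta G_U / C_m$ are a consistency check, not independently validated.
The concerted-motion test detects temporal coincidence, not causality or
mechanism. Problem sizes in the test suite (e.g. 50-replicate fit studies,
200-simulation calibrations, 5000-frame ensembles) are the package's
choice of the smallest designs whose sampling error is comfortably inside
the asserted tolerances.
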