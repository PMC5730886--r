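---
title: "Quantifying lowly populated protein conformers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lowly populated protein conformers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minorstate)
```

`minorstate` quantifies sparsely populated protein conformations from
solution NMR and calorimetry observables. This vignette is the
package's own account of the models it fits, the parameters that
matter, the numerical choices behind the fitters, and what the
synthetic-data generator does and does not emulate. The motivating
system is ubiquitin's equilibrium between its common fold and a
C-terminally retracted conformer, but nothing in the code is specific
to that protein: any two-state amide system fits the same machinery.

## The two-state Bloch–McConnell model

A residue exchanging between a visible major state A and a minor state
B is described by six magnetization components,
$(M_x, M_y, M_z)_A \oplus (M_x, M_y, M_z)_B$, evolving under
$\dot M = L M$. The generator $L$ (built by `evolution_matrix()`,
compiled in C++ for profile generation) combines:

* rotating-frame precession at $\Delta\omega_s = 2\pi(\delta_s -
  \mathrm{offset})\,\nu_N$ rad/s for each state $s$, where $\nu_N$ is
  the ¹⁵N Larmor frequency derived from the spectrometer ¹H frequency
  times the gyromagnetic-ratio magnitude 0.101329 (one constant, one
  place: `larmor_n_mhz()`);
* nutation about x at $\omega_1 = 2\pi B_1$;
* relaxation, $-R_2$ on transverse and $-R_1$ on longitudinal
  components, with $R_1$ shared between states and $R_2$ per state;
* exchange coupling with detailed balance built in:
  $k_{A\to B} = p_B\,k_\mathrm{ex}$, $k_{B\to A} = (1-p_B)\,k_\mathrm{ex}$.

The model is decay-only: there is no inhomogeneous thermal-recovery
term. This is the standard convention for ¹⁵N CEST, where the
exchange period (0.4 s) is analysed as pure decay from the prepared
longitudinal state and the reference slice simply omits that period.
Consequences used throughout: all eigenvalues of $L$ have non-positive
real part, the far-off-resonance plateau of a profile is
$e^{-R_1 t_\mathrm{ex}}$, and $I_0 = 1 - p_B$ exactly.

A CEST profile (`cest_profile()`) starts from equilibrium
magnetization $(0,0,1-p_B,0,0,p_B)$, propagates for
$t_\mathrm{ex}$ via the matrix exponential at every saturation offset,
and reports $I/I_0$ with $I = M_{z,A}(t_\mathrm{ex})$. The matrix
exponential is RcppArmadillo's scaling-and-squaring in the compiled
path and `Matrix::expm()` in the R-level `propagate()`; the accuracy
contract is agreement with an independent fixed-step 4th-order
Runge–Kutta integrator to 1e-8, asserted over random valid parameter
draws in the test suite. The two exponential paths are themselves
cross-checked point-wise to 1e-10.

## Global CEST fitting

`fit_cest()` fits all residues and B₁ fields simultaneously:
$p_B$ and $k_\mathrm{ex}$ are global; the signed ¹⁵N shift difference
$\Delta\varpi$ is per residue; $R_1$, $R_{2,A}$, $R_{2,B}$ are shared
across residues. Major-state shifts are treated as known (from the
assigned spectrum) and held fixed. The choice to share relaxation
rates keeps a seven-residue fit at twelve parameters; per-residue
rates are not identifiable from a single temperature's profiles at
realistic noise.

The least-squares surface has two traps worth documenting:

* **A spurious attractor at $p_B \to 1$.** Because $I_0$ scales with
  $1 - p_B$, runs started far from the truth can drift to full
  minor-state occupancy with a seemingly reasonable residual.
* **Shoulder minima.** At percent-level intensity noise, the steep
  flanks of the deep major-state dip produce local minima that dwarf
  the genuine minor-state dip, so naive dip-picking mis-seeds
  $\Delta\varpi$.

Initialisation is therefore two-staged. First, a per-residue
brute-force scan evaluates the single-residue model over a coarse grid
of occupancy, exchange rate and signed $\Delta\varpi$ (0.4–4.5 ppm in
0.25-ppm steps, both signs) on a thinned copy of the data, scoring
only offsets more than 0.7 ppm from the major resonance so that
residual mismatch around the deep major dip cannot drown out the
shallow minor dip; $R_1$ is pre-seeded from the off-resonance plateau.
Second, a coarse global $(p_B, k_\mathrm{ex})$ grid ranks candidate
starts, and Levenberg–Marquardt (minpack.lm) refines the best few with
box constraints; the first start whose residual reaches the estimated
noise floor (a median-absolute-deviation estimate from point-to-point
differences) short-circuits the rest. Standard errors come from the
residual curvature at the optimum. Fits that stop on the iteration
budget while already at the noise floor are accepted; anything else
errors with the best residual, and occupancies pinned at a bound are
flagged (`p_at_bound`).

Measured behaviour under the packaged conditions: noiseless
seven-residue datasets at the five-field schedule refit every preset
(occupancies 0.68%–99%, rates 46–120 s⁻¹) to machine precision in
roughly ten seconds each; at 1% intensity noise with the two-field
92-offset schedule the median relative error on a 0.68% occupancy is
about 5% over twelve replicates.

`extrapolate_occupancy()` treats $\ln K$, $K = p/(1-p)$, as linear in
$1/T$ through two measured points — a two-point van't Hoff line — so
an occupancy measured at two temperatures for one variant can be
projected to a third temperature. With a positive transition enthalpy
the minor-state occupancy rises with temperature.

## The synthetic-data generator

Every fitter has a forward model, and every generator *is* that
forward model plus noise — the same closed forms and the same
Bloch–McConnell code — so noiseless recovery is exact to optimizer
tolerance by construction, and parameter-recovery tests probe the
estimators, not implementation drift between two model codings.

Noise is Gaussian and multiplicative on raw intensities (a fraction of
the noiseless value), applied before any ratioing; for CEST the
reference slice receives its own draw per residue and B₁ field, so
ratio noise is realistically correlated within a profile. All
generators accept a seed and restore the caller's RNG state.

Default conditions are the packaged study conditions: CEST presets
(wild-type 45 °C: 0.68%, 63 s⁻¹; TVLN 45 °C: 99%, 120 s⁻¹; F4A 45 °C:
4.5%, 83 s⁻¹; F4A 25 °C: 1.3%, 46 s⁻¹) simulated at B₁ = 12.5, 20,
25, 37.5, 50 Hz over 102–134 ppm at 184 offsets with a 400-ms
exchange period; CLEANEX mixing times 5.2–166.4 ms in doubling steps;
phosphorylation half-times of 2 (TVLN, Ubl), 5 (F4A), 90 (wild-type)
and 275 min (L71Y) sampled at 4- or 8-min increments with at least
nine resonances; DSC midpoints 83–97 °C on a 40–110 °C grid.
Per-residue ¹⁵N shift differences for CEST fixtures are drawn
uniformly from 0.5–4 ppm with random sign, mimicking the spread across
exchanging amides and exercising the fitter's sign handling.

Values the source data do not pin down, chosen once: relaxation-rate
defaults $R_1 = 1.2$, $R_{2,A} = 10$, $R_{2,B} = 14$ s⁻¹ (mid-range
for a small globular protein at 25–45 °C); water $R_1 = 0.6$ s⁻¹,
fixed rather than fitted because six mixing times cannot support a
third free parameter per residue; DSC enthalpies 300 kJ/mol with
$\Delta H_\mathrm{vH} = \Delta H_\mathrm{cal}$ (two-state unfolding, a
typical magnitude for the ubiquitin fold — only the midpoint
temperature is treated as a reference quantity); per-resonance
intensity scales for time courses drawn from 0.5–2.

What the generator does **not** emulate: static B₁ inhomogeneity
(nominal B₁ only; a calibration step is out of scope), baseline and
phase artefacts, peak overlap and picking errors, temperature drift
within a series, scan-rate effects in DSC, and any three-state or
ligand-coupled exchange. Passing recovery tests therefore demonstrate
estimator correctness and noise robustness under the stated
conditions, not robustness to spectrometer systematics.

## Solvent exchange, hetNOE, shift perturbation, broadening

CLEANEX buildup follows the two-exponential closed form

$$\frac{I(\tau)}{I_0} = \frac{k}{R_{1,\mathrm{amide}} + k -
R_{1,\mathrm{water}}}\left(e^{-R_{1,\mathrm{water}}\tau} -
e^{-(R_{1,\mathrm{amide}}+k)\tau}\right),$$

whose initial slope is exactly $k$ — the basis of the
`initial_rate` mode (slope through the origin over the earliest three
points) and of the fallback when the full two-parameter fit fails to
converge. Rates are constrained non-negative, all-zero series return
$k = 0$ with a flag, and estimates are invariant to the global
intensity scale. `protection_analysis()` compares apo and bound rate
tables; the default protection rule is $k_\mathrm{bound} <
0.5\,k_\mathrm{apo}$, with residues silent in the bound state flagged
fully protected.

The heteronuclear NOE is the plain intensity ratio $I_\mathrm{on} /
I_\mathrm{off}$ with first-order error propagation from per-spectrum
noise floors. Weighted shift perturbations use
$\sqrt{\Delta_H^2 + (\Delta_N/5)^2}$; the 1/5 weight compensates the
wider ¹⁵N dispersion. Broadening classes use the population (not
sample) standard deviation of bound/free ratios with half-open
boundaries — strong below mean − stdv, moderate below mean −
stdv/2 — which makes the classification exactly invariant under
rescaling either spectrum; residues that vanish in the bound spectrum
are classed strong, since complete exchange broadening is itself
interface evidence. Both stdv conventions (here and in
`aggregate_progress()`) are population-based, matching the worked
fractions {0.4, 0.6} → mean 0.5, stdv 0.1.

## Phosphorylation kinetics

Serial peak heights are normalised by the paper-protocol anchor rule:
substrate (disappearing) traces by their first spectrum, product
(appearing) traces by their last. The generator stamps spectra at
their sampling instants starting at $t = 0$ (first spectrum fully
unconverted), which makes the anchor rule and the first-order model
$f(t) = 1 - e^{-kt}$ exactly consistent — the noiseless half-time
identity $t_{50} = \ln 2 / k$ holds to optimizer precision. When
mapping real acquisition metadata, where each spectrum integrates over
its increment, `increment_times()` provides the stamp convention
(midpoint by default, configurable to increment start). The anchor
rule folds single-spectrum noise into the normalisation; an optional
plateau-average anchor (mean of three edge spectra) is available but
off by default to match the protocol. Because the appearing-species
anchor is the *last* spectrum, a course truncated before completion
biases the fitted rate upward by roughly $e^{-kT}/2$; recovery tests
and the acceptance script therefore run courses past six half-lives.
`fit_rate()` reports both the weighted exponential fit and a
model-free linear interpolation of the 50% crossing; the latter guards
against model misfit but inherits the time-grid discretisation.
Fold-accelerations are half-time ratios, e.g. 90/2 = 45 and
275/2 = 137.5 for the packaged presets.

## DSC endotherms

The non-two-state model lets calorimetric (peak area) and van't Hoff
(peak sharpness) enthalpies vary independently:

$$K(T) = \exp\!\left[\frac{\Delta H_\mathrm{vH}}{R}\left(\frac{1}{T_m}
- \frac{1}{T}\right)\right], \qquad C_p(T) = \frac{\Delta
H_\mathrm{cal}\,\Delta H_\mathrm{vH}\,K}{R\,T^2\,(1+K)^2},$$

with temperatures in Kelvin internally and °C at every interface. At
$T_m$, $K = 1$ and $C_p = \Delta H_\mathrm{cal}\Delta
H_\mathrm{vH}/(4RT_m^2)$; a ratio $\Delta H_\mathrm{vH}/\Delta
H_\mathrm{cal} \approx 1$ diagnoses two-state unfolding. The optional
progress baseline fits linear pre- and post-transition baselines on
the outer 15% of the grid and iterates a sigmoidal interpolation
weighted by fractional unfolding (from the running integral), at most
10 iterations with a 1e-6 relative-change stop. The correction leaks
a few percent of peak area into the baseline when the pre/post levels
differ strongly — the midpoint is robust (within 0.3 °C in tests) but
enthalpies from heavily sloped raw traces carry ~5–10% bias, which is
why the packaged reference quantity is $T_m$ only. Traces with more
than one well-separated peak are rejected with advice to restrict the
range.

## Pipeline and reproducibility

`run_pipeline()` executes simulate-and-fit stages from a single
configuration (list or YAML), writes per-stage TSV tables plus a flat
key–value summary per fit, and returns a manifest with MD5 checksums;
identical configuration and seed give identical checksums, stages
never mutate each other's inputs, and reruns are idempotent.
`replay_config()` packages the study conditions as a ready-made
configuration. Problem sizes in the shipped tests and in
`scripts/acceptance.R` are the full acquisition schedules for the
noiseless recovery checks and a two-field, 92-offset schedule with
twelve replicates for the noise-robustness study — sizes chosen so the
whole suite runs comfortably on a single CPU.

## Known limitations

* Two states only; no three-state, DANTE/multi-frequency CEST, CPMG
  relaxation dispersion or ZZ-exchange fitting.
* Nominal B₁; the optional inhomogeneity averaging the literature
  sometimes applies is not implemented, and B₁ calibration is out of
  scope.
* $\Delta\varpi$ resolution is bounded by the offset grid near the
  major resonance: differences below ~0.4 ppm are attributed mostly by
  the refinement stage, not the scan, and dip *detection* reports the
  apparent minor position, which the sloping tail of the major dip can
  pull by a grid step or two.
* CLEANEX fitting ignores water flip-back and radiation damping, and
  compares raw rates, not protection factors against intrinsic rates.
* Kinetics assume pseudo-first-order conversion (enzyme far below
  substrate); no Michaelis–Menten, lag or burst models.
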