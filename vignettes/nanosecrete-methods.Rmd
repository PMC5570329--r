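---
title: "Models and methods behind nanosecrete"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanosecrete}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nanosecrete` analyses single-cell cytokine secretion measured with
antibody-coated sensor beads in open nanowell arrays. This vignette is the
package's own account of the models it implements, the defaults it ships,
the numerical choices behind the solver and the fitter, and what the
synthetic-data generator does and does not emulate.

## 1. The capture model

A nanowell (square cross-section, default 50 × 50 μm, 60 μm deep; a 40 μm
preset is also provided) holds one secreting cell and one sensor bead, both
modelled as spheres resting inside the well. The free analyte concentration
$C$ obeys Fick's second law, $\partial C/\partial t = D \nabla^2 C$, with
zero flux at the PDMS walls (proteins do not penetrate PDMS) and a constant
molecular source distributed uniformly over the cell surface. On the bead
surface the captured density $C_s$ follows Langmuir kinetics,

$$\frac{\partial C_s}{\partial t} = k_{on} C (\theta_0 - C_s) - k_{off} C_s,$$

with $\theta_0$ the antibody site density. Surface diffusion of bound
analyte, convection, wall adsorption, degradation, and object motion are all
neglected. Initial concentrations are zero everywhere.

**The bulk medium.** The medium above the well mouth is represented as a
buffer column of the same cross-section (default height equal to the well
depth). Two closures are available:

* `open_top = FALSE` (default): the buffer top is a no-flux face, i.e. the
  medium is a finite reservoir. Under this closure a 5 μm bead coated at
  $\theta_0 = 10^{-9}$ mol/m² exhausts its ~47,000 sites within the 6 h
  observation window while denser coatings keep accumulating at the
  secretion-limited rate — the behaviour expected for this assay class, and
  the configuration used by the package's sweep-based validation.
* `open_top = TRUE`: the buffer top is held at zero concentration,
  approximating an infinite sink. Most secreted molecules then escape; this
  variant exercises the full molecule budget (free/bound/escaped) and is
  used for the mass-balance validation precisely because escape is nonzero.

**Kinetic defaults.** The defaults $D = 10^{-10}$ m²/s,
$k_{on} = 10^{6}$ M⁻¹s⁻¹, $k_{off} = 10^{-5}$ s⁻¹ (i.e. $K_d = 10$ pM, a
high-affinity capture antibody), $\theta_0 = 10^{-8}$ mol/m² and a secretion
rate of 10 molecules/s are assumptions chosen so that the transport/capture
balance shows the canonical ambient-analyte behaviour at desk scale: a
simple conductance estimate (binding conductance $k_{on}\theta_0 A$ against
the diffusive supply $4\pi D r_b$ and the escape path) shows that association
rates much below $10^6$ M⁻¹s⁻¹ leave the bead capturing under a percent of
the secreted analyte, which would suppress the low-density saturation that
motivates the density sweep. All constants are plain fields of
`binding_kinetics()` and should be overridden when the chemistry is known.

## 2. Numerics of the solver

The domain is discretised into cubic voxels (finite volumes); spheres become
stair-step masks whose surface-face areas are rescaled so the total equals
the true sphere area, preserving the total antibody site count. The default
voxel is 2 μm: the grid-refinement test shows the independent mass-balance
residual falling roughly fourfold per halving of the voxel, and at 2 μm a
full 6 h run stays in the tens-of-seconds range; 1 μm remains selectable
when sharper geometry is needed.

Time integration is backward Euler with a fixed ramped schedule (1 s steps
over the first minute, 5 s to 10 min, then `dt_max`, default 30 s, chosen to
divide the output interval so outputs land on step boundaries). Each step
solves the implicit diffusion system with the bead-surface Robin coupling
$D\,\partial C/\partial n = k_{on} C (\theta_0 - C_s) - k_{off} C_s$ folded
into the matrix diagonal. Because that coupling touches only the few
bead-adjacent voxels, the solver factorises the constant diffusion operator
once per distinct step size (sparse Cholesky) and applies the surface
perturbation through a Woodbury low-rank correction; the nonlinear
$C$–$C_s$ coupling is resolved by Picard iteration (relative tolerance
$10^{-10}$, default; failure to converge raises an explicit error naming the
time and step size). The bound-mass update is taken from the same discrete
sink term that the $C$-equation used, so free + bound + (scheme) escape
equals secreted to machine precision by construction.

The *reported* mass-balance residual is therefore computed against an
independent second-order one-sided flux quadrature at the open boundary
rather than the scheme's own bookkeeping: it measures genuine discretisation
error, is a few times $10^{-7}$ at the default resolution, and decreases
under refinement — a meaningful solver diagnostic instead of a tautology.

Two oracles guard the solver. A well-mixed two-compartment ODE
(`wellmixed_oracle()`, integrated by `deSolve` at tight tolerance) must
match the PDE in the sealed, 100× diffusivity limit; it also satisfies
closed-form checks (Langmuir isotherm at held concentration, site-limited
and secretion-limited conservation bounds). Degenerate inputs are handled
explicitly: $k_{on} = 0$ yields identically zero occupancy, zero secretion
yields a zero residual, and placements whose spheres leave the well or fall
below the grid resolution are rejected with informative errors.

## 3. Secretion kinetics

Bead fluorescence is fit with the time-domain four-parameter logistic
$\mathrm{MFI}(t) = B + (T - B)\, t^h / (t^h + \mathrm{EC50}^h)$, which
equals $B$ exactly at $t = 0$, so the first frame participates in the fit
without a log-time transform. Fitting is bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`): start values put the plateaus at the data extremes,
EC50 at the first mid-range crossing and $h = 4$; bounds keep the plateaus
within the data range ± 50 % of its width, EC50 in $(0, 2 t_{end}]$ and
$h \in (0, 50]$. Non-convergence is reported as a flag, never an error; an
exactly flat trace returns a converged degenerate fit with $T = B$ and the
call deferred to the classifier.

A bead is called secretion-positive when the running-median-smoothed peak is
at least 2× the baseline (mean of the first three frames) *and* the fit
converged with amplitude $T - B$ above a noise floor (default 100 MFI
units, i.e. half the default baseline — the thresholding rule is a policy
object, reported with the output). The onset time `t_secrete` is the fitted
EC50; the amount proxy is the fitted-curve maximum over minimum across the
observation window (computed from the curve, not the raw data, so it is
noise-robust); the rate proxy is the Hill slope; `immediate` flags onsets at
or below 180 min. Early/late subpopulations split at the sample mean with
ties assigned to late (covered by a test); onset distributions are
summarised by mean, SD and moment skewness $g_1 = m_3/m_2^{3/2}$, together
with the same-mean/SD normal overlay used for histogram comparison.

Under the assay's sampling design (37 frames, 10 min apart) the Monte-Carlo
recovery study in the tests shows the median absolute EC50 error well below
one frame interval at 2 % relative noise.

## 4. Population statistics

Gating is a deterministic quadrant assignment on CD16/CD56 intensities;
cells below the CD56 positivity threshold are `ungated`. Numeric thresholds
default to values matching the generator's intensity scale and can instead
be estimated from the data as the posterior cross-over of a two-component
Gaussian mixture per channel on log10 intensity (`mclust`), mirroring how a
practitioner places a valley threshold on a dot plot.

The secretor frequency is the fraction of positive wells among wells with
exactly one cell and at least one bead; frequencies below the 0.01 %
detection floor are flagged and displayed as below the floor. Wells with
several beads are positive if any bead is positive and inherit the earliest
bead onset; a single-bead-only filter is available in the trace extractor.

Enrichment of a marker among (immediate) secretors uses an exact test on the
2×2 table. The package defaults to the *mid-p* variant (probability-method
two-sided p on the conditional hypergeometric support, observed table
counted with weight one half): the classical Fisher test is deliberately
conservative, and the package's calibration suite — which requires null
p-values to be near-uniform — would misreport a conservative test as
miscalibrated. The classical variant remains available
(`method = "fisher"`). The odds ratio is the sample cross-product ratio with
a Haldane +0.5 correction when any cell is zero. Two further notes on
calibration design: the uniformity check uses disjoint groups (secretor vs
non-secretor cells), because the assay's headline comparison — immediate
secretors against the *full* parent population — has overlapping groups
whose dependence breaks p-value uniformity for any test; the headline
comparison itself is kept in the analysis report.

Group comparisons (amount, rate, early-vs-late marker levels) use the
two-sided Mann–Whitney rank-sum test, exact for small tie-free samples and
normal-approximated with tie correction otherwise; fully tied data return
p = 1.

The cooperation analysis estimates the single-cell secretion probability
$p_1$ from single-cell wells and compares the observed positive fraction of
$k$-cell wells ($k = 2, 3$) with the independence null
$1 - (1 - p_1)^k$ by exact binomial test. The calibration suite runs this
with ~10,000 single-cell wells (the scale of a full array experiment) and
500 two-cell wells per replicate: with that many single-cell wells the
plug-in treatment of $p_1$ as known keeps the type-I error near nominal
(the tests assert the 0.025–0.075 band at $\alpha = 0.05$), and a doubling
of the per-cell probability in multi-cell wells is detected with high power.
With far fewer single-cell wells the plug-in null would inflate the type-I
error; the well counts are therefore part of the test's stated conditions.

## 5. The synthetic-data generator

The generator emulates, with everything drawn from a seeded RNG so that any
table regenerates bit-identically:

* **Loading:** independent Poisson cell and bead counts per well (truncated
  at 5), the standard null for gravity loading; defaults 0.5 cells and 1
  bead per well.
* **Phenotype:** a mixture over the four CD16/CD56 quadrants, 90 %
  CD56^dim CD16⁺ by default, with log-normal channel intensities around
  per-quadrant centers chosen so default gates misclassify a negligible
  fraction.
* **Secretion:** per-phenotype secretion probabilities (defaults give a 10 %
  overall rate, mildly CD16-linked; a uniform profile expresses the
  no-association null and a `synergy_factor` injects multi-cell-well
  synergy for power studies).
* **Kinetics:** log-normal onset times — donor presets with means 62 and
  70 min and modes near 50–55 min, hence positive skew; log-normal Hill
  slopes (around 4) and amplitudes (around 2000 MFI units over a baseline of
  200).
* **Traces:** each bead in a well reports the well's baseline plus one 4PL
  component per secreting cell, sampled on the 6 h / 10 min schedule
  (37 frames) with Gaussian noise scaled to the trace's dynamic range
  (default 2 %) plus additive noise and optional linear drift.
* **Images:** single-plane frames with objects as isotropic Gaussian spots
  on the 100 μm-pitch well grid; the spot amplitude is normalised so the
  mean over the half-maximum core equals the nominal MFI, making the
  renderer and the core-based segmenter a consistent round trip, and the
  summed spot intensity matches the analytic Gaussian integral (the
  quadrature test).

It does *not* emulate optics (real PSFs, defocus, photobleaching, stage
drift), camera noise statistics, cell motility or death, bead aggregation,
spectral spillover, or donor-to-donor variation beyond the preset
parameters. Tests passing on synthetic data therefore certify the analysis
machinery — fitting, calling, gating, statistics, and the image round trip —
not robustness to real-microscopy artefacts.

## 6. The simplified segmenter

Wells are located from the known array grid (the renderer and segmenter
share the layout — fiducial detection is out of scope). Within each well,
objects are found by thresholding above the local background (median of the
well crop) and connected-component labelling (`EBImage::bwlabel`);
components are split at their internal intensity peaks (nearest-peak
deduplication within 2σ), and each object's MFI is the mean over the
half-maximum core around its peak minus the local background median.
Detection and measurement channels are decoupled, so beads are detected on
the bead-marker channel and measured on the cytokine channel. Beads are
matched across frames by nearest centroid within the well (they are sessile
and well-confined); ambiguous assignments mark a trace low-confidence.

## 7. Problem sizes and reproducibility

The shipped tests and the acceptance script choose sizes that make each
property measurable at desk scale: solver validation on the 40 μm preset at
2–4 μm voxels over 6 h; sweeps over
$\theta_0 \in \{10^{-9}, 10^{-8}, 10^{-7}\}$ mol/m² with two bead–cell
placements; 200 Monte-Carlo fit replicates; a 1,000-well classifier cohort;
200–300 calibration replicates for the statistical tests; and a 144-well
imaged end-to-end run at 2 μm pixels (the 0.65 μm default pixel is used in
the intensity-fidelity tests). Every random stage takes an explicit seed,
pipeline outputs carry the configuration hash and seed in a header comment,
and rerunning a configuration reproduces its tables byte-for-byte.

## 8. Known limitations

* The solver handles one cell and one bead per well; multi-object wells are
  generated and analysed statistically but not simulated physically.
* The stair-step geometry needs ≥ 2 μm voxels to resolve a 5 μm bead;
  placements are validated and rejected otherwise rather than silently
  degraded.
* MFI is proportional to captured density with an unspecified constant; no
  absolute analyte calibration (e.g. ng/ml detection limits) is modelled.
* The plug-in cooperation null ignores uncertainty in $p_1$; it is accurate
  at the array-scale single-cell well counts it is run with.
* The mid-p enrichment default trades strict type-I guarantees for
  calibration; use `method = "fisher"` where guaranteed conservatism is
  preferred.
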