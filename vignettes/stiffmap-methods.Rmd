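---
title: "Models and methods behind stiffmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stiffmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiffmap)
```

`stiffmap` reimplements, on synthetic data with known ground truth, the
computational chain of a peri-cellular stiffness study: optical-tweezers
active and passive microrheology, a cell-centric coordinate system with
a folded annular stiffness landscape, hydrogel pore sizing, per-cell
immunofluorescence metrics, and the accompanying statistical models.
This vignette describes the models, the defaults and why they were
chosen, the numerical decisions, and what the synthetic validation does
and does not demonstrate about real data.

## Units

One convention is used everywhere: lengths in µm, forces in pN, time in
s, stiffness in pN/µm, drag in pN·s/µm, energy in pN·µm, moduli in Pa
(1 Pa = 1 pN/µm²). Thermal energy is derived from temperature with
`kB = 1.380649e-5 pN·µm/K`; the default temperature is 310.15 K
(37 °C, incubated samples), giving `kBT ≈ 4.28e-3 pN·µm`.

## Bead dynamics and the active-microrheology loop

The per-axis dynamics of a probe bead in a Kelvin–Voigt medium
(stiffness `kappa_m`, drag `gamma`) held by a linear optical trap of
stiffness `k_trap` whose center follows `x_T(t) = A sin(2*pi*f*t)` are
overdamped (the bead Reynolds number is far below 1, so inertia is
dropped):

```
gamma dx = [-kappa_m x + k_trap (x_T - x)] dt + sqrt(2 kBT gamma) dW.
```

Because this SDE is linear, `gen_amr_signals()` integrates it with the
**exact exponential (Ornstein–Uhlenbeck) one-step update** rather than
Euler–Maruyama: over a step `h` the homogeneous part contracts by
`exp(-lambda h)` with `lambda = (kappa_m + k_trap)/gamma`, the
sinusoidal forcing contributes its closed-form integral, and the noise
increment has exactly the stationary-consistent variance
`(kBT/kappa_tot)(1 - exp(-2 lambda h))`. The update is exact in
distribution at any step size, so stiff media (`kappa_m/gamma` up to
5×10⁶ s⁻¹ in the validation grid) need no stability guard and the
sampled path coincides with the continuous solution at the sample
times. An explicit Euler scheme would need step sizes around 10⁻⁸ s for
the stiffest grid point — about 10⁷ samples per one-second record — for
no gain in fidelity.

The analysis loop mirrors an instrument session:

1. `gen_calibration_sweep()` / `fit_conversion_factor()`: the
   voltage-to-µm factor is the least-squares slope over the **central
   60%** of a 200 nm stage sweep at 100 nm/s. The central restriction
   exists because a real QPD responds sigmoidally near the sweep edges
   (the synthetic sweep reproduces this with tanh tails); fits with
   r² < 0.9 are flagged.
2. `volts_to_displacement()`: division by the gain, then
   mean-centering. Bead/axis identifiers are enforced because a
   calibration is only valid for its own bead and axis.
3. `lockin_extract()`: the record is truncated to an integer number of
   drive cycles after discarding the **first two cycles** (overdamped
   settling transient; the slowest validated configuration has a
   relaxation time well under one cycle), then projected onto
   `exp(-i w t)`. Phases are reported relative to the trap drive, so a
   positive real part means in phase with the drive and the phase of
   `alpha*` is meaningful without an absolute time origin. Over integer
   cycles the projection is exactly linear and exactly rejects
   harmonics.
4. `optical_force()` (`F = k_trap (x_T - x)`), `compute_kappa()`
   (`kappa* = F/X`, reported stiffness `kappa' = Re kappa*`; the
   imaginary part is retained but not reported, consistent with the
   per-axis acquisition this emulates), and `generalized_stokes()`
   (`G* = kappa*/(6 pi r)`, exact in these units: `kappa* = 6*pi` pN/µm
   with `r = 1` µm is 1 Pa).

For a noise-free medium the recovered `kappa'` equals the generative
`kappa_m` to machine precision across `kappa_m` in 5–5000 pN/µm,
`gamma` in 0.001–0.01 pN·s/µm, drive frequencies 20–200 Hz and trap
stiffnesses 10–10⁴ pN/µm (trap-stiffness invariance of the estimator).
With thermal noise at 310 K, a single one-second record carries an
irreducible stochastic error — at `kappa_m = 5` pN/µm its standard
deviation is around 3% regardless of `k_trap` — so the validation
evaluates what the emulated study reports: the **median over 40
one-second bead records per condition**, which recovers `kappa_m`
within 5% with margin. Defaults the study leaves open are free
parameters here, chosen once: `k_trap = 100` pN/µm, QPD gains 5 and
4 V/µm, 1 s per axis, 10 kHz sampling.

## Passive microrheology

`gen_pmr_trajectory()` simulates the trap-off dynamics
(`gamma dx = -kappa_m x dt + sqrt(2 kBT gamma) dW`; a Wiener path when
`kappa_m = 0`), with the initial position drawn from the stationary
distribution so the analytic MSD applies from lag zero. Defaults are
30 s at 10 kHz. `compute_msd()` evaluates the 1-D MSD at log-spaced
lags from one sample to a quarter of the record (about 40 lags; the
longest-lag quarter is excluded because too few independent segments
remain there).

`gser_invert()` uses the local power-law (Mason-type) estimator: the
log-log slope `alpha(tau)` from a quadratic fit over a centered 5-point
window (clipped to [0, 1] — negative or super-diffusive fitted slopes
are unphysical for a passive bead and arise only from estimation
noise), then

```
|G*(w)| = kBT / (3 pi r MSD(1/w) Gamma(1 + alpha)),
G'  = |G*| cos(pi alpha / 2),   G'' = |G*| sin(pi alpha / 2).
```

The factor 3 (not π alone) encodes the **1-D MSD convention**
(`<dr²>_3D = 3 MSD_1D`); with per-axis acquisition this must be stated
explicitly or all moduli silently shift by 3×. The estimator is
validated against analytic limits: a Newtonian medium returns
`G''/w` within 10% of `gamma/(6 pi r)` over 1–100 Hz with
`G' < 0.1 G''`; a Kelvin–Voigt medium returns the plateau
`kappa_m/(6 pi r)` within 10%; `MSD ∝ sqrt(tau)` returns `G' = G''`
exactly. Frequencies are reported as `f = 1/(2 pi tau)`. Because a
single 30 s trace leaves several-percent noise in the MSD at the
longest lags used, the validation averages the MSD over five
trajectories before inversion. The windowing and lag spacing of the
inversion are package choices validated against analytic media only;
they are not claimed to replicate any particular legacy code.

`amr_pmr_compare()` interpolates PMR moduli onto the AMR frequencies in
log-log space within the overlapping support and reports paired
differences with a Wilcoxon signed-rank test; it is descriptive only.
A naive PMR readout of a trap-confined bead (the trap spring adds to
the medium spring) yields an inflated `G'`, and the package reproduces
this bias direction on matched synthetic media.

## Cell-centric geometry

All geometry happens in physical coordinates (µm, y up); masks (row,
column, y down) are converted on entry, and distances scale linearly
with `pixel_size`.

- `orientation_from_mask()`: centroid from first moments, long axis
  from the principal axis of the second central moments (regionprops
  convention, angle in [0°, 180°)). An isotropic shape (circle) has no
  defined axis; it is reported as 0° with a `degenerate` flag rather
  than an arbitrary noise-driven angle.
- `shortest_distance()`: exact minimum point-to-segment distance over
  the outline; beads inside the outline get distance 0 and an `inside`
  flag and are excluded from maps (the method probes the ECM, not the
  cytoplasm).
- `angular_position()`: signed angle between the centroid-to-bead
  vector and the front direction, folded across the long axis into
  [0°, 180°] under the mirror-symmetry assumption (0° = front,
  180° = rear). Folding makes mirrored beads identical and the
  coordinate invariant to rigid motions, provided the front assignment
  moves with the scene.
- The front is assigned per cell by mode: `long_axis` with the sign
  determined by `migration_front()` (rigid stage drift is estimated
  from ≥ 3 matched distal fiducial beads by least squares and
  subtracted from the centroid displacement; if the corrected
  displacement projects less than **0.5 µm** — a package choice, about
  half a bead diameter — the cell is treated as non-migrating),
  `image_axis` (front = image right, the convention for rounded
  non-migrating cells), or `lysis_axis` (front = away from a supplied
  direction of enzymatic matrix degradation, for fibrin).

## The annular stiffness landscape

`bin_grid()` defaults to radial edges 0/25/50/100/150 µm by five 36°
sectors — twenty bins whose inner annulus is the < 25 µm peri-cellular
region and whose outer edge is the 150 µm maximum analysis distance.
The exact partition used in the emulated study is not printed anywhere;
these edges reproduce its bin count and its narrative distances, are
configurable, and are written into every output rather than asserted as
canonical. Intervals are half-open `[lo, hi)` with the two top edges
closed. `build_map()` takes per-bin **medians** (the nonparametric
summary used throughout), restricted to one oscillation axis at a time;
empty bins stay `NA`, and a bead-conservation identity
(`in_range + out_of_range + inside + flagged = total`) is maintained.
`anisotropy_summary()` reshapes per-bead × axis stiffness into blocks
and applies the Friedman test.

## Synthetic stiffness fields

`gen_stiffness_field()` scatters beads uniformly in the annulus between
the outline and `max_distance` (rejection sampling) and draws per-axis
stiffness from the log-normal generative model
`ln kappa' ~ N(beta0 + beta_d d + beta_theta theta + beta_cond,
sigma_log)` — the generative twin of the regression fitted downstream,
which is what makes coefficient-recovery and coverage tests meaningful.
The pipeline defaults emulate the study conditions: four collagen
concentrations with condition effects that raise stiffness
monotonically (reference level 1.0T1C at exp(β₀) ≈ 10–20 pN/µm), an
angular trend `beta_theta = -0.002 per degree` (stiffness declines from
front to rear), no distance trend (`beta_d = 0`; distance was not a
predictor under the emulated 48 h conditions), `sigma_log = 0.5`
(roughly a factor-1.6 log-normal spread, a realistic dispersion for
probed stiffness in fibrous gels), 250 beads per condition probed on 4
axes up to 150 µm. Coefficient-recovery tests use `sigma_log = 0.3`
with `beta_d = -0.01`, the configuration whose confidence-interval
coverage is checked over 100 replicates of 5000 rows.

## Pore sizing

`pore_size_distribution()` reports, per pore, the diameter of the
largest inscribed sphere:

1. **3-D Euclidean distance transform** of the pore phase in physical
   units (separable lower-envelope parabola algorithm; anisotropic
   voxels supported). This is implemented in the package because the
   available image library computes distance maps per 2-D slice only.
2. **Seeded watershed** on the distance map. Seeds are the regional
   maxima of the h-maxima transform — the geodesic reconstruction of
   `dist - h` under `dist` — so maxima shallower than `h` merge with
   their neighbors instead of oversegmenting plateaus; `h` defaults to
   1 voxel and is exposed. Flooding descends quantized distance levels
   (quantization step `h/2`) and never creates regions beyond the
   seeds.
3. Diameter = 2 × the maximum distance-transform value in the pore.
   Pores touching the volume border are excluded because their
   inscribed sphere is truncated.

Carved calibration spheres of 8, 10 and 12 voxels are recovered within
±1 voxel, a 3-voxel wall between two spheres is correctly split, and
increasing fiber density monotonically decreases the median pore size
across seeds. `gen_fiber_stack()` with `n_fibers = 0` produces a solid
block (the carving fixture); with fibers, random dilated line segments.

## Immunofluorescence metrics

Metrics are computed on maximum-intensity projections, matching the
2-D procedure this pipeline emulates even though acquisition is 3-D.
Segmentation (`segment_channels()`) is Gaussian smoothing (σ = 1 px)
followed by Otsu thresholding — the binarization method of the emulated
study is unspecified, so Otsu is a documented stand-in — with the
largest connected component kept for nucleus and F-actin and the
nucleus intersected with the filled F-actin support. The punctate
fibronectin channel is thresholded **without** smoothing: σ = 1 blur
dilutes single-voxel puncta below the Otsu threshold and would bias the
partition toward dense clusters.

- `yap_ratio()`: mean YAP in the nucleus over mean YAP in the
  cytoplasm (F-actin minus nucleus); invariant to global intensity
  scaling; exact on noise-free constructions and within 5% at 5% noise
  through full segmentation.
- `fibronectin_partition()`: `100 (1 - |fn ∩ actin|/|fn|)` percent
  outside; exact counting on constructed masks.
- `shape_metrics()`: area from the pixel count; perimeter from the
  sub-pixel 0.5-level contour of the lightly smoothed (σ = 1) mask.
  Pixel-edge counting biases a disk's circularity by tens of percent,
  which is why the contour route is used: a rasterized disk measures
  circularity 0.99, a square π/4 ± 0.02. Solidity uses the convex hull
  of the contour. The smoothing rounds sharp corners slightly, which
  is visible as a ≈ +0.015 circularity bias for a square — within the
  stated tolerance and documented here rather than hidden.

## Statistics

`mer_fit()` is the package's reading of "multivariate exponential
regression": an exponential mean model estimated as ordinary least
squares of `ln kappa'` on distance, folded angle and dummy-coded
discrete covariates (condition, oscillation axis) against declared
reference levels (1.0T1C; the 0° axis). It is fitted by the package's
own QR decomposition — `stats::lm` serves as the independent
cross-check in the tests, reproducing coefficients, standard errors and
R² to 10⁻¹⁰ — and returns a classed object with `print`, `summary`,
`coef`, `confint`, `predict` (natural scale = conditional median
`exp(X b)`), `residuals` and `simulate` methods. "Variance explained"
is the log-scale R²; a gamma-GLM pseudo-R² would be the main
alternative and is deliberately not the default because the generative
model is log-normal. `sigma_log = 0` data give R² = 1 exactly; constant
data give 0.

The nonparametric battery delegates to base R where base R is the
canonical implementation (Friedman, Kruskal–Wallis, Pearson, KS,
Wilcoxon) behind the module's interface. Two pieces are implemented in
the package because no installed routine provides them: the rank-based
Tukey–Kramer post hoc after Kruskal–Wallis (pairwise mean-rank
differences against the studentized-range critical value with tie
correction) and the Ansari–Bradley p-value, computed by **exact
enumeration of all assignments of the folded-rank scores when
n ≤ 20** (ties handled naturally by enumerating realized scores; the
two-sided p is twice the smaller tail, capped at 1) and by a
finite-population normal approximation otherwise — keeping
`stats::ansari.test` available as an independent cross-check rather
than the implementation.

Calibration: Friedman, KW and AB hold a type-I error of 0.05 ± 0.02
under matched null simulations (1000 replicates at 50 blocks × 4, 3 ×
20, and 2 × 25 respectively — sizes where the asymptotic approximations
are expected to hold; at 5 blocks the Friedman chi-square p can differ
from the exact permutation p by ≈ 0.1, which the tests document).
`ks_normality()` defaults to the pragmatic screen — a one-sample KS
test against a normal with the sample's own mean and SD — and its
documentation carries the caveat that parameter estimation inflates the
p-value (the screen is conservative; its true type-I error at nominal
0.05 is near zero). For a meaningful calibration of the KS machinery
the function accepts fixed `mean`/`sd`, and the fixed-parameter null is
what the calibration harness exercises. A zero-variance sample returns
D = 0.5 (the empirical step function against the limiting point mass)
with a `degenerate` flag. Significance is 0.05 throughout, with the
normality screen read at 0.01.

## Pipeline and problem sizes

`run_experiment()` runs every stage from one configuration
(`default_config()`, overridable by a nested list or YAML file), writes
all intermediates as CSV/JSON plus a cross-linked `report.md`, and is
byte-identical across reruns with the same seed: all randomness derives
from the single config seed. The demo sizes — 3 beads × 4 axes per
condition for AMR, one 30 s PMR trace, 250 beads × 4 axes × 4
conditions for the landscape, 40³-voxel fiber volumes, three imaged
cells — were chosen so a complete run takes well under a minute on one
CPU while still exercising every code path; they are configuration
values, not limits of the methods.

## What the synthetic validation does not show

The generators are the validation's ground truth, and their idealization
bounds what passing tests mean for real data: dynamics are 1-D per
axis with a purely harmonic trap and no hydrodynamic memory (Basset
forces), bead rotation, or anharmonic trapping; the Kelvin–Voigt and
power-law media cannot stand in for the full relaxation spectrum of
collagen or fibrin; synthetic cells are ellipses with uniform
compartment intensities, so segmentation accuracy on noisy, textured
micrographs is untested; fiber volumes are straight dilated segments,
not curved bundled fibers; and instrument systematics (detector
nonlinearity beyond the sigmoidal sweep, drift within a record,
limit-of-detection effects) are out of scope. The published
experimental numbers of the emulated study derive from undeposited
laboratory data and are deliberately not targets; the validation is
property-based throughout.
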