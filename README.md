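# stiffmap

Peri-cellular stiffness mapping by optical-tweezers microrheology.

Cells remodel the extracellular matrix (ECM) around them, and the
stiffness they experience locally can differ sharply from the bulk
rheology of the hydrogel they sit in. `stiffmap` implements, as a tested
and reusable R pipeline, the computational chain used to measure and map
that peri-cellular stiffness with optical tweezers:

- **Active microrheology (AMR).** A trapped probe bead (radius
  *r* = 1 µm) is oscillated sinusoidally (60 nm, 20–200 Hz) along four
  axes (0°, 45°, 90°, 135°). From the quadrant-photodiode (QPD) records
  of trap and bead position, the drive-frequency Fourier components of
  bead displacement *X* and optical force *F* give the complex
  compliance *X = α\*(ω)·F*, the complex stiffness
  *κ\*(ω) = 1/α\*(ω)* (reported stiffness *κ′ = Re κ\**, pN/µm) and,
  via the generalized Stokes relation, the shear modulus
  *G\*(ω) = κ\*(ω)/(6πr)* in Pa.
- **Passive microrheology (PMR).** 30 s thermal bead trajectories at
  10 kHz are reduced to a mean-square displacement (MSD) curve and
  inverted with the generalized Stokes–Einstein relation using the
  local power-law estimator: *|G\*| = k_BT / (3πr·MSD(1/ω)·Γ(1+α))*
  with *α = d ln MSD / d ln τ*.
- **Peri-cellular geometry and mapping.** Each probed bead is placed in
  a cell-centric coordinate system — shortest distance *d* to the traced
  cell outline and angular position θ about the centroid, folded across
  the cell's long axis into [0°, 180°] (0° = front, 180° = rear) — and
  binned into a twenty-bin annular landscape (radial edges
  0/25/50/100/150 µm × 36° sectors; the < 25 µm annulus is the
  peri-cellular region) shaded by median κ′.
- **Hydrogel microstructure and immunofluorescence.** Pore sizes of
  fibrous volumes as the maximum inscribed-sphere diameter per pore via
  a 3-D distance-transform watershed; nuclear/cytoplasmic YAP ratio,
  fibronectin partitioning, circularity *4πA/P²* and solidity
  *A/A_hull* from multi-channel stacks.
- **Statistics.** The multivariate exponential regression (MER) of
  stiffness, *ln κ′ = β₀ + β_d·d + β_θ·θ + Σ β_level·1[level] + ε*,
  with dummy coding against declared reference levels, plus the
  accompanying nonparametric battery (Friedman across oscillation axes,
  Kruskal–Wallis with rank-based Tukey–Kramer post hoc, Ansari–Bradley
  dispersion test with exact small-sample null, Pearson correlation,
  Kolmogorov–Smirnov normality screen).

No laboratory data ship with the package. Every input class has a
synthetic generator with known ground truth — driven overdamped Langevin
bead dynamics, log-normally dispersed stiffness fields with
distance/angle/condition trends, fibrous volumes with carved calibration
cavities, and four-channel cell images with prescribed YAP ratio and
fibronectin partition — so the whole chain is testable end to end.

It is aimed at researchers in cell mechanobiology and microrheology who
want a scripted, reproducible version of this analysis or a validated
reference to compare an instrument pipeline against.

## Worked example

```r
library(stiffmap)

## --- AMR: recover the stiffness of a known medium ---------------------
medium <- medium_params(kappa_m = 50, gamma = 0.01)   # Kelvin-Voigt, 37 C
trap   <- trap_params(k_trap = 100, amplitude = 60, frequency = 50)
sig    <- gen_amr_signals(medium, trap, duration = 1,
                          sampling_rate = 1e4, seed = 1)
cf     <- fit_conversion_factor(gen_calibration_sweep(trap$volts_per_um_det,
                                                      seed = 2))
resp   <- compute_kappa(amr_lockin(sig, trap, cf_det = cf))
resp
#> <complex_response> kappa' = 49.95 pN/um (kappa'' = 3.12) at 314 rad/s
generalized_stokes(resp, radius = 1)
#>    G_prime G_doubleprime frequency source bead_radius
#> 1 2.649924     0.1654528        50    AMR           1
```

The recovered κ′ = 49.95 pN/µm matches the generative κ_m = 50 pN/µm to
0.1% despite thermal noise at 310 K; κ″ = 3.12 equals ωγ at 50 Hz, and
G′ = κ′/(6π) ≈ 2.65 Pa.

```r
## --- a stiffness landscape and the MER --------------------------------
cell  <- make_ellipse_cell(a = 40, b = 15)
trend <- field_trend(beta0 = log(20), beta_theta = -0.002,
                     beta_condition = c("1.0T1C" = 0, "2.0T1C" = 0.69),
                     sigma_log = 0.5)
beads <- rbind(
  gen_stiffness_field(cell, trend, 250, condition = "1.0T1C", seed = 3),
  gen_stiffness_field(cell, trend, 250, condition = "2.0T1C", seed = 4))
build_map(beads[beads$condition == "1.0T1C", ], bin_grid(), axis_filter = 0)
#> <stiffness_map> 4 x 5 bins, 250 beads in range, axis 0 deg
summary(mer_fit(beads))
#>                      Estimate  Std. Error t value Pr(>|t|)
#> (Intercept)        2.95980853  0.04019265 73.6405   <2e-16 ***
#> distance           0.00039466  0.00028143  1.4024   0.1610
#> theta_deg         -0.00194078  0.00020433 -9.4981   <2e-16 ***
#> condition2.0T1C    0.69347507  0.02198816 31.5386   <2e-16 ***
#> ...
#> Variance explained: 35.5%
```

The fit recovers the generative coefficients: the condition contrast
(true 0.69) and the angular trend (true −0.002) are estimated within
one standard error, distance is correctly flagged as a non-predictor,
and the intercept exp(2.96) ≈ 19.3 pN/µm matches exp(β₀) = 20.

The full chain — simulation, calibration, AMR/PMR, geometry, maps, pore
sizing, image metrics, statistics, and a cross-linked `report.md` — runs
from one configuration:

```r
run_experiment(default_config(seed = 3), out_dir = "demo_run")
```

or from a shell via `inst/scripts/run_pipeline.R`.

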