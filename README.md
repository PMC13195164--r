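# uvcled

Analysis toolkit for UV-C LED water-disinfection experiments on indicator
bacteria (*Escherichia coli*, *Enterococcus faecium*). It is aimed at
disinfection researchers who measure plate-count survival curves under UV-C
LEDs at different wavelengths and want, from one tested codebase:

- **Inactivation kinetics** — log reductions `L = log10(C0/C)`, the
  fluence-based inactivation rate constant `kf` (cm²/mJ) from linear
  regression over the initial fluence range, and an origin-constrained
  quadratic fit `L = aF² + bF` capturing the tailing seen at high fluence;
- **Required-fluence tables** — `F = target / kf`, rounded half-up to one
  decimal, for 2-, 4- and 6-log targets;
- **Photoreactivation / dark repair** — recovery `Δlog = L(0 h) − L(t)`
  after post-UV incubation, classified none / limited / substantial;
- **Single-cell microscopy** — classical segmentation (Gaussian smoothing,
  Otsu, distance-transform watershed) or imported label masks, per-cell
  intensity statistics including the population skewness
  `g1 = m3 / m2^{3/2}` of DAPI-stained nucleoids (a metric of UV-induced DNA
  condensation), and PI-positive membrane-integrity fractions from
  SYTO9/PI staining;
- **CPD ELISA calibration** — linear or four-parameter-logistic standard
  curves with inverse prediction of cyclobutane-pyrimidine-dimer
  concentrations, flagging out-of-range and sub-blank (not detected)
  absorbances.

Because raw CFU tables and microscopy images from such studies are rarely
deposited, the package includes first-class synthetic generators: a
two-population survival model
`C(F) = C0·[(1−p)·10^(−kf·F) + p·10^(−ρ·kf·F)]` observed through Poisson
plate counts with a detection limit, multi-channel fluorescence scenes
(phase, FM4-64-like membrane, DAPI-like DNA, SYTO9, PI) with ground-truth
masks and a tunable nucleoid-condensation parameter κ, and monotone ELISA
standards. Every analysis stage is tested against these generators.

## Worked example

Fit kinetics on a simulated tailing survival curve and invert the rate
constant into required fluences:

```r
library(uvcled)

p  <- inactivation_params(1.202, resistant_fraction = 1e-6,
                          resistance_factor = 0.1, C0 = 1e8)
cv <- simulate_survival_curve(p, c(0, 1, 2, 3, 4, 6, 8, 10, 14), seed = 42)
s  <- log_reduction_series(cv)
fit_linear_kinetics(s)
#> Linear inactivation kinetics (fluence <= 6 mJ/cm2)
#>   kf = 1.140 +/- 0.014 cm2/mJ  [R2 = 0.997]  (12 points, 2 replicates)
fit_polynomial_kinetics(s)
#> Quadratic kinetics through origin (fluence <= 14 mJ/cm2)
#>   L = -0.0812 F^2 + 1.5232 F  [R2 = 0.988]
required_fluence(fit_linear_kinetics(s)$kf)
#>   target_log required_fluence
#> 1          2              1.8
#> 2          4              3.5
#> 3          6              5.3
```

`kf` is the slope of log reduction versus fluence (cm²/mJ): 1.14 cm²/mJ
means about 1.1 decades of inactivation per mJ/cm². It lands slightly below
the generating 1.202 because the shielded subpopulation flattens the curve
near the 6 mJ/cm² cutoff, and the negative quadratic coefficient `a`
quantifies exactly that tailing. The required-fluence rows say that, at this
rate constant, ≈ 1.8 / 3.5 / 5.3 mJ/cm² achieve 2 / 4 / 6 decades of kill.

A full table from measured rate constants (shipped for the ten
environmental organism x wavelength combinations):

```r
kf  <- read.csv(system.file("extdata", "environmental_rate_constants.csv",
                            package = "uvcled"))
head(build_fluence_table(kf), 3)
#>   wavelength_nm organism        strain log2_mJcm2 log4_mJcm2 log6_mJcm2
#> 1           255  E. coli environmental        1.7        3.3        5.0
#> 2           260  E. coli environmental        1.8        3.6        5.4
#> 3           265  E. coli environmental        1.2        2.5        3.7
```

Single-cell analysis of a rendered scene (300 cells, κ = 0.5, 5%
PI-positive):

```r
sc  <- render_scene(scene_spec(n_cells = 300L, kappa = 0.5,
                               pi_positive_prob = 0.05, seed = 1))
st  <- as_channel_stack(sc)
rec <- classify_pi_positive(per_cell_stats(st, segment_cells(st)))
summarize_image(rec)
#>   n_cells skewness_mean skewness_median skewness_sd pi_fraction
#> 1     300      1.462497        1.463951   0.0320762    4.333333
```

The command-line wrapper (`system.file("cli", "uvcled.R", package =
"uvcled")`) exposes the same stages — `simulate`, `fit-kinetics`,
`fluence-table`, `reactivation`, `analyze-images`, `cpd`, `report` — driven
by a JSON config; every run writes its resolved configuration beside the
outputs.

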