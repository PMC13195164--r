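---
title: "UV-C LED disinfection analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UV-C LED disinfection analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvcled)
```

This vignette explains the science implemented by `uvcled`: the kinetic
model and its assumptions, what each tunable parameter means, what the
synthetic generators do and do not emulate, the numerical conventions, and
the design choices that were genuinely open.

## Inactivation kinetics

Under ideal conditions UV disinfection follows first-order kinetics in
fluence: the log reduction `L(F) = log10(C0 / C(F))` grows linearly with
the delivered fluence `F` (mJ/cm²), with slope `kf` (cm²/mJ), the
fluence-based inactivation rate constant. Real high-titre suspensions
instead show *tailing*: the curve flattens at high fluence because a small
subpopulation is partially shielded, e.g. inside cell aggregates. We model
this with a two-population mixture,

$$C(F) = C_0\left[(1-p)\,10^{-k_f F} + p\,10^{-\rho k_f F}\right],$$

where `p` is the shielded fraction and `ρ < 1` scales its rate constant.
This is the simplest mechanism that reproduces concave log-survival and has
closed forms for tests: with `p = 0` the model is exactly first-order, and
with `ρ = 0` the log reduction plateaus at `−log10(p)`. The defaults
`p = 1e−6`, `ρ = 0.1` are placeholders chosen to give a shoulder near 6
logs — the magnitude at which tailing is typically seen in such assays with
`C0 ≈ 1e8` CFU/mL — not measured quantities; the shielded fraction is not
identifiable from typical published summaries.

Fitting follows the practice of wavelength-comparison studies:

- **Linear fit** (`fit_linear_kinetics`) over fluences up to a cutoff
  (default 6 mJ/cm², before the shoulder): ordinary least squares with a
  free intercept per replicate. `kf` is the mean of per-replicate slopes and
  `kf_sd` their sample standard deviation, matching the "duplicate
  experiments (and standard deviations)" convention; R² comes from the
  pooled fit. The free intercept absorbs small lag/offset effects, while
  downstream fluence requirements use only `L/kf` — this combination
  reproduces published required-fluence tables cell for cell.
- **Quadratic fit** (`fit_polynomial_kinetics`) over the full range
  (default 14 mJ/cm²): `L = aF² + bF`, constrained through the origin
  because `L(0) = 0` by definition (intercept handling is otherwise
  ambiguous). Tailing data give `a < 0`.
- **Censoring**: zero counts are below the plating detection limit; those
  points carry `L ≥ log10(C0/limit)` and are excluded from fits rather than
  substituted, which would bias slopes toward the substitution constant.

`required_fluence(kf, target)` returns `target / kf` rounded **half-up** to
one decimal (base R's banker's rounding would turn 2.25 into 2.2, which is
not how published dose tables are formatted).

## Plate-count observation model

`plating_protocol()` encodes serial-dilution plating: counts are Poisson
with expectation `C · V / d` for plated volume `V` (default 0.1 mL) and
dilution `d`; plates above 300 colonies are "too numerous to count" and the
next dilution is used; duplicate plates are averaged. The detection limit is
one colony on the least diluted plate (10 CFU/mL at the defaults). Across
100 seeds at `C0 = 1e8` the fitted `kf` recovers the generating value with
well under 5% bias (this is asserted by the test suite and recomputed by
`scripts/acceptance.R`).

## Reactivation

Recovery after post-UV incubation is `Δlog = L(0 h) − L(t)` with `L`
measured against the pre-UV concentration; negative values (continued
decay) are reported as such. Classification: below 0.1 log is "none" (the
floor absorbs duplicate-plate counting noise at 10²–10⁸ CFU/mL); up to and
including the 0.5-log threshold is "limited"; strictly above is
"substantial". The boundary convention is deliberate: recoveries of about
0.46–0.5 log are the magnitudes reported for these indicator organisms at
260–265 nm and are described in the field as limited, so the threshold
value itself classifies as limited. The threshold is a parameter for users
who draw the line elsewhere. The generator applies the configured recovery
at the sampled times after 0 h by default (enzymatic photorepair saturates
within a few hours), and a configurable schedule covers other designs.

## Synthetic microscopy scenes

`render_scene()` emulates the staining patterns of UV-damage microscopy —
not optics. Cells are capsules (rods) or discs (cocci) placed by rejection
sampling with a 2 px clearance, fully inside the frame. Channels:

- **phase**: bright background (600), dark cells (250);
- **membrane**: bright rim, dim interior (FM4-64-like outline);
- **dna**: each cell's signal is split `(1−κ)` uniform + `κ` into a
  Gaussian focus whose footprint is ~10% of the cell area, normalized to
  conserve total intensity. κ = 0 is a homogeneous nucleoid; κ = 1 a single
  bright focus with dim remainder — the condensed pattern seen after UV
  stress. Mean per-cell skewness increases with κ by construction;
- **syto9 / pi**: PI-positive (membrane-compromised) cells are bright in pi
  and quenched in syto9 (PI outcompetes SYTO9 on nucleic acids); intact
  cells the reverse.

Noise is Poisson shot noise on expected counts plus additive Gaussian read
noise (default sd 20 on signals of ~600 over a background of 100, SNR
roughly 15 — widefield EMCCD territory). Defaults: 512×512 px at 0.1 µm/px,
400 cells (the average per-image count in the motivating assays), rods
2.0 × 0.7 µm. Draw order is documented in `?render_scene`; one seed makes a
scene bit-reproducible.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: point-spread blur and defocus, uneven
illumination, staining heterogeneity within a population, aggregates and
biofilm geometry, filamentation, and the continuum of partial membrane
damage (PI state is binary). Results on synthetic scenes validate the
*computations*; they do not validate biological claims about real images.

## Segmentation and per-cell statistics

`segment_cells()` is a classical pipeline (Gaussian smoothing → global Otsu
→ hole filling → distance-transform watershed → area filter → border
exclusion → contiguous relabel) standing in for learned segmentation tools;
externally produced masks can be imported with `import_label_mask()` for
parity work, which validates integrality and per-label connectivity.
The default segmentation channel is **phase**, because it delineates whole
cells regardless of how the fluorescent stains partition; thresholding the
DNA channel collapses the mask onto the bright focus once the nucleoid
condenses (measured mean IoU drops from ~0.99 to ~0.39 at κ = 0.5), which
would destroy the whole-cell ROI that the skewness metric needs. Border
cells are excluded by default since truncated intensity distributions bias
skewness.

The skewness is the population third standardized moment
`g1 = m3 / m2^{3/2}`, `m_k = mean((x − x̄)^k)` — no Bessel correction,
matching common image-measurement platforms. It is computed over **all
pixels of the whole-cell mask** (not a nucleoid sub-region), on raw
intensities; background subtraction is left to the caller since the
measurement platforms this mirrors report raw-intensity skewness.
Zero-variance cells return 0 with a flag rather than NaN. Skewness is
invariant under affine intensity rescaling, so gain/offset choices do not
affect it.

One measured caveat: with classical segmentation the mask overhangs the
true cell by up to a pixel, so a handful of background-level pixels join
each ROI. At κ = 0 this produces *negative* mean skewness (a left tail of
dim pixels) instead of ~0; with tight ground-truth masks the κ = 0 mean is
~0 as expected. The monotone increase of mean skewness in κ — the
scientifically relevant signal — holds through the full segmentation
pipeline in every seed we tested and is asserted as a property test.

`classify_pi_positive()` uses two criteria: the per-cell pi-channel mean
must exceed max(Otsu split of the per-cell pi means, an absolute floor
defaulting to twice their median — which keeps all-negative fields at 0%),
and, when syto9 is present, the max-normalized pi mean must dominate the
max-normalized syto9 mean (the stain flip of compromised cells). All
thresholds used are attached to the returned records. Per-image summaries
report the PI-positive percentage; per-condition summaries report
mean ± sample sd across images (≥ 2 images required for an sd), the format
in which such fractions are reported.

## CPD ELISA calibration

Standard curves are fitted either linearly or with the four-parameter
logistic `y = d + (a − d)/(1 + (x/c)^b)` — the standard immunoassay model —
via Levenberg–Marquardt least squares (`minpack.lm`), requiring a strictly
monotone fit so inverse prediction is unique. Inversion is closed-form;
absorbances outside the fitted response range (for 4PL, outside the
asymptotes) are flagged out-of-range and *not* extrapolated, and
absorbances at or below the blank are reported "not detected" with
concentration 0 — the behaviour expected of dark controls. Outputs stay in
the units of the kit's CPD-DNA standard, normalized to the assay's DNA
input; no unit conversion is invented because kit units are not convertible
without lot-specific information.

## Numerical and testing conventions

- Rounding: half-up at one decimal for fluence tables only; nothing else is
  rounded.
- RNG: every stochastic operation takes one integer seed and documents its
  draw order; the same seed is bit-reproducible.
- Degenerate inputs: blank images segment to empty masks (not errors);
  empty scenes have empty truth tables; all-zero label masks import
  cleanly; constant pixel vectors have zero variance flagged.
- Problem sizes in the test suite and acceptance script — scenes of 300–400
  cells at 512×512 px, 100-seed bias studies, 1000-vector property tests —
  were chosen as the smallest sizes at which the stochastic properties
  under test are stable across seeds.
- Watershed splitting uses tolerance 1 on the distance transform: capsule
  geometry gives one interior ridge per cell, so single rods survive
  unsplit while end-to-end doublets separate at the neck.

## Known limitations

- The two-population tailing model is phenomenological; `p` and `ρ` are not
  identifiable from a single survival curve without dense high-fluence
  sampling.
- Classical segmentation under-performs learned tools on crowded or
  low-contrast fields; import masks from such tools when available.
- The condensation parameter κ is a rendering control, not a biophysical
  quantity; only the *ordering* of skewness across κ levels is meaningful.
- PI classification assumes a bimodal pi-mean distribution when positives
  are present; extremely rare positives (< ~0.5%) may fall below the Otsu
  split and are then caught only by the floor criterion.
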