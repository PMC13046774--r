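---
title: "Models and methods behind evcyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evcyto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcyto)
```

`evcyto` turns per-event flow cytometry measurements of extracellular
vesicles (EVs) into physical quantities — diameters in nm, antibody binding
capacities, particles per mL — and profiles tetraspanin co-expression on the
calibrated events. This vignette explains the models, the defaults and why
they were chosen, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Scatter model

A particle illuminated by a plane wave scatters light according to Mie
theory. For a homogeneous sphere (a polystyrene calibration bead) the
partial-wave coefficients $a_n, b_n$ follow from the classical boundary-value
solution; for a vesicle we use the coated-sphere (Aden–Kerker) extension: an
aqueous core wrapped in a thin lipid shell. What a cytometer measures is not
the total scattering cross-section but the part of it falling into the
detector's collection cone:

$$\sigma_\mathrm{eff}
  = \int_\Omega \frac{|S_1(\theta)|^2 + |S_2(\theta)|^2}{2k^2}\, d\Omega,
  \qquad k = \frac{2\pi n_\mathrm{med}}{\lambda}.$$

Assumptions: plane-wave illumination (no Gaussian-beam correction),
unpolarized detection, spherical particles, real refractive indices by
default (complex accepted with non-negative imaginary part). No
fluorescence radiometry and no polarization-resolved detection.

### Optical defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| wavelength | 405 | nm | violet side scatter resolves sub-wavelength particles better than 488 nm |
| medium RI | 1.343 | – | water at 405 nm |
| polystyrene RI | 1.61 | – | literature value at 405 nm; manufacturer values override |
| vesicle core RI | 1.38 | – | cytosol-like aqueous lumen |
| vesicle shell RI | 1.48 | – | lipid bilayer |
| shell thickness | 5 | nm | bilayer thickness |
| aperture centre | 90 | deg | side scatter |
| aperture half-angle | 60 | deg | wide collection optics typical of small-particle instruments; configurable per instrument |
| quadrature | 24 × 24 | nodes | 576 collection angles |

The collection half-angle and the vesicle model are *declared assumptions*:
commercial instruments do not publish their collection geometry, and the
"right" core/shell indices for a heterogeneous biological vesicle population
are unknowable in principle. Both are stored in the optical configuration and
particle-model objects precisely so users can override them per instrument.
A consequence worth stating plainly: any scatter-equivalent diameter (e.g.
"an 80 nm polystyrene bead scatters like an X nm vesicle") is a
model-conditional statement. `scripts/acceptance.R` computes this quantity
under the defaults above; it moves substantially if the assumed core index or
collection geometry changes, so comparisons against equivalences derived on a
physical instrument are only meaningful when the same model and geometry are
supplied.

### Numerical choices

* Series truncation at $n_\max = \lceil x + 4x^{1/3} + 2\rceil$ (Wiscombe's
  rule), comfortable for the size parameters here ($x < 11$ at 1000 nm).
* Riccati–Bessel $\psi_n$ by downward recurrence normalised at $\psi_0$
  (stable for $n > |z|$), $\chi_n$ by upward recurrence (stable); both in
  complex arithmetic. The test suite cross-checks against a second,
  independently coded series built on base R half-integer Bessel functions
  and the logarithmic-derivative formulation.
* Coated-sphere coefficients reduce analytically to the homogeneous case
  when the shell has zero thickness or is index-matched to the core; those
  degenerate inputs are dispatched to the homogeneous path outright, and the
  coated branch is validated by continuity (vanishing shell) and by the
  exact identity that a shell index-matched to the *medium* scatters like
  the bare core.
* Aperture integration on a tensor Gauss–Legendre grid in
  $(\cos\alpha, \beta)$ over the collection cone; with the default 576 nodes
  the integral is stable to 0.1% under refinement for diameters up to
  500 nm, and over the full sphere it reproduces the series
  $C_\mathrm{sca}$ to better than 0.5%.
* Inversion of intensity to diameter interpolates linearly in
  $\log_{10}\sigma$–$d$ space on a 1 nm grid (30–1000 nm by default) and is
  restricted to the largest strictly-increasing prefix of the curve; out-of
  range intensities are flagged (`below_range` / `above_range`), never
  silently clamped.

## Scatter calibration

Measured bead intensities are scaled onto theory by least squares in log10
space. The default fits the *offset only* (slope fixed at 1): physically the
instrument applies a single multiplicative gain, and with 4–5 beads an
offset-only fit is far better conditioned. A slope-free diagnostic variant
(`slope_free = TRUE`) exists because a slope departing from 1 is a useful
red flag for detector non-linearity. Outlier flagging uses median-centred
residuals with a 3× peer-median rule and a 0.05 log10 floor, so one
miscalibrated bead cannot drag the reference level toward itself. Bead
subsets are user-selectable rather than hard-coded: on a noisy instrument
the smallest standard may sit in background and should be excluded *and
recorded*, not deleted. An optional triggering threshold is converted
through the calibration into a minimum resolvable diameter, reporting the
"everything below this is lost in noise" limit instead of dropping events
silently.

## Fluorescence (surface-area) sizing

Membrane dye uptake is modelled as proportional to membrane area with zero
intercept, $I = k\,\pi d^2$. The liposome standard's median diameter
defaults to 110 nm — the midpoint of its nominal 80–140 nm span — and should
be replaced by the user's own tracking-analysis median when available. The
proprietary kit layouts this mimics may include an intercept; if so, sizes
near the bottom of the range will be biased low, which is why the calibration
object keeps the raw standard median for audit.

## ABC limits of detection

ABC ladders span orders of magnitude, so the regression is done unweighted
in log10–log10 space and summarised by a Pearson R, the shape in which kit
templates report it. The LoD is the ABC equivalent of the blank's median
autofluorescence alone ($k = 0$); a configurable $k\cdot$SD term is provided
because some templates add a spread term, but it defaults off. A blank
mapping outside the calibrated range still yields a finite LoD, flagged
`extrapolated`. The default synthetic ladder is {5e3, 2e4, 8e4, 2.5e5}
antibodies plus a blank.

## Enumeration gating

Scatter-mode cascade: size gate (≤ 300 nm by default, consuming calibrated
diameters; events *below* the calibrated range pass an upper size gate) →
singlet gate (scatter area/height ratio within 0.5–2.0, a declared
assumption since published gates are drawn on plots, not printed) → calcein
positivity. Imaging-mode cascade: size gate on a scatter/intensity proxy
below the largest (151 nm) reference bead's position → brightfield
spot-count gate (spot count 0: any event with a brightfield image is an
artefact at this scale) → calcein gate → in-focus gate. The focus gate is
applied **only for cargo analysis** and never enters the enumeration count.
Thresholds from negative controls use the 99.9th percentile with linear
interpolation between order statistics (type-7 quantile), chosen because it
is reproducible across implementations.

Concentration is `count / acquired_volume(µL) × 1000 × dilution_factor`
(particles/mL); at 10 µL/min a two-minute acquisition gives 20 µL. The
detergent control requires ≥ 90% reduction of the calcein-positive count by
default. Dilution linearity regresses log10(count) on log10(1/dilution) and
calls the series linear iff |slope − 1| ≤ 0.1 and r² ≥ 0.98; a flat series
is reported as possible swarm (coincident sub-resolution particles). Zero
counts are excluded with a warning rather than breaking the log fit.
Background correction subtracts the volume-scaled control count and clamps
at zero with a warning.

## Titration

The stain index is $(\mathrm{med}_+ - \mathrm{med}_-)/(2\,\mathrm{SD}_-)$ —
the field's standard separation metric. Whether a published "stain index"
used medians or means is rarely stated, so the formula is isolated in one
function (`stain_index`) to be swappable. The optimum is the stain-index
argmax with ties broken toward the *lower* concentration (less dye, less
background); the plateau is the lowest concentration whose
background-corrected count is within 10% of the maximum.

## Tetraspanin profiling

Spillover is estimated from background-subtracted channel *medians* of
single-stained vesicle samples rather than by regression: at vesicle signal
levels a median is robust to the large dim fraction, and the matrix entries
are ratios of medians with negative values clamped to zero. Compensation
multiplies each event by the matrix inverse. Each calcein-positive event is
assigned to exactly one of the 8 marker combinations, so combination counts
always partition the calcein-positive set. Replicate summaries use t
intervals (mean ± t(0.975, n−1)·SD/√n); per-sample Poisson intervals are
left as future work since replicate wells dominate the variance in practice.
Counts and concentrations are both reported because it is ambiguous which a
replicate CI should summarise.

`compare_panel_sensitivity` contrasts a mixed panel (one fluorophore per
marker) with a pan panel (all antibodies on one fluorophore) on identical
ground truth under a per-channel detection limit; pooling bound antibodies
onto one detector can only help detection, so the pan sensitivity is
provably ≥ the mixed sensitivity — a directional statement, not an estimate
of any measured percentage.

## The synthetic instrument

The generator's transfer function is deliberately minimal:

* scatter: `gain × sigma_eff(d) × LogNormal(1, cv)` + Gaussian electronic
  noise, then a hard trigger threshold — the smallest model reproducing the
  "lost in noise" floor;
* calcein: zero signal for esterase-negative vesicles, log-normal brightness
  otherwise, plus Gaussian autofluorescence;
* markers: Poisson antigen copies (mean 20 per positive marker — a low-copy
  scenario knob, not a biological claim) × per-copy brightness, mixed
  through a spillover matrix, plus autofluorescence.

Two profiles bundle the study conditions. The *conventional* profile
(gain 10^2.5, noise SD 200, trigger 1500, 10 µL/min, 20 µL) hides a 60 nm
polystyrene bead in background and loses vesicles below roughly 100 nm — the
behaviour a high-trigger instrument exhibits. The *nanoscale* profile
(noise SD 20, trigger 150, 1 µL/min, 2 µL) resolves the lower tail of a
120 nm / GSD 1.4 log-normal population. Both are needed because no single
instrument can simultaneously show the background-limited behaviour and
recover a full vesicle size distribution; end-to-end recovery checks
therefore run on the nanoscale profile and background behaviour on the
conventional one.

What the generator does **not** emulate: doublets/coincidence at the event
level (swarm appears only through the dilution-series scenario), non-lipid
contaminating particles, dye micelles, camera images (image-derived scalars
are drawn directly), instrument drift, and any correlation between vesicle
size and antigen copy number. Passing tests therefore demonstrate that the
*analysis* is correct under the declared noise model, not that the model
captures every failure mode of real samples.

Every generator is bit-reproducible for a fixed seed, and ground truth
travels in `true_*` columns that FCS export strips into a sidecar CSV.

## Problem sizes and runtime

The test suite uses 20,000-event samples for distribution-recovery checks
(binomial 95% intervals at that size are ±0.6% on a 30% fraction), 1000–5000
events per bead population, 1 nm inversion grids up to 1000 nm, and
1000-replicate coverage simulation for the t interval. The whole suite runs
in well under a minute on one core; the acceptance script is a
sub-second deterministic computation.

## Known limitations

* All scatter quantities are conditional on the declared optical geometry
  and particle models; none of the defaults should be treated as instrument
  truth.
* The surface-area sizing assumes zero dye intercept and spherical vesicles.
* LoD from the blank's autofluorescence can overestimate detection limits
  for vesicles, which are far smaller than the calibration beads.
* Spillover-by-medians assumes single stains bright enough to dominate
  autofluorescence; very dim single stains raise the matrix variance.
* FCS support targets a minimal 3.1 dialect (list mode, 32-bit floats,
  linear scale); log-amplifier dialects and FCS 2.0 files are out of scope.
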