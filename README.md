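# evcyto

Small-particle flow cytometry analytics for extracellular vesicles (EVs).

Bronchial epithelial cells — like most cells — shed lipid-bilayer vesicles of
roughly 30–1000 nm that carry tetraspanin surface markers (CD9, CD63, CD81)
and esterase cargo. Counting, sizing and phenotyping them on a flow cytometer
is hard because vesicles scatter orders of magnitude less light than cells,
and because every readout (scatter intensity, antibody fluorescence) arrives
in arbitrary instrument units. `evcyto` implements the calibration and
analysis layer that turns per-event cytometry data into physical quantities,
together with a synthetic event generator so every stage can be exercised and
validated without an instrument.

## What it computes

**Scatter calibration (Mie theory).** The scatter intensity of a particle is
proportional to its effective scattering cross-section, the differential
cross-section integrated over the detector's collection aperture:

    sigma_eff = ∫_Ω (|S1(θ)|² + |S2(θ)|²) / (2k²) dΩ,     k = 2π n_med / λ

where S1, S2 are the Mie amplitude functions of a homogeneous sphere (a
polystyrene calibration bead) or a coated sphere (a vesicle: aqueous core,
lipid shell). The aperture integral uses a 24 × 24 Gauss–Legendre tensor
grid (576 collection angles) centred on the side-scatter axis. Measured bead
intensities are scaled onto theory by a least-squares fit in log10 space
(`fit_scatter_calibration`), and the fitted mapping is inverted through a
core-shell vesicle model to size vesicles from scatter
(`intensity_to_diameter`) or to express one particle's scatter as another
model's "scatter-equivalent diameter" (`scatter_equivalent_diameter`).

**Fluorescence sizing.** Membrane-dye intensity is proportional to surface
area; a liposome standard of known median diameter fixes the constant
k = median(I)/(π d²), after which d = sqrt(I/(π k))
(`fit_surface_area_calibration`).

**ABC limits of detection.** Antibody-binding-capacity bead ladders are fit
by log–log regression of intensity on assigned ABC; the limit of detection of
a fluorophore is the ABC equivalent of an unstained blank population's
autofluorescence (`fit_abc_regression`, `lod_from_blank`, `abc_lod_table`).

**Enumeration and controls.** Calcein-AM marks intact, esterase-containing
vesicles. `apply_cascade` runs the gating cascades (size → singlet → calcein
on scatter instruments; size → brightfield-spot → calcein → focus on an
imaging instrument), converts counts to particles/mL from flow rate, volume
and dilution, and companion checks cover the detergent-lysis control
(`detergent_control_check`), dilution linearity / swarm detection
(`dilution_linearity`), staining titration and stain index
(`titration_optimum`, `stain_index`).

**Tetraspanin profiling.** Spillover estimated from single-stained vesicle
samples (`estimate_spillover`), compensation (`compensate`),
isotype-control thresholds (`isotype_thresholds`), and per-event assignment
of calcein-positive vesicles to the 8 CD9/CD63/CD81 combinations with
replicate t confidence intervals (`combination_counts`, `replicate_ci`).

**Synthetic instrument.** `generate_bead_file`, `generate_ev_sample`,
`generate_buffer_control`, `generate_titration_series` and
`generate_dilution_series` produce event tables with hidden ground truth
under a declared noise model (log-normal optical noise, Gaussian electronic
noise, hard trigger); `instrument_profile("conventional")` and
`instrument_profile("nanoscale")` bundle two sensitivities.

## Worked example

Calibrate a synthetic nanoscale cytometer against its five polystyrene size
standards, size a vesicle sample, and enumerate calcein-positive vesicles:

```r
library(evcyto)
inst <- instrument_profile("nanoscale")

beads_tab <- generate_bead_file("nist", inst, n_per_population = 1000, seed = 42)
meds <- tapply(beads_tab$VSSC_H, beads_tab$true_diameter, median)
cal <- fit_scatter_calibration(
  bead_reference(names(meds), as.numeric(names(meds)),
                 median_intensity = as.numeric(meds)),
  inst$optics)
print(cal)
#> Mie scatter calibration
#>   log10(I) = 1 * log10(sigma_eff) +2.5004   (R^2 = 1.0000)
#>   beads: 60 nm (res -0.000583); 80 nm (res +0.000534); 101 nm (res -0.000687); 125 nm (res +0.000908); 151 nm (res -0.000172)
#>   invertible over 30-1000 nm (vesicle model)

samp <- generate_ev_sample(population_spec(count = 20000), inst, seed = 7)
sized <- predict(cal, samp$VSSC_H)
median(sized$diameter[sized$flag == "ok"])
#> [1] 122.1   # generating median was 120 nm

ctrl <- generate_buffer_control(50000, inst, seed = 8)
thr <- calcein_threshold_from_control(ctrl)
apply_cascade(samp, gate_set(calcein_threshold = thr), sizes = sized)
#> EV gating cascade (scatter mode): 19318 events in
#>   after size      : 19241
#>   after singlet   : 19241
#>   after calcein   : 15378
#>   enumeration (calcein-positive) count: 15378
#>   concentration: 7.689e+06 particles/mL
```

The fitted offset recovers the instrument's simulated gain (10^2.5), the
sized median matches the generating 120 nm distribution, and the
calcein-positive fraction (15378/19318 ≈ 0.80) matches the generating
esterase-positive fraction of 0.8.

A command-line wrapper over the same functions ships at
`inst/cli/evcyto` (subcommands `simulate`, `calibrate-scatter`,
`calibrate-abc`, `size-fluor`, `gate`, `titrate`, `profile`, `report`).

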