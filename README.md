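# sectionquant

Quantitative analysis of multi-channel fluorescence tumor sections in R.

Solid tumors are poorly penetrated by therapeutic antibodies: drug leaving
a blood vessel is captured within a few cell layers, so most of the tumor
never sees an effective concentration. Experiments that try to improve
delivery (for example co-administering a vascular-modulating drug with a
labelled antibody such as Alexa-488–trastuzumab) are read out on frozen
sections imaged in three channels — DAPI for nuclei, rhodamine-lectin for
perfused ("functional") vessels, and FITC for the antibody. `sectionquant`
implements that readout as a tested pipeline:

- **Vessel analysis** — fuzzy c-means clustering of the lectin channel
  (minimizing `J_m = Σ_i Σ_j u_ij^m ‖x_i − v_j‖²` with `Σ_j u_ij = 1`),
  hard assignment to the brighter centroid, and vascular density
  (vessel area / total tumor area).
- **Penetration analysis** — Euclidean distance transform from the vessel
  mask (or tumor surface), mean antibody intensity per distance bin, the
  trapezoidal area under the profile over 0–80 µm, the profile's peak
  depth, and total accumulation per tumor area (AU/µm²), plus percent
  change versus a reference group.
- **Nuclear radiomics** — Laplacian-of-Gaussian contour extraction of
  nuclei restricted to the vessel-proximal band (≤ 80 µm), circularity
  `4πA/P²` with sub-pixel perimeter estimation, and box-counting fractal
  dimension of the nuclear boundary. Healthy nuclei are round (circularity
  near 1, low FD); apoptotic nuclei fragment and roughen (low circularity,
  high FD).
- **Group statistics** — mean ± SD per treatment group, percent change
  versus reference, one-way ANOVA, and the caliper tumor-volume formula
  `width² × length × 0.4`.
- **A synthetic-section generator** — tubular vessels, an antibody field
  decaying exponentially with distance from the nearest vessel
  (`I(d) = A·e^{−d/λ}`), and nuclei rendered as smooth disks or fragmented
  rough blobs, all with exact ground truth, so every stage of the pipeline
  is verifiable without the original microscope data.

## Worked example

```r
library(sectionquant)

spec <- synthetic_spec(rng_seed = 1, n_vessels = 3, noise_sd = 5,
                       decay_length_um = 20, antibody_amplitude = 100)
g <- generate_section(spec)

vm <- segment_vessels(g$section)
round(vm$vascular_density, 3)
#> [1] 0.152

dm <- distance_field(vm, spec$pixel_size_um)
pr <- intensity_profile(g$section, dm, bin_width_um = 1)
#> Warning: 7 empty bin(s) interpolated
round(profile_auc(pr))
#> [1] 2005
round(fit_decay(pr)$decay_length_um, 2)
#> [1] 20.09

acc <- accumulation(g$section)
round(acc$accumulation_density, 2)
#> [1] 126.34

nuc <- extract_nuclei(g$section, distance_um = dm)
near <- proximal_filter(nuc, max_dist_um = 80)
round(mean(as.data.frame(near)$circularity), 2)
#> [1] 0.96
```

Reading the numbers: 15.2% of the tumor area is segmented as functional
vessel; the antibody profile integrates to ≈2005 AU·µm over the first
80 µm (a few sparsely populated bins are flagged and interpolated) and its
fitted decay length (20.09 µm) recovers the generator's λ = 20 µm;
accumulation is ≈126 AU/µm² for this synthetic field; and the
vessel-proximal nuclei, all intact in this simulation, have mean
circularity 0.96, as round nuclei should.

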