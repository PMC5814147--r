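# vasquant

Quantitative image analysis for studies of vascular development and
endothelial monolayer dynamics. The package re-implements, as tested and
reusable R functions, five measurement pipelines that are usually written as
one-off scripts around a microscope:

- **Nematic coordination of a monolayer** (`coordination_*`): segment nuclei
  in a DAPI-like image, fit moment-equivalent ellipses, and score the
  collective orientation of the tissue. Nuclear long axes are nematic
  (headless) directions, so the pairwise score for orientations θ₁, θ₂ is
  `cos 2(θ₁ − θ₂)`: 1 for parallel, 0 at 45°, −1 for perpendicular nuclei,
  and 0 in expectation for random orientations. The readout is the mean
  score of all nucleus pairs binned by their distance.
- **Vascular plexus regularity** (`plexus_*`): threshold a vessel-marker
  (IB4-like) image, extract the closed loops of the plexus (bounded
  complement components, 4-connected, ≥ 86 µm²), and report the sample SD
  of loop area and circularity (`4πA/P²`) plus capillary density.
- **Marker gradients from the sprouting front** (`gradient_*`): normalize a
  marker channel to its extravascular mean, compute the exact Euclidean
  distance of every intravascular pixel to the front, and average in 15 µm
  bins from 0 to 500 µm, with unweighted mean ± SEM across replicates.
- **Photoconversion (FLAP) turnover curves** (`flap_*`): background-subtract,
  bleach-correct against a fixed-cell control (single-exponential fit), and
  normalize ROI traces; the post-conversion decay
  `I(t) = f + (1 − f)·2^(−t/t½)` yields the immobile fraction `f` (plateau)
  and the redistribution half-time `t½` (midpoint crossing of the smoothed
  curve).
- **Blinded junction-patch scoring** (`make_patches`, `crosstab_labels`):
  tile (160 µm)² fields into (16 µm)² patches, shuffle them under anonymous
  names for blind manual classification, de-blind via the manifest, and
  cross-tabulate morphology × turnover categories. An optional quantitative
  retained/total pulse-chase ratio (`turnover_score`) is provided as an
  extension.

Every pipeline has a synthetic-data generator (`gen_*`) that emits images or
traces **together with their ground truth**, so the whole toolchain is
validated end-to-end without microscope data.

## Worked example

```r
library(vasquant)

# --- monolayer coordination on a synthetic field with 100 um correlation ---
g <- gen_nematic_field(nematic_field_spec(n_nuclei = 300, field_size = 800,
                                          correlation_length = 100, seed = 42))
res <- coordination_pipeline(g$image, min_area = 30, max_area = 200,
                             bin_width = 25, max_distance = 400)
head(as.data.frame(res$curve), 4)
#>   bin_lo bin_hi mean_alignment pair_count
#> 1      0     25          0.949         94
#> 2     25     50          0.893        382
#> 3     50     75          0.812        675
#> 4     75    100          0.707        824

# --- plexus regularity on a synthetic vessel network ---
net <- gen_vessel_network(vessel_network_spec(50, perturbation = 0.2, seed = 1))
plexus_pipeline(mask = net$mask, min_loop_area = 86)$report
#> <regularity_report>
#>   loops: 79 (min area 86 um^2, border loops excluded)
#>   area: mean 615.3 um^2, SD 56.96 um^2
#>   circularity: mean 0.954, SD 0.020
#>   vessel density: 0.310

# --- FLAP turnover estimation (truth: f = 0.3, t1/2 = 90 s) ---
pair <- gen_flap_trace(flap_trace_spec(immobile_fraction = 0.3, half_time = 90,
                                       bleach_rate = 1e-3, noise_sd = 1, seed = 2))
flap_pipeline(pair$trace, pair$control)
#> <flap_estimate> immobile fraction 0.300, half-time 85.9 s
#>   plateau: last 10 frames; smoothing window: 5 frames
```

The alignment curve starts near 0.95 (strongly coordinated neighbours) and
decays with distance; the regularity report summarizes loop-geometry
dispersion (low SDs = a regular honeycomb-like plexus); the FLAP estimate
recovers the generator's immobile fraction exactly and the half-time within
a few percent under 1% noise and photobleaching.

A command-line wrapper over the same functions is installed as
`exec/vasquant` (`vasquant --help`).

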