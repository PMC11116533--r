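# stedclust

Quantitative cluster analysis and molecular counting for STED nanoscopy
of membrane proteins.

Super-resolution STED images show ion-channel clusters (the motivating
system is the L-type calcium channel CaV1.3, HaloTag-labeled 1:1 with a
synthetic dye) as diffraction-unlimited spots — but a spot alone says
nothing about stoichiometry. This package implements the full
quantitative chain for researchers who need per-cluster molecule
numbers and densities from such images:

* **Segmentation** — FFT bandpass (2.5–20 px), prominence-based maxima
  detection, half-maximum (FWHM) region growth with watershed splitting,
  and the candidate filters (≥ 5 px, mean intensity ≥ 50% above local
  background).
* **Brightness referencing** — each cluster's background-corrected
  brightness (ring background by differential dilation, 2 vs 4 px;
  aperture-corrected photometry) is divided by a single-dye brightness
  calibrated on DNA-origami-like standards carrying 23 ± 3 or 7 ± 1 dye
  sites, giving real-valued channel counts:
  `counts = B_cluster / B_dye`, with
  `B_dye = median(B_particle) / (n_sites × ELE_ref)`.
* **Geometry and densities** — area, diameter `2√(A/π)`, roundness
  `4A/(πL²)`, per-cluster molecular density `counts/A`, cluster density
  per µm², nearest-neighbour distances.
* **Labeling-efficiency correction** — the systematic count error from
  incomplete labeling is bracketed by
  `factor = ELE_reference / ELE_sample` (e.g. 0.875–1.75 for sample
  efficiencies of 80–40% against 70%-labeled standards).
* **Endosome colocalization** — marker binarization (triangle, Li,
  mean-of-background thresholds after a 4–30 px bandpass) and
  object-based overlap with a random-overlap correction
  (`specific = raw − area_fraction`).
* **Synthetic data with ground truth** — clustered point emitters,
  Gaussian PSF, Poisson noise, binomial labeling, calibration-standard
  fields, coupled cluster/marker pairs, and a line-scan motion-blur
  model, so the whole pipeline is testable without any real data.

Everything is tidyverse-native: images are `image_field` matrices,
results are tibbles, fitted objects have `tidy()`/`glance()` methods,
and `autoplot()`/`plot_*()` give ggplot2 figures.

## Worked example

Calibrate on a simulated 500-particle origami field, then analyze a
simulated 10 × 10 µm membrane field (defaults: 25 nm pixels, 70 nm PSF,
0.7 clusters/µm², lognormal counts with mean 8 / median 5.6):

```r
library(stedclust)

std   <- calibration_standard(23, 3, reference_ele = 0.7)
cal   <- simulate_calibration_field(sim_params(seed = 1001), std, 500)
calib <- calibrate_field(cal$field, std)
calib
#> <calibration_model> single-dye brightness 98 units/dye
#>   496 particles, dispersion 298.4

sim <- simulate_cluster_field(sim_params(seed = 1))
an  <- analyze_field(sim$field, calib)
glance(an)
#>   n_clusters analyzed_area_um2 cluster_density_per_um2 channel_counts_per_um2
#>           64               100                    0.64                  4.485

tidy(an) |> dplyr::select(label, area_um2, diameter_nm, counts, density_per_um2) |> head(3)
#>   label area_um2 diameter_nm counts density_per_um2
#> 1     1  0.00688        93.6   23.1           3354.
#> 2     2  0.00813       102.    20.5           2528.
#> 3     3  0.00688        93.6   19.9           2888.
```

The generating truth for this field is 64 clusters (0.64 µm⁻², matched
exactly) with a mean of 7.41 labeled channels; the pipeline reports a
mean of 7.01 counts, a median of 5.72, and 81% of clusters with ten or
fewer channels. The simulated dye brightness was 100 units; calibration
recovered 98.

Colocalization against an endosomal marker channel:

```r
pair <- simulate_coloc_pair(sim_params(seed = 7), marker_area_fraction = 0.15)
mask <- binarize_marker(pair$marker_field, method = "triangle")
rois <- segment_clusters(pair$cluster_field)
coloc_fraction(rois, mask, marker_label = "Rab5a")
```

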