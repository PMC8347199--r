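# ramanclass

Chemometric discrimination of tissue Raman maps: preprocessing, duplex
train/test splitting, PLS-DA classification and band-level biochemistry
analytics, driven by a synthetic hyperspectral generator with a known
ground truth.

## What problem this solves

Raman micro-spectroscopy maps of tissue — here modeled after maps of the
hypothalamic arcuate nucleus–median eminence complex from high-fat-diet
(HFD) versus control (CTRL) mice — consist of thousands of spectra sitting
on a fluorescence background 5–20× larger than the bands of interest. The
scientific readout is twofold:

1. **Band-level biochemistry**: heights of named bands (glycogen 484/858/
   1460 cm⁻¹, collagen 1007/1127/1172/1260/1661 cm⁻¹, triacylglycerol
   carbonyl 1748 cm⁻¹, silent-zone cyanide 2248 cm⁻¹) and the
   1655/1444 cm⁻¹ height ratio, a lipid-unsaturation index
   (≈ 0.88 in CTRL vs ≈ 0.55 in HFD tissue).
2. **Classification**: can a PLS-DA model on preprocessed spectra separate
   the classes on held-out data, and which spectral regions drive it?

The pipeline is: two-stage baseline correction — iterative 5th-order
modified polynomial fitting, then penalized asymmetric least squares
(AsLS), solving `(W + λ DᵀD) z = W y` on a banded LDLᵀ factorization —
region cropping (500–1800, 2100–3100 cm⁻¹), unit-area normalization,
deterministic per-class **duplex** splitting, training-mean centering, and
**PLS-DA** on a hand-implemented NIPALS PLS1 core with dummy coding
(HFD = 1), a strict 0.5 decision threshold, 10-fold cross-validated
latent-variable selection, and VIP scores
(`VIP_j = sqrt(J Σ_a SSY_a (w_ja/||w_a||)² / Σ_a SSY_a)`) whose VIP > 1
channels form signed discriminant regions.

Because raw spectra from such studies are rarely deposited, the package
includes a first-class synthetic generator (`synth_dataset`) whose band
library encodes the contrasts above — including 1444/1655 amplitudes
solved per class through a 2×2 wing-overlap system so the noiseless
1655/1444 ratios are exactly 0.88/0.55 — and every stage is tested against
that ground truth or against independent numerical oracles.

## Worked example

```r
library(ramanclass)

cfg <- pipeline_config(
  generator = generator_config(n_maps_per_class = 2, spectra_per_map = 100,
                               seed = 7))
report <- run_pipeline(cfg)
report
#> run_report
#>   dataset: 400 x 3180
#>   split: 302 train / 98 test
#>   chosen latent variables: 1
#>   test accuracy (%): CTRL = 100, HFD = 100
#>   1655/1444 ratios: CTRL = 0.891, HFD = 0.576
```

400 synthetic spectra (two maps per class) are generated, baseline-
corrected, cropped and normalized; duplex assigns 302 spectra to training;
cross-validation picks a single latent variable (the synthetic classes
differ by a fixed mean spectrum, so one component suffices); held-out
accuracy is 100% per class; and the recovered saturation ratios sit within
a few percent of the encoded 0.88/0.55 — the residual offset is the
footprint of baseline correction on overlapping bands. Band analytics on
the corrected class averages find the silent-zone cyanide marker:

```r
avg_hfd <- class_average(correct_baselines(synth_dataset(cfg$generator)), "HFD")
detect_peaks(avg_hfd, window = c(2100, 2800), min_prominence = 0.25)
#>   position    height prominence
#> 1     2248 0.4147063  0.3036057
```

## Layout

* `R/synthgen.R` — band library, spectrum/dataset generator, text I/O
* `R/preprocess.R` + `src/asls.cpp` — modified polyfit, banded AsLS,
  regions, normalization, centering, assembly
* `R/bands.R` — class averages, peak detection/assignment, band ratios
* `R/split.R` — duplex and stratified duplex
* `R/plsda.R` — NIPALS PLS1, CV selection, VIP, discriminant regions
* `R/pipeline.R` — end-to-end orchestration and artifact writing
* `inst/scripts/raman-pipeline.R` — thin shell wrapper (`generate`, `run`)
* `vignettes/raman-hfd-discrimination.Rmd` — methods notes
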