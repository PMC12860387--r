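# spotmix

Cell-type deconvolution of spot-based spatial transcriptomics (ST) with a
multitask, multimodal autoencoder — for computational biologists who have a
spot × gene count matrix, spot coordinates, a paired H&E image and a
single-cell reference, and want per-spot cell-type proportions.

Each ST spot aggregates transcripts from several adjacent cells. spotmix
estimates the composition matrix `Y_prop` (spots × cell types, rows on the
simplex) by training one model jointly on two domains:

- **pseudo-spots** simulated from the single-cell reference, whose
  compositions are known exactly (supervised cross-entropy
  `L_deconv = -Σ_ij Y_ij log Ŷ_ij`);
- **real spots**, which contribute a reconstruction loss through a
  conditional decoder, an auxiliary spot-pathology classification loss, and
  an adversarial domain-matching loss through a gradient reversal layer:

  `L_total = L_deconv + λ1·L_hist + λ2·L_recon + λ3·L_match`,
  default `λ = (0.1, 0.1, 0.01)`.

Spatial context enters through a k-nearest-neighbour spot graph
(`k = 5`) encoded by graph convolutions
`H⁽ˡ⁺¹⁾ = ReLU(D̂^(−1/2) Â D̂^(−1/2) H⁽ˡ⁾ W⁽ˡ⁾)`, and tissue morphology
through multi-scale H&E patches (150/100/50 px, resized to 224) that are
token-encoded, attention-pooled, fused into a per-spot perceptual embedding
and injected into every decoder layer by cross-modal attention. A
deterministic stub token encoder ships with the package, so nothing needs a
download; a pretrained pathology encoder can be plugged in through the same
patch → tokens contract.

The package also ships everything needed to exercise the pipeline without
external data: synthetic single-cell references, pseudo-spot simulation with
binomial downsampling, region-structured synthetic slides with tinted
imagery, in-silico H&E artifacts (crack / fold / stain), Pearson +
global-statistics SSIM + RMSE evaluation, and a 10-fold cross-validation
protocol. Training runs on a small tape-based autodiff engine written in R —
no deep-learning framework required — and takes a minute or two at benchmark
scale on one CPU.

## Worked example

Fully synthetic end-to-end run with known ground truth:

```r
library(spotmix)

# single-cell reference: 4 marker-separated types
ref <- generate_synthetic_scrna(n_cells = 2000, n_genes = 200, n_types = 4,
                                marker_fold = 8, seed = 7)

# 500 labelled pseudo-spots (the supervised domain)
ps <- simulate_pseudospots(ref, pseudospot_config(n_spots = 500, seed = 1))
ps$expression
#> spot_matrix: 500 spots x 200 genes [counts]
round(unclass(ps$proportions)[1:3, ], 3)
#>        type1 type2 type3 type4
#> pspot1 0.375 0.000 0.500 0.125
#> pspot2 0.000 0.909 0.000 0.091
#> pspot3 0.000 0.857 0.143 0.000

# a synthetic slide with 4 tissue regions acts as the "real" domain
slide <- generate_synthetic_slide(15, 15, spacing_px = 60, n_regions = 4, seed = 2)
real  <- simulate_slide_spots(ref, slide, seed = 3)
real
#> st_dataset: 225 spots x 200 genes; coords: TRUE; image: TRUE; truth: TRUE; pathology: TRUE
```

`run_recovery_benchmark()` wires these generators to training and
evaluation in one call (about 90 s on one CPU):

```r
bench <- run_recovery_benchmark(seed = 7, epochs = 150)
bench
#> recovery_benchmark (seed 7): mean spot PCC 0.8940 | SSIM 0.8754 | RMSE 0.1351 | argmax accuracy 0.933
```

Mean per-spot PCC of 0.894 means the predicted composition of a typical
spot correlates 0.89 with the planted truth across the four types; argmax
accuracy 0.933 means the dominant cell type is identified correctly for 93%
of the 225 slide spots. Lower-level entry points (`s2ae_fit()`,
`deconvolve()`, `evaluate_folds()`, `s2ae_cross_validate()`) expose each
stage separately; `?spotmix` gives the map.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/spotmix.R simulate --out data --config config.yaml
Rscript inst/cli/spotmix.R train    --data data --out run --config config.yaml
Rscript inst/cli/spotmix.R deconvolve --data data --model run/model.rds --out run
Rscript inst/cli/spotmix.R evaluate --truth data/real_truth.csv \
        --pred run/proportions.csv --coords data/real_coordinates.csv --out report.json
```

## Documentation

The methods vignette (`vignettes/spotmix-methods.Rmd`) describes the model
and its assumptions, every tunable parameter with its default and rationale,
what the synthetic generators do and do not emulate, the numerical choices,
and known limitations.
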