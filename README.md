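# moabench

Benchmarking mechanism-of-action (MoA) prediction from high-content
screening images — brightfield versus fluorescence — on fully synthetic
screens.

## The problem

High-content screens image cells perturbed by compounds and ask whether the
induced morphology identifies each compound's mechanism of action.
Fluorescence (FL) panels such as Cell Painting stain sub-cellular
compartments but are costly, slow and phototoxic; plain brightfield (BF)
z-stacks are cheap and live-cell friendly but low-contrast. A fair
comparison of the two modalities needs a shared pipeline: plate-level
normalization against DMSO solvent controls, compound-stratified data
splits (a compound never appears in both training and test), a common
classifier architecture, and profile-level diagnostics that separate
biological signal from plate ("batch") effects.

`moabench` implements that pipeline end to end for R users, together with a
synthetic screen generator so every stage is testable without any
proprietary image data. The generator emulates the structure such assays
actually have: 384-well plates, ten MoA classes plus a DMSO control class,
compounds replicated three times on a plate (technical replicates) and
across two plates (biological replicates), several imaging sites per well,
per-plate gain/offset batch effects, smooth brightfield illumination
inhomogeneity, and per-compound phenotype strength that the analysis should
recover. Every injected nuisance parameter is logged, so recovery is
assertable.

## What is computed

* **Preprocessing** — Gaussian background subtraction for BF z-planes
  (kernel expressed as a fraction of the image side), then either DMSO
  plate-level normalization `x' = (x − μ_DMSO)/σ_DMSO` or per-image site
  normalization.
* **Classification** — an 11-class (10 MoA + DMSO) convolutional network on
  5-channel FL or 6-plane BF stacks, and a one-hidden-layer (512 unit,
  ReLU + batch-norm) network on engineered feature tables as a benchmark;
  both report macro-F1 (the unweighted mean of per-class F1), pooled
  per-MoA F1, confusion matrices and compound-level accuracy, plus Pearson
  agreement between modalities with "consistently better/worse" boxes at
  accuracy 0.6/0.4.
* **Grit score** — for a profile *i* of compound *c* with replicate
  correlations `R_i` and control correlations `C_i`:
  `grit_i = mean_{r in R_i} (r − mean(C_i)) / sd(C_i)`,
  a z-like statistic of phenotype strength; accuracy is reported in ten
  equal-count grit bins.
* **Batch-effect diagnostics** — penultimate-layer embeddings, cosine
  similarity within/across MoA classes, plate-by-plate Pearson correlation
  of control features, and silhouette of control profiles grouped by plate.
* **Biological matching** — well-level mean profiles, ZCA sphering fitted on
  control wells, `W = (Σ_c + λ tr(Σ_c)/d · I)^(−1/2)`, and cosine-ranked
  mean average precision (mAP) of same-MoA retrieval, swept over λ.

## Worked example

```r
library(moabench)

run_dir <- tempfile("moabench_demo_")
run_pipeline(demo_pipeline_config(seed = 9), run_dir)

jsonlite::read_json(file.path(run_dir, "evaluate", "metrics.json"))
```

The demo screen (2 plates, 10 MoA classes x 4 compounds, 48-pixel images,
two compound-stratified splits) runs in under a minute on one CPU and
prints, for seed 9:

```
macro_f1:  BF_split1 0.609  BF_split2 0.182
           FL_split1 0.976  FL_split2 0.518
           CP_split1 0.451  CP_split2 0.514
agreement: pearson_ab 0.466  (BF vs FL compound accuracy)
           pearson_ac 0.200  (BF vs feature benchmark)
```

Fluorescence beats brightfield at this tiny scale, the feature benchmark
sits in between, and the split-to-split spread is large because each test
fold holds only ten compounds — the per-split macro-F1 table, pooled
per-class F1 CSVs, compound-accuracy scatter data, grit-binned accuracy
curves, plate-correlation matrices and the sphering/mAP sweep are all
written under `run_dir` as machine-readable CSV/JSON. Re-running with the
same seed reproduces every metric file byte for byte.

```r
read.csv(file.path(run_dir, "match", "map_sweep.csv"))
#>   lambda   map
#> 1  0.001 0.245
#> 2  0.010 0.247
#> 3  0.100 0.260
#> 4  1.000 0.301
```

## Notes on scale

All defaults are desk scale: images are 96 x 96 (not 2160 x 2160), the CNN
is a 3-stage convolutional network (not a ResNet-50), and screens span 2-18
plates. Spatial parameters are expressed as fractions of the image side so
the analysis code is resolution-independent; the vignette
(`vignettes/moabench-methods.Rmd`) documents the models, parameter choices
and what desk-scale results do and do not demonstrate.
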