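# popgraphstager

Staging Alzheimer's disease — cognitively normal (CN), mild cognitive
impairment (MCI), Alzheimer's dementia (AD) — as **transductive node
classification on a population graph**. Every subject is a node; node
features are anatomical embeddings extracted from gray-matter density
volumes by a 3D DenseNet; weighted edges encode pairwise subject
similarity from imaging and/or non-imaging phenotypes; a two-layer graph
convolutional network (GCN) classifies all subjects at once, with only
training-node labels entering the loss.

The package is aimed at researchers studying *how the construction of
the population graph — especially the edge-assigning function — affects
staging performance*. It provides the full pipeline plus a synthetic
cohort simulator calibrated to published ADNI-1 summary statistics, so
every stage is runnable and testable without access-controlled data.

## The model

Edge weights between subjects $i$ and $j$ come from three families:

- **Imaging (baseline)**: cosine similarity of the CNN embeddings,
  $S_{\mathrm{img}}(i,j) = \dfrac{x_i \cdot x_j}{\lVert x_i \rVert \lVert x_j \rVert}$
- **Non-imaging**: for each chosen phenotype, a Kronecker delta
  ($n_i = n_j$) if categorical (gender, ApoE4 count) or a unit step
  $\mathbf{1}\{|n_i - n_j| < \beta\}$ if quantitative (age, MMSE,
  CDR-SB, ...), summed over the $P$ phenotypes.
- **Combined**:
  $S_{\mathrm{com}}(i,j) = S_{\mathrm{img}}(i,j)\sum_{p=1}^{P} S_{\mathrm{nimg}}^{(p)}(i,j)$.

The GCN applies the symmetric renormalized propagation operator
$S = \hat D^{-1/2}(A + I)\,\hat D^{-1/2}$ in each of two layers:
$\mathrm{softmax}\!\big(S\,\mathrm{ReLU}(S X W^{(0)})\,W^{(1)}\big)$,
32 hidden units, dropout 0.5, Adam, early stopping on validation
accuracy. Performance is reported as accuracy, precision, recall, F1 and
Matthews correlation (percent) from the test-split confusion matrix.

Both networks — the 3D DenseNet (dense blocks with 1×1×1 bottleneck and
3×3×3 growth convolutions, compressing transitions, a 512-unit embedding
layer) and the GCN — are implemented in base R with hand-derived
backpropagation, verified against finite differences in the test suite.

## Worked example

Simulate an ADNI-1-like cohort, sweep neuropsychological edge functions
on the AD-vs-MCI task, and compare against the imaging-only baseline:

```r
library(popgraphstager)

cfg <- cohort_config(class_counts = c(CN = 90, MCI = 120, AD = 90),
                     feature_dim = 64, seed = 2024)
cohort   <- generate_cohort(cfg)
features <- generate_features(cohort, cfg)

spec <- experiment_spec("ad_mci", seeds = 1:5,
                        scores = c("CDR_SB", "MMSE", "ADNI_VS"))
out <- run_experiment_2(cohort, features, spec)
dplyr::select(out$results, edge, acc_mean, acc_sd, rec_mean, f1_mean)
#> # A tibble: 7 × 5
#>   edge           acc_mean acc_sd rec_mean f1_mean
#>   <chr>             <dbl>  <dbl>    <dbl>   <dbl>
#> 1 Simg               57.1   0         0       0
#> 2 Snimg(CDR_SB)      73.8  11.8      38.9    51.0
#> 3 Snimg(MMSE)        81.0   5.05     64.4    73.4
#> 4 Snimg(ADNI_VS)     61.0   9.90     30      31.2
#> 5 Scom(CDR_SB)       73.8  11.8      42.2    53.3
#> 6 Scom(MMSE)         81.4   4.26     64.4    73.8
#> 7 Scom(ADNI_VS)      62.4   8.32     14.4    19.8
```

Each row is one edge-assigning function; `acc_mean ± acc_sd` is test
accuracy over the five GCN seeds. The strongly class-linked global
screens (CDR-SB, MMSE — calibrated means differ by 1–4 points between
MCI and AD) beat the imaging-only baseline by 15–25 accuracy points,
while a weakly class-linked composite (visuospatial) barely moves it:
on the synthetic cohort, as on the real one, the edge-assigning function
dominates performance. The baseline's 0% recall shows its over-smoothed
graph collapsing to the majority class.

Single stages are exposed as plain functions that chain with the pipe —
`generate_cohort() |> build_graph() |> train_gcn() |> predict()`, with
`tidy()`/`glance()` methods on fits, `autoplot()` methods for graphs,
fits and confusion matrices, and a thin command-line wrapper in
`inst/cli/popgraph-stager.R` (subcommands `synth`, `features`, `graph`,
`train`, `evaluate`, `experiment`, `pipeline`).

The CNN path runs the same way from volumes:

```r
vols  <- generate_volumes(cohort, shape = c(8, 8, 8), atrophy_amplitude = 1, seed = 1)
model <- train_extractor(vols,
                         labels = setNames(as.character(cohort$diagnosis), cohort$id),
                         split  = setNames(cohort$split, cohort$id),
                         config = densenet_config(input_shape = c(8, 8, 8),
                                                  n_blocks = 2, units_per_block = 2,
                                                  growth_rate = 4, bottleneck_channels = 8,
                                                  stem_channels = 8, fc_sizes = c(32, 16)))
features <- extract_features(model, vols)
```

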