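# phenoclass

Interpretable land-use classification from multispectral satellite time
series, built around a stacked bidirectional LSTM implemented from first
principles in R.

## The problem

Land-use monitoring for agricultural policy (e.g. the EU Common
Agricultural Policy) classifies every 10 m pixel of a region from one
agronomic year (September–August) of Sentinel-2 acquisitions. Recurrent
networks do this very accurately, but accuracy alone is not enough when
classifications steer public payments: the operator must be able to say
*which* spectral predictors and *which* acquisition dates drive the
decision. `phenoclass` packages both halves of that workflow — the
classifier and its interpretability analyses — for scientists working on
crop-type mapping and model auditing.

Each pixel is a sequence of 14 predictors over 30 cloud-free dates: the
12 Sentinel-2 L2A surface-reflectance bands, the vegetation index
NDVI = (B8 − B4)/(B8 + B4), and E_NDVI, a local Shannon-entropy texture
of the NDVI map. The classifier is a stacked BiLSTM: per timestep the
LSTM unit computes

    c̃_t = tanh(W_c x_t + U_c h_{t−1} + b_c)
    i_t = σ(W_i x_t + U_i h_{t−1} + b_i)
    f_t = σ(W_f x_t + U_f h_{t−1} + b_f)
    c_t = i_t ⊙ c̃_t + f_t ⊙ c_{t−1}
    o_t = σ(W_o x_t + U_o h_{t−1} + b_o)
    h_t = o_t ⊙ tanh(c_t)

with forward and backward passes concatenated per layer, a softmax head
on the two directions' final states, cross-entropy training (Adam, full
backpropagation through time — both implemented in the package and
verified against numerical gradients and an independent unrolled oracle).

Interpretability follows the added-noise permutation principle: Gaussian
noise N(0, σ²) with σ² = 3% of the signal amplitude is added to one
predictor at all dates (or all predictors at one date); the resulting
drop in overall accuracy, normalized to the most relevant item, is that
predictor's (or date's) relevance. Per-timestep probability evolution and
hidden-unit activation summaries complete the picture.

Reference land-use labels of this kind are administrative in-situ data
and not publicly deposited, so the package includes a synthetic scene
generator (double-logistic NDVI phenology per class, spectral band rules,
parcel-block spatial structure) that both exercises the full pipeline and
— more importantly — plants *known* ground truth against which the
interpretability analyses are validated.

## Worked example

```r
library(phenoclass)

# a ~5000-pixel scene whose class signal lives only in B4/B8 (hence NDVI
# and its entropy texture) -- planted ground truth for relevance
scene <- benchmark_scene("spectral", seed = 1)
fit   <- benchmark_fit(scene, "spectral", seed = 1)
fit$report
#> <metrics_report> overall accuracy 94.9% on 1555 test samples (pixel split)
#>  class precision recall   f1
#>     L1      97.1   98.8 97.9
#>     L2      95.7   92.4 94.0
#>     L3      89.6   94.5 92.0
#>     L4      97.3   93.5 95.4

rel <- relevance(fit$model, fit$test_cube, "predictor", n_repeats = 5, seed = 2)
round(sort(rel$scores, decreasing = TRUE), 2)
#>     B8   NDVI E_NDVI     B4     B3     B1     B2     B5     B6     B7
#>   1.00   0.91   0.65   0.10   0.08   0.00   0.00   0.00   0.00   0.00
#>    B8a     B9    B11    B12
#>   0.00   0.00   0.00   0.00
```

The four predictors that actually carry class signal — B8, NDVI, E_NDVI,
B4 — occupy the four top ranks (the top item scores exactly 1 by
normalization), and the ten bands generated without any class signal
score near zero: the relevance analysis recovers the planted truth. B4's
own score is modest because its information is largely redundant with B8
and NDVI; which of the redundant trio the network leans on hardest varies
with the training seed.

The full pipeline — simulate → featurize → train → evaluate → interpret →
report — runs as one call, or from the shell via the thin wrapper in
`inst/cli/`:

```r
run_pipeline(out_dir = "run1", seed = 7)   # writes metrics, relevance,
                                           # figures, report.md, manifest
```

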