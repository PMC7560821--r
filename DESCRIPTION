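Package: phenoclass
Title: Interpretable Bidirectional LSTM Classification of Multispectral
    Phenology Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for land-use classification from annual time series of
    multispectral surface reflectance, built around a stacked bidirectional
    long short-term memory (BiLSTM) network implemented from first
    principles. Includes a synthetic phenology scene generator with
    class-specific seasonal NDVI trajectories and parcel spatial structure,
    construction of the 14-predictor feature cube (12 spectral bands, NDVI
    and a local NDVI entropy texture), network training and evaluation
    (overall accuracy, per-class precision, recall and F-1), and
    interpretability analyses: added-noise permutation relevance in the
    spectral and temporal domains, per-timestep class-probability
    evolution, and hidden-unit activation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
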