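Package: itquant
Title: Time-Causal Information Theory Quantifiers for Environmental Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinal-pattern (Bandt-Pompe) symbolization of regularly sampled
    time series and the information-theory quantifiers built on it: normalized
    permutation entropy, Jensen-Shannon statistical complexity, discrete Fisher
    information, and their variance-weighted variants. Includes the
    entropy-complexity limit curves, causal information planes, a
    Jensen-Shannon divergence for model benchmarking against observations,
    per-grid-cell quantifier maps with RGB composites and mismatch (divergence
    and root-mean-square-error) maps for space-time fields, and a
    model-structure diagnostic that rasterizes causal-plane point clouds and
    separates runs by principal component analysis. Canonical synthetic
    processes (white and 1/f^k noise, the logistic map, harmonic signals, and
    seasonal productivity-like series and grids) are generated in-package so
    every stage is testable without external data. A command-line interface
    exposes the main computations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ncdf4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
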