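Package: perplexr
Title: Held-Out Perplexity for Transcript Abundance Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the quality of RNA-seq transcript abundance estimates
    without ground truth by computing the perplexity (inverse geometric mean
    per-fragment likelihood) of a held-out validation fragment set, using the
    range-factorized equivalence-class approximation of the quantification
    likelihood. Handles validation fragments that an estimate calls impossible
    via Laplacian and Simple Good-Turing smoothing of the per-transcript
    distribution, and implements the full quantify-then-validate K-fold
    cross-validation protocol for hyperparameter selection, including removal
    of necessarily-impossible fragments and a sparsity-aware tie-break. Ships
    a minimal EM/VBEM equivalence-class quantifier with a reads-per-transcript
    prior and a synthetic-data generator with controlled multi-mapping
    ambiguity so the whole protocol runs without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
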