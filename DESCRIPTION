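Package: gradasym
Title: Hemispheric Asymmetry of Functional Connectome Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying hemispheric asymmetry of functional connectome
    gradients in case-control cohorts. Builds Fisher-z functional connectivity
    from parcellated time series, splits it into intra- and inter-hemispheric
    blocks, computes diffusion-map gradient embeddings with Procrustes alignment
    to a template, derives homotopic left-minus-right asymmetry indices,
    removes multi-site batch effects with an empirical-Bayes location/scale
    model, tests group, age-group and interaction effects with parcel-wise
    Hotelling multivariate statistics under FDR control, decodes statistic maps
    against term-activation dictionaries with percentile-bin weighted scores,
    and predicts symptom scores with a permuted cross-validated elastic net.
    Includes a synthetic multi-site cohort generator with planted ground truth
    so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    optparse
Config/testthat/edition: 3
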