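Package: lowPmaize
Title: Mixed-Model Analysis and Selection Indices for Low-Phosphorus
    Seedling Screening of Maize Inbred Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the statistical analysis of two-condition
    (applied versus non-applied phosphorus) randomized-block seedling
    phenotyping trials of maize inbred lines.  Fits per-condition and
    combined mixed models by REML to estimate variance components and
    predict genotypic values (BLUPs), tests random effects by likelihood
    ratio, and computes broad-sense heritabilities, coefficients of
    variation and stress-response statistics.  Downstream stages cover
    Pearson/Spearman correlation structure of genotypic values,
    variance-inflation-factor pruning of collinear traits, UPGMA
    phenotypic-diversity clustering with a Mojena dendrogram cut, and
    PCA-weighted low-phosphorus tolerance (LPTI) and performance (LPPI)
    selection indices with four-group classification and top/bottom-k
    selection.  A synthetic-data generator reproduces the randomized-block
    two-condition design with configurable genetic, genotype-by-condition,
    block and residual variance components so the whole pipeline can be
    exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
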