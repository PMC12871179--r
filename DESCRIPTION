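Package: skewsign
Title: Cohort Trait Skewness and Minor-Allele Sign Bias in GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how the skewness of a cohort's trait
    distribution drives apparent directional (sign) bias of minor-allele
    effects in genome-wide association studies. Provides two forward
    simulators of biased cohort ascertainment from Hardy-Weinberg
    populations with matched pairs of trait-increasing and
    trait-decreasing alleles (a quantile-bin multinomial sampler and a
    tri-modal latent-mode sampler), ordinary-least-squares association
    on simulated cohorts, QC filtering of summary-statistic tables, an
    empirical-Bayes adaptive-shrinkage estimator of per-variant
    posterior sign probabilities under a zero-centered normal mixture
    prior, certainty-weighted aggregation of sign bias over
    approximately independent LD blocks with block-bootstrap and
    random-replicate uncertainty, and quadratic logit-scale regressions
    of sign bias on trait skewness with leverage and Cook's-distance
    influence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ash.R'
    'utils.R'
    'experiment.R'
    'gwas.R'
    'io.R'
    'methods.R'
    'signbias.R'
    'simulate.R'
    'skewfit.R'
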