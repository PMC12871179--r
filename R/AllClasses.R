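#' @import methods
#' @importFrom stats dnorm pnorm pt qnorm rbinom rmultinom rnorm runif
#'   median sd var quantile coef lm model.matrix hatvalues cooks.distance
#'   residuals fitted cor.test setNames complete.cases
NULL

#' Simulated population of genotypes and trait values
#'
#' A forward-simulated population of `N` diploid individuals typed at `M`
#' biallelic variants arranged in matched pairs: within each pair the two
#' variants share an allele frequency and carry effects of equal magnitude
#' and opposite sign, so the population carries no directional signal by
#' construction. Traits are the additive genetic value plus independent
#' Gaussian environmental noise with variance `1 - h2`.
#'
#' Genotype dosages are stored as a raw-typed `N x M` matrix (values 0/1/2,
#' one byte per entry) or omitted entirely (`dim c(0, 0)`) when a population
#' is generated for its trait distribution only; use [dosages()] to extract
#' numeric dosage matrices.
#'
#' @slot genotypes raw matrix of dosages (individuals x variants), possibly
#'   empty.
#' @slot effects numeric vector of signed true allelic effects, common
#'   magnitude.
#' @slot freqs numeric vector of assigned allele frequencies (shared within
#'   pairs).
#' @slot traits numeric vector of trait values, one per individual.
#' @slot modes character vector of latent mode labels (`"L"`, `"C"`, `"R"`)
#'   for tri-modal populations; `character(0)` for unimodal ones.
#' @slot scheme `"A"` (unimodal) or `"B"` (tri-modal).
#' @slot h2 narrow-sense heritability used in the simulation.
#' @slot params list echoing the generating parameters.
#'
#' @seealso [simulatePopulationA()], [simulatePopulationB()]
#' @name Population-class
#' @aliases Population
#' @exportClass Population
setClass("Population",
    representation(
        genotypes = "matrix",
        effects   = "numeric",
        freqs     = "numeric",
        traits    = "numeric",
        modes     = "character",
        scheme    = "character",
        h2        = "numeric",
        params    = "list"
    )
)

setValidity("Population", function(object) {
    msg <- NULL
    M <- length(object@effects)
    N <- length(object@traits)
    if (length(object@freqs) != M)
        msg <- c(msg, "freqs and effects lengths differ")
    if (M %% 2L != 0L)
        msg <- c(msg, "number of variants must be even (matched pairs)")
    if (M > 0) {
        mags <- abs(object@effects)
        if (diff(range(mags)) > 1e-12 * max(mags))
            msg <- c(msg, "effect magnitudes are not constant")
        if (sum(object@effects > 0) != M / 2)
            msg <- c(msg, "effects are not half positive, half negative")
    }
    if (nrow(object@genotypes) > 0L &&
        (nrow(object@genotypes) != N || ncol(object@genotypes) != M))
        msg <- c(msg, "genotype matrix dimensions do not match traits/effects")
    if (length(object@modes) > 0L && length(object@modes) != N)
        msg <- c(msg, "modes length does not match number of individuals")
    if (!object@scheme %in% c("A", "B"))
        msg <- c(msg, "scheme must be \"A\" or \"B\"")
    if (is.null(msg)) TRUE else msg
})

#' Ascertained cohort drawn from a simulated population
#'
#' A subset of a [Population] selected by one of the biased sampling rules
#' (quantile-bin multinomial for unimodal populations, mode-window weighted
#' sampling for tri-modal ones), together with the realized trait skewness
#' and the sampling design that produced it.
#'
#' @slot population the parent [Population] (stored by reference; R's
#'   copy-on-write semantics mean no duplication).
#' @slot members integer indices of cohort members in the population.
#' @slot design list of sampler parameters (scheme-specific).
#' @slot skewness realized standardized third central moment of cohort
#'   traits.
#'
#' @seealso [sampleCohortA()], [sampleCohortB()]
#' @name Cohort-class
#' @aliases Cohort
#' @exportClass Cohort
setClass("Cohort",
    representation(
        population = "Population",
        members    = "integer",
        design     = "list",
        skewness   = "numeric"
    )
)

setValidity("Cohort", function(object) {
    msg <- NULL
    N <- length(object@population@traits)
    if (anyDuplicated(object@members))
        msg <- c(msg, "cohort member indices must be distinct")
    if (length(object@members) &&
        (min(object@members) < 1L || max(object@members) > N))
        msg <- c(msg, "member indices outside the population")
    if (is.null(msg)) TRUE else msg
})

#' Fitted zero-centered normal-mixture prior for allelic effects
#'
#' Result of the empirical-Bayes adaptive-shrinkage fit: mixture weights
#' over a fixed grid of zero-centered normal components (the first with
#' standard deviation 0, a point mass at "no effect"), estimated by EM on
#' the penalized marginal likelihood of observed effects and their standard
#' errors.
#'
#' @slot sds component standard deviations; `sds[1] == 0` is the null point
#'   mass.
#' @slot weights fitted mixture weights (simplex).
#' @slot loglik penalized marginal log-likelihood trace over EM iterations
#'   (nondecreasing).
#' @slot converged whether the relative-change stopping rule was met before
#'   `maxIter`.
#' @slot penalty Dirichlet-style pseudo-count penalty on the null component.
#'
#' @seealso [fitAshMixture()], [posteriorSigns()]
#' @name AshFit-class
#' @aliases AshFit
#' @exportClass AshFit
setClass("AshFit",
    representation(
        sds       = "numeric",
        weights   = "numeric",
        loglik    = "numeric",
        converged = "logical",
        penalty   = "numeric"
    )
)

setValidity("AshFit", function(object) {
    msg <- NULL
    if (length(object@sds) != length(object@weights))
        msg <- c(msg, "sds and weights lengths differ")
    if (length(object@sds) && object@sds[1] != 0)
        msg <- c(msg, "first grid component must be the null (sd 0)")
    if (any(object@weights < -1e-12))
        msg <- c(msg, "negative mixture weight")
    if (length(object@weights) && abs(sum(object@weights) - 1) > 1e-8)
        msg <- c(msg, "mixture weights do not sum to 1")
    if (is.null(msg)) TRUE else msg
})

#' Certainty-weighted sign-bias estimate over a variant set
#'
#' The aggregate posterior sign bias of a set of representative variants
#' (one per LD block or per consecutive index group), weighted by the
#' certainty of each variant's posterior sign, with resampling-based
#' uncertainty.
#'
#' @slot etaHat certainty-weighted aggregate sign bias, in `[-1, 1]`.
#' @slot se standard error (block bootstrap or random-replicate SD).
#' @slot nBlocks number of contributing blocks/groups.
#' @slot mode representative-selection mode (`"top"` or `"random"`).
#' @slot replicates number of resampling replicates used.
#'
#' @seealso [bootstrapSignBias()], [randomReplicateSignBias()]
#' @name SignBiasEstimate-class
#' @aliases SignBiasEstimate
#' @exportClass SignBiasEstimate
setClass("SignBiasEstimate",
    representation(
        etaHat     = "numeric",
        se         = "numeric",
        nBlocks    = "integer",
        mode       = "character",
        replicates = "integer"
    )
)

setValidity("SignBiasEstimate", function(object) {
    if (length(object@etaHat) == 1L && is.finite(object@etaHat) &&
        abs(object@etaHat) > 1 + 1e-9)
        "etaHat outside [-1, 1]" else TRUE
})

#' Quadratic logit-scale regression of sign bias on trait skewness
#'
#' An ordinary-least-squares fit of logit-mapped sign bias on trait
#' skewness and its square, optionally with cohort-specific intercept
#' shifts or full cohort interactions, plus per-observation influence
#' diagnostics.
#'
#' @slot model the underlying `lm` fit on the logit scale.
#' @slot spec `"pooled"`, `"intercepts"` or `"interactions"`.
#' @slot records the observation table used (one row per trait x cohort).
#' @slot kPred number of predictors excluding the intercept.
#'
#' @seealso [fitSkewModel()], [influenceExclude()]
#' @name SkewModelFit-class
#' @aliases SkewModelFit
#' @exportClass SkewModelFit
setClass("SkewModelFit",
    representation(
        model   = "ANY",
        spec    = "character",
        records = "data.frame",
        kPred   = "integer"
    )
)
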