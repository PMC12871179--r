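#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn Population-class numeric dosage matrix (optionally a row
#'   subset)
#' @param x,rows see [dosages()]
#' @export
setMethod("dosages", "Population", function(x, rows = NULL) {
    if (nrow(x@genotypes) == 0L)
        stop("population was simulated without stored genotypes")
    g <- if (is.null(rows)) x@genotypes else x@genotypes[rows, , drop = FALSE]
    storage.mode(g) <- "integer"
    storage.mode(g) <- "double"
    g
})

#' @describeIn Cohort-class dosage matrix of cohort members
#' @param x,rows see [dosages()]
#' @export
setMethod("dosages", "Cohort", function(x, rows = NULL) {
    idx <- if (is.null(rows)) x@members else x@members[rows]
    dosages(x@population, rows = idx)
})

#' @export
#' @describeIn Population-class trait values
setMethod("traits", "Population", function(x) x@traits)

#' @export
#' @describeIn Cohort-class trait values of cohort members
setMethod("traits", "Cohort", function(x) x@population@traits[x@members])

#' @export
#' @describeIn Population-class signed true effects
setMethod("effects", "Population", function(x) x@effects)

#' @export
#' @describeIn Cohort-class signed true effects (from the parent population)
setMethod("effects", "Cohort", function(x) x@population@effects)

#' @export
#' @describeIn Population-class assigned allele frequencies
setMethod("freqs", "Population", function(x) x@freqs)

#' @export
#' @describeIn Cohort-class assigned allele frequencies
setMethod("freqs", "Cohort", function(x) x@population@freqs)

#' @export
#' @describeIn Population-class latent mode labels
setMethod("modes", "Population", function(x) x@modes)

#' @export
#' @describeIn Cohort-class latent mode labels of cohort members
setMethod("modes", "Cohort", function(x) {
    if (length(x@population@modes) == 0L) character(0)
    else x@population@modes[x@members]
})

#' @export
#' @describeIn Population-class number of individuals
setMethod("nIndividuals", "Population", function(x) length(x@traits))

#' @export
#' @describeIn Cohort-class cohort size
setMethod("nIndividuals", "Cohort", function(x) length(x@members))

#' @export
#' @describeIn Population-class number of variants
setMethod("nVariants", "Population", function(x) length(x@effects))

#' @export
#' @describeIn Cohort-class number of variants
setMethod("nVariants", "Cohort", function(x) length(x@population@effects))

#' @export
#' @describeIn Cohort-class member indices in the parent population
setMethod("members", "Cohort", function(x) x@members)

#' @export
#' @describeIn Cohort-class realized trait skewness
setMethod("realizedSkewness", "Cohort", function(x) x@skewness)

#' @export
#' @describeIn SignBiasEstimate-class point estimate
setMethod("etaHat", "SignBiasEstimate", function(x) x@etaHat)

#' @export
#' @describeIn AshFit-class fitted mixture weights
setMethod("mixtureWeights", "AshFit", function(x) x@weights)

setMethod("show", "Population", function(object) {
    cat(sprintf(
        "Population (scheme %s): %d individuals, %d paired variants\n",
        object@scheme, length(object@traits), length(object@effects)))
    cat(sprintf("  h2 = %.3g, |beta| = %.4g, genotypes %s\n",
        object@h2,
        if (length(object@effects)) abs(object@effects[1]) else NA_real_,
        if (nrow(object@genotypes)) "stored (raw)" else "not stored"))
    if (length(object@modes))
        cat("  latent modes:",
            paste(sprintf("%s=%d", names(table(object@modes)),
                          as.integer(table(object@modes))), collapse = " "),
            "\n")
})

setMethod("show", "Cohort", function(object) {
    cat(sprintf("Cohort: %d members (scheme %s), realized skewness %.3f\n",
        length(object@members), object@population@scheme, object@skewness))
})

setMethod("show", "AshFit", function(object) {
    cat(sprintf(
        "AshFit: %d components (null + %d normals), null weight %.3f\n",
        length(object@sds), length(object@sds) - 1L, object@weights[1]))
    cat(sprintf("  EM iterations %d, converged: %s, penalized loglik %.4f\n",
        length(object@loglik), object@converged,
        object@loglik[length(object@loglik)]))
})

setMethod("show", "SignBiasEstimate", function(object) {
    cat(sprintf(
        "SignBiasEstimate (%s): etaHat = %.4f, SE = %.4f, %d blocks, %d reps\n",
        object@mode, object@etaHat, object@se, object@nBlocks,
        object@replicates))
})

setMethod("show", "SkewModelFit", function(object) {
    cat(sprintf("SkewModelFit (%s): %d observations, %d predictors\n",
        object@spec, nrow(object@records), object@kPred))
    print(coef(object@model))
    cat(sprintf("  adjusted R2 = %.4f\n", adjustedR2(object)))
})
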