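#' @include AllClasses.R
NULL

#' Extract numeric genotype dosages
#'
#' Returns the dosage matrix (individuals x variants, values 0/1/2) of a
#' [Population] or [Cohort] as a base numeric matrix. For cohorts only the
#' member rows are materialized, so a large population can be held in its
#' compact raw representation while cohort-level analyses work on ordinary
#' numerics.
#'
#' @param x a `Population` or `Cohort`.
#' @param rows optional integer subset of rows (individuals) to extract.
#' @return numeric matrix of dosages.
#' @export
setGeneric("dosages", function(x, rows = NULL) standardGeneric("dosages"))

#' Trait values
#' @param x a `Population` or `Cohort`.
#' @return numeric vector of trait values.
#' @export
setGeneric("traits", function(x) standardGeneric("traits"))

#' True signed allelic effects
#' @param x a `Population` or `Cohort`.
#' @return numeric vector of signed effects (common magnitude).
#' @export
setGeneric("effects", function(x) standardGeneric("effects"))

#' Assigned allele frequencies
#' @param x a `Population` or `Cohort`.
#' @return numeric vector of generating allele frequencies.
#' @export
setGeneric("freqs", function(x) standardGeneric("freqs"))

#' Latent mode labels
#' @param x a `Population` or `Cohort`.
#' @return character vector of mode labels (`"L"/"C"/"R"`), or
#'   `character(0)` for unimodal populations.
#' @export
setGeneric("modes", function(x) standardGeneric("modes"))

#' Number of individuals
#' @param x a `Population` or `Cohort`.
#' @return integer count.
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' Number of variants
#' @param x a `Population` or `Cohort`.
#' @return integer count.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' Cohort member indices
#' @param x a `Cohort`.
#' @return integer indices into the parent population.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Realized trait skewness of a cohort
#' @param x a `Cohort`.
#' @return numeric scalar, the standardized third central moment of cohort
#'   traits.
#' @export
setGeneric("realizedSkewness", function(x) standardGeneric("realizedSkewness"))

#' Point estimate of a sign-bias aggregate
#' @param x a `SignBiasEstimate`.
#' @return numeric scalar in `[-1, 1]` (possibly `NA`).
#' @export
setGeneric("etaHat", function(x) standardGeneric("etaHat"))

#' Mixture weights of an adaptive-shrinkage fit
#' @param x an `AshFit`.
#' @return numeric simplex vector, one weight per grid component.
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))
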