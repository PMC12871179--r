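#' @include AllClasses.R AllGenerics.R
NULL

#' Sample skewness (standardized third central moment)
#'
#' `m3 / m2^(3/2)` with plain central sample moments; no small-sample
#' (Fisher-Pearson) correction is applied.
#'
#' @param values numeric vector, length >= 3, nonconstant.
#' @return numeric scalar.
#' @examples
#' skewness(c(0, 0, 0, 1))   # 2 / sqrt(3)
#' @export
skewness <- function(values) {
    values <- as.numeric(values)
    if (length(values) < 3) stop("need at least 3 values")
    m <- mean(values)
    m2 <- mean((values - m)^2)
    if (m2 == 0) stop("zero variance: skewness undefined")
    mean((values - m)^3) / m2^1.5
}

#' Skewness of a binary trait from its prevalence
#'
#' The standardized third central moment of a 0/1 variable with case
#' fraction `prevalence`: `(1 - 2 phi) / sqrt(phi (1 - phi))`. Used for
#' disease endpoints where only the reported case fraction is available.
#'
#' @param prevalence case fraction in (0, 1).
#' @return numeric scalar (vectorized).
#' @examples
#' binarySkewness(0.25)      # equals skewness(c(0, 0, 0, 1))
#' @export
binarySkewness <- function(prevalence) {
    if (any(!is.finite(prevalence)) || any(prevalence <= 0) ||
        any(prevalence >= 1))
        stop("prevalence must lie strictly within (0, 1)")
    (1 - 2 * prevalence) / sqrt(prevalence * (1 - prevalence))
}

#' Map a sign-bias estimate to the probability and logit scales
#'
#' `pHat = (etaHat + 1) / 2` is the implied posterior probability that a
#' minor-allele effect is trait-increasing; the regression response is
#' `logit(pHat)`. Because near-saturated estimates (`|etaHat|` close to
#' 1) would give infinite logits, `pHat` is clipped to
#' `[clipEps, 1 - clipEps]` first.
#'
#' @param etaHat numeric vector in `[-1, 1]`.
#' @param clipEps clipping bound (default 1e-6).
#' @return `data.frame(p_hat, logit)`.
#' @examples
#' toLogit(c(0, 0.9, 1))
#' @export
toLogit <- function(etaHat, clipEps = 1e-6) {
    if (any(!is.na(etaHat) & abs(etaHat) > 1 + 1e-9))
        stop("etaHat values must lie in [-1, 1]")
    p <- pmin(pmax((etaHat + 1) / 2, clipEps), 1 - clipEps)
    data.frame(p_hat = p, logit = log(p / (1 - p)))
}

skewModelFormula <- function(spec) {
    switch(spec,
        pooled = logit ~ kappa + I(kappa^2),
        intercepts = logit ~ cohort + kappa + I(kappa^2),
        interactions = logit ~ cohort * (kappa + I(kappa^2)))
}

#' Fit a quadratic logit-scale regression of sign bias on skewness
#'
#' Fits, by ordinary least squares on the logit scale, one of three
#' nested specifications: a pooled quadratic in skewness; the pooled
#' quadratic plus cohort-specific intercept shifts (reference cohort
#' absorbed into the global intercept); or cohort-specific intercepts and
#' quadratic slopes (full interactions). Leverage (hat diagonal) and
#' Cook's distance are computed per observation.
#'
#' @param records `data.frame` with columns `trait`, `cohort`,
#'   `skewness`, and either `eta_hat` (mapped through [toLogit()]) or a
#'   precomputed `logit` response.
#' @param spec `"pooled"`, `"intercepts"` or `"interactions"`.
#' @param reference cohort label used as the reference level (default:
#'   first level encountered).
#' @param clipEps passed to [toLogit()] when the response is built from
#'   `eta_hat`.
#' @return a [SkewModelFit].
#' @export
fitSkewModel <- function(records, spec = c("pooled", "intercepts",
                                           "interactions"),
                         reference = NULL, clipEps = 1e-6) {
    spec <- match.arg(spec)
    stopifnot(is.data.frame(records))
    need <- c("trait", "cohort", "skewness")
    if (!all(need %in% names(records)))
        stop("records must have columns: ", paste(need, collapse = ", "))
    if (!"logit" %in% names(records)) {
        if (!"eta_hat" %in% names(records))
            stop("records must carry 'eta_hat' or a precomputed 'logit'")
        records$logit <- toLogit(records$eta_hat, clipEps)$logit
    }
    records$kappa <- records$skewness
    records$cohort <- factor(records$cohort)
    if (!is.null(reference)) {
        if (!reference %in% levels(records$cohort))
            stop("reference cohort not present in the records")
        records$cohort <- stats::relevel(records$cohort, ref = reference)
    }
    if (spec != "pooled" && nlevels(records$cohort) < 2)
        stop("rank-deficient design: cohort terms need at least two ",
             "cohort labels")
    form <- skewModelFormula(spec)
    kPred <- ncol(model.matrix(form, records)) - 1L
    if (nrow(records) < kPred + 2)
        stop("need at least k_pred + 2 observations")
    fit <- lm(form, data = records)
    if (anyNA(coef(fit)))
        stop("rank-deficient design: collinear terms ",
             paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
    new("SkewModelFit", model = fit, spec = spec, records = records,
        kPred = as.integer(kPred))
}

#' Adjusted R-squared of a skew-model fit
#' @param fit a [SkewModelFit].
#' @return numeric scalar,
#'   `1 - (1 - R2) (n_obs - 1) / (n_obs - k_pred - 1)`.
#' @export
adjustedR2 <- function(fit) {
    stopifnot(is(fit, "SkewModelFit"))
    summary(fit@model)$adj.r.squared
}

#' Influence diagnostics of a skew-model fit
#' @param fit a [SkewModelFit].
#' @return `data.frame(trait, cohort, leverage, cooks)` aligned with the
#'   fitted observations.
#' @export
influenceDiagnostics <- function(fit) {
    stopifnot(is(fit, "SkewModelFit"))
    data.frame(trait = fit@records$trait, cohort = fit@records$cohort,
               leverage = unname(hatvalues(fit@model)),
               cooks = unname(cooks.distance(fit@model)))
}

#' Incremental adjusted R-squared between nested fits
#'
#' `adjustedR2(large) - adjustedR2(small)`; may be negative when the
#' extra terms fail to earn their degrees of freedom. Both fits must use
#' exactly the same observations.
#'
#' @param fitSmall,fitLarge nested [SkewModelFit] objects (e.g. pooled
#'   vs. intercepts, intercepts vs. interactions).
#' @return numeric scalar.
#' @export
incrementalAdjustedR2 <- function(fitSmall, fitLarge) {
    stopifnot(is(fitSmall, "SkewModelFit"), is(fitLarge, "SkewModelFit"))
    a <- fitSmall@records; b <- fitLarge@records
    same <- nrow(a) == nrow(b) &&
        identical(as.character(a$trait), as.character(b$trait)) &&
        identical(as.character(a$cohort), as.character(b$cohort)) &&
        isTRUE(all.equal(a$logit, b$logit))
    if (!same) stop("fits were computed on different observation sets")
    order <- c(pooled = 1, intercepts = 2, interactions = 3)
    if (order[fitSmall@spec] > order[fitLarge@spec])
        stop("'fitSmall' must be the smaller (nested) specification")
    adjustedR2(fitLarge) - adjustedR2(fitSmall)
}

#' Joint high-leverage / high-influence exclusion rule
#'
#' Flags observations that are simultaneously very high leverage
#' (`hat > 3 (k_pred + 1) / n_obs`) and highly influential (Cook's
#' distance above twice the conventional `4 / n_obs` threshold, i.e.
#' `> 8 / n_obs`). Both conditions are required; the rule is applied
#' once, without iterative re-diagnosis.
#'
#' @param fit a [SkewModelFit].
#' @param refit also return the model refit without the flagged
#'   observations (default `TRUE`).
#' @return list with `excluded` (integer row indices into the fit's
#'   records, possibly empty), `diagnostics` (the full diagnostics
#'   table), and — when `refit` and any exclusion — `refit`, the
#'   [SkewModelFit] on the remaining observations.
#' @export
influenceExclude <- function(fit, refit = TRUE) {
    stopifnot(is(fit, "SkewModelFit"))
    d <- influenceDiagnostics(fit)
    n <- nrow(d)
    levCut <- 3 * (fit@kPred + 1) / n
    cookCut <- 8 / n
    excluded <- which(d$leverage > levCut & d$cooks > cookCut)
    out <- list(excluded = excluded, diagnostics = d,
                thresholds = c(leverage = levCut, cooks = cookCut))
    if (refit && length(excluded))
        out$refit <- fitSkewModel(fit@records[-excluded, , drop = FALSE],
                                  spec = fit@spec)
    out
}

#' Pooled Spearman correlation between skewness and sign bias
#'
#' Rank correlation of `(skewness, eta_hat)` pooled over all records
#' (traits x cohorts), with a two-sided asymptotic p-value.
#'
#' @param records `data.frame` with columns `skewness` and `eta_hat`.
#' @return list with `rho` and `p_value`.
#' @export
pooledSpearman <- function(records) {
    stopifnot(is.data.frame(records),
              all(c("skewness", "eta_hat") %in% names(records)))
    if (nrow(records) < 4) stop("need at least 4 records")
    if (length(unique(records$skewness)) < 2 ||
        length(unique(records$eta_hat)) < 2)
        stop("constant ranks: Spearman correlation undefined")
    ct <- suppressWarnings(cor.test(records$skewness, records$eta_hat,
                                    method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p_value = ct$p.value)
}
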