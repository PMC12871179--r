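#' @include AllClasses.R AllGenerics.R
NULL

#' Default grid of mixture-component standard deviations
#'
#' Builds the adaptive-shrinkage component grid: a null point mass
#' (sd 0) followed by a geometric sequence with common ratio `sqrt(2)`
#' from `min(se) / 10` up to at least `2 * max(abs(betahat))`. When every
#' observed effect is zero the sequence degenerates to
#' `c(0, sigma_min, sigma_min * sqrt(2))`.
#'
#' @param betahat numeric vector of observed effects.
#' @param se numeric vector of their standard errors (> 0).
#' @return numeric vector of component sds, first element 0.
#' @export
buildAshGrid <- function(betahat, se) {
    if (length(betahat) == 0L || length(betahat) != length(se))
        stop("'betahat' and 'se' must be nonempty vectors of equal length")
    if (any(!is.finite(se)) || any(se <= 0))
        stop("all standard errors must be finite and > 0")
    sigMin <- min(se) / 10
    sigMax <- 2 * max(abs(betahat))
    if (sigMax <= sigMin * sqrt(2)) sigMax <- sigMin * sqrt(2)
    k <- ceiling(log(sigMax / sigMin) / log(sqrt(2)))
    c(0, sigMin * sqrt(2)^(0:k))
}

# Marginal likelihood matrix: L[i, c] = N(betahat_i; 0, sd_c^2 + se_i^2),
# scaled row-wise for numerical stability (log row maxima returned).
ashLikelihood <- function(betahat, se, sds) {
    n <- length(betahat)
    sdMat <- sqrt(outer(se^2, sds^2, "+"))
    logL <- dnorm(matrix(betahat, n, length(sds)), 0, sdMat, log = TRUE)
    rowMax <- apply(logL, 1L, max)
    list(lik = exp(logL - rowMax), logScale = rowMax)
}

#' Fit the zero-centered normal-mixture prior by penalized EM
#'
#' Maximizes the penalized marginal log-likelihood
#' `sum_i log sum_c pi_c N(betahat_i; 0, sd_c^2 + se_i^2)
#'  + sum_c (lambda_c - 1) log pi_c`
#' over the mixture weights, where `lambda` places `nullPenalty - 1`
#' pseudo-counts on the null component (favouring the "no effect"
#' explanation when the data permit) and 0 on the others. Standard errors
#' are treated as fixed and known. The EM trace is recorded and is
#' nondecreasing by construction.
#'
#' @param betahat,se observed effects and standard errors.
#' @param grid component sds from [buildAshGrid()]; built from the data
#'   when `NULL`.
#' @param nullPenalty Dirichlet-style penalty on the null weight
#'   (default 10; 1 = no penalty).
#' @param tol relative penalized-loglik change for convergence
#'   (default 1e-7).
#' @param maxIter maximum EM iterations (default 2000).
#' @return an [AshFit].
#' @examples
#' set.seed(1)
#' b <- c(rnorm(200, 0, sqrt(2)), rnorm(200, 0, 1e-3))
#' fit <- fitAshMixture(b, rep(1, 400))
#' mixtureWeights(fit)[1]   # weight on the null point mass
#' @export
fitAshMixture <- function(betahat, se, grid = NULL, nullPenalty = 10,
                          tol = 1e-7, maxIter = 2000) {
    if (length(betahat) != length(se))
        stop("'betahat' and 'se' must have the same length")
    if (any(!is.finite(betahat)) || any(!is.finite(se)) || any(se <= 0))
        stop("inputs must be finite with se > 0")
    if (nullPenalty < 1) stop("'nullPenalty' must be >= 1")
    if (is.null(grid)) grid <- buildAshGrid(betahat, se)
    if (grid[1] != 0 || is.unsorted(grid, strictly = TRUE))
        stop("grid must start at 0 and be strictly increasing")
    K <- length(grid)
    n <- length(betahat)
    lk <- ashLikelihood(betahat, se, grid)
    lambda <- c(nullPenalty, rep(1, K - 1))
    pi <- rep(1 / K, K)
    penLog <- function(pi) {
        dens <- as.vector(lk$lik %*% pi)
        if (any(dens <= 0) || any(!is.finite(dens)))
            stop("non-finite marginal likelihood during EM")
        extra <- sum((lambda - 1)[pi > 0] * log(pi[pi > 0]))
        sum(log(dens) + lk$logScale) + extra
    }
    trace <- penLog(pi)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        dens <- as.vector(lk$lik %*% pi)
        # E-step responsibilities summed over variants, plus pseudo-counts
        nc <- as.vector(crossprod(lk$lik, 1 / dens)) * pi + (lambda - 1)
        pi <- nc / sum(nc)
        ll <- tryCatch(penLog(pi), error = function(e)
            stop(sprintf("non-finite penalized loglik at EM iteration %d",
                         it)))
        trace <- c(trace, ll)
        if (abs(ll - trace[length(trace) - 1]) <
            tol * (abs(ll) + .Machine$double.eps)) {
            converged <- TRUE
            break
        }
    }
    new("AshFit", sds = grid, weights = pi, loglik = trace,
        converged = converged, penalty = nullPenalty)
}

#' Posterior sign probabilities and per-variant sign score eta
#'
#' Given a fitted mixture prior, computes for each variant the posterior
#' probabilities that its true effect is positive, negative, or exactly
#' zero (the null point mass), and the sign score
#' `eta = Pr(beta > 0 | data) - Pr(beta < 0 | data)` in `[-1, 1]`.
#' Within a normal component with prior sd `sigma`, the conjugate
#' posterior of the true effect is
#' `Normal(sigma^2 betahat / (sigma^2 + se^2),
#'         sigma^2 se^2 / (sigma^2 + se^2))`;
#' tail masses are averaged over components with the posterior
#' responsibilities.
#'
#' @param fit an [AshFit].
#' @param betahat,se the observed effects and standard errors to score
#'   (typically those the fit was computed on).
#' @return `data.frame(pr_pos, pr_neg, pr_null, eta)`, one row per
#'   variant.
#' @export
posteriorSigns <- function(fit, betahat, se) {
    stopifnot(is(fit, "AshFit"))
    if (length(betahat) != length(se))
        stop("'betahat' and 'se' must have the same length")
    sds <- fit@sds
    lk <- ashLikelihood(betahat, se, sds)
    wLik <- sweep(lk$lik, 2L, fit@weights, "*")
    resp <- wLik / rowSums(wLik)
    n <- length(betahat)
    prPos <- numeric(n)
    prNeg <- numeric(n)
    for (c in seq_along(sds)[-1]) {
        v <- sds[c]^2
        postMean <- v * betahat / (v + se^2)
        postSd <- sqrt(v * se^2 / (v + se^2))
        z <- postMean / postSd
        prPos <- prPos + resp[, c] * pnorm(z)
        prNeg <- prNeg + resp[, c] * pnorm(-z)
    }
    data.frame(pr_pos = prPos, pr_neg = prNeg, pr_null = resp[, 1],
               eta = prPos - prNeg)
}
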