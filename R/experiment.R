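#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Estimated sign bias of a simulated cohort
#'
#' Runs the full summary-statistic pipeline on one cohort: per-variant
#' OLS association, empirical-Bayes shrinkage of all segregating
#' variants, posterior sign scores, MAF restriction, representative
#' selection by consecutive index groups (one minimum-p SNP per group of
#' `groupSize`), and the certainty-weighted aggregate. Uncertainty comes
#' from resampling the contributing groups with replacement, exactly as
#' the LD-block bootstrap.
#'
#' @param cohort a [Cohort] with stored genotypes.
#' @param mafMax sample-MAF threshold for the variant set (default 0.01).
#' @param groupSize consecutive-index group size (default 6).
#' @param nullPenalty,tol,maxIter passed to [fitAshMixture()].
#' @param bootstrapReps group-bootstrap replicates for the SE (default
#'   200; set 0 to skip).
#' @param seed integer seed.
#' @return a [SignBiasEstimate] (mode `"top"`), with attribute `details`
#'   holding the GWAS table, sign scores and selected representatives.
#' @export
estimateCohortSignBias <- function(cohort, mafMax = 0.01, groupSize = 6,
                                   nullPenalty = 10, tol = 1e-7,
                                   maxIter = 2000, bootstrapReps = 200,
                                   seed = NULL) {
    gwas <- olsGwas(cohort)
    fit <- fitAshMixture(gwas$beta_minor, gwas$se, nullPenalty = nullPenalty,
                         tol = tol, maxIter = maxIter)
    signs <- posteriorSigns(fit, gwas$beta_minor, gwas$se)
    reps <- groupRepresentatives(gwas, groupSize = groupSize,
                                 mafMax = mafMax)
    eta <- signs$eta[reps]
    point <- suppressWarnings(aggregateEta(eta))
    b <- length(eta)
    se <- NA_real_
    if (bootstrapReps > 0 && is.finite(point)) {
        boot <- withSeed(deriveSeed(seed, "groupboot"),
            vapply(seq_len(bootstrapReps), function(r) {
                v <- eta[sample.int(b, b, replace = TRUE)]
                if (sum(abs(v)) == 0) NA_real_ else sum(v) / sum(abs(v))
            }, numeric(1)))
        boot <- boot[is.finite(boot)]
        if (length(boot))
            se <- sqrt(mean((boot - mean(boot))^2))
    }
    out <- new("SignBiasEstimate", etaHat = point, se = se,
               nBlocks = as.integer(b), mode = "top",
               replicates = as.integer(bootstrapReps))
    attr(out, "details") <- list(gwas = gwas, ashFit = fit, signs = signs,
                                 representatives = reps)
    out
}

defaultTuningGrid <- function(scheme) {
    if (scheme == "A") seq(0, 0.95, by = 0.005)
    else c(seq(0.001, 0.02, by = 0.0005), seq(0.021, 0.35, by = 0.003))
}

#' Run the full skewness-to-sign-bias simulation experiment
#'
#' For one simulated population: per target skewness, tunes the sampler
#' parameter (quantile cutoff for scheme A, right-mode fraction for
#' scheme B) by grid search, draws replicate cohorts, and records for
#' each the realized skewness, the true (generative) cohort sign bias
#' and the pipeline-estimated sign bias for variants at sample MAF below
#' `mafMax`. The population minor-allele sign bias — exactly zero by the
#' paired construction — is reported alongside.
#'
#' @param scheme `"A"` or `"B"`.
#' @param nIndividuals,nVariants,h2,freqRange population settings (see
#'   [simulatePopulationA()]).
#' @param tailFraction,shift scheme-B population settings.
#' @param targets numeric vector of target skewness values (default
#'   `1:10`).
#' @param replicates cohorts per target (default 20).
#' @param cohortSize cohort size n.
#' @param shape,uniformMix,nBins scheme-A sampler settings.
#' @param windowHalfWidths,concentrations scheme-B sampler settings.
#' @param grid tuning grid (default: `seq(0, 0.95, 0.005)` for A, a
#'   fine-to-coarse fraction grid for B).
#' @param tuneDraws cohorts per grid point during tuning (default 1).
#' @param mafMax,groupSize,bootstrapReps sign-bias pipeline settings.
#' @param seed integer master seed; all stages derive independent
#'   streams from it.
#' @param population optionally, a pre-simulated [Population] to reuse
#'   (its scheme must match).
#' @return `data.frame` with one row per (target, replicate): `target`,
#'   `replicate`, `parameter`, `skewness`, `true_bias`, `est_bias`,
#'   `est_se`, `n_groups`. Attributes: `populationSignBias` (exactly 0),
#'   `summary` (per-target means and normal-theory 95% CIs of the
#'   estimated bias).
#' @export
runSchemeExperiment <- function(scheme = c("A", "B"), nIndividuals,
                                nVariants = 4000, h2 = 0.6,
                                freqRange = c(1e-4, 0.1),
                                tailFraction = 0.1, shift = 0.5,
                                targets = 1:10, replicates = 20,
                                cohortSize, shape = 20, uniformMix = 0.01,
                                nBins = 200,
                                windowHalfWidths = c(C = 0.1, R = 0.037),
                                concentrations = c(C = 200, R = 2),
                                grid = NULL, tuneDraws = 1, mafMax = 0.01,
                                groupSize = 6, bootstrapReps = 0,
                                seed = NULL, population = NULL) {
    scheme <- match.arg(scheme)
    if (is.null(grid)) grid <- defaultTuningGrid(scheme)
    pop <- if (!is.null(population)) {
        stopifnot(is(population, "Population"), population@scheme == scheme)
        population
    } else if (scheme == "A") {
        simulatePopulationA(nIndividuals, nVariants, h2, freqRange,
                            keepGenotypes = TRUE,
                            seed = deriveSeed(seed, "population"))
    } else {
        simulatePopulationB(nIndividuals, nVariants, h2, freqRange,
                            tailFraction, shift, keepGenotypes = TRUE,
                            seed = deriveSeed(seed, "population"))
    }
    rows <- list()
    for (tgt in targets) {
        par <- tuneSkewTarget(pop, targetSkew = tgt, grid = grid,
                              cohortSize = cohortSize, draws = tuneDraws,
                              shape = shape, uniformMix = uniformMix,
                              nBins = nBins,
                              windowHalfWidths = windowHalfWidths,
                              concentrations = concentrations,
                              seed = deriveSeed(seed, paste0("tune", tgt)))
        for (r in seq_len(replicates)) {
            cseed <- deriveSeed(seed, paste0("cohort", tgt, "_", r))
            cohort <- if (scheme == "A")
                sampleCohortA(pop, cohortSize, cutoff = as.numeric(par),
                              shape = shape, uniformMix = uniformMix,
                              nBins = nBins, seed = cseed)
            else
                sampleCohortB(pop, cohortSize,
                              rightFraction = as.numeric(par),
                              windowHalfWidths = windowHalfWidths,
                              concentrations = concentrations, seed = cseed)
            est <- estimateCohortSignBias(cohort, mafMax = mafMax,
                                          groupSize = groupSize,
                                          bootstrapReps = bootstrapReps,
                                          seed = cseed)
            rows[[length(rows) + 1L]] <- data.frame(
                target = tgt, replicate = r, parameter = as.numeric(par),
                skewness = realizedSkewness(cohort),
                true_bias = trueSignBias(cohort, mafMax = mafMax),
                est_bias = etaHat(est), est_se = est@se,
                n_groups = est@nBlocks)
        }
    }
    out <- do.call(rbind, rows)
    agg <- do.call(rbind, lapply(split(out, out$target), function(d) {
        m <- mean(d$est_bias, na.rm = TRUE)
        s <- sd(d$est_bias, na.rm = TRUE) / sqrt(sum(is.finite(d$est_bias)))
        data.frame(target = d$target[1],
                   mean_skewness = mean(d$skewness),
                   mean_true_bias = mean(d$true_bias, na.rm = TRUE),
                   mean_est_bias = m,
                   ci_lo = m - qnorm(0.975) * s,
                   ci_hi = m + qnorm(0.975) * s)
    }))
    rownames(agg) <- NULL
    attr(out, "populationSignBias") <- populationSignBias(pop)
    attr(out, "summary") <- agg
    out
}
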