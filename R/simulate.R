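#' @include AllClasses.R AllGenerics.R utils.R
NULL

# Shared variant layout for both schemes: M/2 pairs, each pair sharing a
# log-uniform allele frequency and carrying effects (+b, -b), with
# b = sqrt(h2 / sum_j 2 p_j (1 - p_j)) so the genetic variance is h2.
pairedVariantLayout <- function(nVariants, h2, freqRange, seed) {
    stopifnotScalar(nVariants, "nVariants", lower = 2, integer = TRUE)
    if (nVariants %% 2 != 0)
        stop("'nVariants' must be even: variants come in matched +/- pairs")
    stopifnotScalar(h2, "h2", lower = 0, upper = 1,
                    openLower = TRUE, openUpper = TRUE)
    if (length(freqRange) != 2 || !(freqRange[1] > 0) ||
        !(freqRange[1] < freqRange[2]) || !(freqRange[2] <= 0.5))
        stop("'freqRange' must satisfy 0 < p_min < p_max <= 0.5")
    pPair <- withSeed(deriveSeed(seed, "freqs"),
        exp(runif(nVariants / 2, log(freqRange[1]), log(freqRange[2]))))
    p <- rep(pPair, each = 2L)
    b <- sqrt(h2 / sum(2 * p * (1 - p)))
    beta <- rep(c(b, -b), times = nVariants / 2)
    list(freqs = p, effects = beta, magnitude = b)
}

# Accumulate genetic values (and optionally store raw dosages) chunk-wise,
# keeping transient memory at ~chunk x N integers.
genotypeSweep <- function(nInd, probsForChunk, effects, keepGenotypes,
                          chunkSize = 100L) {
    M <- length(effects)
    gval <- numeric(nInd)
    geno <- if (keepGenotypes)
        matrix(as.raw(0), nrow = nInd, ncol = M) else matrix(raw(0), 0, 0)
    start <- 1L
    while (start <= M) {
        cols <- start:min(start + chunkSize - 1L, M)
        pr <- probsForChunk(cols)      # nInd x length(cols), or recycled vector
        g <- rbinom(nInd * length(cols), 2L, pr)
        if (keepGenotypes)
            geno[, cols] <- as.raw(g)
        dim(g) <- c(nInd, length(cols))
        gval <- gval + as.vector(g %*% effects[cols])
        start <- start + chunkSize
    }
    list(gval = gval, geno = geno)
}

#' Simulate a unimodal population with paired opposite-effect variants
#'
#' Generates `nIndividuals` diploid individuals at `nVariants` independent
#' biallelic variants under Hardy-Weinberg equilibrium. Variants form
#' matched pairs sharing an allele frequency drawn log-uniformly on
#' `freqRange`; within a pair one variant is trait-increasing and one
#' trait-decreasing with common magnitude `sqrt(h2 / sum(2 p (1 - p)))`, so
#' the expected genetic value is zero and the genetic variance equals `h2`.
#' Traits add independent `Normal(0, 1 - h2)` environmental noise, giving a
#' trait variance near 1.
#'
#' @param nIndividuals population size N.
#' @param nVariants number of variants M (even; default 4000).
#' @param h2 narrow-sense heritability in (0, 1) (default 0.6).
#' @param freqRange allele-frequency range for the log-uniform draw
#'   (default `c(1e-4, 0.1)`).
#' @param keepGenotypes store the dosage matrix (raw-typed, one byte per
#'   genotype)? Set `FALSE` when only the trait distribution is needed.
#' @param seed integer master seed (`NULL` = use the current RNG stream).
#' @param chunkSize variants per generation chunk (memory/speed trade-off).
#' @return a [Population] (scheme `"A"`).
#' @examples
#' pop <- simulatePopulationA(2000, nVariants = 100, seed = 1)
#' var(traits(pop))  # close to 1
#' @export
simulatePopulationA <- function(nIndividuals, nVariants = 4000, h2 = 0.6,
                                freqRange = c(1e-4, 0.1),
                                keepGenotypes = TRUE, seed = NULL,
                                chunkSize = 100L) {
    stopifnotScalar(nIndividuals, "nIndividuals", lower = 1, integer = TRUE)
    lay <- pairedVariantLayout(nVariants, h2, freqRange, seed)
    sweep <- withSeed(deriveSeed(seed, "genotypes"),
        genotypeSweep(nIndividuals,
            probsForChunk = function(cols)
                rep(lay$freqs[cols], each = nIndividuals),
            effects = lay$effects, keepGenotypes = keepGenotypes,
            chunkSize = chunkSize))
    eps <- withSeed(deriveSeed(seed, "noise"),
        rnorm(nIndividuals, 0, sqrt(1 - h2)))
    new("Population",
        genotypes = sweep$geno, effects = lay$effects, freqs = lay$freqs,
        traits = sweep$gval + eps, modes = character(0), scheme = "A",
        h2 = h2,
        params = list(nIndividuals = nIndividuals, nVariants = nVariants,
                      h2 = h2, freqRange = freqRange, seed = seed))
}

#' Simulate a tri-modal population with latent mode structure
#'
#' As [simulatePopulationA()], but each individual is first assigned a
#' latent mode `L`/`C`/`R` with probabilities `f, 1 - 2f, f`, and the
#' allele frequency of variant `j` within mode `z` is shifted to
#' `p_j (1 + delta * zeta_j * t(z))` with `t(L) = -1`, `t(C) = 0`,
#' `t(R) = +1` and `zeta_j = sign(beta_j)`: trait-increasing alleles are
#' commoner in the right mode and trait-decreasing alleles in the left
#' mode, separating the modes genetically while leaving every variant's
#' marginal allele frequency exactly `p_j` and the overall trait
#' distribution symmetric.
#'
#' @inheritParams simulatePopulationA
#' @param tailFraction f, probability of each outer mode (default 0.1).
#' @param shift delta >= 0, relative mode-specific frequency shift
#'   (default 0.5); must keep every `p_j (1 + delta)` below 1.
#' @return a [Population] (scheme `"B"`) with mode labels stored.
#' @examples
#' pop <- simulatePopulationB(2000, nVariants = 100, seed = 1)
#' table(modes(pop))
#' @export
simulatePopulationB <- function(nIndividuals, nVariants = 4000, h2 = 0.6,
                                freqRange = c(1e-4, 0.1), tailFraction = 0.1,
                                shift = 0.5, keepGenotypes = TRUE,
                                seed = NULL, chunkSize = 50L) {
    stopifnotScalar(nIndividuals, "nIndividuals", lower = 1, integer = TRUE)
    stopifnotScalar(tailFraction, "tailFraction", lower = 0, upper = 0.5,
                    openLower = TRUE, openUpper = TRUE)
    stopifnotScalar(shift, "shift", lower = 0)
    lay <- pairedVariantLayout(nVariants, h2, freqRange, seed)
    pHi <- lay$freqs * (1 + shift)
    pLo <- lay$freqs * (1 - shift)
    if (any(pHi >= 1) || any(pLo <= 0))
        stop("mode-specific frequency p_j (1 +/- shift) outside (0, 1); ",
             "reduce 'shift' or the frequency range")
    f <- tailFraction
    mode <- withSeed(deriveSeed(seed, "modes"),
        sample(c("L", "C", "R"), nIndividuals, replace = TRUE,
               prob = c(f, 1 - 2 * f, f)))
    tz <- c(L = -1, C = 0, R = 1)[mode]          # length N
    zeta <- sign(lay$effects)
    sweep <- withSeed(deriveSeed(seed, "genotypes"),
        genotypeSweep(nIndividuals,
            probsForChunk = function(cols) {
                # p*_j(z) = p_j (1 + delta zeta_j t(z)); N x k matrix
                outer(shift * tz, lay$freqs[cols] * zeta[cols]) +
                    rep(lay$freqs[cols], each = nIndividuals)
            },
            effects = lay$effects, keepGenotypes = keepGenotypes,
            chunkSize = chunkSize))
    eps <- withSeed(deriveSeed(seed, "noise"),
        rnorm(nIndividuals, 0, sqrt(1 - h2)))
    new("Population",
        genotypes = sweep$geno, effects = lay$effects, freqs = lay$freqs,
        traits = sweep$gval + eps, modes = mode, scheme = "B", h2 = h2,
        params = list(nIndividuals = nIndividuals, nVariants = nVariants,
                      h2 = h2, freqRange = freqRange,
                      tailFraction = tailFraction, shift = shift,
                      seed = seed))
}

#' Per-bin sampling probabilities for the quantile-bin cohort sampler
#'
#' Bins partition the population into `nBins` equal-count trait-quantile
#' slices with mid-quantile ranks `r_v = (v - 0.5) / nBins`. Bins with
#' `r_v >= cutoff` are retained; within the retained set the rescaled rank
#' is `r* = (r - cutoff) / (1 - cutoff)`, the weight `w = (1 - r*)^shape`
#' concentrates mass just above the cutoff for large `shape`, and a
#' fraction `uniformMix` of the probability is spread uniformly over
#' retained bins:
#' `p_v = uniformMix / |Vq| + (1 - uniformMix) * w_v / sum(w)`.
#'
#' @param nBins number of quantile bins V.
#' @param cutoff q in `[0, 1)`; bins below it get probability 0.
#' @param shape gamma >= 0, concentration of mass near the cutoff.
#' @param uniformMix tau in `[0, 1]`, uniform mixture fraction.
#' @return numeric vector of length `nBins` summing to 1.
#' @examples
#' binProbabilities(4, cutoff = 0.5, shape = 1, uniformMix = 0)
#' @export
binProbabilities <- function(nBins, cutoff, shape, uniformMix) {
    stopifnotScalar(nBins, "nBins", lower = 1, integer = TRUE)
    stopifnotScalar(cutoff, "cutoff", lower = 0, upper = 1, openUpper = TRUE)
    stopifnotScalar(shape, "shape", lower = 0)
    stopifnotScalar(uniformMix, "uniformMix", lower = 0, upper = 1)
    r <- (seq_len(nBins) - 0.5) / nBins
    keep <- r >= cutoff
    if (!any(keep))
        stop("cutoff leaves no bins")
    rstar <- (r[keep] - cutoff) / (1 - cutoff)
    w <- (1 - rstar)^shape
    p <- numeric(nBins)
    p[keep] <- uniformMix / sum(keep) + (1 - uniformMix) * w / sum(w)
    p
}

#' Draw a biased cohort from a unimodal population by quantile bins
#'
#' Individuals are rank-ordered by trait (ties broken by index) and cut
#' into `nBins` equal-count bins; per-bin cohort counts are multinomial
#' with probabilities from [binProbabilities()], and members are drawn
#' uniformly without replacement within each bin. If a multinomial count
#' exceeds a bin's occupancy it is capped and the deficit redrawn from the
#' remaining retained bins' renormalized probabilities (with a warning).
#'
#' @param pop a [Population].
#' @param cohortSize number of cohort members n.
#' @param cutoff,shape,uniformMix,nBins sampler parameters; see
#'   [binProbabilities()]. Defaults `shape = 20`, `uniformMix = 0.01`,
#'   `nBins = 200` reproduce the standard biased-ascertainment setting.
#' @param seed integer seed for the bin counts and within-bin draws.
#' @return a [Cohort].
#' @export
sampleCohortA <- function(pop, cohortSize, cutoff, shape = 20,
                          uniformMix = 0.01, nBins = 200, seed = NULL) {
    stopifnot(is(pop, "Population"))
    N <- nIndividuals(pop)
    stopifnotScalar(cohortSize, "cohortSize", lower = 1, upper = N,
                    integer = TRUE)
    if (N %% nBins != 0)
        stop("'nBins' must divide the population size exactly")
    binSize <- N %/% nBins
    p <- binProbabilities(nBins, cutoff, shape, uniformMix)
    if (cohortSize > sum(p > 0) * binSize)
        stop("cohort size exceeds the capacity of the retained bins")
    ord <- order(pop@traits, seq_len(N))      # stable rank order
    counts <- withSeed(deriveSeed(seed, "bincounts"), {
        C <- as.vector(rmultinom(1, cohortSize, p))
        if (any(C > binSize)) {
            warning("bin sample counts exceeded bin occupancy; ",
                    "capped and redistributed")
            repeat {
                C <- pmin(C, binSize)
                deficit <- cohortSize - sum(C)
                if (deficit == 0L) break
                room <- p > 0 & C < binSize
                C[room] <- C[room] +
                    as.vector(rmultinom(1, deficit, p[room] / sum(p[room])))
            }
        }
        C
    })
    members <- withSeed(deriveSeed(seed, "withinbin"), {
        picks <- vector("list", nBins)
        for (v in which(counts > 0L)) {
            binMembers <- ord[((v - 1L) * binSize + 1L):(v * binSize)]
            picks[[v]] <- binMembers[sample.int(binSize, counts[v])]
        }
        unlist(picks, use.names = FALSE)
    })
    y <- pop@traits[members]
    new("Cohort", population = pop, members = as.integer(members),
        design = list(scheme = "A", cutoff = cutoff, shape = shape,
                      uniformMix = uniformMix, nBins = nBins,
                      cohortSize = cohortSize, seed = seed),
        skewness = skewness(y))
}

#' Draw a two-component cohort from a tri-modal population
#'
#' A fraction `rightFraction` of the cohort (rounded half-to-even) is
#' drawn from the right latent mode and the remainder from the center
#' mode. Within mode `z`, sampling is restricted to the window
#' `|Y - m_z| <= u_z * s_z` around the empirical mode median `m_z` (with
#' `s_z` the empirical within-mode SD), and individuals are drawn without
#' replacement with weight `exp(-lambda_z ((Y - m_z) / s_z)^2)`.
#'
#' @param pop a [Population] of scheme `"B"` (mode labels required).
#' @param cohortSize cohort size n.
#' @param rightFraction rho in `[0, 1]`, fraction drawn from the right
#'   mode.
#' @param windowHalfWidths named numeric `c(C = , R = )` window half-widths
#'   `u_z` in units of within-mode SD (default `c(C = 0.1, R = 0.037)`).
#' @param concentrations named numeric `c(C = , R = )` weight
#'   concentrations `lambda_z` (default `c(C = 200, R = 2)`).
#' @param seed integer seed for the weighted draws.
#' @return a [Cohort].
#' @export
sampleCohortB <- function(pop, cohortSize, rightFraction,
                          windowHalfWidths = c(C = 0.1, R = 0.037),
                          concentrations = c(C = 200, R = 2), seed = NULL) {
    stopifnot(is(pop, "Population"))
    if (length(pop@modes) == 0L)
        stop("population has no latent modes; use a scheme-B population")
    stopifnotScalar(cohortSize, "cohortSize", lower = 1, integer = TRUE)
    stopifnotScalar(rightFraction, "rightFraction", lower = 0, upper = 1)
    if (any(windowHalfWidths <= 0) || any(concentrations < 0))
        stop("window half-widths must be > 0 and concentrations >= 0")
    nR <- as.integer(round(rightFraction * cohortSize))
    nC <- as.integer(cohortSize) - nR
    drawMode <- function(z, nz, tagSeed) {
        if (nz == 0L) return(integer(0))
        inMode <- which(pop@modes == z)
        y <- pop@traits[inMode]
        m <- median(y); s <- sd(y)
        u <- windowHalfWidths[[z]]; lam <- concentrations[[z]]
        elig <- inMode[abs(y - m) <= u * s]
        if (length(elig) < nz)
            stop(sprintf(
                "mode %s: only %d individuals in the sampling window, %d needed",
                z, length(elig), nz))
        w <- exp(-lam * ((pop@traits[elig] - m) / s)^2)
        withSeed(tagSeed, elig[sample.int(length(elig), nz, prob = w)])
    }
    members <- c(drawMode("C", nC, deriveSeed(seed, "drawC")),
                 drawMode("R", nR, deriveSeed(seed, "drawR")))
    y <- pop@traits[members]
    new("Cohort", population = pop, members = as.integer(members),
        design = list(scheme = "B", rightFraction = rightFraction,
                      windowHalfWidths = windowHalfWidths,
                      concentrations = concentrations,
                      cohortSize = cohortSize, seed = seed),
        skewness = skewness(y))
}

#' Grid-search a sampler parameter for a target cohort skewness
#'
#' For each grid value of the tuned parameter (the quantile cutoff `q` for
#' scheme A, the right-mode fraction `rho` for scheme B) draws `draws`
#' cohorts, averages their realized skewness, and returns the grid value
#' whose mean skewness is closest to `targetSkew` (ties broken toward the
#' smaller parameter). Grid values whose cohorts cannot be drawn (e.g. a
#' window with too few eligible individuals) are skipped.
#'
#' @param pop a [Population].
#' @param targetSkew target cohort skewness.
#' @param grid numeric grid of candidate parameter values.
#' @param cohortSize cohort size used during tuning.
#' @param draws cohorts drawn per grid point (default 1).
#' @param shape,uniformMix,nBins scheme-A sampler settings.
#' @param windowHalfWidths,concentrations scheme-B sampler settings.
#' @param seed integer seed.
#' @return the selected parameter value, with attributes `skewness` (its
#'   mean realized skewness) and `grid` (a data.frame of all evaluations).
#' @export
tuneSkewTarget <- function(pop, targetSkew, grid, cohortSize, draws = 1,
                           shape = 20, uniformMix = 0.01, nBins = 200,
                           windowHalfWidths = c(C = 0.1, R = 0.037),
                           concentrations = c(C = 200, R = 2), seed = NULL) {
    if (length(grid) == 0) stop("empty tuning grid")
    one <- function(par, d) {
        co <- if (pop@scheme == "A")
            sampleCohortA(pop, cohortSize, cutoff = par, shape = shape,
                          uniformMix = uniformMix, nBins = nBins,
                          seed = deriveSeed(seed, paste("tune", par, d)))
        else
            sampleCohortB(pop, cohortSize, rightFraction = par,
                          windowHalfWidths = windowHalfWidths,
                          concentrations = concentrations,
                          seed = deriveSeed(seed, paste("tune", par, d)))
        co@skewness
    }
    meanSkew <- vapply(grid, function(par) {
        s <- tryCatch(
            vapply(seq_len(draws), function(d)
                suppressWarnings(one(par, d)), numeric(1)),
            error = function(e) NA_real_)
        mean(s)
    }, numeric(1))
    ok <- is.finite(meanSkew)
    if (!any(ok)) stop("no grid value produced a valid cohort")
    dist <- abs(meanSkew - targetSkew)
    # ties broken toward the smaller parameter value
    cand <- which(ok)[order(dist[ok], grid[ok])][1]
    structure(grid[cand], skewness = meanSkew[cand],
              grid = data.frame(parameter = grid, skewness = meanSkew))
}
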