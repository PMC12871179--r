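# Simulators: paired-variant populations and biased cohort samplers.

test_that("paired layout cancels exactly and hits the target variance", {
    pop <- simulatePopulationA(200, nVariants = 4, h2 = 0.6,
                               freqRange = c(0.05, 0.1), seed = 1)
    b <- abs(effects(pop)[1])
    expect_equal(effects(pop), c(b, -b, b, -b))
    expect_equal(freqs(pop)[1], freqs(pop)[2])
    # expected genetic value sum_j 2 p_j beta_j is exactly zero
    expect_equal(sum(2 * freqs(pop) * effects(pop)), 0)
    # genetic variance is h2 by construction of |beta|
    expect_equal(sum(2 * freqs(pop) * (1 - freqs(pop)) * effects(pop)^2),
                 0.6, tolerance = 1e-12)

    big <- simulatePopulationA(2e4, nVariants = 2000, h2 = 0.6, seed = 2)
    expect_gt(var(traits(big)), 0.95)
    expect_lt(var(traits(big)), 1.05)
    expect_error(simulatePopulationA(100, nVariants = 3),
                 "even")
    expect_error(simulatePopulationA(100, nVariants = 4, h2 = 1.2),
                 "h2")
})

test_that("bin probabilities follow the retained-bin weighting rule", {
    # hand evaluation: V=4, q=0.5, gamma=1, tau=0
    p <- binProbabilities(4, cutoff = 0.5, shape = 1, uniformMix = 0)
    expect_equal(p, c(0, 0, 0.75, 0.25))
    # pure uniform component
    expect_equal(binProbabilities(7, 0, shape = 3, uniformMix = 1),
                 rep(1 / 7, 7))
    # shape 0 makes the weighted component uniform over retained bins too
    p0 <- binProbabilities(10, 0.5, shape = 0, uniformMix = 0.3)
    expect_equal(p0[6:10], rep(1 / 5, 5))
    # mass decreasing from the first retained bin at large shape
    p <- binProbabilities(200, 0.46, shape = 20, uniformMix = 0.01)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
    ret <- which(p > 0)
    # mass decays from the cutoff; far bins flatten onto the uniform
    # component once the power-law weight underflows
    expect_true(all(diff(p[ret]) <= 0))
    expect_true(all(diff(p[ret][1:20]) < 0))
    expect_equal(which.max(p), ret[1])
    # zero outside the retained set
    expect_true(all(p[seq_len(min(ret) - 1)] == 0))
    expect_error(binProbabilities(4, 0.95, 1, 0), "no bins")
})

test_that("quantile-bin sampler returns exact-size cohorts of distinct members", {
    pop <- simulatePopulationA(4000, nVariants = 200, seed = 3,
                               keepGenotypes = FALSE)
    co <- sampleCohortA(pop, 500, cutoff = 0.4, shape = 2,
                        uniformMix = 0.2, nBins = 40, seed = 4)
    expect_s4_class(co, "Cohort")
    expect_length(members(co), 500)
    expect_false(anyDuplicated(members(co)) > 0)
    # realized skewness is recomputable from the stored traits
    expect_equal(realizedSkewness(co), skewness(traits(co)))
    # sampling is restricted to the retained upper bins: first retained bin
    # is v = 17 (r_v = 16.5/40 >= 0.4), holding ranks 1601..1700
    expect_true(all(traits(co) >= sort(traits(pop))[1601]))
    expect_error(sampleCohortA(pop, 500, cutoff = 0.4, nBins = 39),
                 "divide")
})

test_that("uniform sampling (q=0, tau=1) is unbiased for skewness", {
    pop <- simulatePopulationA(2e4, nVariants = 400, seed = 5,
                               keepGenotypes = FALSE)
    sk <- vapply(1:5, function(s)
        realizedSkewness(sampleCohortA(pop, 10000, cutoff = 0,
                                       uniformMix = 1, seed = s)),
        numeric(1))
    expect_lt(abs(median(sk) - skewness(traits(pop))), 0.2)
})

test_that("shape-0 bin counts are multinomial-uniform over retained bins", {
    pop <- simulatePopulationA(5000, nVariants = 40, seed = 6,
                               keepGenotypes = FALSE)
    co <- sampleCohortA(pop, 1500, cutoff = 0.5, shape = 0,
                        uniformMix = 0.5, nBins = 50, seed = 7)
    # recover bin counts from member ranks; compare against the uniform
    # multinomial by chi-square goodness of fit
    ord <- order(traits(pop), seq_len(5000))
    rank <- integer(5000); rank[ord] <- seq_len(5000)
    bin <- (rank[members(co)] - 1L) %/% 100L + 1L
    counts <- tabulate(bin, nbins = 50)
    expect_true(all(counts[1:25] == 0))
    gof <- suppressWarnings(chisq.test(counts[26:50]))
    expect_gt(gof$p.value, 1e-4)
})

test_that("bin-occupancy overflow is capped and redistributed with a warning", {
    pop <- simulatePopulationA(1000, nVariants = 20, seed = 8,
                               keepGenotypes = FALSE)
    # 10 retained bins x 20 occupancy, heavily concentrated: overflow certain
    expect_warning(
        co <- sampleCohortA(pop, 150, cutoff = 0.8, shape = 50,
                            uniformMix = 0, nBins = 50, seed = 9),
        "occupancy")
    expect_length(members(co), 150)
    expect_false(anyDuplicated(members(co)) > 0)
})

test_that("tri-modal population has symmetric modes and exact marginal frequencies", {
    pop <- simulatePopulationB(3e4, nVariants = 40, h2 = 0.6,
                               freqRange = c(0.02, 0.1), seed = 10)
    z <- modes(pop)
    expect_setequal(unique(z), c("L", "C", "R"))
    f <- mean(z == "L")
    expect_lt(abs(f - 0.1), 0.01)
    # mode-conditional allele frequency matches p*(z) = p (1 + delta zeta t(z))
    G <- dosages(pop)
    p <- freqs(pop); zeta <- sign(effects(pop))
    for (zz in c("L", "C", "R")) {
        t <- c(L = -1, C = 0, R = 1)[[zz]]
        af <- colMeans(G[z == zz, , drop = FALSE]) / 2
        pstar <- p * (1 + 0.5 * zeta * t)
        seBin <- sqrt(pstar * (1 - pstar) / (2 * sum(z == zz)))
        expect_true(all(abs(af - pstar) < 4.5 * seBin))
    }
    # marginal frequency is exactly p_j in expectation: empirical check
    afAll <- colMeans(G) / 2
    seAll <- sqrt(p * (1 - p) / (2 * 3e4))
    expect_true(all(abs(afAll - p) < 4.5 * seAll))
    # invalid shift is rejected
    expect_error(simulatePopulationB(100, 10, freqRange = c(0.3, 0.5),
                                     shift = 1.5), "outside")
})

test_that("mode-window sampler hits the two-point skewness and honors windows", {
    pop <- simulatePopulationB(5e4, nVariants = 2000, seed = 11,
                               keepGenotypes = FALSE)
    co <- sampleCohortB(pop, 1000, rightFraction = 0.009, seed = 12)
    expect_length(members(co), 1000)
    # closed-form two-point oracle at rho = 0.009
    rho <- 0.009
    oracle <- (1 - 2 * rho) / sqrt(rho * (1 - rho))
    expect_lt(abs(realizedSkewness(co) - oracle), 2)
    # member counts per mode follow round-half-even of rho * n
    expect_equal(sum(modes(co) == "R"), round(0.009 * 1000))
    expect_equal(sum(modes(co) == "C"), 1000 - round(0.009 * 1000))
    # rho = 0: symmetric narrow window, low skew
    co0 <- sampleCohortB(pop, 1000, rightFraction = 0, seed = 13)
    expect_lt(abs(realizedSkewness(co0)), 0.5)
    # window eligibility: members lie inside u_z * s_z of the mode median
    z <- modes(pop)
    yR <- traits(pop)[z == "R"]
    mR <- median(yR); sR <- sd(yR)
    expect_true(all(abs(traits(co)[modes(co) == "R"] - mR) <= 0.037 * sR))
    # impossible request names the offending mode
    expect_error(sampleCohortB(pop, 2000, rightFraction = 0.9), "mode R")
})

test_that("skew-target tuning is the grid argmin with small-value tie-break", {
    pop <- simulatePopulationA(10000, nVariants = 200, seed = 14,
                               keepGenotypes = FALSE)
    grid <- c(0, 0.2, 0.4, 0.6, 0.8)
    tuned <- tuneSkewTarget(pop, targetSkew = 5, grid = grid,
                            cohortSize = 1000, draws = 2, seed = 15)
    # independent brute force with the same derived seeds
    skews <- vapply(grid, function(q) {
        mean(vapply(1:2, function(d) {
            co <- suppressWarnings(
                sampleCohortA(pop, 1000, cutoff = q,
                              seed = deriveSeed(15, paste("tune", q, d))))
            realizedSkewness(co)
        }, numeric(1)))
    }, numeric(1))
    best <- grid[order(abs(skews - 5), grid)][1]
    expect_equal(as.numeric(tuned), best)
    # target 0 selects q = 0 (uniform-ish sampling is least skewed)
    t0 <- tuneSkewTarget(pop, targetSkew = 0, grid = grid,
                         cohortSize = 1000, draws = 2, seed = 16)
    expect_equal(as.numeric(t0), 0)
})

test_that("realized skewness responds monotonically to the tuned parameter", {
    popA <- simulatePopulationA(5e4, nVariants = 400, seed = 17,
                                keepGenotypes = FALSE)
    qs <- seq(0, 0.45, by = 0.05)
    mA <- vapply(qs, function(q) {
        mean(vapply(1:20, function(r)
            realizedSkewness(sampleCohortA(popA, 1000, cutoff = q,
                seed = deriveSeed(18, paste(q, r)))), numeric(1)))
    }, numeric(1))
    expect_gt(cor(qs, mA, method = "spearman"), 0.95)

    popB <- simulatePopulationB(1e5, nVariants = 400, seed = 19,
                                keepGenotypes = FALSE)
    rhos <- c(0.009, 0.02, 0.04, 0.07, 0.1, 0.14, 0.18, 0.22, 0.26, 0.28)
    mB <- vapply(rhos, function(rho) {
        mean(vapply(1:20, function(r)
            realizedSkewness(sampleCohortB(popB, 500, rightFraction = rho,
                seed = deriveSeed(20, paste(rho, r)))), numeric(1)))
    }, numeric(1))
    # skewness shrinks as the right-mode fraction grows (two-point form)
    expect_lt(cor(rhos, mB, method = "spearman"), -0.95)
})
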