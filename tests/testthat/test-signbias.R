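# Block assignment, representative selection and certainty-weighted
# aggregation of posterior sign scores.

test_that("block assignment respects the half-open BED convention", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t200", "chr1\t200\t300", "chr2\t0\t150"), bed)
    blocks <- readLdBlocks(bed)
    tab <- toyGwasTable(7,
        chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr3"),
        pos = c(101L, 200L, 201L, 350L, 1L, 150L, 10L))
    idx <- assignBlocks(tab, blocks)
    # 1-based 101 and 200 fall in [100,200); 201 in [200,300); 350 nowhere
    expect_equal(as.vector(idx), c(1L, 1L, 2L, NA, 3L, 3L, NA))
    expect_equal(attr(idx, "nUnassigned"), 2L)
    expect_error(assignBlocks(tab[, c("id", "maf")], blocks), "chrom")
})

test_that("representative selection enforces the block-size rule and tie-breaks", {
    # two blocks: one with 10 eligible SNPs, one with 9 (excluded)
    tab <- toyGwasTable(19, p_value = rep(0.5, 19))
    blockIdx <- c(rep(1L, 10), rep(2L, 9))
    tab$p_value[3] <- 0.001
    eta <- rep(0.5, 19)
    sel <- selectRepresentatives(tab, eta, blockIdx, mode = "top")
    expect_equal(as.vector(sel), 3L)
    # p-value tie resolved to the lowest genomic position (brute force)
    tab2 <- toyGwasTable(10, p_value = rep(0.01, 10),
                         pos = sample(seq(1000, 1009)))
    sel2 <- selectRepresentatives(tab2, rep(1, 10), rep(1L, 10),
                                  mode = "top")
    expect_equal(tab2$pos[sel2], min(tab2$pos))
    # all blocks below the minimum size: error
    expect_error(selectRepresentatives(tab, eta, blockIdx,
                                       minBlockSnps = 50),
                 "no contributing blocks")
    # MAF rule applies before block membership counting
    tab3 <- toyGwasTable(12, maf = c(rep(0.005, 9), rep(0.4, 3)))
    expect_error(selectRepresentatives(tab3, rep(1, 12), rep(1L, 12),
                                       mafMax = 0.01, minBlockSnps = 10),
                 "no contributing blocks")
})

test_that("group-of-m selection partitions by index with a kept remainder", {
    tab <- toyGwasTable(13)
    set.seed(3)
    tab$p_value <- runif(13)
    reps <- groupRepresentatives(tab, groupSize = 6)
    expect_length(reps, 3L)                  # groups of 6, 6 and 1
    expect_equal(reps[3], 13L)               # remainder group kept
    expect_equal(reps[1], which.min(tab$p_value[1:6]))
    expect_equal(reps[2], 6L + which.min(tab$p_value[7:12]))
    # group size 1 is the identity selection
    expect_equal(as.vector(groupRepresentatives(tab, groupSize = 1)), 1:13)
    # 4000 variants in groups of 6: 667 groups (666 full + remainder of 4)
    big <- toyGwasTable(4000)
    expect_length(groupRepresentatives(big, groupSize = 6), 667L)
    expect_error(groupRepresentatives(big[0, ]), "empty")
})

test_that("certainty-weighted aggregation is odd, bounded and order-free", {
    expect_equal(aggregateEta(c(0.9, -0.1, 0.5)), 1.3 / 1.5)
    expect_equal(aggregateEta(rep(0.3, 7)), 1)
    expect_equal(aggregateEta(c(0.4, -0.4)), 0)
    set.seed(4)
    eta <- runif(50, -1, 1)
    expect_equal(aggregateEta(eta), aggregateEta(sample(eta)))
    expect_equal(aggregateEta(-eta), -aggregateEta(eta))
    expect_lte(abs(aggregateEta(eta)), 1)
    expect_warning(out <- aggregateEta(c(0, 0)), "zero")
    expect_true(is.na(out))
})

test_that("block bootstrap matches exhaustive enumeration for few blocks", {
    # b = 1: every resample identical
    tab1 <- toyGwasTable(1)
    b1 <- bootstrapSignBias(tab1, eta = 0.7, blockIdx = 1L,
                            minBlockSnps = 1, reps = 50, seed = 1)
    expect_equal(b1@se, 0)
    expect_equal(etaHat(b1), 1)
    # b = 2 with per-block etas {0.8}, {-0.2}: exhaustive resample values
    # {1, 0.6, 0.6, -1}; mean 0.3, population SD ~ 0.768
    tab2 <- toyGwasTable(2)
    b2 <- bootstrapSignBias(tab2, eta = c(0.8, -0.2), blockIdx = c(1L, 2L),
                            minBlockSnps = 1, reps = 10000, seed = 2)
    expect_equal(etaHat(b2), (0.8 - 0.2) / (0.8 + 0.2))
    expect_lt(abs(b2@se - exhaustiveBootstrapSd(c(0.8, -0.2))), 0.05)
    expect_equal(exhaustiveBootstrapSd(c(0.8, -0.2)),
                 sqrt(mean((c(1, 0.6, 0.6, -1) - 0.3)^2)))
    # b = 3 exhaustive oracle
    eta3 <- c(0.9, -0.3, 0.4)
    tab3 <- toyGwasTable(3)
    b3 <- bootstrapSignBias(tab3, eta = eta3, blockIdx = 1:3,
                            minBlockSnps = 1, reps = 20000, seed = 3)
    expect_lt(abs(b3@se - exhaustiveBootstrapSd(eta3)), 0.05)
    expect_error(bootstrapSignBias(tab3, eta3, rep(NA_integer_, 3)),
                 "no contributing blocks")
})

test_that("random-replicate estimates agree with exhaustive enumeration", {
    # single eligible SNP per block: all replicates identical, SE 0
    tab <- toyGwasTable(2)
    r1 <- randomReplicateSignBias(tab, eta = c(0.5, 0.3),
                                  blockIdx = c(1L, 2L), minBlockSnps = 1,
                                  reps = 100, seed = 4)
    expect_equal(r1@se, 0)
    expect_equal(etaHat(r1), aggregateEta(c(0.5, 0.3)))
    # two blocks x two SNPs: enumerate the four equiprobable selections
    tab4 <- toyGwasTable(4)
    eta4 <- c(0.9, 0.1, -0.5, 0.2)
    blocks4 <- c(1L, 1L, 2L, 2L)
    combos <- expand.grid(a = 1:2, b = 3:4)
    exact <- mean(apply(combos, 1, function(i) {
        v <- eta4[i]
        sum(v) / sum(abs(v))
    }))
    r2 <- randomReplicateSignBias(tab4, eta4, blocks4, minBlockSnps = 1,
                                  reps = 1000, seed = 5)
    expect_lt(abs(etaHat(r2) - exact), 0.05)
    # point estimate stabilizes as replicates grow
    rA <- randomReplicateSignBias(tab4, eta4, blocks4, minBlockSnps = 1,
                                  reps = 10000, seed = 6)
    rB <- randomReplicateSignBias(tab4, eta4, blocks4, minBlockSnps = 1,
                                  reps = 100000, seed = 7)
    expect_lt(abs(etaHat(rA) - etaHat(rB)), 0.01)
})

test_that("true sign bias orients effects to the cohort minor allele", {
    # 4 variants with sample frequencies {0.4, 0.6, 0.01, 0.99} and true
    # effect signs {+, +, -, -}: flips at 0.6 and 0.99 cancel exactly
    n <- 100
    colFor <- function(af) c(rep(2, af * n), rep(0, n - af * n))
    G <- cbind(colFor(0.4), colFor(0.6), colFor(0.01), colFor(0.99))
    co <- toyCohort(G, rnorm(n), effects = c(1, 1, -1, -1))
    expect_equal(trueSignBias(co, mafMax = 0.5), 0)
    # restricting to rare variants keeps only the {0.01, 0.99} pair
    expect_equal(trueSignBias(co, mafMax = 0.011), 0)
    expect_warning(out <- trueSignBias(co, mafBin = c(0.1, 0.2)), "MAF")
    expect_true(is.na(out))
    # population-level minor-allele sign bias is exactly zero by pairing
    pop <- simulatePopulationA(500, nVariants = 4000, seed = 21,
                               keepGenotypes = FALSE)
    expect_identical(populationSignBias(pop), 0)
    popB <- simulatePopulationB(500, nVariants = 4000, seed = 22,
                                keepGenotypes = FALSE)
    expect_identical(populationSignBias(popB), 0)
})
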