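#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Assign summary-statistic variants to LD blocks
#'
#' Maps each variant (1-based position) to the approximately independent
#' LD block (0-based half-open BED interval, represented as a `GRanges`
#' from [readLdBlocks()]) that contains it. Variants outside every block
#' are unassigned (`NA`) and are excluded from block-based aggregation.
#'
#' @param table GWAS summary `data.frame` with `chrom` and `pos` columns
#'   (1-based positions).
#' @param blocks `GRanges` of LD blocks.
#' @return integer vector of block indices (row of `blocks`), `NA` when
#'   unassigned, with attribute `nUnassigned`.
#' @export
assignBlocks <- function(table, blocks) {
    if (!all(c("chrom", "pos") %in% names(table)))
        stop("summary table must carry 'chrom' and 'pos' for block assignment")
    if (any(is.na(table$chrom)) || any(is.na(table$pos)))
        stop("missing variant coordinates")
    snps <- GenomicRanges::GRanges(
        seqnames = as.character(table$chrom),
        ranges = IRanges::IRanges(start = table$pos, width = 1L))
    hit <- GenomicRanges::findOverlaps(snps, blocks, select = "first")
    out <- as.integer(hit)
    attr(out, "nUnassigned") <- sum(is.na(out))
    out
}

# Eligible rows after the MAF rule: an upper threshold (maf <= mafMax) or a
# half-open bin (mafBin[1] <= maf < mafBin[2]). The rule is applied before
# block membership is counted.
mafEligible <- function(maf, mafMax = NULL, mafBin = NULL) {
    if (!is.null(mafMax) && !is.null(mafBin))
        stop("give either 'mafMax' or 'mafBin', not both")
    if (!is.null(mafMax)) {
        stopifnotScalar(mafMax, "mafMax", lower = 0, upper = 0.5,
                        openLower = TRUE)
        return(maf <= mafMax)
    }
    if (!is.null(mafBin)) {
        if (length(mafBin) != 2 || mafBin[1] >= mafBin[2])
            stop("'mafBin' must be c(low, high) with low < high")
        return(maf >= mafBin[1] & maf < mafBin[2])
    }
    rep(TRUE, length(maf))
}

# Internal: per-block bookkeeping shared by the selection/resampling
# routines. Returns, per retained block, the eligible row indices and the
# deterministic top-significance representative (min p, ties to the
# smallest position/index).
blockBook <- function(table, eta, blockIdx, mafMax, mafBin, minBlockSnps) {
    stopifnot(nrow(table) == length(eta), nrow(table) == length(blockIdx))
    elig <- mafEligible(table$maf, mafMax, mafBin) & !is.na(blockIdx)
    rows <- which(elig)
    if (length(rows) == 0L) stop("no contributing blocks")
    split <- split(rows, blockIdx[rows])
    split <- split[lengths(split) >= minBlockSnps]
    if (length(split) == 0L) stop("no contributing blocks")
    tieKey <- if ("pos" %in% names(table)) table$pos
              else if ("index" %in% names(table)) table$index
              else seq_len(nrow(table))
    top <- vapply(split, function(r)
        r[order(table$p_value[r], tieKey[r])][1], integer(1))
    list(blocks = split, top = as.integer(top), eta = eta)
}

#' Select one representative SNP per LD block
#'
#' Applies the MAF rule, drops blocks with fewer than `minBlockSnps`
#' eligible SNPs, and picks one representative per remaining block: the
#' smallest-p-value SNP (`mode = "top"`; p-value ties broken by genomic
#' position, then index) or a uniformly random eligible SNP
#' (`mode = "random"`).
#'
#' @param table GWAS summary `data.frame` with `p_value`, `maf` and
#'   (optionally) `pos` columns.
#' @param eta numeric vector of per-variant posterior sign scores aligned
#'   with `table` rows.
#' @param blockIdx block assignment from [assignBlocks()] (or any integer
#'   grouping vector; `NA` = unassigned).
#' @param mafMax,mafBin MAF rule: either an upper threshold
#'   (`maf <= mafMax`) or a half-open bin (`mafBin[1] <= maf < mafBin[2]`);
#'   give at most one.
#' @param mode `"top"` or `"random"`.
#' @param minBlockSnps minimum eligible SNPs for a block to contribute
#'   (default 10).
#' @param seed integer seed (random mode).
#' @return integer vector of selected row indices, one per retained
#'   block.
#' @export
selectRepresentatives <- function(table, eta, blockIdx, mafMax = NULL,
                                  mafBin = NULL,
                                  mode = c("top", "random"),
                                  minBlockSnps = 10, seed = NULL) {
    mode <- match.arg(mode)
    bb <- blockBook(table, eta, blockIdx, mafMax, mafBin, minBlockSnps)
    if (mode == "top") return(bb$top)
    withSeed(seed, vapply(bb$blocks, function(r)
        r[sample.int(length(r), 1L)], integer(1)))
}

#' Representative selection by consecutive index groups
#'
#' For simulated (blockless) data: orders the retained variants by their
#' generation index, partitions them into consecutive groups of
#' `groupSize` (a trailing remainder group of at least one variant is
#' kept), and selects the smallest-p-value variant in each group (ties
#' broken by index). Mirrors the block protocol when no genomic map
#' exists.
#'
#' @param table GWAS summary `data.frame` with `index` and `p_value`
#'   columns (MAF rule applied beforehand or via `mafMax`/`mafBin`).
#' @param groupSize variants per group (default 6).
#' @param mafMax,mafBin optional MAF rule applied before partitioning.
#' @return integer vector of selected row indices, plus attribute
#'   `groupIdx` (the group id of every eligible row, for resampling).
#' @export
groupRepresentatives <- function(table, groupSize = 6, mafMax = NULL,
                                 mafBin = NULL) {
    if (nrow(table) == 0L) stop("empty summary table")
    stopifnotScalar(groupSize, "groupSize", lower = 1, integer = TRUE)
    elig <- which(mafEligible(table$maf, mafMax, mafBin))
    if (length(elig) == 0L) stop("no variants pass the MAF rule")
    elig <- elig[order(table$index[elig])]
    grp <- (seq_along(elig) - 1L) %/% as.integer(groupSize) + 1L
    split <- split(elig, grp)
    reps <- vapply(split, function(r)
        r[order(table$p_value[r], table$index[r])][1], integer(1))
    structure(as.integer(reps), groupIdx = grp, eligible = elig)
}

#' Certainty-weighted aggregate sign bias (point value)
#'
#' Aggregates per-variant posterior sign scores as
#' `etaHat = sum(eta) / sum(abs(eta))`: a weighted average of the signs
#' with weights proportional to the certainty `|eta|`, bounded in
#' `[-1, 1]`. Returns `NA` with a warning when every score is exactly
#' zero.
#'
#' @param eta numeric vector of posterior sign scores of the
#'   representative SNPs.
#' @return numeric scalar in `[-1, 1]` (or `NA`).
#' @examples
#' aggregateEta(c(0.9, -0.1, 0.5))   # 1.3 / 1.5
#' @export
aggregateEta <- function(eta) {
    if (length(eta) == 0L) stop("no sign scores supplied")
    denom <- sum(abs(eta))
    if (denom == 0) {
        warning("all sign scores are zero; aggregate sign bias undefined")
        return(NA_real_)
    }
    sum(eta) / denom
}

#' Block-bootstrap sign-bias estimate (top-significance mode)
#'
#' Point estimate: the certainty-weighted aggregate over the
#' minimum-p representative of each contributing block. Uncertainty: the
#' `b` contributing blocks are resampled with replacement `reps` times,
#' the (deterministic) min-p representative taken per resampled block,
#' the aggregate recomputed, and the SE reported as the SD of the
#' replicates (population convention, denominator `reps`).
#'
#' @inheritParams selectRepresentatives
#' @param reps bootstrap replicates (default 1000).
#' @return a [SignBiasEstimate] with `mode = "top"`.
#' @export
bootstrapSignBias <- function(table, eta, blockIdx, mafMax = NULL,
                              mafBin = NULL, minBlockSnps = 10,
                              reps = 1000, seed = NULL) {
    bb <- blockBook(table, eta, blockIdx, mafMax, mafBin, minBlockSnps)
    topEta <- eta[bb$top]
    b <- length(topEta)
    point <- aggregateEta(topEta)
    boot <- withSeed(seed, {
        vapply(seq_len(reps), function(r) {
            v <- topEta[sample.int(b, b, replace = TRUE)]
            if (sum(abs(v)) == 0) NA_real_ else sum(v) / sum(abs(v))
        }, numeric(1))
    })
    boot <- boot[is.finite(boot)]
    se <- if (length(boot)) sqrt(mean((boot - mean(boot))^2)) else NA_real_
    new("SignBiasEstimate", etaHat = point, se = se, nBlocks = as.integer(b),
        mode = "top", replicates = as.integer(reps))
}

#' Random-replicate sign-bias estimate (random-selection mode)
#'
#' In each of `reps` replicates one eligible SNP is selected uniformly at
#' random within every contributing block and the certainty-weighted
#' aggregate recomputed. The point estimate is the replicate mean and the
#' SE the replicate SD (population convention).
#'
#' @inheritParams bootstrapSignBias
#' @return a [SignBiasEstimate] with `mode = "random"`.
#' @export
randomReplicateSignBias <- function(table, eta, blockIdx, mafMax = NULL,
                                    mafBin = NULL, minBlockSnps = 10,
                                    reps = 1000, seed = NULL) {
    bb <- blockBook(table, eta, blockIdx, mafMax, mafBin, minBlockSnps)
    b <- length(bb$blocks)
    vals <- withSeed(seed, {
        vapply(seq_len(reps), function(r) {
            pick <- vapply(bb$blocks, function(rows)
                rows[sample.int(length(rows), 1L)], integer(1))
            v <- eta[pick]
            if (sum(abs(v)) == 0) NA_real_ else sum(v) / sum(abs(v))
        }, numeric(1))
    })
    ok <- is.finite(vals)
    point <- if (any(ok)) mean(vals[ok]) else NA_real_
    se <- if (any(ok)) sqrt(mean((vals[ok] - point)^2)) else NA_real_
    new("SignBiasEstimate", etaHat = point, se = se, nBlocks = as.integer(b),
        mode = "random", replicates = as.integer(reps))
}

#' True (generative) sign bias of a cohort
#'
#' Orients each variant's true simulated effect to the cohort minor
#' allele (flipping the sign where the effect allele is the cohort major
#' allele) and averages the resulting signs over the variants segregating
#' in the cohort that pass the MAF rule. In the simulated populations the
#' population-level value is exactly zero by the paired construction, so
#' any nonzero cohort value is ascertainment-induced.
#'
#' @param cohort a [Cohort] with stored genotypes.
#' @param mafMax upper sample-MAF threshold (default 0.01); variants
#'   monomorphic in the cohort are excluded.
#' @param mafBin optional half-open MAF bin instead of `mafMax`.
#' @return numeric scalar in `[-1, 1]` (or `NA` with a warning when no
#'   variant is retained).
#' @export
trueSignBias <- function(cohort, mafMax = 0.01, mafBin = NULL) {
    stopifnot(is(cohort, "Cohort"))
    if (!is.null(mafBin)) mafMax <- NULL
    X <- dosages(cohort)
    af <- colMeans(X) / 2
    maf <- pmin(af, 1 - af)
    orient <- ifelse(af > 0.5, -1, 1)
    keep <- maf > 0 & mafEligible(maf, mafMax, mafBin)
    if (!any(keep)) {
        warning("no variants pass the MAF rule; true sign bias undefined")
        return(NA_real_)
    }
    mean(sign(effects(cohort)[keep]) * orient[keep])
}

#' Population-level minor-allele sign bias
#'
#' The mean sign of the true effects oriented to the minor allele at the
#' assigned population frequencies. Equals exactly 0 for both simulation
#' schemes by the matched-pair construction.
#'
#' @param pop a [Population].
#' @return numeric scalar.
#' @export
populationSignBias <- function(pop) {
    stopifnot(is(pop, "Population"))
    orient <- ifelse(pop@freqs > 0.5, -1, 1)
    mean(sign(pop@effects) * orient)
}
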