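#' @include AllClasses.R AllGenerics.R
NULL

#' Polarize an allelic effect to the minor allele
#'
#' If the effect allele's frequency exceeds 0.5 the effect sign is flipped
#' and the frequency complemented, so the returned sign always refers to
#' the minor allele. An exact tie at 0.5 keeps the stated allele
#' orientation (deterministic and order-independent).
#'
#' @param beta numeric vector of effect estimates for the stated allele.
#' @param af numeric vector of stated-allele frequencies in (0, 1).
#' @return `data.frame(beta_minor, maf)`.
#' @examples
#' polarizeToMinor(c(0.2, -0.5), c(0.7, 0.1))
#' @export
polarizeToMinor <- function(beta, af) {
    if (length(beta) != length(af))
        stop("'beta' and 'af' must have the same length")
    if (any(!is.finite(af)) || any(af <= 0) || any(af >= 1))
        stop("allele frequencies must lie strictly within (0, 1)")
    flip <- af > 0.5
    data.frame(beta_minor = ifelse(flip, -beta, beta),
               maf = ifelse(flip, 1 - af, af))
}

#' Per-variant ordinary-least-squares association scan on a cohort
#'
#' Regresses the cohort trait on each variant's dosage separately
#' (intercept + slope, no covariates), with two-sided p-values from the t
#' distribution on `n - 2` degrees of freedom. Effects are then polarized
#' to the cohort minor allele and the sample MAF/MAC recorded. Variants
#' that are monomorphic in the cohort have no defined slope and are
#' dropped; their ids are reported in the `"dropped"` attribute.
#'
#' @param cohort a [Cohort] whose parent population stores genotypes.
#' @return a `data.frame` (one row per retained variant) with columns
#'   `id`, `index` (generation index), `beta_minor`, `se`, `p_value`,
#'   `maf`, `mac`, plus attribute `dropped` (ids of monomorphic variants).
#' @export
olsGwas <- function(cohort) {
    stopifnot(is(cohort, "Cohort"))
    X <- dosages(cohort)
    y <- traits(cohort)
    n <- length(y)
    if (n < 3) stop("need at least 3 individuals for OLS association")
    sx <- colSums(X)
    sxx <- colSums(X * X)
    sy <- sum(y)
    syy <- sum(y * y)
    sxy <- as.vector(crossprod(X, y))
    ssx <- sxx - sx^2 / n
    ssy <- syy - sy^2 / n
    sxyC <- sxy - sx * sy / n
    poly <- ssx > 0
    slope <- sxyC[poly] / ssx[poly]
    sse <- pmax(ssy - slope * sxyC[poly], 0)
    se <- sqrt(sse / (n - 2) / ssx[poly])
    tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p <- pmin(pmax(p, 0), 1)
    p[se == 0 & slope == 0] <- 1    # degenerate fit: constant trait
    af <- sx[poly] / (2 * n)
    pol <- polarizeToMinor(slope, af)
    mac <- ifelse(af > 0.5, 2L * n - sx[poly], sx[poly])
    idx <- which(poly)
    out <- data.frame(
        id = sprintf("snp%05d", idx), index = idx,
        beta_minor = pol$beta_minor, se = se, p_value = p,
        maf = pol$maf, mac = as.integer(mac))
    attr(out, "dropped") <- sprintf("snp%05d", which(!poly))
    out
}

#' QC-filter a GWAS summary table
#'
#' Applies the standard summary-statistic exclusions as strict printed
#' comparisons: variants with `info < minInfo`, Hardy-Weinberg exact-test
#' `hwe_p < hwePExclude`, minor allele count `mac <= macExclude`, and
#' non-biallelic variants are removed. A filter whose column is absent
#' from the table is skipped with a message. Filters are applied in the
#' order biallelic, INFO, HWE, MAC; the per-filter removal counts are
#' returned in the `"qcReport"` attribute. The operation is idempotent.
#'
#' @param table a GWAS summary `data.frame` (see [olsGwas()] /
#'   [readGwasTable()]); optional QC columns `info`, `hwe_p`, `mac`,
#'   `biallelic`.
#' @param minInfo imputation-quality threshold (default 0.8).
#' @param hwePExclude Hardy-Weinberg exact-test p threshold (default
#'   1e-10).
#' @param macExclude minor-allele-count threshold; `mac <= macExclude`
#'   removed (default 20).
#' @param requireBiallelic drop rows whose `biallelic` flag is `FALSE`
#'   (default `TRUE`).
#' @return the surviving rows, with attribute `qcReport` (named removal
#'   counts).
#' @export
qcFilter <- function(table, minInfo = 0.8, hwePExclude = 1e-10,
                     macExclude = 20, requireBiallelic = TRUE) {
    stopifnot(is.data.frame(table))
    if (minInfo < 0 || hwePExclude < 0 || macExclude < 0)
        stop("QC thresholds must be nonnegative")
    report <- c(non_biallelic = 0L, low_info = 0L, hwe_fail = 0L,
                low_mac = 0L)
    apply1 <- function(tab, col, keepFun, label, active = TRUE) {
        if (!active) return(tab)
        if (!col %in% names(tab)) {
            message(sprintf("qcFilter: column '%s' absent; filter skipped",
                            col))
            return(tab)
        }
        keep <- keepFun(tab[[col]])
        keep[is.na(keep)] <- FALSE
        report[label] <<- report[label] + sum(!keep)
        tab[keep, , drop = FALSE]
    }
    out <- table
    out <- apply1(out, "biallelic", function(x) as.logical(x),
                  "non_biallelic", active = requireBiallelic)
    out <- apply1(out, "info", function(x) x >= minInfo, "low_info")
    out <- apply1(out, "hwe_p", function(x) x >= hwePExclude, "hwe_fail")
    out <- apply1(out, "mac", function(x) x > macExclude, "low_mac")
    attr(out, "qcReport") <- report
    out
}
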