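# Small in-code fixtures shared across test files.

# A Population wrapped around hand-specified dosages and traits, so the
# association and sign-bias stages can be tested on exactly known inputs.
# Effects default to alternating +1/-1 (satisfying the paired layout).
toyPopulation <- function(G, y, effects = NULL, freqs = NULL) {
    G <- as.matrix(G)
    M <- ncol(G)
    stopifnot(M %% 2 == 0, nrow(G) == length(y))
    if (is.null(effects)) effects <- rep(c(1, -1), length.out = M)
    if (is.null(freqs)) freqs <- rep(0.1, M)
    geno <- matrix(as.raw(G), nrow = nrow(G), ncol = M)
    new("Population", genotypes = geno, effects = as.numeric(effects),
        freqs = as.numeric(freqs), traits = as.numeric(y),
        modes = character(0), scheme = "A", h2 = 0.5, params = list())
}

toyCohort <- function(G, y, ...) {
    pop <- toyPopulation(G, y, ...)
    sk <- tryCatch(skewness(y), error = function(e) NA_real_)
    new("Cohort", population = pop, members = seq_len(nrow(as.matrix(G))),
        design = list(scheme = "A"), skewness = sk)
}

# GWAS summary data.frame builder with the pipeline's column names.
toyGwasTable <- function(n, p_value = runif(n), maf = rep(0.05, n),
                         beta = rnorm(n), se = rep(1, n),
                         chrom = rep("chr1", n), pos = seq_len(n)) {
    data.frame(id = sprintf("snp%05d", seq_len(n)), index = seq_len(n),
               beta_minor = beta, se = se, p_value = p_value, maf = maf,
               mac = as.integer(round(maf * 100)), chrom = chrom, pos = pos)
}

# Exhaustive block bootstrap: enumerate all b^b equiprobable resamples of
# per-block representative etas and return the population SD of the
# aggregate (independent oracle for bootstrapSignBias).
exhaustiveBootstrapSd <- function(topEta) {
    b <- length(topEta)
    idx <- as.matrix(expand.grid(rep(list(seq_len(b)), b)))
    vals <- apply(idx, 1, function(i) {
        v <- topEta[i]
        sum(v) / sum(abs(v))
    })
    sqrt(mean((vals - mean(vals))^2))
}
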