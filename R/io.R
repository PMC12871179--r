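#' @include AllClasses.R AllGenerics.R
NULL

#' Default logical-to-physical column mapping for summary tables
#'
#' Maps the logical fields used by the sign-bias pipeline to the column
#' headers common in public GWAS summary releases. Override individual
#' entries by passing a modified copy to [readGwasTable()].
#'
#' @return named character vector (logical field -> column name).
#' @export
defaultColumnMap <- function() {
    c(id = "ID", chrom = "CHR", pos = "POS", beta = "BETA", se = "SE",
      p = "P", af = "AF", info = "INFO", mac = "MAC", hwe_p = "HWE_P",
      biallelic = "BIALLELIC")
}

detectSep <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited (tab or comma; gzip accepted) summary table, maps
#' columns through `colmap`, coerces numeric fields, drops malformed rows
#' (non-finite beta/se/af, se <= 0, af outside (0, 1)) with a logged
#' count, and polarizes effects to the minor allele using the allele
#' frequency column.
#'
#' @param path file path (plain or gzipped text with a header row).
#' @param colmap named character vector, see [defaultColumnMap()]. Fields
#'   `beta`, `se`, `af` are required; `id`, `chrom`, `pos`, `p`, `info`,
#'   `mac`, `hwe_p`, `biallelic` are attached when present.
#' @return `data.frame` with columns `id`, `beta_minor`, `se`, `p_value`
#'   (if available), `maf`, and any optional QC columns; attribute
#'   `nSkipped` counts dropped malformed rows.
#' @export
readGwasTable <- function(path, colmap = defaultColumnMap()) {
    sep <- detectSep(path)
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             comment.char = "")
    for (field in c("beta", "se", "af"))
        if (!colmap[[field]] %in% names(raw))
            stop(sprintf("required column '%s' (field '%s') is missing",
                         colmap[[field]], field))
    num <- function(x) suppressWarnings(as.numeric(x))
    beta <- num(raw[[colmap[["beta"]]]])
    se <- num(raw[[colmap[["se"]]]])
    af <- num(raw[[colmap[["af"]]]])
    ok <- is.finite(beta) & is.finite(se) & se > 0 &
        is.finite(af) & af > 0 & af < 1
    if (any(!ok))
        message(sprintf("readGwasTable: skipped %d malformed row(s)",
                        sum(!ok)))
    pol <- polarizeToMinor(beta[ok], af[ok])
    out <- data.frame(
        id = if (colmap[["id"]] %in% names(raw))
            as.character(raw[[colmap[["id"]]]])[ok]
        else sprintf("row%d", which(ok)),
        beta_minor = pol$beta_minor, se = se[ok], maf = pol$maf)
    optional <- c(chrom = "character", pos = "integer", p = "numeric",
                  info = "numeric", mac = "integer", hwe_p = "numeric",
                  biallelic = "logical")
    rename <- c(p = "p_value")
    for (field in names(optional)) {
        colName <- colmap[[field]]
        if (!is.null(colName) && !is.na(colName) && colName %in% names(raw)) {
            v <- raw[[colName]][ok]
            v <- switch(optional[[field]],
                        character = as.character(v),
                        integer = as.integer(num(v)),
                        numeric = num(v),
                        logical = as.logical(v))
            out[[if (field %in% names(rename)) rename[[field]]
                 else field]] <- v
        }
    }
    attr(out, "nSkipped") <- sum(!ok)
    out
}

#' Write a GWAS summary table as TSV
#'
#' @param table `data.frame` as produced by [olsGwas()] or
#'   [readGwasTable()].
#' @param path output path (gzipped when it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
writeGwasTable <- function(table, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    utils::write.table(table, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read approximately independent LD blocks from a BED3 file
#'
#' Parses a three-column BED file (chrom, start, end; 0-based half-open
#' coordinates), validates every interval (`start < end`, reported with
#' its line number) and rejects overlapping intervals within a
#' chromosome. Returns a `GRanges` (1-based closed coordinates, i.e.
#' `[start + 1, end]`) sorted within chromosome, suitable for
#' [assignBlocks()].
#'
#' @param path BED3 file path (gzip accepted; no header).
#' @return `GRanges` of LD blocks with a `blockId` metadata column.
#' @export
readLdBlocks <- function(path) {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (ncol(tab) < 3) stop("BED3 input needs chrom, start, end columns")
    chrom <- as.character(tab[[1]])
    start <- suppressWarnings(as.numeric(tab[[2]]))
    end <- suppressWarnings(as.numeric(tab[[3]]))
    bad <- which(!is.finite(start) | !is.finite(end) | start >= end)
    if (length(bad))
        stop(sprintf("invalid interval (start >= end or non-numeric) at line %d",
                     bad[1]))
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start + 1, end = end))
    gr <- GenomicRanges::sort(gr)
    ov <- GenomicRanges::findOverlaps(gr)
    if (any(S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)))
        stop("LD blocks overlap within a chromosome")
    gr$blockId <- seq_along(gr)
    gr
}

#' Read a YAML run configuration
#'
#' Reads a YAML file mirroring the arguments of the simulation and
#' analysis functions (scheme, population settings, skew targets,
#' replicates, sampler and sign-bias settings, seed). Returned as a
#' plain named list for splicing into [runSchemeExperiment()] via
#' `do.call()`.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (!is.list(cfg)) stop("configuration must be a YAML mapping")
    cfg
}
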