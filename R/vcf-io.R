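#' Read a pooled VCF into a PoolCalls object
#'
#' Parses a multi-sample VCF in which every sample column is a sequenced
#' pool, and extracts the per-pool AD (allele depths) and DP (total depth)
#' FORMAT fields. Sample columns must match the manifest pool ids as a
#' set; columns are reordered to manifest order. Parsing is delegated to
#' \pkg{vcfR}.
#'
#' A missing AD or DP value for some pool at some locus is tolerated at
#' read time (a capped warning names the first offending loci); the cell
#' becomes `NA` and the locus is later removed by the no-missing filter.
#' A sample set that does not match the manifest is a fatal error.
#'
#' @param path VCF file (plain text or gzipped).
#' @param pools pool manifest from [readPoolManifest()].
#' @return A [PoolCalls-class] object with loci in file order.
#' @export
readPooledVcf <- function(path, pools) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    emptyCalls <- function() PoolCalls(character(), integer(), character(),
                                       character(),
                                       matrix(integer(), 0, nrow(pools)),
                                       matrix(integer(), 0, nrow(pools)),
                                       matrix(integer(), 0, nrow(pools)),
                                       pools)
    if (nrow(vcf@fix) == 0L) return(emptyCalls())
    samples <- colnames(vcf@gt)[-1L]
    if (!setequal(samples, rownames(pools)) ||
        length(samples) != nrow(pools))
        stop("VCF sample columns do not match the manifest pool ids; ",
             "missing: ", paste(setdiff(rownames(pools), samples),
                                collapse = ", "),
             "; unexpected: ", paste(setdiff(samples, rownames(pools)),
                                     collapse = ", "))
    fmt <- strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)
    if (!all(vapply(fmt, function(f) all(c("AD", "DP") %in% f), logical(1))))
        stop("every record must carry AD and DP FORMAT fields")
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix)))  # single-record VCFs drop to a vector
        fix <- matrix(fix, nrow = 1L,
                      dimnames = list(NULL, names(fix)))
    ad <- vcfR::extract.gt(vcf, element = "AD")
    dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                            as.numeric = TRUE))
    ord <- match(rownames(pools), samples)
    ad <- ad[, ord, drop = FALSE]
    dp <- dp[, ord, drop = FALSE]
    refCounts <- altCounts <- matrix(NA_integer_, nrow(ad), ncol(ad))
    parts <- strsplit(ifelse(is.na(ad) | ad == ".", ",", ad), ",",
                      fixed = TRUE)
    first <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    second <- suppressWarnings(as.integer(vapply(parts, function(p)
        if (length(p) >= 2L) p[2L] else NA_character_, "")))
    refCounts[] <- first
    altCounts[] <- second
    bad <- is.na(refCounts) | is.na(altCounts) | is.na(dp)
    if (any(bad)) {
        loci <- unique(paste0(fix[, "CHROM"], ":",
                              fix[, "POS"])[rowSums(bad) > 0])
        warning(sum(rowSums(bad) > 0), " locus/loci with missing AD/DP, ",
                "e.g. ", paste(head(loci, 5L), collapse = ", "),
                "; cells set to NA")
    }
    PoolCalls(fix[, "CHROM"], as.integer(fix[, "POS"]), fix[, "REF"],
              fix[, "ALT"], refCounts, altCounts,
              matrix(as.integer(dp), nrow(dp)), pools)
}

#' Write a PoolCalls object as a plain-text VCF 4.2
#'
#' Emits GT:AD:DP per pool. Genotypes are hard-called from the observed
#' alternative read fraction with thresholds 0.1 / 0.9 (below: `0/0`,
#' above: `1/1`, between: `0/1`); pools with missing depths get `./.` and
#' `.` fields. Output is deterministic (byte-identical for equal input).
#'
#' @param calls a [PoolCalls-class] object.
#' @param path output VCF path.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
writePooledVcf <- function(calls, path, contigs = NULL) {
    pools <- poolInfo(calls)
    con <- file(path, "wb")  # binary: fixed \n line endings
    on.exit(close(con))
    wl <- function(x) writeLines(x, con, sep = "\n")
    wl("##fileformat=VCFv4.2")
    wl("##source=poolColorScan")
    if (!is.null(contigs))
        wl(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)))
    wl('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
    wl(paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,',
              'Description="Allelic depths (ref,alt)">'))
    wl('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
    wl(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
               "INFO", "FORMAT", rownames(pools)), collapse = "\t"))
    if (nrow(calls) == 0L) return(invisible(path))
    rr <- rowRanges(calls)
    adr <- assay(calls, "ad_ref"); ada <- assay(calls, "ad_alt")
    dp <- assay(calls, "dp")
    tot <- adr + ada
    q <- ifelse(tot > 0, ada / tot, NA_real_)
    gt <- matrix("./.", nrow(calls), ncol(calls))
    gt[!is.na(q) & q < 0.1] <- "0/0"
    gt[!is.na(q) & q >= 0.1 & q <= 0.9] <- "0/1"
    gt[!is.na(q) & q > 0.9] <- "1/1"
    field <- matrix(paste0(gt, ":",
                           ifelse(is.na(adr), ".", adr), ",",
                           ifelse(is.na(ada), ".", ada), ":",
                           ifelse(is.na(dp), ".", dp)),
                    nrow(calls), ncol(calls))
    lines <- paste(as.character(seqnames(rr)), start(rr), ".",
                   mcols(rr)$ref, mcols(rr)$alt, ".", "PASS", ".",
                   "GT:AD:DP",
                   apply(field, 1L, paste, collapse = "\t"), sep = "\t")
    wl(lines)
    invisible(path)
}

#' Export an AF matrix as TSV
#'
#' Loci as rows (chrom, pos, ref, alt), pools as columns.
#'
#' @param pf a [PoolFreq-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportAFMatrix <- function(pf, path) {
    rr <- rowRanges(pf)
    tab <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                      ref = mcols(rr)$ref, alt = mcols(rr)$alt,
                      afMatrix(pf), check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
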