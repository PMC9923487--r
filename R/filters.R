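#' Per-pool allele frequencies from allele depths
#'
#' AF is the proper allele-count fraction `ad_alt / (ad_ref + ad_alt)`.
#' The DP field can exceed the informative depth (uninformative reads),
#' so DP is used only by the depth filter, never as the AF denominator.
#' Pools with `ad_ref + ad_alt == 0` (or missing depths) yield `NA`,
#' the missing-data signal consumed by [applySiteFilters()].
#'
#' @param x a [PoolCalls-class] object.
#' @return Numeric matrix, loci x pools, values in [0, 1] or `NA`.
#' @aliases computeAF,PoolCalls-method
#' @export
setMethod("computeAF", "PoolCalls", function(x, ...) {
    tot <- assay(x, "ad_ref") + assay(x, "ad_alt")
    af <- assay(x, "ad_alt") / tot
    af[!is.na(tot) & tot == 0L] <- NA_real_
    af
})

#' Post-calling site filters
#'
#' Applies the four retention rules in a fixed order and attributes each
#' removed locus to its first failing rule:
#' \enumerate{
#'   \item \strong{biallelic}: exactly one alternative allele, and REF/ALT
#'     either both single-base or of equal length (a block substitution
#'     destined for [decomposeBlockSub()]). Indels fail here.
#'   \item \strong{depth}: reported DP at least `min_dp` (default 20) in
#'     every pool (`dp_scope = "per_pool"`) or summed over pools
#'     (`dp_scope = "total"`).
#'   \item \strong{missing}: no pool may lack an AF estimate.
#'   \item \strong{maf}: folded minor allele frequency
#'     `min(p, 1 - p)` of the unweighted across-pool mean AF `p` at least
#'     `min_maf` (default 1\%).
#' }
#' The kept set is order-independent; only the attribution of rejections
#' depends on the order above.
#'
#' @param x a [PoolCalls-class] object.
#' @param min_dp minimum depth, default 20 ("below 20" is removed).
#' @param min_maf minimum folded MAF as a fraction, default 0.01.
#' @param dp_scope `"per_pool"` (default, strictest reading) or `"total"`.
#' @return A list with `kept` (a [PoolCalls-class]) and `rejected`, a named
#'   integer vector with counts for `biallelic`, `depth`, `missing`, `maf`.
#' @aliases applySiteFilters,PoolCalls-method
#' @export
setMethod("applySiteFilters", "PoolCalls",
function(x, min_dp = 20L, min_maf = 0.01,
         dp_scope = c("per_pool", "total"), ...) {
    dp_scope <- match.arg(dp_scope)
    rej <- c(biallelic = 0L, depth = 0L, missing = 0L, maf = 0L)
    if (nrow(x) == 0L) return(list(kept = x, rejected = rej))
    rr <- mcols(rowRanges(x))
    okBi <- rr$n_alt == 1L &
        (nchar(rr$ref) == nchar(rr$alt)) &
        !grepl(",", rr$alt, fixed = TRUE)
    dp <- assay(x, "dp")
    dpOK <- !is.na(dp) & dp >= min_dp
    okDepth <- if (dp_scope == "per_pool") rowSums(dpOK) == ncol(x)
               else rowSums(ifelse(is.na(dp), 0L, dp)) >= min_dp
    af <- computeAF(x)
    okMiss <- rowSums(is.na(af)) == 0L
    pbar <- rowMeans(af)
    okMAF <- !is.na(pbar) & pmin(pbar, 1 - pbar) >= min_maf
    firstFail <- rep(NA_character_, nrow(x))
    firstFail[!okMAF] <- "maf"
    firstFail[!okMiss] <- "missing"
    firstFail[!okDepth] <- "depth"
    firstFail[!okBi] <- "biallelic"
    keep <- okBi & okDepth & okMiss & okMAF
    tab <- table(factor(firstFail[!keep],
                        levels = c("biallelic", "depth", "missing", "maf")))
    rej[names(tab)] <- as.integer(tab)
    list(kept = x[keep, ], rejected = rej)
})

#' Decompose biallelic block substitutions into SNPs
#'
#' Equal-length multi-base REF/ALT records (MNPs, reported by haplotype
#' callers as "complex events") are split into one single-base SNP per
#' mismatching position, at `pos + offset`, each child inheriting the
#' parent's per-pool depths verbatim (splitting without re-counting).
#' Single-base records pass through unchanged; records with unequal REF
#' and ALT lengths (indels) are dropped and counted in
#' `metadata(result)$n_dropped_indel`. The output is sorted by
#' (chrom, pos).
#'
#' @param x a [PoolCalls-class] object (biallelic records).
#' @return A [PoolCalls-class] of single-base SNPs.
#' @aliases decomposeBlockSub,PoolCalls-method
#' @export
setMethod("decomposeBlockSub", "PoolCalls", function(x, ...) {
    pools <- poolInfo(x)
    rr <- rowRanges(x)
    ref <- mcols(rr)$ref; alt <- mcols(rr)$alt
    if (any(!nzchar(ref)) || any(!nzchar(alt)))
        stop("malformed record: empty REF or ALT")
    if (any(mcols(rr)$n_alt != 1L))
        stop("decomposeBlockSub requires biallelic records")
    equalLen <- nchar(ref) == nchar(alt)
    nIndel <- sum(!equalLen)
    idx <- which(equalLen)
    outChrom <- character(); outPos <- integer()
    outRef <- character(); outAlt <- character(); parent <- integer()
    for (i in idx) {
        r <- strsplit(ref[i], "", fixed = TRUE)[[1L]]
        a <- strsplit(alt[i], "", fixed = TRUE)[[1L]]
        mism <- which(r != a)
        if (!length(mism)) next
        outChrom <- c(outChrom,
                      rep(as.character(seqnames(rr))[i], length(mism)))
        outPos <- c(outPos, start(rr)[i] + mism - 1L)
        outRef <- c(outRef, r[mism]); outAlt <- c(outAlt, a[mism])
        parent <- c(parent, rep(i, length(mism)))
    }
    sub <- function(m) m[parent, , drop = FALSE]
    out <- PoolCalls(outChrom, outPos, outRef, outAlt,
                     sub(assay(x, "ad_ref")), sub(assay(x, "ad_alt")),
                     sub(assay(x, "dp")), pools)
    ord <- order(outChrom, outPos)
    out <- out[ord, ]
    metadata(out)$n_dropped_indel <- nIndel
    out
})

#' Assemble the filtered AF matrix
#'
#' Converts filtered, decomposed calls into a complete [PoolFreq-class]
#' matrix, ordered by (chrom, pos). Records must be pre-filtered: any
#' missing AF cell or duplicate locus key is an error.
#'
#' @param x a [PoolCalls-class] object.
#' @return A [PoolFreq-class] object.
#' @aliases buildAFMatrix,PoolCalls-method
#' @export
setMethod("buildAFMatrix", "PoolCalls", function(x, ...) {
    af <- computeAF(x)
    if (anyNA(af))
        stop("missing AF cells: records must be filtered before ",
             "buildAFMatrix (no-missing rule)")
    rr <- rowRanges(x)
    ord <- order(as.character(seqnames(rr)), start(rr))
    key <- lociKeys(x)[ord]
    if (anyDuplicated(key))
        stop("duplicate locus key: ", key[anyDuplicated(key)])
    PoolFreq(af[ord, , drop = FALSE], rr[ord], poolInfo(x))
})
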