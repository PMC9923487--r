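#' Container for pooled variant calls
#'
#' `PoolCalls` holds one row per VCF locus and one column per sequenced
#' pool, with per-pool allele depths in assays `ad_ref`, `ad_alt` and
#' `dp` (the VCF AD/DP FORMAT fields). Row metadata carries `ref`, `alt`
#' (comma-joined when multiallelic) and `n_alt`. Column metadata is the
#' pool manifest: `site`, `color`, `n_individuals`, `ploidy`.
#'
#' Depth cells may be `NA` (missing genotyping); such loci are removed by
#' [applySiteFilters()]. `dp` may exceed `ad_ref + ad_alt` because a caller
#' can report uninformative reads in DP.
#'
#' @seealso [readPooledVcf()], [applySiteFilters()], [decomposeBlockSub()],
#'   [buildAFMatrix()]
#' @export
setClass("PoolCalls", contains = "RangedSummarizedExperiment")

setValidity("PoolCalls", function(object) {
    msg <- character()
    need <- c("ad_ref", "ad_alt", "dp")
    if (!all(need %in% assayNames(object)))
        msg <- c(msg, paste("assays must include",
                            paste(need, collapse = ", ")))
    needCols <- c("site", "color", "n_individuals", "ploidy")
    if (!all(needCols %in% colnames(colData(object))))
        msg <- c(msg, paste("colData must include",
                            paste(needCols, collapse = ", ")))
    if (nrow(object) > 0L) {
        rr <- mcols(rowRanges(object))
        if (!all(c("ref", "alt", "n_alt") %in% colnames(rr)))
            msg <- c(msg, "rowRanges mcols must include ref, alt, n_alt")
        else if (any(!nzchar(rr$ref)) || any(!nzchar(rr$alt)))
            msg <- c(msg, "ref and alt must be non-empty")
    }
    if (ncol(object) > 0L) {
        ni <- colData(object)$n_individuals
        if (any(is.na(ni)) || any(ni < 1L))
            msg <- c(msg, "n_individuals must be >= 1")
    }
    if (length(msg)) msg else TRUE
})

#' Pools-by-loci allele-frequency container
#'
#' `PoolFreq` is the filtered end-product of the import stage: a complete
#' matrix of alternative-allele frequencies (assay `af`, values in [0, 1],
#' no missing cells) with loci as rows (a `GRanges` with `ref`/`alt`) and
#' pools as columns (the manifest in `colData`). It is the input to
#' [genomeScan()] and to the descriptive summaries.
#'
#' @seealso [buildAFMatrix()], [genomeScan()], [pcaAF()], [windowedPi()]
#' @export
setClass("PoolFreq", contains = "RangedSummarizedExperiment")

setValidity("PoolFreq", function(object) {
    msg <- character()
    if (!"af" %in% assayNames(object))
        msg <- c(msg, "assay 'af' is required")
    else {
        af <- assay(object, "af")
        if (anyNA(af))
            msg <- c(msg, "af must have no missing values")
        else if (length(af) && (min(af) < 0 || max(af) > 1))
            msg <- c(msg, "af values must lie in [0, 1]")
    }
    if (nrow(object) > 1L) {
        key <- lociKeys(object)
        if (anyDuplicated(key))
            msg <- c(msg, "locus keys (chrom, pos, ref, alt) must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' Minimal strand-aware gene model
#'
#' A transcript-level gene model used by the effect annotator: transcript
#' bounds, sorted exons, and CDS intervals whose total length is a
#' multiple of three. Coordinates are 1-based inclusive.
#'
#' @slot gene_id single gene identifier.
#' @slot chrom chromosome/scaffold name.
#' @slot strand `"+"` or `"-"`.
#' @slot tx_start,tx_end transcript bounds, 1-based inclusive.
#' @slot exons sorted, non-overlapping [IRanges::IRanges] within the
#'   transcript bounds.
#' @slot cds sorted [IRanges::IRanges], each contained in an exon; total
#'   width divisible by 3. May be empty for non-coding models.
#' @seealso [annotateSnp()], [aaChange()], [readGeneModelsGff3()]
#' @export
setClass("GeneModel",
    representation(gene_id = "character", chrom = "character",
                   strand = "character", tx_start = "integer",
                   tx_end = "integer", exons = "IRanges", cds = "IRanges"))

setValidity("GeneModel", function(object) {
    msg <- character()
    if (length(object@gene_id) != 1L || !nzchar(object@gene_id))
        msg <- c(msg, "gene_id must be a single non-empty string")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (object@tx_start > object@tx_end)
        msg <- c(msg, "tx_start must be <= tx_end")
    ex <- object@exons
    if (length(ex)) {
        if (min(start(ex)) < object@tx_start || max(end(ex)) > object@tx_end)
            msg <- c(msg, "exons must lie within the transcript bounds")
        if (is.unsorted(start(ex)) ||
            any(start(ex)[-1] <= end(ex)[-length(ex)]))
            msg <- c(msg, "exons must be sorted and non-overlapping")
    }
    cds <- object@cds
    if (length(cds)) {
        inExon <- vapply(seq_along(cds), function(i) {
            any(start(cds)[i] >= start(ex) & end(cds)[i] <= end(ex))
        }, logical(1))
        if (!all(inExon))
            msg <- c(msg, "each CDS interval must be contained in an exon")
        if (sum(width(cds)) %% 3L != 0L)
            msg <- c(msg, "total CDS length must be divisible by 3")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a gene model
#'
#' @param gene_id,chrom,strand,tx_start,tx_end,exons,cds see
#'   [GeneModel-class].
#' @return A validated [GeneModel-class] object.
#' @examples
#' GeneModel("g1", "chr1", "+", 1000L, 2000L,
#'           exons = IRanges::IRanges(1000, 2000),
#'           cds = IRanges::IRanges(1100, 1399))
#' @export
GeneModel <- function(gene_id, chrom, strand, tx_start, tx_end,
                      exons, cds = IRanges()) {
    new("GeneModel", gene_id = as.character(gene_id),
        chrom = as.character(chrom), strand = strand,
        tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
        exons = exons, cds = cds)
}

setMethod("show", "GeneModel", function(object) {
    cat(sprintf("GeneModel %s %s:%d-%d(%s), %d exon(s), CDS %d bp\n",
                object@gene_id, object@chrom, object@tx_start,
                object@tx_end, object@strand, length(object@exons),
                sum(width(object@cds))))
})

setMethod("show", "PoolCalls", function(object) {
    cat(sprintf("PoolCalls: %d locus/loci x %d pool(s)\n",
                nrow(object), ncol(object)))
    if (ncol(object))
        cat("  pools:", paste(head(colnames(object), 6L), collapse = ", "),
            if (ncol(object) > 6L) "..." else "", "\n")
})

setMethod("show", "PoolFreq", function(object) {
    cat(sprintf("PoolFreq: %d locus/loci x %d pool(s), AF in [%s, %s]\n",
                nrow(object), ncol(object),
                if (nrow(object)) format(min(assay(object, "af")), digits = 3)
                else "-",
                if (nrow(object)) format(max(assay(object, "af")), digits = 3)
                else "-"))
})

#' Build a PoolCalls object from per-pool depth matrices
#'
#' @param chrom,pos,ref,alt per-locus vectors; `alt` is comma-joined for
#'   multiallelic records.
#' @param ad_ref,ad_alt,dp integer matrices, loci x pools; `NA` marks
#'   missing genotyping.
#' @param pools pool manifest as returned by [readPoolManifest()].
#' @return A [PoolCalls-class] object.
#' @export
PoolCalls <- function(chrom, pos, ref, alt, ad_ref, ad_alt, dp, pools) {
    ad_ref <- as.matrix(ad_ref); ad_alt <- as.matrix(ad_alt)
    dp <- as.matrix(dp)
    chrom <- rep_len(as.character(chrom), length(pos))
    stopifnot(nrow(ad_ref) == length(pos), ncol(ad_ref) == nrow(pools))
    nAlt <- lengths(strsplit(as.character(alt), ",", fixed = TRUE))
    rr <- GRanges(chrom, IRanges(as.integer(pos),
                                 width = nchar(as.character(ref))))
    mcols(rr) <- DataFrame(ref = toupper(as.character(ref)),
                           alt = toupper(as.character(alt)),
                           n_alt = as.integer(nAlt))
    dimnames(ad_ref) <- dimnames(ad_alt) <- dimnames(dp) <-
        list(NULL, rownames(pools))
    new("PoolCalls", SummarizedExperiment(
        assays = list(ad_ref = ad_ref, ad_alt = ad_alt, dp = dp),
        rowRanges = rr, colData = pools))
}

#' Build a PoolFreq object from an AF matrix
#'
#' @param af numeric matrix, loci x pools, values in [0, 1], no `NA`.
#' @param loci `GRanges` with mcols `ref` and `alt`.
#' @param pools pool manifest as returned by [readPoolManifest()].
#' @return A [PoolFreq-class] object.
#' @export
PoolFreq <- function(af, loci, pools) {
    af <- as.matrix(af)
    dimnames(af) <- list(NULL, rownames(pools))
    new("PoolFreq", SummarizedExperiment(assays = list(af = af),
                                         rowRanges = loci, colData = pools))
}

lociKeys <- function(x) {
    rr <- rowRanges(x)
    paste(as.character(seqnames(rr)), start(rr), mcols(rr)$ref,
          mcols(rr)$alt, sep = ":")
}

#' Extract the allele-frequency matrix
#'
#' Returns loci-by-pools allele frequencies. For `PoolCalls` this is
#' computed from depths (see [computeAF()]); for `PoolFreq` it is the
#' stored assay.
#'
#' @param x a [PoolCalls-class] or [PoolFreq-class] object.
#' @return Numeric matrix, loci x pools.
#' @aliases afMatrix,PoolFreq-method afMatrix,PoolCalls-method
#' @export
setMethod("afMatrix", "PoolFreq", function(x, ...) assay(x, "af"))

setMethod("afMatrix", "PoolCalls", function(x, ...) computeAF(x))

#' Pool manifest accessor
#'
#' @param x a [PoolCalls-class] or [PoolFreq-class] object.
#' @return The pool manifest (`DataFrame` with site, color, n_individuals,
#'   ploidy; rownames are pool ids).
#' @aliases poolInfo,RangedSummarizedExperiment-method
#' @export
setMethod("poolInfo", "RangedSummarizedExperiment",
          function(x, ...) colData(x))
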