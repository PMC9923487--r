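.effectImpact <- c(stop_gained = "HIGH", stop_lost = "HIGH",
                   start_lost = "HIGH", missense_variant = "MODERATE",
                   synonymous_variant = "LOW",
                   upstream_gene_variant = "MODIFIER",
                   downstream_gene_variant = "MODIFIER",
                   intron_variant = "MODIFIER",
                   intergenic_variant = "MODIFIER")

.impactOrder <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Impact category of an effect term
#'
#' Fixed SnpEff-style mapping: stop/start gain or loss are HIGH,
#' amino-acid changes MODERATE, synonymous LOW, and
#' upstream/downstream/intron/intergenic MODIFIER.
#'
#' @param effect character vector of effect terms.
#' @return Character vector of impact categories.
#' @export
impactOf <- function(effect) {
    out <- .effectImpact[effect]
    if (anyNA(out))
        stop("unknown effect term(s): ",
             paste(unique(effect[is.na(out)]), collapse = ", "))
    unname(out)
}

#' Most severe impact of a set of annotations
#'
#' Reducer for summaries when a SNP hits several genes:
#' HIGH > MODERATE > LOW > MODIFIER.
#'
#' @param impacts character vector of impact categories.
#' @return The single most severe category.
#' @export
mostSevereImpact <- function(impacts) {
    .impactOrder[min(match(impacts, .impactOrder))]
}

#' Translate a CDS nucleotide sequence
#'
#' Standard genetic code; stops are rendered `*` and translation runs the
#' full length (internal stops are retained so stop-gain detection can
#' see them).
#'
#' @param seq DNA string over {A, C, G, T}, length a multiple of 3.
#' @return Amino-acid string.
#' @examples
#' translateCds("ATGACCGAA")  # "MTE"
#' @export
translateCds <- function(seq) {
    seq <- toupper(as.character(seq))
    if (nchar(seq) %% 3L != 0L)
        stop("CDS length must be a multiple of 3")
    if (grepl("[^ACGT]", seq))
        stop("CDS contains non-ACGT characters")
    codons <- substring(seq, seq(1L, nchar(seq), 3L),
                        seq(3L, nchar(seq), 3L))
    paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Amino-acid change induced by a coding SNP
#'
#' Locates the SNP within the spliced, strand-oriented CDS of a gene
#' model, substitutes the alternative base, and translates the affected
#' codon. For minus-strand genes the CDS is read from the reverse
#' complement. The reference base in `refseq` must agree with the
#' record's REF allele (data-inconsistency error otherwise).
#'
#' @param model a [GeneModel-class] with a CDS containing `pos`.
#' @param pos 1-based genomic position of the SNP.
#' @param ref,alt single reference/alternative bases (genomic strand).
#' @param refseq reference sequence for the gene's chromosome
#'   (`DNAString`, `DNAStringSet` keyed by chromosome, or character).
#' @return A list: `ref_aa`, `aa_pos` (1-based in the protein), `alt_aa`,
#'   and the derived `effect` (synonymous/missense/stop_gained/stop_lost/
#'   start_lost).
#' @export
aaChange <- function(model, pos, ref, alt, refseq) {
    chromSeq <- .chromSeq(refseq, model@chrom)
    cds <- model@cds
    genomicPos <- unlist(lapply(seq_along(cds), function(i)
        seq(start(cds)[i], end(cds)[i])))
    if (!pos %in% genomicPos)
        stop("position ", pos, " is not inside the CDS of ",
             model@gene_id)
    bases <- strsplit(substringSeq(chromSeq, genomicPos), "")[[1]]
    refAtPos <- bases[match(pos, genomicPos)]
    if (refAtPos != toupper(ref))
        stop("reference mismatch at ", model@chrom, ":", pos,
             ": sequence has ", refAtPos, ", record says ", ref)
    if (model@strand == "+") {
        cdsIdx <- match(pos, genomicPos)
        cdsRef <- paste(bases, collapse = "")
        altBase <- toupper(alt)
    } else {
        L <- length(genomicPos)
        cdsIdx <- L - match(pos, genomicPos) + 1L
        cdsRef <- paste(rev(unname(.complement[bases])), collapse = "")
        altBase <- unname(.complement[toupper(alt)])
    }
    codonIdx <- (cdsIdx - 1L) %/% 3L + 1L
    within <- (cdsIdx - 1L) %% 3L + 1L
    refCodon <- substr(cdsRef, 3L * codonIdx - 2L, 3L * codonIdx)
    altCodon <- refCodon
    substr(altCodon, within, within) <- altBase
    refAA <- unname(Biostrings::GENETIC_CODE[refCodon])
    altAA <- unname(Biostrings::GENETIC_CODE[altCodon])
    effect <- if (refAA == altAA) "synonymous_variant"
        else if (altAA == "*") "stop_gained"
        else if (refAA == "*") "stop_lost"
        else if (codonIdx == 1L && refAA == "M") "start_lost"
        else "missense_variant"
    list(ref_aa = refAA, aa_pos = codonIdx, alt_aa = altAA,
         effect = effect)
}

.chromSeq <- function(refseq, chrom) {
    if (is.character(refseq) && is.null(names(refseq)) &&
        length(refseq) == 1L)
        return(refseq)
    if (is(refseq, "DNAString")) return(as.character(refseq))
    if (is(refseq, "DNAStringSet") || (is.character(refseq) &&
                                       !is.null(names(refseq)))) {
        if (!chrom %in% names(refseq))
            stop("chromosome ", chrom, " not found in reference sequence")
        return(as.character(refseq[[chrom]]))
    }
    stop("unsupported reference sequence type")
}

substringSeq <- function(seqChar, positions) {
    paste(substring(seqChar, positions, positions), collapse = "")
}

#' Annotate one SNP against a set of gene models
#'
#' Emits one annotation per gene overlapping or flanking the position.
#' Positions inside the transcript are resolved CDS-wise (codon
#' translation via [aaChange()]) or fall to `intron_variant`; positions
#' within `flank` bp 5' of the gene (strand-aware) are
#' `upstream_gene_variant`, within `flank` bp 3' are
#' `downstream_gene_variant`; with no gene within reach a single
#' `intergenic_variant` row is returned (an absent chromosome is
#' intergenic, not an error). Non-CDS exonic positions are classed
#' `intron_variant`: the supported effect vocabulary has no UTR term.
#'
#' @param chrom,pos,ref,alt the SNP (single-base substitution).
#' @param models list of [GeneModel-class] objects.
#' @param refseq reference sequence (required when a CDS is hit).
#' @param flank flanking distance in bp, default 2000 on each side of the
#'   gene (the conventional upstream/downstream window).
#' @return A `data.frame` with one row per annotation: `effect`,
#'   `impact`, `gene_id`, `ref_aa`, `aa_pos`, `alt_aa`, `ann` (compact
#'   `effect|impact|gene|aachange` string).
#' @export
annotateSnp <- function(chrom, pos, ref, alt, models, refseq = NULL,
                        flank = 2000L) {
    if (nchar(ref) != 1L || nchar(alt) != 1L)
        stop("annotateSnp expects a single-base substitution")
    rows <- list()
    for (m in models) {
        if (m@chrom != chrom) next
        if (pos >= m@tx_start && pos <= m@tx_end) {
            inCds <- length(m@cds) &&
                any(pos >= start(m@cds) & pos <= end(m@cds))
            if (inCds) {
                if (is.null(refseq))
                    stop("reference sequence required to annotate a ",
                         "coding SNP in ", m@gene_id)
                ch <- aaChange(m, pos, ref, alt, refseq)
                rows[[length(rows) + 1L]] <- data.frame(
                    effect = ch$effect, impact = impactOf(ch$effect),
                    gene_id = m@gene_id, ref_aa = ch$ref_aa,
                    aa_pos = ch$aa_pos, alt_aa = ch$alt_aa)
            } else {
                rows[[length(rows) + 1L]] <- data.frame(
                    effect = "intron_variant", impact = "MODIFIER",
                    gene_id = m@gene_id, ref_aa = NA_character_,
                    aa_pos = NA_integer_, alt_aa = NA_character_)
            }
        } else if (pos >= m@tx_start - flank && pos < m@tx_start) {
            eff <- if (m@strand == "+") "upstream_gene_variant"
                   else "downstream_gene_variant"
            rows[[length(rows) + 1L]] <- data.frame(
                effect = eff, impact = "MODIFIER", gene_id = m@gene_id,
                ref_aa = NA_character_, aa_pos = NA_integer_,
                alt_aa = NA_character_)
        } else if (pos > m@tx_end && pos <= m@tx_end + flank) {
            eff <- if (m@strand == "+") "downstream_gene_variant"
                   else "upstream_gene_variant"
            rows[[length(rows) + 1L]] <- data.frame(
                effect = eff, impact = "MODIFIER", gene_id = m@gene_id,
                ref_aa = NA_character_, aa_pos = NA_integer_,
                alt_aa = NA_character_)
        }
    }
    if (!length(rows))
        rows[[1L]] <- data.frame(effect = "intergenic_variant",
                                 impact = "MODIFIER",
                                 gene_id = NA_character_,
                                 ref_aa = NA_character_,
                                 aa_pos = NA_integer_,
                                 alt_aa = NA_character_)
    out <- do.call(rbind, rows)
    aach <- ifelse(is.na(out$ref_aa), "",
                   paste0(out$ref_aa, out$aa_pos, out$alt_aa))
    out$ann <- paste(out$effect, out$impact,
                     ifelse(is.na(out$gene_id), "", out$gene_id),
                     aach, sep = "|")
    out
}

#' Annotate a table of SNPs
#'
#' Vectorised wrapper around [annotateSnp()]; adds the locus columns to
#' each annotation row.
#'
#' @param loci `data.frame` with columns chrom, pos, ref, alt (e.g. the
#'   [genomeScan()] table).
#' @param models,refseq,flank as in [annotateSnp()].
#' @return A `data.frame`, one row per (locus, annotation).
#' @export
annotateLoci <- function(loci, models, refseq = NULL, flank = 2000L) {
    if (nrow(loci) == 0L)
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          effect = character(), impact = character(),
                          gene_id = character(), ref_aa = character(),
                          aa_pos = integer(), alt_aa = character(),
                          ann = character()))
    out <- lapply(seq_len(nrow(loci)), function(i) {
        ann <- annotateSnp(loci$chrom[i], loci$pos[i], loci$ref[i],
                           loci$alt[i], models, refseq, flank)
        cbind(loci[rep(i, nrow(ann)), c("chrom", "pos", "ref", "alt"),
                   drop = FALSE], ann, row.names = NULL)
    })
    do.call(rbind, out)
}

#' Read gene models from GFF3
#'
#' Expects `gene` features with `ID`, and `exon`/`CDS` features whose
#' `Parent` points to the gene directly or through an `mRNA` feature.
#' Import is delegated to \pkg{rtracklayer}; coordinates stay 1-based
#' inclusive.
#'
#' @param path GFF3 file.
#' @return List of [GeneModel-class] objects.
#' @export
readGeneModelsGff3 <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    genes <- gr[type == "gene"]
    if (!length(genes)) stop("model-load error: no gene features in ", path)
    parentOf <- function(x) as.character(unlist(x$Parent))
    mrna <- gr[type == "mRNA"]
    mrnaToGene <- setNames(parentOf(mrna), as.character(mrna$ID))
    resolveGene <- function(parents) {
        ifelse(parents %in% names(mrnaToGene), mrnaToGene[parents],
               parents)
    }
    lapply(seq_along(genes), function(i) {
        g <- genes[i]
        gid <- as.character(g$ID)
        sub <- gr[type %in% c("exon", "CDS")]
        par <- resolveGene(parentOf(sub))
        sub <- sub[par == gid]
        ex <- sub[as.character(sub$type) == "exon"]
        cd <- sub[as.character(sub$type) == "CDS"]
        exR <- IRanges(start(ex), end(ex))
        exR <- exR[order(start(exR))]
        cdR <- IRanges(start(cd), end(cd))
        cdR <- cdR[order(start(cdR))]
        if (!length(exR)) exR <- IRanges(start(g), end(g))
        GeneModel(gid, as.character(seqnames(g)),
                  as.character(strand(g)), start(g), end(g), exR, cdR)
    })
}

#' Read gene models from BED12
#'
#' Blocks become exons and the thick range intersected with the blocks
#' becomes the CDS; BED's 0-based half-open coordinates are converted to
#' 1-based inclusive.
#'
#' @param path BED12 file.
#' @return List of [GeneModel-class] objects.
#' @export
readGeneModelsBed12 <- function(path) {
    gr <- rtracklayer::import(path, format = "bed")
    lapply(seq_along(gr), function(i) {
        g <- gr[i]
        blocks <- if (!is.null(g$blocks)) g$blocks[[1L]]
                  else IRanges(1L, width(g))
        exR <- IRanges(start(g) + start(blocks) - 1L,
                       start(g) + end(blocks) - 1L)
        thick <- g$thick[1L]
        cdR <- IRanges()
        if (!is.na(start(thick)) && width(thick) > 0L) {
            inter <- IRanges::pintersect(
                rep(thick, length(exR)), exR, resolve.empty = "start.x")
            cdR <- inter[width(inter) > 0L]
        }
        GeneModel(as.character(g$name), as.character(seqnames(g)),
                  as.character(strand(g)), start(g), end(g),
                  exR[order(start(exR))], cdR[order(start(cdR))])
    })
}

#' Write gene models as GFF3
#'
#' Companion writer for toy genomes produced by [simulateToyGenome()];
#' emits gene, exon and CDS features with `Parent` set to the gene id.
#'
#' @param models list of [GeneModel-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(models, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines("##gff-version 3", con, sep = "\n")
    for (m in models) {
        lines <- sprintf("%s\tpoolColorScan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                         m@chrom, m@tx_start, m@tx_end, m@strand,
                         m@gene_id)
        for (i in seq_along(m@exons))
            lines <- c(lines, sprintf(
                "%s\tpoolColorScan\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                m@chrom, start(m@exons)[i], end(m@exons)[i], m@strand,
                m@gene_id))
        for (i in seq_along(m@cds))
            lines <- c(lines, sprintf(
                "%s\tpoolColorScan\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                m@chrom, start(m@cds)[i], end(m@cds)[i], m@strand,
                m@gene_id))
        writeLines(lines, con, sep = "\n")
    }
    invisible(path)
}
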