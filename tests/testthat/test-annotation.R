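# Plus-strand toy gene with a two-exon CDS at hand-chosen coordinates:
# genome 1..240, gene 101..190, exon1 101..130, intron 131..160,
# exon2 161..190, CDS = exons (60 bp = 20 codons).
toyGene <- function() {
    cdsSeq <- paste0("ATG", "ACC", "GAA", "TAC", "GGC", "TTA", "CAT",
                     "CAA", "GTC", "GCA", "ATC", "TGG", "CGT", "AAA",
                     "CCG", "TCT", "GAC", "GTT", "AGA", "TAA")
    before <- paste(rep("ACGT", 25), collapse = "")   # 1..100
    intron <- paste(rep("GT", 15), collapse = "")     # 131..160
    after <- paste(rep("TTAC", 50), collapse = "")    # pad past 190
    genome <- paste0(before, substr(cdsSeq, 1, 30), intron,
                     substr(cdsSeq, 31, 60), after)
    model <- GeneModel("toygene", "toy", "+", 101L, 190L,
                       exons = IRanges(c(101L, 161L), c(130L, 190L)),
                       cds = IRanges(c(101L, 161L), c(130L, 190L)))
    list(model = model, seq = setNames(genome, "toy"), cds = cdsSeq)
}

test_that("codon translation follows the standard genetic code", {
    expect_identical(translateCds("ATG"), "M")
    expect_identical(translateCds("TAA"), "*")
    expect_identical(translateCds("ATGACCGAA"), "MTE")
    # full-length translation keeps internal stops visible
    expect_identical(translateCds("ATGTAAGAA"), "M*E")
    expect_error(translateCds("ATGA"), "multiple of 3")
    expect_error(translateCds("ATN"), "non-ACGT")
})

test_that("amino-acid changes derive the documented effects", {
    tg <- toyGene()
    # codon 2 ACC -> ATC: Thr -> Ile missense (position 105 is the C)
    ch <- aaChange(tg$model, 105L, "C", "T", tg$seq)
    expect_identical(ch[c("ref_aa", "aa_pos", "alt_aa", "effect")],
                     list(ref_aa = "T", aa_pos = 2L, alt_aa = "I",
                          effect = "missense_variant"))
    # codon 4 TAC -> TAA: stop gained (third base, position 112)
    ch <- aaChange(tg$model, 112L, "C", "A", tg$seq)
    expect_identical(ch$effect, "stop_gained")
    expect_identical(ch$alt_aa, "*")
    # codon 3 GAA -> GAG: synonymous third-position change
    ch <- aaChange(tg$model, 109L, "A", "G", tg$seq)
    expect_identical(ch$effect, "synonymous_variant")
    expect_identical(ch$ref_aa, ch$alt_aa)
    # final codon TAA -> CAA: stop lost
    ch <- aaChange(tg$model, 188L, "T", "C", tg$seq)
    expect_identical(ch$effect, "stop_lost")
    # first codon ATG -> GTG: start lost; spliced position 2 crosses the
    # intron correctly for codons in exon 2
    ch <- aaChange(tg$model, 101L, "A", "G", tg$seq)
    expect_identical(ch$effect, "start_lost")
    ch <- aaChange(tg$model, 161L, "A", "T", tg$seq)  # codon 11 ATC->TTC
    expect_identical(ch$aa_pos, 11L)
    # reference mismatch is a data-inconsistency error
    expect_error(aaChange(tg$model, 105L, "G", "T", tg$seq), "mismatch")
})

test_that("effects partition a single-gene genome at the breakpoints", {
    tg <- toyGene()
    models <- list(tg$model)
    flank <- 60L
    effectAt <- function(pos) {
        ann <- annotateSnp("toy", pos, substr(tg$seq, pos, pos),
                           if (substr(tg$seq, pos, pos) == "A") "G"
                           else "A",
                           models, tg$seq, flank = flank)
        expect_identical(nrow(ann), 1L)
        # coding effects collapse to one region label for the sweep
        if (ann$effect %in% c("synonymous_variant", "missense_variant",
                              "stop_gained", "stop_lost", "start_lost"))
            "coding" else ann$effect
    }
    sweep <- vapply(1:240, effectAt, character(1))
    expected <- c(rep("intergenic_variant", 40),           # 1..40
                  rep("upstream_gene_variant", 60),        # 41..100
                  rep("coding", 30),                       # exon 1
                  rep("intron_variant", 30),               # intron
                  rep("coding", 30),                       # exon 2
                  rep("downstream_gene_variant", 60),      # 191..250
                  rep("intergenic_variant", 240 - 250 + 10))
    expect_identical(sweep, expected[1:240])
    # effect changes exactly at the declared breakpoints
    breaks <- which(sweep[-1] != sweep[-240]) + 1L
    expect_identical(breaks, c(41L, 101L, 131L, 161L, 191L, 251L)[1:5])
})

test_that("impact mapping is fixed and surjective", {
    expect_identical(impactOf(c("stop_gained", "stop_lost", "start_lost")),
                     rep("HIGH", 3))
    expect_identical(impactOf("missense_variant"), "MODERATE")
    expect_identical(impactOf("synonymous_variant"), "LOW")
    expect_identical(impactOf(c("upstream_gene_variant",
                                "downstream_gene_variant",
                                "intron_variant", "intergenic_variant")),
                     rep("MODIFIER", 4))
    expect_error(impactOf("frameshift_variant"), "unknown")
    expect_identical(mostSevereImpact(c("MODIFIER", "LOW", "HIGH")),
                     "HIGH")
    expect_identical(mostSevereImpact(c("MODIFIER", "LOW")), "LOW")
})

test_that("minus-strand annotation equals the mirrored plus-strand gene", {
    for (seed in c(3, 4)) {
        toy <- simulateToyGenome(seed, n_genes = 2L)
        minus <- Filter(function(m) m@strand == "-", toy$models)[[1]]
        # reverse-complement the whole chromosome and mirror coordinates
        L <- nchar(toy$seq)
        rc <- as.character(reverseComplement(DNAString(unname(toy$seq))))
        mirror <- function(r) IRanges(L - end(r) + 1L, L - start(r) + 1L)
        plus <- GeneModel(minus@gene_id, "toy1", "+",
                          L - minus@tx_end + 1L, L - minus@tx_start + 1L,
                          sortIR(mirror(minus@exons)),
                          sortIR(mirror(minus@cds)))
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        positions <- seq(minus@tx_start - 2100L, minus@tx_end + 2100L,
                         by = 37L)
        positions <- positions[positions >= 1 & positions <= L]
        for (pos in positions) {
            refb <- substr(toy$seq, pos, pos)
            altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
            annM <- annotateSnp("toy1", pos, refb, altb, list(minus),
                                toy$seq)
            annP <- annotateSnp("toy1", L - pos + 1L,
                                unname(comp[refb]), unname(comp[altb]),
                                list(plus), setNames(rc, "toy1"))
            expect_identical(annM$effect, annP$effect)
            expect_identical(annM$impact, annP$impact)
            expect_identical(annM$aa_pos, annP$aa_pos)
            expect_identical(annM$ref_aa, annP$ref_aa)
            expect_identical(annM$alt_aa, annP$alt_aa)
        }
    }
})

test_that("SNPs outside any flank are intergenic, and multiple genes in
           reach each emit an annotation", {
    toy <- simulateToyGenome(12, n_genes = 2L, intergenic = 1500L)
    g1 <- toy$models[[1]]; g2 <- toy$models[[2]]
    ann <- annotateSnp("toy1", g1@tx_end + 100L,
                       substr(toy$seq, g1@tx_end + 100L,
                              g1@tx_end + 100L), "A" , toy$models,
                       toy$seq)
    expect_true(all(ann$gene_id %in% c("gene1", "gene2")))
    # gap of 1500 bp < 2 x 2000 flank: both genes annotate mid-gap SNPs
    mid <- g1@tx_end + 750L
    annMid <- annotateSnp("toy1", mid, substr(toy$seq, mid, mid), "A",
                          toy$models, toy$seq)
    expect_identical(nrow(annMid), 2L)
    # absent chromosome: intergenic, not an error
    annOff <- annotateSnp("chrZ", 5L, "A", "G", toy$models)
    expect_identical(annOff$effect, "intergenic_variant")
})

test_that("GFF3 and BED12 gene-model readers round-trip toy models", {
    toy <- simulateToyGenome(21, n_genes = 2L)
    gff <- withr::local_tempfile(fileext = ".gff3")
    writeGff3(toy$models, gff)
    back <- readGeneModelsGff3(gff)
    expect_identical(length(back), 2L)
    for (i in 1:2) {
        expect_identical(back[[i]]@gene_id, toy$models[[i]]@gene_id)
        expect_identical(back[[i]]@strand, toy$models[[i]]@strand)
        expect_identical(start(back[[i]]@exons),
                         start(toy$models[[i]]@exons))
        expect_identical(start(back[[i]]@cds),
                         start(toy$models[[i]]@cds))
    }
    # equivalent BED12 line for a one-gene model
    m <- toy$models[[1]]
    bed <- withr::local_tempfile(fileext = ".bed")
    sizes <- paste(width(m@exons), collapse = ",")
    starts <- paste(start(m@exons) - m@tx_start, collapse = ",")
    writeLines(paste("toy1", m@tx_start - 1L, m@tx_end, m@gene_id, 0,
                     m@strand, m@tx_start - 1L, m@tx_end, "0",
                     length(m@exons), sizes, starts, sep = "\t"), bed)
    fromBed <- readGeneModelsBed12(bed)[[1]]
    expect_identical(start(fromBed@exons), start(m@exons))
    expect_identical(end(fromBed@cds), end(m@cds))
})
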