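#' Default 12-pool study layout
#'
#' Four sites (three wild atolls/islands and one hatchery) crossed with
#' three inner-shell colors, 172 diploid individuals in total: 20 per
#' hatchery color pool and 12-13 per wild pool. This mirrors the pooled
#' whole-genome design the analysis is built for.
#'
#' @return Pool manifest `DataFrame` (12 rows).
#' @export
defaultPoolManifest <- function() {
    sites <- c("Takapoto", "Katiu", "Gambier", "Hatchery")
    colors <- c("red", "yellow", "green")
    n <- c(13, 12, 13,   # Takapoto
           12, 13, 12,   # Katiu
           13, 12, 12,   # Gambier
           20, 20, 20)   # Hatchery
    site <- rep(sites, each = 3L)
    color <- rep(colors, times = 4L)
    makePoolManifest(paste(site, color, sep = "_"), site, color, n, 2L)
}

#' Simulation configuration
#'
#' Defines the study conditions the simulator reproduces: a single
#' pseudo-chromosome carrying `n_loci` biallelic SNPs of four classes -
#' neutral, color-associated (one color shifted identically at every
#' site), site-associated (one site shifted for all colors), and jointly
#' associated - with pool-sampling and read-depth noise layered on top.
#'
#' @param seed integer root seed (mandatory; all draws derive from it).
#' @param n_loci number of loci.
#' @param fractions named fractions for `neutral`, `color`, `site`,
#'   `both`; must sum to 1.
#' @param color_effect,site_effect AF shift magnitudes in (0, 1).
#' @param baseline_lo,baseline_hi bounds of the uniform baseline AF
#'   distribution.
#' @param mean_depth mean sequencing depth per pool (Poisson).
#' @param pools pool manifest; default [defaultPoolManifest()].
#' @param chrom pseudo-chromosome name.
#' @param chrom_length chromosome length in bp for position placement.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(seed, n_loci = 5000L,
                      fractions = c(neutral = 0.9, color = 0.04,
                                    site = 0.04, both = 0.02),
                      color_effect = 0.4, site_effect = 0.4,
                      baseline_lo = 0.05, baseline_hi = 0.95,
                      mean_depth = 80, pools = defaultPoolManifest(),
                      chrom = "chr1", chrom_length = 1000000L) {
    if (missing(seed) || is.null(seed) || is.na(seed))
        stop("seed is mandatory for simulation")
    fractions <- fractions[c("neutral", "color", "site", "both")]
    if (anyNA(fractions) || any(fractions < 0) ||
        abs(sum(fractions) - 1) > 1e-9)
        stop("fractions must be nonnegative and sum to 1")
    if (color_effect <= 0 || color_effect >= 1 ||
        site_effect <= 0 || site_effect >= 1)
        stop("effects must lie in (0, 1)")
    if (n_loci > chrom_length)
        stop("n_loci cannot exceed chrom_length")
    if (mean_depth <= 0) stop("mean_depth must be positive")
    validatePoolManifest(pools)
    structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                   fractions = fractions, color_effect = color_effect,
                   site_effect = site_effect, baseline_lo = baseline_lo,
                   baseline_hi = baseline_hi, mean_depth = mean_depth,
                   pools = pools, chrom = chrom,
                   chrom_length = as.integer(chrom_length)),
              class = "SimConfig")
}

.deriveSeed <- function(root, i) {
    as.integer((as.numeric(root) * 69069 + as.numeric(i) * 1234567) %%
               2147483647)
}

#' Simulate the ground truth of a pool-seq dataset
#'
#' Draws baseline AFs, assigns each locus a class according to the
#' configured fractions, and applies the planted shifts: a color locus
#' adds `color_effect` to the AF of one color's pools at \emph{all}
#' sites (the "universal control of color" structure), a site locus
#' shifts all pools of one site, and a `both` locus does both
#' independently. Shifted AFs are clamped to [0.01, 0.99] so planted
#' loci survive the MAF filter by construction. Positions are drawn
#' uniformly without replacement and sorted. Fully reproducible from the
#' config seed.
#'
#' @param config a `SimConfig`.
#' @return A list of class `SimTruth`: `truth` (`data.frame` with chrom,
#'   pos, ref, alt, class, affected_color, affected_site, baseline),
#'   `af` (true per-pool AF matrix, loci x pools), `pools`, `config`.
#' @export
simulateTruth <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(.deriveSeed(config$seed, 0L))
    n <- config$n_loci
    pools <- config$pools
    pos <- sort(sample.int(config$chrom_length, n))
    cls <- sample(names(config$fractions), n, replace = TRUE,
                  prob = config$fractions)
    p0 <- runif(n, config$baseline_lo, config$baseline_hi)
    colors <- unique(pools$color); sites <- unique(pools$site)
    affColor <- ifelse(cls %in% c("color", "both"),
                       sample(colors, n, replace = TRUE), NA)
    affSite <- ifelse(cls %in% c("site", "both"),
                      sample(sites, n, replace = TRUE), NA)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    af <- matrix(p0, n, nrow(pools))
    for (j in seq_len(nrow(pools))) {
        shift <- ifelse(!is.na(affColor) & affColor == pools$color[j],
                        config$color_effect, 0) +
                 ifelse(!is.na(affSite) & affSite == pools$site[j],
                        config$site_effect, 0)
        af[, j] <- pmin(pmax(p0 + shift, 0.01), 0.99)
    }
    colnames(af) <- rownames(pools)
    truth <- data.frame(chrom = config$chrom, pos = pos, ref = ref,
                        alt = unname(alt), class = cls,
                        affected_color = affColor,
                        affected_site = affSite, baseline = p0)
    structure(list(truth = truth, af = af, pools = pools,
                   config = config),
              class = "SimTruth")
}

#' Two-stage pool-seq read sampling
#'
#' Models the two noise stages that distinguish pool-seq from individual
#' sequencing: first the finite pool of chromosomes
#' (`c ~ Binomial(ploidy * n, p)`, realised pool frequency
#' `q = c / (ploidy * n)`), then the reads
#' (`dp ~ Poisson(mean_depth)` floored at 1,
#' `ad_alt ~ Binomial(dp, q)`, `ad_ref = dp - ad_alt`). The resulting AF
#' variance exceeds the single-stage binomial read variance by the
#' pool-sampling term.
#'
#' @param true_af true population AF(s) in [0, 1].
#' @param n_individuals diploid individuals in the pool (recycled
#'   against `true_af`, so one call can draw a whole locus across
#'   pools of different sizes).
#' @param mean_depth mean read depth.
#' @param ploidy default 2.
#' @return A list of vectors `ad_ref`, `ad_alt`, `dp` (one entry per
#'   element of `true_af`).
#' @export
simulatePoolReads <- function(true_af, n_individuals, mean_depth,
                              ploidy = 2L) {
    stopifnot(all(true_af >= 0), all(true_af <= 1), mean_depth > 0)
    nChr <- ploidy * n_individuals
    q <- rbinom(length(true_af), nChr, true_af) / nChr
    dp <- pmax(rpois(length(true_af), mean_depth), 1L)
    adAlt <- rbinom(length(true_af), dp, q)
    list(ad_ref = dp - adAlt, ad_alt = adAlt, dp = dp, q = q)
}

#' Simulate observed depths for a whole truth table
#'
#' Applies [simulatePoolReads()] to every locus, with a per-locus random
#' stream derived from the root seed by an integer hash so that the
#' draws of a locus do not depend on how many other loci exist before it
#' in the table.
#'
#' @param sim a `SimTruth` from [simulateTruth()].
#' @return A [PoolCalls-class] object with the simulated AD/DP values.
#' @export
simulateReads <- function(sim) {
    stopifnot(inherits(sim, "SimTruth"))
    pools <- sim$pools
    n <- nrow(sim$truth)
    adr <- ada <- dp <- matrix(0L, n, nrow(pools))
    qmat <- matrix(0, n, nrow(pools))
    for (i in seq_len(n)) {
        set.seed(.deriveSeed(sim$config$seed, i))
        r <- simulatePoolReads(sim$af[i, ], pools$n_individuals,
                               sim$config$mean_depth, pools$ploidy)
        adr[i, ] <- r$ad_ref; ada[i, ] <- r$ad_alt
        dp[i, ] <- r$dp; qmat[i, ] <- r$q
    }
    out <- PoolCalls(sim$truth$chrom, sim$truth$pos, sim$truth$ref,
                     sim$truth$alt, adr, ada, dp, pools)
    # realized finite-pool frequencies: the read stage samples these,
    # not the population AF
    metadata(out)$realized_af <- qmat
    out
}

#' Write a simulated dataset to disk
#'
#' Emits three plain-text files: a VCF 4.2 with one sample column per
#' pool (GT hard-called at alt-fraction 0.1/0.9, AD as "ref,alt", DP), a
#' truth sidecar TSV keyed by (chrom, pos) with the class labels and
#' true per-pool AFs, and the pool manifest TSV. Deterministic: the same
#' config and seed give byte-identical files.
#'
#' @param sim a `SimTruth`.
#' @param out_prefix path prefix; writes `<prefix>.vcf`,
#'   `<prefix>_truth.tsv`, `<prefix>_manifest.tsv`.
#' @param calls optional pre-simulated [PoolCalls-class] (from
#'   [simulateReads()]); simulated here when absent.
#' @return Named character vector of the three paths, invisibly.
#' @export
emitDataset <- function(sim, out_prefix, calls = NULL) {
    stopifnot(inherits(sim, "SimTruth"))
    if (is.null(calls)) calls <- simulateReads(sim)
    vcf <- paste0(out_prefix, ".vcf")
    writePooledVcf(calls, vcf,
                   contigs = setNames(sim$config$chrom_length,
                                      sim$config$chrom))
    truthPath <- paste0(out_prefix, "_truth.tsv")
    truthTab <- cbind(sim$truth,
                      setNames(as.data.frame(sim$af),
                               paste0("af_", colnames(sim$af))))
    write.table(truthTab, truthPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manPath <- paste0(out_prefix, "_manifest.tsv")
    writePoolManifest(sim$pools, manPath)
    invisible(c(vcf = vcf, truth = truthPath, manifest = manPath))
}

.codingCodons <- setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA"))

#' Generate a toy annotated genome
#'
#' Builds a small single-chromosome genome with `n_genes` non-overlapping
#' genes at known coordinates for exercising the effect annotator: each
#' gene has 1-3 exons, a CDS starting with ATG, built from non-stop
#' codons and ending with a stop codon; strands alternate. Intergenic
#' spacers are random sequence.
#'
#' @param seed integer seed.
#' @param n_genes number of genes.
#' @param chrom chromosome name.
#' @param intergenic bp of random sequence between/around genes.
#' @return A list: `models` (list of [GeneModel-class]), `seq` (named
#'   character vector of length 1), `chrom_length`.
#' @export
simulateToyGenome <- function(seed, n_genes = 2L, chrom = "toy1",
                              intergenic = 3000L) {
    set.seed(.deriveSeed(seed, 99L))
    bases <- c("A", "C", "G", "T")
    randSeq <- function(n) paste(sample(bases, n, replace = TRUE),
                                 collapse = "")
    seqParts <- character(); models <- list(); cursor <- 0L
    for (g in seq_len(n_genes)) {
        spacer <- randSeq(intergenic)
        seqParts <- c(seqParts, spacer); cursor <- cursor + intergenic
        nExon <- sample(1:3, 1L)
        exonCodons <- sample(10:30, nExon, replace = TRUE)
        intronLens <- if (nExon > 1L) sample(50:200, nExon - 1L,
                                             replace = TRUE) else integer()
        strand <- if (g %% 2L == 1L) "+" else "-"
        codons <- c("ATG", sample(.codingCodons, sum(exonCodons) - 2L,
                                  replace = TRUE), "TAA")
        cdsSeq <- paste(codons, collapse = "")
        if (strand == "-")
            cdsSeq <- as.character(reverseComplement(DNAString(cdsSeq)))
        exLens <- exonCodons * 3L
        if (strand == "-") exLens <- rev(exLens)
        exStarts <- integer(nExon); exEnds <- integer(nExon)
        genePart <- character(); offset <- cursor; cdsOffset <- 0L
        for (e in seq_len(nExon)) {
            exStarts[e] <- offset + 1L
            exEnds[e] <- offset + exLens[e]
            genePart <- c(genePart,
                          substr(cdsSeq, cdsOffset + 1L,
                                 cdsOffset + exLens[e]))
            cdsOffset <- cdsOffset + exLens[e]
            offset <- offset + exLens[e]
            if (e < nExon) {
                genePart <- c(genePart, randSeq(intronLens[e]))
                offset <- offset + intronLens[e]
            }
        }
        seqParts <- c(seqParts, genePart)
        ex <- IRanges(exStarts, exEnds)
        models[[g]] <- GeneModel(paste0("gene", g), chrom, strand,
                                 exStarts[1L], exEnds[nExon], ex, ex)
        cursor <- offset
    }
    seqParts <- c(seqParts, randSeq(intergenic))
    genome <- paste(seqParts, collapse = "")
    list(models = models, seq = setNames(genome, chrom),
         chrom_length = nchar(genome))
}
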