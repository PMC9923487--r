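.knownConfigKeys <- c("vcf", "manifest", "gff", "fasta", "out_dir",
                      "seed", "simulate", "filters", "association",
                      "summaries", "annotate")
.knownSimKeys <- c("n_loci", "fractions", "color_effect", "site_effect",
                   "baseline_lo", "baseline_hi", "mean_depth",
                   "chrom", "chrom_length")

#' Read and validate a run configuration
#'
#' YAML file with top-level keys `out_dir`, `seed`, input paths (`vcf`,
#' `manifest`, `gff`, `fasta`) and optional blocks `simulate`
#' (generator settings), `filters` (`min_dp`, `min_maf`), `association`
#' (`alpha`, `correction`), `summaries` (`window_bp`, `bins`,
#' `n_components`), `annotate` (`all`, `flank`). Unknown keys are an
#' error listing them.
#'
#' @param path YAML file.
#' @return A list of class `RunConfig`.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(cfg), .knownConfigKeys)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    if (!is.null(cfg$simulate)) {
        unknownSim <- setdiff(names(cfg$simulate), .knownSimKeys)
        if (length(unknownSim))
            stop("unknown simulate key(s): ",
                 paste(unknownSim, collapse = ", "))
    }
    if (is.null(cfg$out_dir)) cfg$out_dir <- "."
    alpha <- cfg$association$alpha
    if (!is.null(alpha) && (alpha <= 0 || alpha >= 1))
        stop("alpha must lie in (0, 1)")
    structure(cfg, class = "RunConfig")
}

.cfgPath <- function(cfg, name) file.path(cfg$out_dir, name)

.writeRunManifest <- function(cfg, stage, outputs) {
    info <- list(stage = stage,
                 package_version =
                     as.character(utils::packageVersion("poolColorScan")),
                 r_version = as.character(getRversion()),
                 config = unclass(cfg),
                 outputs = as.list(outputs),
                 output_md5 = as.list(tools::md5sum(unlist(outputs))))
    jsonlite::write_json(info, .cfgPath(cfg,
                                        paste0("run_", stage, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the simulation stage
#'
#' Generates a dataset from the `simulate` block of the config (the seed
#' is mandatory) and writes VCF, truth TSV, manifest TSV plus a
#' run-manifest JSON with versions and output checksums.
#'
#' @param cfg a `RunConfig` (or path to one).
#' @return Named vector of output paths, invisibly.
#' @export
runSimulate <- function(cfg) {
    if (is.character(cfg)) cfg <- readRunConfig(cfg)
    if (is.null(cfg$seed)) stop("seed is mandatory for simulate")
    sim <- cfg$simulate
    args <- c(list(seed = cfg$seed),
              sim[intersect(names(sim), .knownSimKeys)])
    if (!is.null(args$fractions))
        args$fractions <- unlist(args$fractions)
    config <- do.call(simConfig, args)
    truth <- simulateTruth(config)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- emitDataset(truth, .cfgPath(cfg, "simulated"))
    .writeRunManifest(cfg, "simulate", out)
    message("simulate: wrote ", length(out), " files to ", cfg$out_dir)
    invisible(out)
}

#' Run the association stage
#'
#' Executes the fixed stage order filter -> decompose -> AF matrix ->
#' genome scan -> classification, logging per-filter rejection counts,
#' and writes the per-locus classification TSV plus summary-count
#' TSV/JSON. Zero loci surviving the filters is a warning with empty
#' outputs, not an error.
#'
#' @param cfg a `RunConfig` (or path); needs `vcf` and `manifest` (which
#'   default to the outputs of [runSimulate()] in `out_dir`).
#' @return The `GenomeScanResult`, invisibly.
#' @export
runAssociate <- function(cfg) {
    if (is.character(cfg)) cfg <- readRunConfig(cfg)
    vcfPath <- if (!is.null(cfg$vcf)) cfg$vcf
               else .cfgPath(cfg, "simulated.vcf")
    manPath <- if (!is.null(cfg$manifest)) cfg$manifest
               else .cfgPath(cfg, "simulated_manifest.tsv")
    pools <- readPoolManifest(manPath)
    calls <- readPooledVcf(vcfPath, pools)
    message("associate: read ", nrow(calls), " records for ",
            ncol(calls), " pools")
    minDp <- if (is.null(cfg$filters$min_dp)) 20L else cfg$filters$min_dp
    minMaf <- if (is.null(cfg$filters$min_maf)) 0.01
              else cfg$filters$min_maf
    flt <- applySiteFilters(calls, min_dp = minDp, min_maf = minMaf)
    message("associate: rejection counts - ",
            paste(names(flt$rejected), flt$rejected, sep = "=",
                  collapse = ", "))
    snps <- decomposeBlockSub(flt$kept)
    if (nrow(snps) == 0L) {
        warning("no loci survived the filters; writing empty outputs")
    }
    pf <- buildAFMatrix(snps)
    alpha <- if (is.null(cfg$association$alpha)) 1e-9
             else cfg$association$alpha
    corr <- if (is.null(cfg$association$correction)) "bonferroni"
            else cfg$association$correction
    scan <- genomeScan(pf, alpha = alpha, correction = corr)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    exportAFMatrix(pf, .cfgPath(cfg, "af_matrix.tsv"))
    paths <- exportScanResults(scan, .cfgPath(cfg, "scan"))
    .writeRunManifest(cfg, "associate",
                      c(paths, .cfgPath(cfg, "af_matrix.tsv")))
    message("associate: ", scan$counts$color_associated,
            " color-associated, ", scan$counts$geography_associated,
            " geography-associated loci")
    invisible(scan)
}

#' Run the annotation stage
#'
#' Annotates the classified loci against gene models; by default only
#' the color-associated loci are annotated (set `annotate: all: true`
#' for every locus), matching the order of the analysis the package
#' implements. Requires the classification table from [runAssociate()].
#'
#' @param cfg a `RunConfig` (or path); needs `gff` and `fasta`.
#' @return The annotation `data.frame`, invisibly.
#' @export
runAnnotate <- function(cfg) {
    if (is.character(cfg)) cfg <- readRunConfig(cfg)
    classPath <- .cfgPath(cfg, "scan_classification.tsv")
    if (!file.exists(classPath))
        stop("missing ", classPath, "; run the associate stage first")
    if (is.null(cfg$gff)) stop("config key 'gff' is required to annotate")
    tab <- read.delim(classPath, check.names = FALSE)
    if (!isTRUE(cfg$annotate$all) && nrow(tab))
        tab <- tab[tab$color_associated, , drop = FALSE]
    models <- readGeneModelsGff3(cfg$gff)
    refseq <- if (!is.null(cfg$fasta)) {
        ss <- readDNAStringSet(cfg$fasta)
        names(ss) <- sub("\\s.*", "", names(ss))
        ss
    } else NULL
    flank <- if (is.null(cfg$annotate$flank)) 2000L else cfg$annotate$flank
    ann <- annotateLoci(tab, models, refseq, flank)
    annPath <- .cfgPath(cfg, "annotation.tsv")
    write.table(ann, annPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    impPath <- .cfgPath(cfg, "impact_counts.tsv")
    imp <- as.data.frame(table(factor(ann$impact, levels = .impactOrder)),
                         stringsAsFactors = FALSE)
    names(imp) <- c("impact", "n")
    write.table(imp, impPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    .writeRunManifest(cfg, "annotate", c(annPath, impPath))
    message("annotate: ", nrow(ann), " annotation rows")
    invisible(ann)
}

#' Run the summary stage
#'
#' Emits windowed nucleotide diversity per pool, PCA coordinates with a
#' scree JSON, the 30-bin AF histogram, and the pairwise Wilcoxon
#' letters comparing per-pool AF distributions. Requires the AF matrix
#' from [runAssociate()].
#'
#' @param cfg a `RunConfig` (or path).
#' @return List of written paths, invisibly.
#' @export
runSummarize <- function(cfg) {
    if (is.character(cfg)) cfg <- readRunConfig(cfg)
    afPath <- .cfgPath(cfg, "af_matrix.tsv")
    if (!file.exists(afPath))
        stop("missing ", afPath, "; run the associate stage first")
    manPath <- if (!is.null(cfg$manifest)) cfg$manifest
               else .cfgPath(cfg, "simulated_manifest.tsv")
    pools <- readPoolManifest(manPath)
    tab <- read.delim(afPath, check.names = FALSE)
    af <- as.matrix(tab[, rownames(pools), drop = FALSE])
    loci <- GRanges(tab$chrom, IRanges(tab$pos, width = 1L))
    mcols(loci) <- DataFrame(ref = tab$ref, alt = tab$alt)
    pf <- PoolFreq(af, loci, pools)
    winBp <- if (is.null(cfg$summaries$window_bp)) 10000L
             else cfg$summaries$window_bp
    bins <- if (is.null(cfg$summaries$bins)) 30L else cfg$summaries$bins
    piTab <- windowedPi(pf, window_bp = winBp)
    piPath <- .cfgPath(cfg, "windowed_pi.tsv")
    write.table(piTab, piPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    pca <- pcaAF(pf, cfg$summaries$n_components)
    pcaPath <- .cfgPath(cfg, "pca_coordinates.tsv")
    write.table(data.frame(pool_id = rownames(pools), pca$coordinates),
                pcaPath, sep = "\t", quote = FALSE, row.names = FALSE)
    screePath <- .cfgPath(cfg, "pca_scree.json")
    jsonlite::write_json(
        list(explained_variance_fraction =
                 pca$explained_variance_fraction),
        screePath, digits = NA)
    histPath <- .cfgPath(cfg, "af_histogram.tsv")
    counts <- afHistogram(as.vector(af), bins)
    br <- attr(counts, "breaks")
    write.table(data.frame(bin_start = br[-length(br)],
                           bin_end = br[-1L], count = counts),
                histPath, sep = "\t", quote = FALSE, row.names = FALSE)
    groups <- lapply(seq_len(ncol(af)), function(j) af[, j])
    names(groups) <- rownames(pools)
    wilcoxPath <- .cfgPath(cfg, "wilcoxon_letters.tsv")
    if (nrow(af) >= 2L) {
        pw <- pairwiseWilcoxon(groups)
        write.table(data.frame(pool_id = names(pw$letters),
                               letters = unname(pw$letters)),
                    wilcoxPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    out <- c(piPath, pcaPath, screePath, histPath, wilcoxPath)
    .writeRunManifest(cfg, "summarize", out)
    message("summarize: wrote ", length(out), " files")
    invisible(out)
}

#' Run the whole pipeline
#'
#' Stage order is fixed: simulate (when a `simulate` block is present),
#' associate, annotate (when `gff` is configured), summarize.
#'
#' @param cfg a `RunConfig` (or path).
#' @return The `GenomeScanResult` of the associate stage, invisibly.
#' @export
runAll <- function(cfg) {
    if (is.character(cfg)) cfg <- readRunConfig(cfg)
    if (!is.null(cfg$simulate)) runSimulate(cfg)
    scan <- runAssociate(cfg)
    if (!is.null(cfg$gff)) runAnnotate(cfg)
    runSummarize(cfg)
    invisible(scan)
}
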