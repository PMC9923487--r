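#' Read a pool manifest
#'
#' The manifest maps each sequenced pool to its geographic site, its color
#' phenotype and the number of diploid individuals that went into the
#' library. The haploid sample size of a pool is
#' `ploidy * n_individuals` and must be at least 2.
#'
#' @param path TSV file with header columns `pool_id`, `site`, `color`,
#'   `n_individuals` and optionally `ploidy` (default 2).
#' @return A `DataFrame` with one row per pool in file order; rownames are
#'   the pool ids.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("pool_id\tsite\tcolor\tn_individuals",
#'              "A_red\tA\tred\t10", "A_green\tA\tgreen\t12"), tf)
#' readPoolManifest(tf)
#' @export
readPoolManifest <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character")
    need <- c("pool_id", "site", "color", "n_individuals")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
    if (!"ploidy" %in% colnames(tab)) tab$ploidy <- rep("2", nrow(tab))
    ni <- suppressWarnings(as.numeric(tab$n_individuals))
    if (nrow(tab) && (anyNA(ni) || any(ni != round(ni))))
        stop("n_individuals must be integer")
    pl <- suppressWarnings(as.numeric(tab$ploidy))
    if (nrow(tab) && (anyNA(pl) || any(pl != round(pl)) || any(pl < 1)))
        stop("ploidy must be a positive integer")
    makePoolManifest(tab$pool_id, tab$site, tab$color,
                     as.integer(ni), as.integer(pl))
}

#' Assemble and validate a pool manifest in code
#'
#' @param pool_id,site,color character vectors of equal length.
#' @param n_individuals positive integers, one per pool.
#' @param ploidy positive integer(s), default 2 (diploid).
#' @return A validated `DataFrame`, as [readPoolManifest()].
#' @export
makePoolManifest <- function(pool_id, site, color, n_individuals,
                             ploidy = 2L) {
    n <- length(pool_id)
    man <- DataFrame(site = as.character(site), color = as.character(color),
                     n_individuals = as.integer(n_individuals),
                     ploidy = as.integer(rep_len(ploidy, n)),
                     row.names = as.character(pool_id))
    validatePoolManifest(man)
    man
}

validatePoolManifest <- function(man) {
    if (nrow(man) == 0L) return(invisible(man))
    if (anyDuplicated(rownames(man)))
        stop("duplicate pool_id in manifest: ",
             paste(unique(rownames(man)[duplicated(rownames(man))]),
                   collapse = ", "))
    if (any(man$n_individuals < 1L))
        stop("n_individuals must be >= 1 for every pool")
    if (any(man$ploidy * man$n_individuals < 2L))
        stop("haploid sample size (ploidy * n_individuals) must be >= 2")
    cells <- paste(man$site, man$color, sep = "\r")
    if (anyDuplicated(cells))
        stop("(site, color) pairs must be unique across the manifest")
    invisible(man)
}

#' Write a pool manifest as TSV
#'
#' @param pools manifest `DataFrame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePoolManifest <- function(pools, path) {
    tab <- data.frame(pool_id = rownames(pools),
                      site = pools$site, color = pools$color,
                      n_individuals = pools$n_individuals,
                      ploidy = pools$ploidy)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
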