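#' Windowed nucleotide diversity per pool
#'
#' Per-site diversity is the finite-sample-corrected expected
#' heterozygosity of the pool,
#' `pi_i = n_chr / (n_chr - 1) * 2 * p_i * (1 - p_i)` with `n_chr` the
#' haploid pool size (`ploidy * n_individuals`), summed over the variant
#' sites of each non-overlapping genomic window and divided by the window
#' span in bp (default) or by the number of variant sites
#' (`denominator = "sites"`). Monomorphic sites (p of 0 or 1) contribute
#' zero; invariant windows report `pi = 0`. Windows tile each chromosome
#' from position 1.
#'
#' @param pf a [PoolFreq-class] object.
#' @param window_bp window width in bp, default 10000.
#' @param denominator `"bp"` (window span) or `"sites"` (variant count).
#' @return A `data.frame`: pool_id, chrom, win_start, win_end,
#'   n_variant_sites, pi.
#' @export
windowedPi <- function(pf, window_bp = 10000L,
                       denominator = c("bp", "sites")) {
    denominator <- match.arg(denominator)
    pools <- poolInfo(pf)
    nchrom <- pools$ploidy * pools$n_individuals
    if (any(nchrom < 2L))
        stop("haploid pool size must be >= 2 to estimate diversity")
    rr <- rowRanges(pf)
    af <- afMatrix(pf)
    chrom <- as.character(seqnames(rr)); pos <- start(rr)
    out <- list()
    for (j in seq_len(nrow(pools))) {
        corr <- nchrom[j] / (nchrom[j] - 1)
        piSite <- corr * 2 * af[, j] * (1 - af[, j])
        for (ch in unique(chrom)) {
            sel <- chrom == ch
            win <- (pos[sel] - 1L) %/% window_bp
            maxWin <- max(win)
            counts <- integer(maxWin + 1L); sums <- numeric(maxWin + 1L)
            variant <- af[sel, j] > 0 & af[sel, j] < 1
            tb <- tapply(piSite[sel], win, sum)
            sums[as.integer(names(tb)) + 1L] <- tb
            tc <- tapply(variant, win, sum)
            counts[as.integer(names(tc)) + 1L] <- tc
            denom <- if (denominator == "bp") window_bp
                     else pmax(counts, 1L)
            out[[length(out) + 1L]] <- data.frame(
                pool_id = rownames(pools)[j], chrom = ch,
                win_start = (seq_len(maxWin + 1L) - 1L) * window_bp + 1L,
                win_end = seq_len(maxWin + 1L) * window_bp,
                n_variant_sites = counts, pi = sums / denom)
        }
    }
    do.call(rbind, out)
}

#' PCA of pool allele frequencies
#'
#' Column-centred (per-locus) singular value decomposition of the
#' pools-by-loci AF matrix, with a deterministic sign convention: each
#' component is flipped so that its largest-magnitude loading is
#' positive.
#'
#' @param pf a [PoolFreq-class] object (at least 2 pools, 1 locus).
#' @param n_components number of components to return; clipped with a
#'   warning to `min(n_pools - 1, n_loci)`.
#' @return A list of class `PCAResult`: `coordinates` (pools x
#'   components), `explained_variance_fraction`, `rotation` (loci x
#'   components).
#' @export
pcaAF <- function(pf, n_components = NULL) {
    x <- t(afMatrix(pf))                       # pools x loci
    if (nrow(x) < 2L || ncol(x) < 1L)
        stop("PCA needs at least 2 pools and 1 locus")
    kmax <- min(nrow(x) - 1L, ncol(x))
    if (is.null(n_components)) n_components <- kmax
    if (n_components > kmax) {
        warning("n_components clipped to ", kmax)
        n_components <- kmax
    }
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    k <- seq_len(n_components)
    rot <- pc$rotation[, k, drop = FALSE]
    coords <- pc$x[, k, drop = FALSE]
    for (i in k) {
        jmax <- which.max(abs(rot[, i]))
        if (rot[jmax, i] < 0) {
            rot[, i] <- -rot[, i]
            coords[, i] <- -coords[, i]
        }
    }
    ev <- pc$sdev^2
    structure(list(coordinates = coords,
                   explained_variance_fraction = (ev / sum(ev))[k],
                   rotation = rot),
              class = "PCAResult")
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-squared reference with k-1 df) that returns H = 0 and
#' p = 1 for fully tied data instead of `NaN`.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return A list: `statistic` (H), `df`, `p.value`.
#' @export
kruskalWallis <- function(groups) {
    if (length(groups) < 2L || any(lengths(groups) == 0L))
        stop("need at least two non-empty groups")
    values <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    if (length(unique(values)) == 1L)
        return(list(statistic = 0, df = length(groups) - 1L, p.value = 1))
    kt <- kruskal.test(values, g)
    list(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value)
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni adjustment
#'
#' Two-sided rank-sum test for every group pair via
#' [stats::wilcox.test()]: exact enumeration when the combined sample
#' size is at most 20 and there are no ties, normal approximation with
#' tie and continuity correction otherwise. P-values are Bonferroni
#' adjusted over the number of pairs, and groups are summarised by a
#' compact letter display (see [compactLetters()]).
#'
#' @param groups named list of at least two non-empty numeric vectors.
#' @param alpha significance level for the letter display.
#' @return A list: `p_adj` (symmetric matrix), `p_raw`, `letters` (named
#'   character vector).
#' @export
pairwiseWilcoxon <- function(groups, alpha = 0.05) {
    k <- length(groups)
    if (k < 2L) stop("need at least two groups")
    if (any(lengths(groups) == 0L)) stop("empty group")
    nm <- names(groups)
    if (is.null(nm)) nm <- paste0("g", seq_len(k))
    praw <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
    npairs <- k * (k - 1L) / 2L
    for (j in 2:k) for (i in 1:(j - 1L)) {
        x <- groups[[i]]; y <- groups[[j]]
        exact <- (length(x) + length(y)) <= 20L &&
            !anyDuplicated(c(x, y))
        wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                           correct = TRUE))
        praw[i, j] <- praw[j, i] <- wt$p.value
    }
    padj <- praw * npairs
    padj[!is.na(padj) & padj > 1] <- 1
    diag(padj) <- NA_real_
    diag(praw) <- NA_real_
    letters <- compactLetters(padj < alpha, nm)
    list(p_adj = padj, p_raw = praw, letters = letters)
}

#' Compact letter display from a significance matrix
#'
#' Greedy insert-and-absorb: starting from one letter covering all
#' groups, each significantly different pair splits every letter set that
#' still contains both members; subsets of other sets are absorbed. Ties
#' are broken by group order. Groups that are not significantly different
#' share at least one letter.
#'
#' @param sigMatrix logical matrix, `TRUE` where a pair differs
#'   significantly (diagonal ignored).
#' @param names group names.
#' @return Named character vector of letter strings.
#' @export
compactLetters <- function(sigMatrix, names = rownames(sigMatrix)) {
    k <- nrow(sigMatrix)
    sets <- list(seq_len(k))
    for (j in 2:k) for (i in 1:(j - 1L)) {
        if (!isTRUE(sigMatrix[i, j])) next
        newSets <- list()
        for (s in sets) {
            if (i %in% s && j %in% s) {
                newSets <- c(newSets, list(setdiff(s, i)),
                             list(setdiff(s, j)))
            } else newSets <- c(newSets, list(s))
        }
        keep <- rep(TRUE, length(newSets))
        for (a in seq_along(newSets)) for (b in seq_along(newSets)) {
            if (a != b && keep[b] &&
                all(newSets[[a]] %in% newSets[[b]]) &&
                (length(newSets[[a]]) < length(newSets[[b]]) || a > b))
                keep[a] <- FALSE
        }
        sets <- newSets[keep]
    }
    # letters follow group order: the set containing the earliest group
    # comes first
    sets <- sets[order(vapply(sets, min, numeric(1)))]
    out <- vapply(seq_len(k), function(g) {
        paste(letters[which(vapply(sets, function(s) g %in% s,
                                   logical(1)))], collapse = "")
    }, character(1))
    setNames(out, names)
}

#' Allele-frequency histogram
#'
#' Thirty (by default) equal-width bins on [0, 1]; bins are left-closed
#' with the last bin right-closed so AF = 1 is counted. Counts always sum
#' to the input length.
#'
#' @param values numeric vector in [0, 1].
#' @param bins number of bins, default 30.
#' @return Integer vector of bin counts with a `breaks` attribute.
#' @export
afHistogram <- function(values, bins = 30L) {
    if (length(values) && (min(values) < 0 || max(values) > 1))
        stop("AF values must lie in [0, 1]")
    idx <- pmin(floor(values * bins) + 1L, bins)
    counts <- tabulate(idx, nbins = bins)
    attr(counts, "breaks") <- seq(0, 1, length.out = bins + 1L)
    counts
}
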