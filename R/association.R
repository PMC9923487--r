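#' Treatment-coded two-factor design
#'
#' Builds the reference-cell (treatment) coded design matrix for the
#' per-SNP model `AF ~ color + site`: an intercept column, then one dummy
#' per non-reference color level, then one dummy per non-reference site
#' level, in level order. The first level of each factor is the
#' reference. A factor with a single level contributes no column.
#'
#' @param pools pool manifest (`DataFrame` with `color` and `site`).
#' @param color_levels,site_levels ordered level vectors; default is the
#'   order of first appearance in the manifest.
#' @return A list of class `DesignInfo`: `X` (n_pools x p matrix),
#'   `color_levels`, `site_levels`, `rank_ok` (FALSE when empty
#'   (site, color) cells leave a dummy column all-zero or collinear).
#' @examples
#' man <- defaultPoolManifest()
#' d <- encodeDesign(man)
#' dim(d$X)  # 12 x 6
#' @export
encodeDesign <- function(pools, color_levels = NULL, site_levels = NULL) {
    color <- as.character(pools$color); site <- as.character(pools$site)
    if (is.null(color_levels)) color_levels <- unique(color)
    if (is.null(site_levels)) site_levels <- unique(site)
    if (!all(color %in% color_levels))
        stop("unseen color label(s): ",
             paste(setdiff(color, color_levels), collapse = ", "))
    if (!all(site %in% site_levels))
        stop("unseen site label(s): ",
             paste(setdiff(site, site_levels), collapse = ", "))
    n <- nrow(pools)
    X <- matrix(1, n, 1L, dimnames = list(rownames(pools), "(Intercept)"))
    dummies <- function(vals, levels, prefix) {
        if (length(levels) < 2L)
            return(matrix(0, n, 0L))
        m <- vapply(levels[-1L], function(l) as.numeric(vals == l),
                    numeric(n))
        m <- matrix(m, n, length(levels) - 1L,
                    dimnames = list(NULL, paste0(prefix, levels[-1L])))
        m
    }
    X <- cbind(X, dummies(color, color_levels, "color"),
               dummies(site, site_levels, "site"))
    rank_ok <- qr(X)$rank == ncol(X)
    if (!rank_ok)
        warning("design matrix is rank deficient (empty (site, color) ",
                "cells); fits will be refused unless handled explicitly")
    structure(list(X = X, color_levels = color_levels,
                   site_levels = site_levels, rank_ok = rank_ok),
              class = "DesignInfo")
}

#' Per-SNP ordinary least-squares fit of allele frequency
#'
#' Fits the Gaussian identity-link model (OLS) used for every SNP:
#' `beta = (X'X)^{-1} X'y`, `sigma2 = RSS / df_resid`,
#' `cov_beta = sigma2 (X'X)^{-1}`. The bounded AF response is treated as
#' continuous, matching the default family of the modelling interface the
#' method is built around.
#'
#' @param af numeric vector of allele frequencies, one per pool.
#' @param design a `DesignInfo` from [encodeDesign()].
#' @return A list of class `ModelFit`: `beta`, `sigma2`, `df_resid`,
#'   `cov_beta`, `XtXinv`, and the `design`.
#' @export
fitAFGlm <- function(af, design) {
    X <- design$X
    if (length(af) != nrow(X))
        stop("af length must equal the number of pools")
    if (!design$rank_ok)
        stop("rank-deficient design: refusing to fit")
    df <- nrow(X) - ncol(X)
    if (df < 1L)
        stop("zero residual degrees of freedom: cannot estimate sigma2")
    XtX <- crossprod(X)
    XtXinv <- solve(XtX)
    beta <- drop(XtXinv %*% crossprod(X, af))
    resid <- af - drop(X %*% beta)
    sigma2 <- sum(resid^2) / df
    structure(list(beta = beta, sigma2 = sigma2, df_resid = df,
                   cov_beta = sigma2 * XtXinv, XtXinv = XtXinv,
                   design = design),
              class = "ModelFit")
}

#' Tukey all-pairs contrast matrix for one factor
#'
#' One row per unordered level pair (A, B) with A later than B in level
#' order, encoding `mean(A) - mean(B)` under treatment coding; labels are
#' `"A - B"`. Rows have at most two nonzero entries in {-1, 0, +1}.
#'
#' @param factor `"color"` or `"site"`.
#' @param design a `DesignInfo`.
#' @return A list of class `ContrastSet`: `factor`, `labels`, `K` (rows x
#'   p contrast matrix conforming to the design).
#' @export
pairwiseContrasts <- function(factor = c("color", "site"), design) {
    factor <- match.arg(factor)
    levels <- if (factor == "color") design$color_levels
              else design$site_levels
    if (length(levels) < 2L)
        stop("factor '", factor, "' needs at least 2 levels")
    p <- ncol(design$X)
    cols <- colnames(design$X)
    dummyCol <- function(level) {
        i <- match(paste0(factor, level), cols)
        i
    }
    labels <- character(); K <- NULL
    for (j in 2:length(levels)) for (i in 1:(j - 1L)) {
        row <- numeric(p)
        row[dummyCol(levels[j])] <- 1
        if (i > 1L) row[dummyCol(levels[i])] <- -1
        K <- rbind(K, row)
        labels <- c(labels, paste(levels[j], "-", levels[i]))
    }
    dimnames(K) <- list(labels, cols)
    structure(list(factor = factor, labels = labels, K = K),
              class = "ContrastSet")
}

#' Simultaneous test of stacked contrast families
#'
#' Stacks the color (K1) and site (K2) all-pairs contrast matrices into a
#' single family `rbind(K1, K2)` and tests every row against the fitted
#' coefficients: estimate `(K beta)_j`, standard error
#' `sqrt((K cov_beta K')_jj)`, two-sided Student-t p-value with the
#' residual degrees of freedom, and a single Bonferroni correction over
#' all stacked rows (m = 9 for 3 colors and 4 sites).
#'
#' Degenerate zero-residual fits (noise-free or saturated data) do not
#' abort: a contrast with zero standard error gets `p_raw = 1` when its
#' estimate is zero (no evidence) and `p_raw = 0` otherwise (perfect
#' separation), and the result is flagged `degenerate`.
#'
#' @param fit a `ModelFit` from [fitAFGlm()].
#' @param sets list of `ContrastSet`s (typically color then site).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return A `data.frame` with columns `factor`, `label`, `estimate`,
#'   `se`, `statistic`, `p_raw`, `p_adj`, `degenerate`.
#' @export
simultaneousTest <- function(fit, sets, correction = c("bonferroni",
                                                       "none")) {
    correction <- match.arg(correction)
    K <- do.call(rbind, lapply(sets, `[[`, "K"))
    labels <- unlist(lapply(sets, `[[`, "labels"))
    facs <- unlist(lapply(sets, function(s) rep(s$factor,
                                                length(s$labels))))
    if (ncol(K) != length(fit$beta))
        stop("contrast matrix does not conform to the coefficients")
    est <- drop(K %*% fit$beta)
    kvar <- rowSums((K %*% fit$XtXinv) * K)
    degenerate <- fit$sigma2 <= .sigma2Tol
    se <- sqrt(fit$sigma2 * kvar)
    if (degenerate) {
        p <- ifelse(abs(est) > .estTol, 0, 1)
        stat <- ifelse(abs(est) > .estTol, Inf * sign(est), 0)
    } else {
        stat <- est / se
        p <- 2 * pt(-abs(stat), fit$df_resid)
    }
    m <- nrow(K)
    p_adj <- if (correction == "bonferroni") pmin(1, m * p) else p
    data.frame(factor = facs, label = labels, estimate = est, se = se,
               statistic = stat, p_raw = p, p_adj = p_adj,
               degenerate = degenerate, row.names = NULL)
}

.sigma2Tol <- 1e-20
.estTol <- 1e-10

#' Classify one SNP from its pairwise contrast results
#'
#' Decision rules, applied to the Bonferroni-adjusted p-values at
#' threshold `alpha` (default 1e-9):
#' \itemize{
#'   \item geography-associated: at least one pairwise \emph{site}
#'     comparison significant;
#'   \item color-associated: at least one pairwise \emph{color}
#'     comparison significant \strong{and} no site comparison significant
#'     (the exclusion rule that removes jointly geography-driven loci);
#'   \item color-specific for color c: color-associated and every
#'     pairwise comparison involving c significant. When all color pairs
#'     are significant every color would qualify, so no specific color is
#'     assigned and the `all_pairs` flag is set.
#' }
#'
#' @param results `data.frame` from [simultaneousTest()] covering every
#'   color and site pair exactly once.
#' @param alpha significance threshold on adjusted p-values.
#' @return A list of class `SNPClassification`: `color_associated`,
#'   `specific_color` (label or `"none"`), `geography_associated`,
#'   `all_pairs`, `significant_pairs` (character vector of labels).
#' @export
classifySNP <- function(results, alpha = 1e-9) {
    if (anyDuplicated(results$label))
        stop("duplicate pairwise label in results")
    sig <- results$p_adj < alpha
    colorRows <- results$factor == "color"
    siteRows <- results$factor == "site"
    geo <- any(sig[siteRows])
    colorAny <- any(sig[colorRows])
    colorAssoc <- colorAny && !geo
    colorLabels <- results$label[colorRows]
    colorSig <- sig[colorRows]
    levels <- unique(unlist(strsplit(colorLabels, " - ", fixed = TRUE)))
    expectPairs <- choose(length(levels), 2L)
    if (length(colorLabels) != expectPairs)
        stop("missing pairwise color label(s): expected ", expectPairs,
             ", got ", length(colorLabels))
    allPairs <- all(colorSig)
    specific <- "none"
    if (colorAssoc) {
        pairLevels <- strsplit(colorLabels, " - ", fixed = TRUE)
        qualifies <- vapply(levels, function(l) {
            involved <- vapply(pairLevels, function(p) l %in% p,
                               logical(1))
            all(colorSig[involved])
        }, logical(1))
        if (allPairs || sum(qualifies) > 1L) specific <- "none"
        else if (sum(qualifies) == 1L) specific <- levels[qualifies]
    }
    structure(list(color_associated = colorAssoc,
                   specific_color = specific,
                   geography_associated = geo,
                   all_pairs = allPairs && colorAssoc,
                   significant_pairs = results$label[sig]),
              class = "SNPClassification")
}

#' Genome-wide association scan
#'
#' Runs fit, stacked contrasts, simultaneous test and classification for
#' every locus of a [PoolFreq-class] matrix, fully vectorised across loci
#' (the design, its inverse cross-product and the contrast variances are
#' shared by all loci). Deterministic given its input; degenerate
#' zero-residual fits are flagged per locus, never fatal.
#'
#' @param x a [PoolFreq-class] object.
#' @param alpha classification threshold on adjusted p-values (default
#'   1e-9, the stringency that plays the genome-wide role here; the
#'   Bonferroni family is the 9 within-SNP contrasts, not the genome).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param color_levels,site_levels optional explicit level orders.
#' @return A list of class `GenomeScanResult`:
#'   \describe{
#'     \item{table}{`data.frame`, one row per locus: chrom, pos, ref, alt,
#'       one `est.<pair>` and `padj.<pair>` column per contrast, flags
#'       `degenerate` and `all_pairs`, `geography_associated`,
#'       `color_associated`, `specific_color`.}
#'     \item{counts}{list with `pairwise` (significant loci per contrast,
#'       the chord-diagram counts), `color_associated`, `specific`
#'       (per color), `specific_total`, `geography_associated`.}
#'     \item{alpha, labels}{the threshold and contrast labels used.}
#'   }
#' @aliases genomeScan,PoolFreq-method
#' @export
setMethod("genomeScan", "PoolFreq",
function(x, alpha = 1e-9, correction = c("bonferroni", "none"),
         color_levels = NULL, site_levels = NULL, ...) {
    correction <- match.arg(correction)
    pools <- poolInfo(x)
    design <- encodeDesign(pools, color_levels, site_levels)
    kc <- pairwiseContrasts("color", design)
    ks <- pairwiseContrasts("site", design)
    K <- rbind(kc$K, ks$K)
    labels <- c(kc$labels, ks$labels)
    nc <- length(kc$labels)
    m <- nrow(K)
    rr <- rowRanges(x)
    emptyCounts <- list(
        pairwise = setNames(integer(m), labels),
        color_associated = 0L,
        specific = setNames(integer(length(design$color_levels)),
                            design$color_levels),
        specific_total = 0L, geography_associated = 0L)
    if (nrow(x) == 0L)
        return(structure(list(table = data.frame(), counts = emptyCounts,
                              alpha = alpha, labels = labels),
                         class = "GenomeScanResult"))
    X <- design$X
    df <- nrow(X) - ncol(X)
    XtXinv <- solve(crossprod(X))
    Y <- afMatrix(x)                      # loci x pools
    B <- (Y %*% X) %*% XtXinv             # loci x p coefficients
    fitted <- B %*% t(X)
    rss <- rowSums((Y - fitted)^2)
    sigma2 <- rss / df
    Est <- B %*% t(K)                     # loci x m
    kvar <- rowSums((K %*% XtXinv) * K)
    se <- sqrt(outer(sigma2, kvar))
    degenerate <- sigma2 <= .sigma2Tol
    P <- matrix(NA_real_, nrow(x), m)
    if (any(!degenerate)) {
        stat <- Est[!degenerate, , drop = FALSE] /
            se[!degenerate, , drop = FALSE]
        P[!degenerate, ] <- 2 * pt(-abs(stat), df)
    }
    if (any(degenerate))
        P[degenerate, ] <- ifelse(
            abs(Est[degenerate, , drop = FALSE]) > .estTol, 0, 1)
    Padj <- if (correction == "bonferroni")
        matrix(pmin(1, m * P), nrow(x), m) else P
    sig <- Padj < alpha
    colorIdx <- seq_len(nc); siteIdx <- (nc + 1L):m
    geo <- rowSums(sig[, siteIdx, drop = FALSE]) > 0L
    colorAny <- rowSums(sig[, colorIdx, drop = FALSE]) > 0L
    colorAssoc <- colorAny & !geo
    levels <- design$color_levels
    qual <- vapply(levels, function(l) {
        involved <- vapply(strsplit(kc$labels, " - ", fixed = TRUE),
                           function(p) l %in% p, logical(1))
        rowSums(sig[, colorIdx[involved], drop = FALSE]) == sum(involved)
    }, logical(nrow(x)))
    qual <- matrix(qual, nrow(x), length(levels),
                   dimnames = list(NULL, levels))
    allPairs <- rowSums(sig[, colorIdx, drop = FALSE]) == nc
    nQual <- rowSums(qual)
    specific <- rep("none", nrow(x))
    one <- colorAssoc & nQual == 1L & !allPairs
    if (any(one))
        specific[one] <- levels[max.col(qual[one, , drop = FALSE])]
    estCols <- as.data.frame(Est)
    names(estCols) <- paste0("est.", labels)
    padjCols <- as.data.frame(Padj)
    names(padjCols) <- paste0("padj.", labels)
    tab <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                      ref = mcols(rr)$ref, alt = mcols(rr)$alt,
                      estCols, padjCols,
                      degenerate = degenerate,
                      all_pairs = allPairs & colorAssoc,
                      geography_associated = geo,
                      color_associated = colorAssoc,
                      specific_color = specific,
                      check.names = FALSE, row.names = NULL)
    counts <- list(
        pairwise = setNames(as.integer(colSums(sig)), labels),
        color_associated = sum(colorAssoc),
        specific = vapply(levels, function(l) sum(specific == l),
                          integer(1)),
        specific_total = sum(specific != "none"),
        geography_associated = sum(geo))
    structure(list(table = tab, counts = counts, alpha = alpha,
                   labels = labels),
              class = "GenomeScanResult")
})

#' @export
print.GenomeScanResult <- function(x, ...) {
    cat(sprintf("GenomeScanResult: %d locus/loci at alpha %g\n",
                nrow(x$table), x$alpha))
    cat(sprintf("  color-associated: %d (specific: %s; total %d)\n",
                x$counts$color_associated,
                paste(names(x$counts$specific), x$counts$specific,
                      sep = "=", collapse = ", "),
                x$counts$specific_total))
    cat(sprintf("  geography-associated: %d\n",
                x$counts$geography_associated))
    invisible(x)
}

#' Export genome-scan outputs
#'
#' Writes the per-locus table as TSV and the summary counts as TSV and
#' JSON next to it.
#'
#' @param scan a `GenomeScanResult`.
#' @param prefix output path prefix; files `<prefix>_classification.tsv`,
#'   `<prefix>_counts.tsv` and `<prefix>_counts.json` are produced.
#' @return Character vector of the written paths, invisibly.
#' @export
exportScanResults <- function(scan, prefix) {
    tsv <- paste0(prefix, "_classification.tsv")
    write.table(scan$table, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    ctsv <- paste0(prefix, "_counts.tsv")
    ptab <- data.frame(comparison = names(scan$counts$pairwise),
                       n_significant = as.integer(scan$counts$pairwise))
    write.table(ptab, ctsv, sep = "\t", quote = FALSE, row.names = FALSE)
    cjson <- paste0(prefix, "_counts.json")
    jsonlite::write_json(scan$counts, cjson, auto_unbox = TRUE,
                         digits = NA)
    invisible(c(tsv, ctsv, cjson))
}
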