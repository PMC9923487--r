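# Shared in-code fixtures and independent oracles.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(IRanges)
    library(GenomicRanges)
})

sortIR <- function(r) r[order(IRanges::start(r))]

twoPoolManifest <- function() {
    makePoolManifest(c("poolA", "poolB"), c("S1", "S1"),
                     c("red", "green"), c(10L, 10L))
}

# Small PoolCalls built directly in code (no file I/O).
makeCalls <- function(chrom, pos, ref, alt, ad_ref, ad_alt, dp,
                      pools = twoPoolManifest()) {
    chrom <- rep_len(chrom, length(pos))
    PoolCalls(chrom, pos, ref, alt,
              matrix(ad_ref, nrow = length(pos), byrow = TRUE),
              matrix(ad_alt, nrow = length(pos), byrow = TRUE),
              matrix(dp, nrow = length(pos), byrow = TRUE), pools)
}

extdata <- function(name) {
    system.file("extdata", name, package = "poolColorScan",
                mustWork = TRUE)
}

# Independent textbook least-squares + contrast t-test oracle.
# Uses a QR path on X (not the normal equations of the implementation).
contrastOracle <- function(af, X, K, df = nrow(X) - ncol(X)) {
    qrX <- qr(X)
    beta <- qr.coef(qrX, af)
    resid <- af - X %*% beta
    sigma2 <- sum(resid^2) / df
    XtXinv <- chol2inv(qr.R(qrX))
    est <- drop(K %*% beta)
    se <- sqrt(sigma2 * rowSums((K %*% XtXinv) * K))
    stat <- est / se
    p <- 2 * pt(-abs(stat), df)
    list(estimate = est, se = se, statistic = stat, p_raw = p,
         p_adj = pmin(1, nrow(K) * p))
}

# Brute-force classification of a single locus from a 0/1 significance
# pattern over the stacked contrasts (independent of classifySNP).
bruteClassify <- function(sigColor, sigSite, colorLevels) {
    geo <- any(sigSite)
    colorAssoc <- any(sigColor) && !geo
    pairs <- t(combn(length(colorLevels), 2L))[, 2:1, drop = FALSE]
    # pair order must match pairwiseContrasts: (2,1),(3,1),(3,2),...
    ord <- order(pairs[, 1L], pairs[, 2L])
    pairs <- pairs[ord, , drop = FALSE]
    specific <- "none"
    if (colorAssoc) {
        qualifies <- vapply(seq_along(colorLevels), function(l)
            all(sigColor[pairs[, 1L] == l | pairs[, 2L] == l]),
            logical(1))
        if (sum(qualifies) == 1L && !all(sigColor))
            specific <- colorLevels[qualifies]
    }
    list(color_associated = colorAssoc, specific_color = specific,
         geography_associated = geo)
}

# Exact two-sided rank-sum p by full enumeration of all assignments.
wilcoxEnumerate <- function(x, y) {
    m <- length(x)
    vals <- c(x, y)
    ranks <- rank(vals)
    obs <- sum(ranks[seq_len(m)])
    combs <- combn(length(vals), m)
    stats <- apply(combs, 2L, function(idx) sum(ranks[idx]))
    mu <- m * (length(vals) + 1L) / 2
    mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Gaussian-noise null AF matrix as a PoolFreq (for calibration checks).
nullPoolFreq <- function(n_loci, pools = defaultPoolManifest(),
                         sd = 0.05, mean_af = 0.5) {
    af <- matrix(pmin(pmax(rnorm(n_loci * nrow(pools), mean_af, sd),
                           0), 1),
                 n_loci, nrow(pools))
    loci <- GenomicRanges::GRanges(rep("chr1", n_loci),
                                   IRanges::IRanges(seq_len(n_loci),
                                                    width = 1L))
    S4Vectors::mcols(loci) <- S4Vectors::DataFrame(
        ref = rep("A", n_loci), alt = rep("T", n_loci))
    PoolFreq(af, loci, pools)
}
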