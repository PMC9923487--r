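test_that("design encoding gives the documented shapes and errors", {
    man <- defaultPoolManifest()
    d <- encodeDesign(man)
    expect_identical(dim(d$X), c(12L, 6L))
    expect_identical(qr(d$X)$rank, 6L)
    expect_identical(colnames(d$X)[1], "(Intercept)")
    # single-level factor contributes no column
    man2 <- makePoolManifest(c("p1", "p2"), c("A", "A"),
                             c("red", "green"), c(10L, 10L))
    d2 <- encodeDesign(man2)
    expect_identical(dim(d2$X), c(2L, 2L))
    expect_error(encodeDesign(man, color_levels = c("red", "yellow")),
                 "unseen")
})

test_that("noise-free additive AF construction is recovered exactly", {
    man <- defaultPoolManifest()
    d <- encodeDesign(man)
    # af = 0.2 + 0.3 [color == red is reference, use yellow] + 0.1 [Katiu]
    beta <- c(0.2, 0.3, 0, 0.1, 0, 0)
    af <- drop(d$X %*% beta)
    fit <- fitAFGlm(af, d)
    expect_equal(unname(fit$beta), beta, tolerance = 1e-12)
    expect_lt(fit$sigma2, 1e-20)
    # constant response: intercept only
    fitc <- fitAFGlm(rep(0.3, 12), d)
    expect_equal(unname(fitc$beta), c(0.3, rep(0, 5)), tolerance = 1e-12)
    # planted pairwise difference appears exactly in the contrast
    res <- simultaneousTest(fit, list(pairwiseContrasts("color", d),
                                      pairwiseContrasts("site", d)))
    expect_true(all(res$degenerate))
    expect_equal(res$estimate[res$label == "yellow - red"], 0.3,
                 tolerance = 1e-12)
    expect_identical(res$p_raw[res$label == "yellow - red"], 0)
    # green and the red reference share a mean: no evidence
    expect_identical(res$p_raw[res$label == "green - red"], 1)
})

test_that("contrast sets enumerate unordered level pairs", {
    d <- encodeDesign(defaultPoolManifest())
    kc <- pairwiseContrasts("color", d)
    ks <- pairwiseContrasts("site", d)
    expect_identical(length(kc$labels), 3L)
    expect_identical(length(ks$labels), 6L)
    expect_true(all(kc$K %in% c(-1, 0, 1)))
    expect_true(all(rowSums(kc$K != 0) <= 2))
    # 2-level factor: single row, +1 on its dummy
    man2 <- makePoolManifest(paste0("p", 1:4), c("A", "A", "B", "B"),
                             c("red", "green", "red", "green"),
                             rep(10L, 4))
    d2 <- encodeDesign(man2)
    k2 <- pairwiseContrasts("site", d2)
    expect_identical(length(k2$labels), 1L)
    expect_identical(sum(k2$K != 0), 1L)
})

test_that("estimates, SEs and p-values match independent oracles", {
    set.seed(101)
    man <- defaultPoolManifest()
    d <- encodeDesign(man)
    kc <- pairwiseContrasts("color", d)
    ks <- pairwiseContrasts("site", d)
    K <- rbind(kc$K, ks$K)
    worst <- 0
    for (i in 1:120) {
        af <- runif(12, 0.05, 0.95)
        fit <- fitAFGlm(af, d)
        res <- simultaneousTest(fit, list(kc, ks))
        oracle <- contrastOracle(af, d$X, K)
        worst <- max(worst,
                     abs(res$estimate - oracle$estimate),
                     abs(res$se - oracle$se),
                     abs(res$p_raw - oracle$p_raw),
                     abs(res$p_adj - oracle$p_adj))
    }
    expect_lt(worst, 1e-8)
})

test_that("results agree with the multcomp reference implementation", {
    skip_if_not_installed("multcomp")
    set.seed(202)
    man <- defaultPoolManifest()
    d <- encodeDesign(man)
    kc <- pairwiseContrasts("color", d)
    ks <- pairwiseContrasts("site", d)
    dat0 <- data.frame(color = factor(man$color,
                                      levels = unique(man$color)),
                       site = factor(man$site,
                                     levels = unique(man$site)))
    for (i in 1:10) {
        dat <- dat0
        dat$af <- runif(12, 0.1, 0.9)
        res <- simultaneousTest(fitAFGlm(dat$af, d), list(kc, ks))
        mod <- stats::lm(af ~ color + site, data = dat)
        K <- rbind(multcomp::glht(mod,
                       multcomp::mcp(color = "Tukey"))$linfct,
                   multcomp::glht(mod,
                       multcomp::mcp(site = "Tukey"))$linfct)
        s <- summary(multcomp::glht(mod, linfct = K),
                     test = multcomp::adjusted("bonferroni"))
        idx <- match(res$label, rownames(K))
        expect_lt(max(abs(res$estimate -
                          unname(s$test$coefficients[idx]))), 1e-10)
        expect_lt(max(abs(res$se - unname(s$test$sigma[idx]))), 1e-10)
        expect_lt(max(abs(res$p_adj - unname(s$test$pvalues[idx]))),
                  1e-10)
    }
})

test_that("classification rules match brute force over all patterns", {
    man <- defaultPoolManifest()
    colorLevels <- unique(man$color)
    labels <- c("yellow - red", "green - red", "green - yellow",
                "Katiu - Takapoto", "Gambier - Takapoto",
                "Gambier - Katiu", "Hatchery - Takapoto",
                "Hatchery - Katiu", "Hatchery - Gambier")
    facs <- rep(c("color", "site"), c(3L, 6L))
    for (pattern in 0:511) {
        sig <- as.logical(bitwAnd(bitwShiftR(pattern, 0:8), 1L))
        res <- data.frame(factor = facs, label = labels,
                          p_adj = ifelse(sig, 1e-12, 0.5))
        got <- classifySNP(res, alpha = 1e-9)
        want <- bruteClassify(sig[1:3], sig[4:9], colorLevels)
        expect_identical(got$color_associated, want$color_associated)
        expect_identical(got$geography_associated,
                         want$geography_associated)
        expect_identical(got$specific_color, want$specific_color)
        # invariants of the rule system
        if (got$specific_color != "none")
            expect_true(got$color_associated)
        if (got$color_associated)
            expect_false(got$geography_associated)
    }
})

test_that("forced classification examples behave as documented", {
    labels <- c("yellow - red", "green - red", "green - yellow",
                "Katiu - Takapoto", "Gambier - Takapoto",
                "Gambier - Katiu", "Hatchery - Takapoto",
                "Hatchery - Katiu", "Hatchery - Gambier")
    facs <- rep(c("color", "site"), c(3L, 6L))
    mk <- function(p) data.frame(factor = facs, label = labels, p_adj = p)
    # nothing significant
    none <- classifySNP(mk(rep(1, 9)))
    expect_false(none$color_associated)
    expect_false(none$geography_associated)
    expect_identical(none$specific_color, "none")
    # both red pairs significant, third color pair and all sites not
    red <- classifySNP(mk(c(1e-12, 1e-12, 0.5, rep(0.9, 6))))
    expect_true(red$color_associated)
    expect_identical(red$specific_color, "red")
    # one color pair and one site pair significant: geography wins
    geo <- classifySNP(mk(c(0.9, 0.9, 1e-12, 1e-12, rep(0.9, 5))))
    expect_false(geo$color_associated)
    expect_true(geo$geography_associated)
    # all three color pairs significant: ambiguous, flagged
    amb <- classifySNP(mk(c(1e-12, 1e-12, 1e-12, rep(0.9, 6))))
    expect_true(amb$color_associated)
    expect_identical(amb$specific_color, "none")
    expect_true(amb$all_pairs)
})

test_that("shrinking alpha never adds a significant pair", {
    set.seed(33)
    man <- defaultPoolManifest()
    d <- encodeDesign(man)
    kc <- pairwiseContrasts("color", d); ks <- pairwiseContrasts("site", d)
    for (i in 1:25) {
        res <- simultaneousTest(fitAFGlm(runif(12), d), list(kc, ks))
        alphas <- sort(runif(6))
        nsig <- vapply(alphas, function(a) sum(res$p_adj < a), integer(1))
        expect_true(all(diff(nsig) >= 0))
        expect_true(all(res$p_adj >= res$p_raw))
    }
})

test_that("degenerate zero-residual fits are flagged, not fatal", {
    man <- defaultPoolManifest()
    d <- encodeDesign(man)
    res <- simultaneousTest(fitAFGlm(rep(0.25, 12), d),
                            list(pairwiseContrasts("color", d),
                                 pairwiseContrasts("site", d)))
    expect_true(all(res$degenerate))
    expect_true(all(res$p_adj == 1))
    expect_lt(max(abs(res$estimate)), 1e-12)
})
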