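test_that("sliding windows tile each chromosome from zero and truncate", {
    w <- makeWindows(c(chr1 = 100000), 50000, 10000)
    expect_equal(GenomicRanges::start(w) - 1L, seq(0L, 90000L, 10000L))
    expect_equal(max(GenomicRanges::end(w)), 100000L)
    ## short chromosome: single truncated window
    w2 <- makeWindows(c(chr1 = 30000), 50000, 10000)
    expect_equal(GenomicRanges::start(w2[1]) - 1L, 0L)
    expect_equal(GenomicRanges::end(w2[1]), 30000L)
    ## window == step gives a non-overlapping tiling covering every base
    w3 <- makeWindows(c(chr1 = 95000), 10000, 10000)
    expect_true(all(GenomicRanges::width(GenomicRanges::reduce(w3)) ==
                    sum(GenomicRanges::width(w3))))
    expect_equal(sum(GenomicRanges::width(w3)), 95000)
    expect_message(makeWindows(c(chr1 = 1000, chr0 = 0)), "chr0")
    expect_error(makeWindows(c(chr1 = 1000), window = 5, step = 10))
})

test_that("window counting uses half-open membership and class definitions", {
    spec <- toySpec()
    gt <- rbind(c("0/1", "0/0", "0/0", "0/1", "0/0", "0/0"),  # POLY_BOTH
                c("1/1", "1/1", "1/1", "0/0", "0/0", "0/0"),  # FIXED_A
                c("0/0", "0/0", "0/0", "1/1", "1/1", "1/1"))  # FIXED_B
    colnames(gt) <- c(paste0("A", 1:3), paste0("B", 1:3))
    ## positions: 10000 belongs to window [0,10000), 10001 to the next one
    sites <- makeSites(gt, pos = c(10000L, 10001L, 15000L))
    cl <- classifySites(sites, spec)
    w <- countWindowSites(cl, makeWindows(c(chr1 = 20000), 10000, 10000))
    m <- S4Vectors::mcols(w)
    expect_equal(m$P_A, c(1L, 0L))   # POLY_BOTH increments both P columns
    expect_equal(m$P_B, c(1L, 0L))
    expect_equal(m$F_A, c(0L, 1L))
    expect_equal(m$F_B, c(0L, 1L))
})

test_that("homogeneity test reproduces printed, degenerate and tiny tables", {
    ## published 2x2 coding-variant table
    expect_equal(homogeneityTest(1021, 1553, 2481, 4587), 4.239e-05,
                 tolerance = 1e-3)
    ## identical odds carry no signal
    expect_equal(homogeneityTest(10, 10, 10, 10), 1)
    ## [[3,0],[0,3]]: enumeration gives 2 * 1/C(6,3) = 0.1
    expect_equal(homogeneityTest(3, 0, 0, 3), 0.1)
    ## zero row or zero column -> p = 1 by convention
    expect_equal(homogeneityTest(0, 0, 5, 9), 1)
    expect_equal(homogeneityTest(0, 5, 0, 9), 1)
    ## chi-square route matches stats::chisq.test without correction
    expect_equal(homogeneityTest(12, 30, 5, 40, method = "chisq"),
                 suppressWarnings(chisq.test(matrix(c(12, 30, 5, 40), 2,
                                                    byrow = TRUE),
                                             correct = FALSE))$p.value)
    expect_error(homogeneityTest(-1, 2, 3, 4), "negative")
})

test_that("Fisher p equals exhaustive hypergeometric enumeration (small)", {
    for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
        if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
            next
        expect_equal(homogeneityTest(a, b, cc, d),
                     enumFisherP(a, b, cc, d), tolerance = 1e-9,
                     info = paste(a, b, cc, d))
    }
})

test_that("Bonferroni control multiplies by the tested-family size", {
    expect_equal(bonferroniAdjust(0.01), 0.01)
    expect_equal(bonferroniAdjust(c(0.001, 0.2)), c(0.002, 0.4))
    expect_equal(bonferroniAdjust(rep(1e-6, 1000)), rep(1e-3, 1000))
    ## NA (untested window) does not inflate the family
    expect_equal(bonferroniAdjust(c(0.01, NA)), c(0.01, NA))
    ## adjusted p is monotone in raw p (ties allowed at the cap of 1)
    p <- runif(50)
    expect_true(all(diff(bonferroniAdjust(p)[order(p)]) >= 0))
})

test_that("PASS calling selects directional significant windows and merges", {
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 40001, 100001, 200001),
                         c(50000, 90000, 150000, 250000)))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        P_A = c(2L, 2L, 2L, 5L), F_A = c(50L, 40L, 0L, 10L),
        P_B = c(30L, 30L, 30L, 5L), F_B = c(1L, 1L, 50L, 10L),
        p_raw = c(1e-9, 1e-8, 1e-9, 0.04),
        p_adj = c(4e-9, 4e-8, 4e-9, 0.16),
        tested = TRUE,
        direction_a = c(TRUE, TRUE, FALSE, FALSE))
    pass <- callPassRegions(gr, alpha = 0.05)
    ## overlapping selected windows merge into one region
    expect_equal(length(pass), 1L)
    expect_equal(GenomicRanges::start(pass), 1L)
    expect_equal(GenomicRanges::end(pass), 90000L)
    expect_equal(S4Vectors::mcols(pass)$n_windows, 2L)
    expect_equal(S4Vectors::mcols(pass)$min_p_adj, 4e-9)
    ## window 3 is significant but fails the direction rule (F_A < F_B)
    expect_error(callPassRegions(gr, alpha = 0), "alpha")
    ## a tie at alpha is not significant (strict inequality)
    gr2 <- gr[1]
    S4Vectors::mcols(gr2)$p_adj <- 0.05
    expect_equal(length(callPassRegions(gr2, alpha = 0.05)), 0L)
})

test_that("direction rule and p-values behave under population exchange", {
    spec <- toySpec()
    set.seed(11)
    gts <- c("0/0", "0/1", "1/1")
    gt <- matrix(sample(gts, 80 * 6, replace = TRUE), ncol = 6,
                 dimnames = list(NULL, c(paste0("A", 1:3), paste0("B", 1:3))))
    sites <- makeSites(gt, pos = sort(sample(1:50000, 80)))
    win <- makeWindows(c(chr1 = 50000), 20000, 10000)
    s1 <- scanWindows(countWindowSites(classifySites(sites, spec), win))
    s2 <- scanWindows(countWindowSites(
        classifySites(sites, swapPopulations(spec)), win))
    expect_equal(S4Vectors::mcols(s1)$p_raw, S4Vectors::mcols(s2)$p_raw)
    ## where the table is asymmetric, direction flips
    m1 <- S4Vectors::mcols(s1); m2 <- S4Vectors::mcols(s2)
    asym <- which(m1$F_A * m1$P_B != m1$F_B * m1$P_A)
    expect_true(all(!(m1$direction_a[asym] & m2$direction_a[asym])))
})

test_that("planted sweep windows carry the fixed-difference excess", {
    w <- defaultWorld()
    spec <- populationSpec(w$pops$samples$A, w$pops$samples$B)
    sites <- sitesFromPops(w$pops)
    cl <- classifySites(sites, spec)
    scan <- scanWindows(countWindowSites(cl,
        makeWindows(w$world$chromSizes)))
    insw <- GenomicRanges::countOverlaps(scan, w$truth@sweeps,
        type = "within") > 0
    m <- S4Vectors::mcols(scan)
    expect_gt(mean(m$F_A[insw]), 5 * mean(m$F_A[!insw]))
    ## merged PASS regions are disjoint and no longer than their windows
    pass <- callPassRegions(scan)
    expect_true(length(pass) >= 1)
    expect_true(all(GenomicRanges::width(GenomicRanges::reduce(pass)) ==
                    GenomicRanges::width(pass)))
})
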