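test_that("Tajima's D matches hand enumeration of the four-haplotype case", {
    sites <- fourHaplotypeSites()
    win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
    res <- windowTajimaD(sites, fourHapSpec(), win, population = "A")
    m <- S4Vectors::mcols(res)
    ## oracle: enumerate all 6 haplotype pairs explicitly
    haps <- c("AA", "AT", "AT", "TT")   # the two variant positions only
    pairs <- combn(4, 2)
    diffs <- apply(pairs, 2, function(ij)
        sum(strsplit(haps[ij[1]], "")[[1]] != strsplit(haps[ij[2]], "")[[1]]))
    thetaPi <- mean(diffs)
    expect_equal(m$S, 2L)
    expect_equal(m$n, 4L)
    expect_equal(m$theta_pi, thetaPi)                 # = 1, not 8/6
    a1 <- 1 + 1/2 + 1/3
    expect_equal(m$theta_w, 2 / a1)
    ## independent reconstruction of the variance constants (Tajima 1989)
    n <- 4
    a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    S <- 2
    expect_equal(m$D, (thetaPi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)))
    expect_true(m$defined)
})

test_that("Tajima's D is undefined without segregating sites and negative
           under a singleton-heavy spectrum", {
    spec <- populationSpec(paste0("A", 1:10), c("B1", "B2"),
                           minCalledA = 10, minCalledB = 2)
    win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
    ## monomorphic window
    gtMono <- matrix("0/0", 3, 12,
                     dimnames = list(NULL, c(paste0("A", 1:10), "B1", "B2")))
    resMono <- windowTajimaD(makeSites(gtMono, pos = c(10L, 20L, 30L)),
                             spec, win, "A")
    expect_false(S4Vectors::mcols(resMono)$defined)
    expect_true(is.na(S4Vectors::mcols(resMono)$D))
    ## every variant a singleton (one heterozygote) at n = 20 haplotypes
    gtSing <- matrix("0/0", 12, 12,
                     dimnames = list(NULL, c(paste0("A", 1:10), "B1", "B2")))
    for (i in 1:12) gtSing[i, (i %% 10) + 1] <- "0/1"
    resSing <- windowTajimaD(makeSites(gtSing, pos = 1:12 * 10L),
                             spec, win, "A")
    expect_lt(S4Vectors::mcols(resSing)$D, 0)
    ## sign of D equals the sign of theta_pi - theta_w
    m <- S4Vectors::mcols(resSing)
    expect_equal(sign(m$D), sign(m$theta_pi - m$theta_w))
    expect_gte(m$theta_pi, 0); expect_gte(m$theta_w, 0)
})

test_that("Weir-Cockerham Fst is 1 at opposite fixation, near 0 without
           differentiation, and the window estimate is a ratio of sums", {
    spec <- populationSpec(paste0("A", 1:10), paste0("B", 1:10),
                           minCalledA = 10, minCalledB = 10)
    samples <- c(paste0("A", 1:10), paste0("B", 1:10))
    win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
    ## complete opposite fixation
    gtFix <- matrix(rep(c("1/1", "0/0"), each = 10), 1, 20,
                    dimnames = list(NULL, samples))
    rFix <- windowWcFst(makeSites(gtFix, pos = 50L), spec, win)
    expect_equal(S4Vectors::mcols(rFix)$fst_weighted, 1)
    expect_equal(S4Vectors::mcols(rFix)$fst_mean, 1)
    ## identical allele frequency 0.5 in both populations, no heterozygotes
    gtHalf <- matrix(rep(c("1/1", "0/0"), 10), 1, 20,
                     dimnames = list(NULL, samples))
    rHalf <- windowWcFst(makeSites(gtHalf, pos = 50L), spec, win)
    expect_lte(S4Vectors::mcols(rHalf)$fst_mean, 0.05)
    ## mixed window: ratio of sums lies between the per-site estimates
    gtBoth <- rbind(gtFix, gtHalf)
    rBoth <- windowWcFst(makeSites(gtBoth, pos = c(50L, 60L)), spec, win)
    fw <- S4Vectors::mcols(rBoth)$fst_weighted
    expect_gt(fw, S4Vectors::mcols(rHalf)$fst_weighted)
    expect_lt(fw, 1)
    expect_equal(S4Vectors::mcols(rBoth)$n_sites, 2L)
    ## window with no usable site is flagged undefined
    gtNone <- matrix("0/0", 1, 20, dimnames = list(NULL, samples))
    rNone <- windowWcFst(makeSites(gtNone, pos = 50L), spec, win)
    expect_false(S4Vectors::mcols(rNone)$defined)
})

test_that("popgen statistics are invariant to sample relabeling within a
           population", {
    set.seed(99)
    samples <- c(paste0("A", 1:5), paste0("B", 1:5))
    spec <- populationSpec(paste0("A", 1:5), paste0("B", 1:5),
                           minCalledA = 4, minCalledB = 4)
    gt <- matrix(sample(c("0/0", "0/1", "1/1"), 40 * 10, replace = TRUE),
                 ncol = 10, dimnames = list(NULL, samples))
    pos <- sort(sample(1:20000, 40))
    win <- makeWindows(c(chr1 = 20000), 10000, 10000)
    perm <- c(sample(1:5), 5 + sample(1:5))
    gtPerm <- gt[, perm]
    colnames(gtPerm) <- samples
    for (fn in list(
        function(s) S4Vectors::mcols(windowTajimaD(s, spec, win, "A"))$D,
        function(s) S4Vectors::mcols(windowWcFst(s, spec, win))$fst_weighted))
        expect_equal(fn(makeSites(gt, pos = pos)),
                     fn(makeSites(gtPerm, pos = pos)))
})

test_that("fixed-variant density is per kb with truncated terminal windows", {
    spec <- toySpec()
    gtF <- matrix(rep(c("1/1", "0/0"), each = 3), 25, 6, byrow = TRUE,
                  dimnames = list(NULL, c(paste0("A", 1:3), paste0("B", 1:3))))
    sites <- makeSites(gtF, pos = seq(101L, by = 300L, length.out = 25))
    cl <- classifySites(sites, spec)
    win <- makeWindows(c(chr1 = 15000), 10000, 10000)  # [0,10k) + [10k,15k)
    d <- fixedDensity(cl, win)
    m <- S4Vectors::mcols(d)
    ## 33 sites? no: 25 sites at 300-bp spacing -> 33 would overflow; count
    inFirst <- sum(seq(101, by = 300, length.out = 25) <= 10000)
    expect_equal(m$fixed_count_a, c(inFirst, 25L - inFirst))
    expect_equal(m$density_a, c(inFirst / 10, (25 - inFirst) / 5))
    expect_equal(m$density_b, c(0, 0))
})

test_that("population A diversity is depressed inside planted sweeps", {
    w <- defaultWorld()
    spec <- populationSpec(w$pops$samples$A, w$pops$samples$B)
    sites <- sitesFromPops(w$pops)
    stw <- makeWindows(w$world$chromSizes, 10000, 10000)
    taj <- windowTajimaD(sites, spec, stw, "A")
    insw <- GenomicRanges::countOverlaps(taj, w$truth@sweeps) > 0
    m <- S4Vectors::mcols(taj)
    expect_lt(mean(m$D[insw], na.rm = TRUE), mean(m$D[!insw], na.rm = TRUE))
    ## fixed-difference density is likewise enriched in sweeps
    cl <- classifySites(sites, spec)
    dens <- fixedDensity(cl, stw)
    md <- S4Vectors::mcols(dens)
    expect_gt(mean(md$density_a[insw]), mean(md$density_a[!insw]))
})
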