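#' @importFrom GenomicRanges findOverlaps
NULL

## Tajima (1989) constants for n haploid sequences.
.tajimaConstants <- function(n) {
    stopifnot(n >= 2)
    i <- seq_len(n - 1)
    a1 <- sum(1 / i)
    a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
         e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

## Per-site per-population allele bookkeeping.  Returns, for the samples in
## `cols`: called diploid count, per-allele counts (sites x alleles matrix,
## alleles 0..K), and per-allele heterozygote-carrier counts (individuals
## with exactly one copy).
.alleleCounts <- function(a1, a2, cols, K) {
    a1 <- a1[, cols, drop = FALSE]
    a2 <- a2[, cols, drop = FALSE]
    called <- !is.na(a1) & !is.na(a2)
    a1[!called] <- NA_integer_
    a2[!called] <- NA_integer_
    cnt <- matrix(0L, nrow(a1), K + 1L)
    het <- matrix(0L, nrow(a1), K + 1L)
    for (k in 0:K) {
        isk1 <- a1 == k
        isk2 <- a2 == k
        cnt[, k + 1L] <- rowSums(isk1, na.rm = TRUE) +
                         rowSums(isk2, na.rm = TRUE)
        het[, k + 1L] <- rowSums(xor(isk1, isk2), na.rm = TRUE)
    }
    list(nCalled = as.integer(rowSums(called)), cnt = cnt, het = het)
}

.retainedIdx <- function(sites, spec) {
    a1 <- assay(sites, "allele1"); a2 <- assay(sites, "allele2")
    samp <- colnames(sites)
    cA <- match(spec@samplesA, samp); cB <- match(spec@samplesB, samp)
    calledA <- rowSums(!is.na(a1[, cA, drop = FALSE]) &
                       !is.na(a2[, cA, drop = FALSE]))
    calledB <- rowSums(!is.na(a1[, cB, drop = FALSE]) &
                       !is.na(a2[, cB, drop = FALSE]))
    calledA >= spec@minCalledA & calledB >= spec@minCalledB
}

#' Tajima's D in genomic windows for one population
#'
#' Computes the segregating-site count S, mean pairwise diversity
#' \eqn{\theta_\pi}, Watterson's \eqn{\theta_W = S/a_1} and the standardized
#' difference D per window, using the Tajima (1989) constants.  Sites failing
#' the two-population retention filter are dropped; the haploid sample size n
#' of a window is twice the minimum called-sample count across its retained
#' sites, and per-site heterozygosity uses the site's own called allele
#' frequencies.  Windows with S = 0 or n < 4 are flagged undefined and carry
#' \code{NA} for D.
#'
#' @param sites a [GenotypeSites-class].
#' @param spec a [PopulationSpec-class].
#' @param windows \code{GRanges}, e.g. the non-overlapping 10-kb tiling from
#'   [makeWindows()] with \code{window == step}.
#' @param population \code{"A"} or \code{"B"}.
#' @return \code{windows} with columns \code{S}, \code{n}, \code{theta_pi},
#'   \code{theta_w}, \code{D}, \code{defined}.
#' @references Tajima F (1989) Statistical method for testing the neutral
#'   mutation hypothesis by DNA polymorphism. Genetics 123:585-595.
#' @export
windowTajimaD <- function(sites, spec, windows, population = c("A", "B")) {
    population <- match.arg(population)
    a1m <- assay(sites, "allele1"); a2m <- assay(sites, "allele2")
    samp <- colnames(sites)
    cols <- match(if (population == "A") spec@samplesA else spec@samplesB,
                  samp)
    if (anyNA(cols)) stop("spec samples absent from genotypes")
    keep <- .retainedIdx(sites, spec)
    K <- max(1L, max(lengths(mcols(rowRanges(sites))$alt)))
    ac <- .alleleCounts(a1m, a2m, cols, K)
    hap <- 2L * ac$nCalled
    freqsq <- rowSums((ac$cnt / pmax(hap, 1L))^2)
    nAlleles <- rowSums(ac$cnt > 0L)
    seg <- nAlleles >= 2L
    usable <- keep & ac$nCalled > 0L
    ov <- findOverlaps(windows, granges(rowRanges(sites))[usable])
    widx <- S4Vectors::queryHits(ov)
    sidx <- which(usable)[S4Vectors::subjectHits(ov)]
    nw <- length(windows)
    S <- integer(nw); n <- integer(nw)
    tp <- numeric(nw); tw <- rep(NA_real_, nw); D <- rep(NA_real_, nw)
    defined <- logical(nw)
    for (w in unique(widx)) {
        si <- sidx[widx == w]
        nmin <- 2L * min(ac$nCalled[si])
        n[w] <- nmin
        S[w] <- sum(seg[si])
        if (S[w] == 0L || nmin < 4L) next
        const <- .tajimaConstants(nmin)
        piSite <- (1 - freqsq[si]) * nmin / (nmin - 1)
        tp[w] <- sum(piSite)
        tw[w] <- S[w] / const$a1
        denom <- sqrt(const$e1 * S[w] + const$e2 * S[w] * (S[w] - 1))
        D[w] <- (tp[w] - tw[w]) / denom
        defined[w] <- TRUE
    }
    mcols(windows)$S <- S
    mcols(windows)$n <- n
    mcols(windows)$theta_pi <- tp
    mcols(windows)$theta_w <- tw
    mcols(windows)$D <- D
    mcols(windows)$defined <- defined
    windows
}

## Weir & Cockerham (1984) per-site variance components for two populations,
## summed over alleles.  Inputs are per-site vectors/matrices for the two
## populations.  Returns per-site a and a+b+c.
.wcComponents <- function(nA, nB, cntA, cntB, hetA, hetB) {
    r <- 2
    nbar <- (nA + nB) / 2
    nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
    aSum <- numeric(length(nA))
    abcSum <- numeric(length(nA))
    K <- ncol(cntA)
    for (k in seq_len(K)) {
        pA <- cntA[, k] / (2 * nA)
        pB <- cntB[, k] / (2 * nB)
        hA <- hetA[, k] / nA
        hB <- hetB[, k] / nB
        pbar <- (nA * pA + nB * pB) / (r * nbar)
        s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
        hbar <- (nA * hA + nB * hB) / (r * nbar)
        a <- (nbar / nc) *
            (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                 (nbar - 1))
        b <- (nbar / (nbar - 1)) *
            (pbar * (1 - pbar) - (r - 1) / r * s2 -
                 (2 * nbar - 1) / (4 * nbar) * hbar)
        cc <- hbar / 2
        aSum <- aSum + a
        abcSum <- abcSum + a + b + cc
    }
    list(a = aSum, abc = abcSum)
}

#' Weir-Cockerham Fst in genomic windows
#'
#' Per-site Weir & Cockerham (1984) variance components between the two
#' populations, aggregated per window both as the ratio-of-sums ("weighted")
#' estimate \eqn{\sum a / \sum (a+b+c)} and as the mean of per-site estimates
#' over sites with a nonzero denominator.  Negative per-site estimates are
#' retained.  Sites need at least one called genotype in each population and
#' must pass the retention filter; windows with no usable polymorphic site
#' are flagged undefined.
#'
#' @inheritParams windowTajimaD
#' @return \code{windows} with columns \code{n_sites}, \code{fst_weighted},
#'   \code{fst_mean}, \code{defined}.
#' @references Weir BS, Cockerham CC (1984) Estimating F-statistics for the
#'   analysis of population structure. Evolution 38:1358-1370.
#' @export
windowWcFst <- function(sites, spec, windows) {
    a1m <- assay(sites, "allele1"); a2m <- assay(sites, "allele2")
    samp <- colnames(sites)
    cA <- match(spec@samplesA, samp); cB <- match(spec@samplesB, samp)
    keep <- .retainedIdx(sites, spec)
    K <- max(1L, max(lengths(mcols(rowRanges(sites))$alt)))
    acA <- .alleleCounts(a1m, a2m, cA, K)
    acB <- .alleleCounts(a1m, a2m, cB, K)
    usable <- keep & acA$nCalled > 0L & acB$nCalled > 0L
    ## pooled polymorphism: >= 2 alleles across both populations
    pooled <- acA$cnt + acB$cnt
    poly <- rowSums(pooled > 0L) >= 2L
    usable <- usable & poly
    comp <- .wcComponents(pmax(acA$nCalled, 1L), pmax(acB$nCalled, 1L),
                          acA$cnt, acB$cnt, acA$het, acB$het)
    ov <- findOverlaps(windows, granges(rowRanges(sites))[usable])
    widx <- S4Vectors::queryHits(ov)
    sidx <- which(usable)[S4Vectors::subjectHits(ov)]
    nw <- length(windows)
    nSites <- integer(nw)
    fw <- rep(NA_real_, nw); fm <- rep(NA_real_, nw)
    for (w in unique(widx)) {
        si <- sidx[widx == w]
        nSites[w] <- length(si)
        aS <- sum(comp$a[si]); abcS <- sum(comp$abc[si])
        if (abcS != 0) fw[w] <- aS / abcS
        ok <- comp$abc[si] != 0
        if (any(ok)) fm[w] <- mean(comp$a[si][ok] / comp$abc[si][ok])
    }
    mcols(windows)$n_sites <- nSites
    mcols(windows)$fst_weighted <- fw
    mcols(windows)$fst_mean <- fm
    mcols(windows)$defined <- nSites > 0L
    windows
}

#' Fixed-variant density per window
#'
#' Fixed variants per kb, per population, in (typically 10-kb) windows;
#' truncated terminal windows use their actual length.
#'
#' @param classes \code{GRanges} from [classifySites()].
#' @param windows non-overlapping \code{GRanges} windows.
#' @return \code{windows} with columns \code{fixed_count_a},
#'   \code{fixed_count_b}, \code{density_a}, \code{density_b} (per kb).
#' @export
fixedDensity <- function(classes, windows) {
    cls <- mcols(classes)$class
    fa <- countOverlaps(windows, classes[cls == "FIXED_A"])
    fb <- countOverlaps(windows, classes[cls == "FIXED_B"])
    kb <- width(windows) / 1000
    mcols(windows)$fixed_count_a <- fa
    mcols(windows)$fixed_count_b <- fb
    mcols(windows)$density_a <- fa / kb
    mcols(windows)$density_b <- fb / kb
    windows
}

#' Write a per-window statistic GRanges as TSV (0-based half-open)
#' @param gr windows with metadata columns.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeWindowTsv <- function(gr, path) {
    df <- cbind(data.frame(chrom = as.character(seqnames(gr)),
                           start = start(gr) - 1L, end = end(gr)),
                as.data.frame(mcols(gr)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    invisible(path)
}
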