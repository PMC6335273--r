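#' @importFrom GenomicRanges GRanges reduce findOverlaps countOverlaps
#' @importFrom stats fisher.test chisq.test p.adjust
NULL

#' Build sliding windows over a genome
#'
#' Windows are anchored at coordinate 0 on every chromosome and advance by
#' \code{step}; the final window(s) are truncated at the chromosome end, so
#' every base is covered.  With \code{window == step} this yields the
#' non-overlapping tiling used for the per-window statistics.
#'
#' @param chromSizes named numeric vector of chromosome lengths (bp).
#' @param window window length in bp (default 50000, the scan window).
#' @param step step size in bp (default 10000); must satisfy
#'   \code{window >= step > 0}.
#' @return A \code{GRanges} of windows (1-based closed coordinates internally;
#'   a window covering the 0-based half-open interval \[s, e) is stored as
#'   \code{start = s + 1, end = e}).  Zero-length chromosomes are skipped
#'   with a message.
#' @examples
#' makeWindows(c(chr1 = 100000), 50000, 10000)
#' @export
makeWindows <- function(chromSizes, window = 50000L, step = 10000L) {
    window <- as.integer(window); step <- as.integer(step)
    stopifnot(step > 0L, window >= step)
    if (is.null(names(chromSizes)) || any(names(chromSizes) == ""))
        stop("chromSizes must be a named vector")
    empty <- chromSizes <= 0
    if (any(empty)) {
        message("skipping zero-length chromosome(s): ",
                paste(names(chromSizes)[empty], collapse = ", "))
        chromSizes <- chromSizes[!empty]
    }
    parts <- lapply(names(chromSizes), function(chr) {
        L <- as.integer(chromSizes[[chr]])
        starts <- seq.int(0L, L - 1L, by = step)
        data.frame(chr = chr, start = starts + 1L,
                   end = pmin(starts + window, L))
    })
    df <- do.call(rbind, parts)
    GRanges(df$chr, IRanges(df$start, df$end),
            seqinfo = GenomeInfoDb::Seqinfo(names(chromSizes)))
}

#' Count fixed and polymorphic sites per window
#'
#' Fills each window's 2x2 scan quantities: \code{P_A} counts sites of class
#' \code{POLY_A_ONLY} or \code{POLY_BOTH}, \code{F_A} counts \code{FIXED_A};
#' symmetrically for B.  A site at 1-based position p belongs to the 0-based
#' half-open window \[s, e) iff s < p <= e, which is exactly the GRanges
#' overlap of the stored 1-based windows.
#'
#' @param classes \code{GRanges} from [classifySites()].
#' @param windows \code{GRanges} from [makeWindows()].
#' @return \code{windows} with metadata columns \code{P_A}, \code{F_A},
#'   \code{P_B}, \code{F_B}.
#' @export
countWindowSites <- function(classes, windows) {
    cls <- mcols(classes)$class
    cnt <- function(keep) {
        if (!any(keep)) return(integer(length(windows)))
        countOverlaps(windows, classes[keep])
    }
    mcols(windows)$P_A <- cnt(cls %in% c("POLY_A_ONLY", "POLY_BOTH"))
    mcols(windows)$F_A <- cnt(cls == "FIXED_A")
    mcols(windows)$P_B <- cnt(cls %in% c("POLY_B_ONLY", "POLY_BOTH"))
    mcols(windows)$F_B <- cnt(cls == "FIXED_B")
    windows
}

#' HKA-style homogeneity test on one window's 2x2 table
#'
#' Tests the null that the polymorphic-to-fixed ratio is the same in both
#' populations, on the table \code{[[F_A, P_A], [F_B, P_B]]}.  Tables with a
#' zero row or zero column carry no information about the ratio and return
#' p = 1.
#'
#' @param fA,pA,fB,pB nonnegative counts (vectorized).
#' @param method \code{"fisher"} (two-sided exact, default) or \code{"chisq"}
#'   (Pearson chi-square without continuity correction).
#' @return numeric vector of two-sided p-values.
#' @examples
#' homogeneityTest(1021, 1553, 2481, 4587)   # 4.24e-05
#' @export
homogeneityTest <- function(fA, pA, fB, pB, method = c("fisher", "chisq")) {
    method <- match.arg(method)
    if (any(c(fA, pA, fB, pB) < 0)) stop("negative counts")
    n <- length(fA)
    stopifnot(length(pA) == n, length(fB) == n, length(pB) == n)
    p <- numeric(n)
    degenerate <- (fA + pA == 0) | (fB + pB == 0) |
                  (fA + fB == 0) | (pA + pB == 0)
    p[degenerate] <- 1
    for (i in which(!degenerate)) {
        tab <- matrix(c(fA[i], pA[i], fB[i], pB[i]), nrow = 2, byrow = TRUE)
        p[i] <- if (method == "fisher")
            stats::fisher.test(tab)$p.value
        else
            suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    pmin(p, 1)
}

#' Scan windows: test, adjust, flag direction
#'
#' Runs [homogeneityTest()] on every window with a non-degenerate table,
#' Bonferroni-adjusts over the number of \emph{tested} windows (degenerate
#' zero-margin tables are excluded from the family), and computes the
#' directionality flag for excess fixation in population A:
#' \code{F_A * P_B > F_B * P_A} (odds ratio toward A) and
#' \code{F_A > minFRatio * F_B}.
#'
#' @param windowCounts \code{GRanges} from [countWindowSites()].
#' @param method test method, see [homogeneityTest()].
#' @param minFRatio required fold excess of \code{F_A} over \code{F_B}
#'   (default 1, i.e. plain \code{F_A > F_B}).
#' @return the input with added columns \code{p_raw}, \code{p_adj},
#'   \code{tested}, \code{direction_a}.
#' @export
scanWindows <- function(windowCounts, method = c("fisher", "chisq"),
                        minFRatio = 1) {
    method <- match.arg(method)
    m <- mcols(windowCounts)
    tested <- (m$F_A + m$P_A > 0) & (m$F_B + m$P_B > 0) &
              (m$F_A + m$F_B > 0) & (m$P_A + m$P_B > 0)
    p <- rep(NA_real_, length(windowCounts))
    p[tested] <- homogeneityTest(m$F_A[tested], m$P_A[tested],
                                 m$F_B[tested], m$P_B[tested], method = method)
    padj <- stats::p.adjust(p, method = "bonferroni")   # m = # non-NA
    mcols(windowCounts)$p_raw <- p
    mcols(windowCounts)$p_adj <- padj
    mcols(windowCounts)$tested <- tested
    mcols(windowCounts)$direction_a <-
        (m$F_A * m$P_B > m$F_B * m$P_A) & (m$F_A > minFRatio * m$F_B)
    windowCounts
}

#' Bonferroni adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "bonferroni")}: each
#' p-value is multiplied by the number of (non-missing) tests and capped at 1.
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed; NAs are not
#'   counted in the family size).
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(p) stats::p.adjust(p, method = "bonferroni")

#' Call PASS regions from scanned windows
#'
#' Selects windows with \code{p_adj < alpha} (strict) and \code{direction_a},
#' then merges selected windows per chromosome when they overlap or abut
#' (bookended merging at distance 0, bedtools-merge semantics), recording the
#' number of merged windows and the smallest adjusted p.
#'
#' @param scanned \code{GRanges} from [scanWindows()].
#' @param alpha family-wise significance level in (0, 1\] (default 0.05).
#' @return \code{GRanges} of disjoint PASS regions with columns
#'   \code{n_windows} and \code{min_p_adj}.
#' @export
callPassRegions <- function(scanned, alpha = 0.05) {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
        stop("alpha must be in (0, 1]")
    m <- mcols(scanned)
    sel <- !is.na(m$p_adj) & m$p_adj < alpha & m$direction_a
    hits <- scanned[sel]
    if (length(hits) == 0L) {
        out <- GRanges()
        mcols(out) <- DataFrame(n_windows = integer(), min_p_adj = numeric())
        return(out)
    }
    red <- reduce(hits, min.gapwidth = 1L, with.revmap = TRUE)
    rv <- mcols(red)$revmap
    mcols(red) <- DataFrame(
        n_windows = lengths(rv),
        min_p_adj = vapply(rv, function(i) min(mcols(hits)$p_adj[i]),
                           numeric(1)))
    red
}

#' Write scan windows as TSV (0-based half-open coordinates)
#' @param scanned \code{GRanges} from [scanWindows()].
#' @param path output file.
#' @param alpha significance level used for the \code{selected} column.
#' @return \code{path}, invisibly.
#' @export
writeWindowStats <- function(scanned, path, alpha = 0.05) {
    m <- mcols(scanned)
    df <- data.frame(chrom = as.character(seqnames(scanned)),
                     start = start(scanned) - 1L, end = end(scanned),
                     P_A = m$P_A, F_A = m$F_A, P_B = m$P_B, F_B = m$F_B,
                     p_raw = m$p_raw, p_adj = m$p_adj,
                     selected = !is.na(m$p_adj) & m$p_adj < alpha &
                         m$direction_a)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
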