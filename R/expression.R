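#' @importFrom stats sd pt p.adjust
NULL

#' TPM normalization
#'
#' Transcripts per kilobase of exon model per million mapped reads: per
#' sample, each gene's count is divided by its effective length in kb and the
#' resulting rates are rescaled to sum to one million.
#'
#' @param counts genes x samples matrix of raw read counts.
#' @param lengths per-gene effective lengths in bp (recycled by name when
#'   named, else by position).
#' @return matrix of TPM values; every column sums to 1e6 except all-zero
#'   samples, which stay all-zero with a warning.
#' @examples
#' tpmNormalize(matrix(c(10, 10), 2, 1), c(1000, 2000))
#' @export
tpmNormalize <- function(counts, lengths) {
    counts <- as.matrix(counts)
    if (!is.null(names(lengths)) && !is.null(rownames(counts)))
        lengths <- lengths[rownames(counts)]
    stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
    rate <- counts / (lengths / 1000)
    tot <- colSums(rate)
    zero <- tot == 0
    if (any(zero)) {
        warning("all-zero sample column(s): ",
                paste(colnames(counts)[zero], collapse = ", "))
        tot[zero] <- 1
    }
    sweep(rate, 2, tot, "/") * 1e6
}

#' Bayes-regularized paired t-test (Cyber-T style)
#'
#' For each gene, paired differences \eqn{d_i = case_i - control_i} give a
#' mean m and sample SD s.  A background SD \eqn{\sigma_0} is the running
#' mean of s over \code{window} genes ranked by mean expression, pooling
#' information across similarly expressed genes.  The posterior SD
#' \deqn{\sigma_p^2 = (v_0 \sigma_0^2 + (n-1) s^2) / (v_0 + n - 1)}
#' shrinks s toward \eqn{\sigma_0} with \eqn{v_0} pseudo-observations, and
#' \eqn{t = m / (\sigma_p/\sqrt{n})} is referred to a t distribution with
#' \eqn{v_0 + n - 1} degrees of freedom.  With \code{v0 = 0} this is exactly
#' the classical paired t-test.
#'
#' @param case,control genes x pairs matrices on the testing scale
#'   (conventionally \code{log2(TPM + 1)}); columns are paired by position.
#' @param v0 prior degrees of freedom (pseudo-observations) for the
#'   background variance; default 10.
#' @param window running-average window (genes) for the background SD;
#'   default 101, truncated symmetrically at the ends.
#' @return \code{data.frame} with gene, n, mean_diff, sd, sd_bg, t_reg, df,
#'   p, q (Benjamini-Hochberg over the input genes).
#' @export
cyberTPaired <- function(case, control, v0 = 10, window = 101) {
    case <- as.matrix(case); control <- as.matrix(control)
    stopifnot(all(dim(case) == dim(control)))
    n <- ncol(case)
    if (n < 2) stop("need at least 2 pairs")
    if (v0 < 0) stop("v0 must be >= 0")
    d <- case - control
    m <- rowMeans(d)
    s <- apply(d, 1, stats::sd)
    ## background SD: running mean of s over genes ranked by mean expression
    expr <- rowMeans((case + control) / 2)
    ord <- order(expr)
    half <- max(0L, (as.integer(window) - 1L) %/% 2L)
    ng <- nrow(case)
    sOrd <- s[ord]
    s0Ord <- vapply(seq_len(ng), function(i) {
        lo <- max(1L, i - half); hi <- min(ng, i + half)
        mean(sOrd[lo:hi])
    }, numeric(1))
    s0 <- numeric(ng)
    s0[ord] <- s0Ord
    sigma2 <- (v0 * s0^2 + (n - 1) * s^2) / (v0 + n - 1)
    df <- v0 + n - 1
    t <- ifelse(sigma2 > 0, m / (sqrt(sigma2) / sqrt(n)), 0)
    p <- 2 * stats::pt(-abs(t), df = df)
    data.frame(gene = if (is.null(rownames(case))) as.character(seq_len(ng))
                      else rownames(case),
               n = n, mean_diff = m, sd = s, sd_bg = s0,
               t_reg = t, df = df, p = p,
               q = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Wrapper over \code{stats::p.adjust(method = "BH")}.
#' @param p p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Per-stage differential expression on a paired design
#'
#' Runs [cyberTPaired()] on \code{log2(TPM + 1)} separately for each stage
#' and flags a gene differentially expressed when \code{q < fdr} at any
#' stage.
#'
#' @param counts genes x samples raw count matrix.
#' @param lengths per-gene lengths (bp).
#' @param pairing \code{data.frame} with columns \code{case}, \code{control},
#'   \code{stage}: sample column names paired within stage.
#' @param v0,window see [cyberTPaired()].
#' @param fdr FDR threshold (default 0.05).
#' @param log2Transform test on \code{log2(TPM + 1)} (default) or raw TPM.
#' @return list with \code{perStage} (named list of per-stage tables) and
#'   \code{deGenes} (genes with q < fdr at any stage).
#' @export
differentialExpression <- function(counts, lengths, pairing, v0 = 10,
                                   window = 101, fdr = 0.05,
                                   log2Transform = TRUE) {
    stopifnot(all(c("case", "control", "stage") %in% colnames(pairing)))
    tpm <- tpmNormalize(counts, lengths)
    x <- if (log2Transform) log2(tpm + 1) else tpm
    perStage <- lapply(split(pairing, pairing$stage), function(pp) {
        cyberTPaired(x[, pp$case, drop = FALSE],
                     x[, pp$control, drop = FALSE],
                     v0 = v0, window = window)
    })
    de <- sort(unique(unlist(lapply(perStage, function(tab)
        tab$gene[tab$q < fdr]))))
    list(perStage = perStage, deGenes = de)
}

#' Integrate SAAC, PASS and expression evidence into candidate genes
#'
#' PASS genes are the SAAC genes whose span overlaps a PASS region by at
#' least 1 bp; candidates are
#' \code{marked} \eqn{\cap} \code{saac} \eqn{\cap} (\code{pass}
#' \eqn{\cup} \code{de}).
#'
#' @param saacGenes character, SAAC gene IDs of the selected population.
#' @param passRegions \code{GRanges} of PASS regions.
#' @param geneRanges \code{GRanges} of gene spans, named by gene ID (or with
#'   a \code{gene_id} metadata column).
#' @param deGenes character, differentially expressed gene IDs.
#' @param markedGenes character, pathway-marked genes of interest.
#' @return list with \code{passGenes}, \code{deGenes}, \code{candidates}.
#'   SAAC genes lacking a location are excluded from \code{passGenes} with a
#'   warning.
#' @export
integrateCandidates <- function(saacGenes, passRegions, geneRanges, deGenes,
                                markedGenes) {
    ids <- if (!is.null(mcols(geneRanges)$gene_id))
        as.character(mcols(geneRanges)$gene_id) else names(geneRanges)
    located <- saacGenes[saacGenes %in% ids]
    if (length(located) < length(saacGenes))
        warning("SAAC gene(s) without location: ",
                paste(setdiff(saacGenes, located), collapse = ", "))
    gr <- geneRanges[match(located, ids)]
    hit <- countOverlaps(gr, passRegions, ignore.strand = TRUE) > 0L
    passGenes <- located[hit]
    candidates <- intersect(markedGenes,
                            intersect(saacGenes, union(passGenes, deGenes)))
    list(passGenes = sort(passGenes),
         deGenes = sort(intersect(deGenes, saacGenes)),
         candidates = sort(candidates))
}
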