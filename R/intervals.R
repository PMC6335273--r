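#' @importFrom GenomicRanges intersect reduce
NULL

#' Read a BED file of regions
#'
#' BED input is 0-based half-open on disk; ranges come back 1-based closed as
#' usual for \code{GRanges}.  RGD-style 1-based inclusive interval tables can
#' be read with \code{oneBased = TRUE} (3-column TSV chrom/start/end plus an
#' optional name column).
#'
#' @param path BED (or TSV when \code{oneBased}) file.
#' @param oneBased treat the file as 1-based inclusive TSV instead of BED.
#' @return a \code{GRanges}.
#' @export
readRegions <- function(path, oneBased = FALSE) {
    if (!oneBased) return(rtracklayer::import(path, format = "BED"))
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("malformed interval file: ", path)
    bad <- which(!(df[[2]] <= df[[3]]))
    if (length(bad) > 0L)
        stop("malformed interval at line ", bad[1L], " of ", path)
    gr <- GRanges(df[[1]], IRanges(df[[2]], df[[3]]))
    if (ncol(df) >= 4L) mcols(gr)$name <- df[[4]]
    gr
}

#' Write regions as BED6
#'
#' @param regions \code{GRanges}; a \code{min_p_adj} column, if present, is
#'   exported as the BED score \code{-log10(min_p_adj)} capped at 1000, and
#'   names default to \code{PASS_1..n}.
#' @param path output BED path.
#' @param namePrefix prefix for auto-generated names.
#' @return \code{path}, invisibly.
#' @export
writeRegionsBed <- function(regions, path, namePrefix = "PASS") {
    score <- if (!is.null(mcols(regions)$min_p_adj))
        pmin(1000, -log10(pmax(mcols(regions)$min_p_adj, 1e-300)))
    else rep(0, length(regions))
    df <- data.frame(chrom = as.character(seqnames(regions)),
                     start = start(regions) - 1L, end = end(regions),
                     name = paste0(namePrefix, "_", seq_along(regions)),
                     score = round(score, 4), strand = ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Merge regions (bedtools-merge semantics)
#'
#' Unions intervals that overlap or lie within \code{distance} bp of each
#' other; the default distance 0 merges bookended intervals.
#'
#' @param regions \code{GRanges}.
#' @param distance maximum gap (bp) to bridge.
#' @return merged, sorted, disjoint \code{GRanges}.
#' @export
mergeRegions <- function(regions, distance = 0L) {
    reduce(GenomicRanges::sort(regions), min.gapwidth = distance + 1L)
}

#' Overlap summary between two merged region sets
#'
#' @param a,b \code{GRanges}; merged internally for safety.
#' @return list with \code{overlap_bp} (total intersected bases),
#'   \code{frac_a_covered} (overlap / total bases of \code{a}) and
#'   \code{n_b_hit} (number of \code{b} intervals with >= 1 bp overlap).
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' intersectSummary(a, b)   # 50 bp, half of a, 1 interval hit
#' @export
intersectSummary <- function(a, b) {
    am <- mergeRegions(a); bm <- mergeRegions(b)
    ov <- suppressWarnings(GenomicRanges::intersect(am, bm,
                                                    ignore.strand = TRUE))
    list(overlap_bp = sum(as.numeric(width(ov))),
         frac_a_covered = if (length(am) == 0L) NA_real_
             else sum(as.numeric(width(ov))) / sum(as.numeric(width(am))),
         n_b_hit = sum(countOverlaps(bm, am, ignore.strand = TRUE) > 0L))
}
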