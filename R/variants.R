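#' @importFrom VariantAnnotation readVcf ScanVcfParam geno ref alt
#' @importFrom Biostrings DNAStringSet
#' @importFrom GenomeInfoDb seqnames seqlevels
NULL

.SITE_CLASSES <- c("FIXED_A", "FIXED_B", "POLY_A_ONLY", "POLY_B_ONLY",
                   "POLY_BOTH", "SHARED_FIXED_ALT", "MONOMORPHIC_REF",
                   "UNINFORMATIVE")

#' Site classification levels
#'
#' The eight mutually exclusive classes a retained site can take:
#' fixed difference in A or B (one population homozygous for a single
#' alternate allele while the other matches the reference), polymorphic in
#' one or both populations, shared fixed alternate, monomorphic reference,
#' or uninformative (retention filter failed, or both populations fixed for
#' different alternate alleles).
#' @return character vector of class levels, in canonical order.
#' @export
siteClassLevels <- function() .SITE_CLASSES

## Parse a character GT matrix into two integer allele matrices.
## Works on the (small) set of distinct GT strings, so cost is independent
## of matrix size beyond one match().
.parseGT <- function(gt) {
    u <- unique(as.vector(gt))
    pieces <- strsplit(u, "[/|]")
    npieces <- lengths(pieces)
    bad <- npieces != 2L
    if (any(bad))
        stop("non-diploid genotype encountered: '", u[bad][1L],
             "' (ploidy 2 required)")
    toInt <- function(k) {
        v <- vapply(pieces, `[`, character(1), k)
        v[v == "."] <- NA_character_
        as.integer(v)
    }
    u1 <- toInt(1L); u2 <- toInt(2L)
    idx <- match(gt, u)
    dim(idx) <- dim(gt)
    a1 <- u1[idx]; dim(a1) <- dim(gt); dimnames(a1) <- dimnames(gt)
    a2 <- u2[idx]; dim(a2) <- dim(gt); dimnames(a2) <- dimnames(gt)
    list(a1 = a1, a2 = a2)
}

#' Read genotypes of a multi-sample VCF
#'
#' Loads a VCF 4.x file (plain or bgzipped) into a [GenotypeSites-class]
#' container: one row per record (multiallelic records stay unsplit), one
#' column per sample, with integer allele assays.  Genotypes must be diploid;
#' half-missing calls count as missing.
#'
#' @param vcfPath path to the VCF file.
#' @param spec optional [PopulationSpec-class]; when given, all its samples
#'   must be present in the VCF header (a missing sample is a configuration
#'   error) and columns are restricted to them.
#' @param snvOnly if \code{TRUE}, records whose REF or any ALT allele is not a
#'   single base are dropped.
#' @param genome genome label recorded on the ranges (cosmetic).
#' @return A [GenotypeSites-class] object, rows in file order
#'   (coordinate-sorted input is enforced).
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "sweepHKA")
#' gs <- readGenotypeSites(vcf)
#' dim(gs)
#' @export
readGenotypeSites <- function(vcfPath, spec = NULL, snvOnly = FALSE,
                              genome = "toy") {
    if (!file.exists(vcfPath))
        stop("VCF file not found: ", vcfPath)
    vcf <- suppressWarnings(VariantAnnotation::readVcf(vcfPath, genome = genome))
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt))
        stop("VCF has no GT genotype field: ", vcfPath)
    if (!is.null(spec)) {
        want <- c(spec@samplesA, spec@samplesB)
        missing <- setdiff(want, colnames(gt))
        if (length(missing) > 0L)
            stop("sample(s) missing from VCF header: ",
                 paste(missing, collapse = ", "))
        gt <- gt[, want, drop = FALSE]
    }
    rr <- SummarizedExperiment::rowRanges(vcf)
    ## enforce coordinate order within each chromosome block
    pos <- start(rr)
    chr <- as.character(seqnames(rr))
    ooo <- which(chr[-1] == chr[-length(chr)] & diff(pos) < 0)
    if (length(ooo) > 0L)
        stop("VCF not coordinate-sorted; first out-of-order record at ",
             chr[ooo[1L] + 1L], ":", pos[ooo[1L] + 1L])
    refs <- as.character(ref(vcf))
    alts <- as(alt(vcf), "CharacterList")
    altOk <- vapply(as.list(alts), function(z) all(nchar(z) == 1L),
                    logical(1))
    isSNV <- nchar(refs) == 1L & altOk
    gr <- granges(rr, use.mcols = FALSE)
    names(gr) <- NULL
    mcols(gr) <- DataFrame(ref = refs, alt = alts, isSNV = as.logical(isSNV))
    al <- .parseGT(gt)
    out <- SummarizedExperiment(
        assays = SimpleList(allele1 = al$a1, allele2 = al$a2),
        rowRanges = gr)
    out <- new("GenotypeSites", out)
    if (snvOnly) out <- out[mcols(rowRanges(out))$isSNV, ] else out
}

## Per-population per-site summary: called count, min and max allele index
## among called samples (NA when no sample called), any-heterozygote flag.
.popSummary <- function(a1, a2, cols) {
    a1 <- a1[, cols, drop = FALSE]
    a2 <- a2[, cols, drop = FALSE]
    called <- !is.na(a1) & !is.na(a2)
    ## mask half-called entries entirely
    a1[!called] <- NA_integer_
    a2[!called] <- NA_integer_
    df <- c(as.data.frame(a1), as.data.frame(a2))
    mins <- suppressWarnings(do.call(pmin, c(df, na.rm = TRUE)))
    maxs <- suppressWarnings(do.call(pmax, c(df, na.rm = TRUE)))
    list(nCalled = as.integer(rowSums(called)), min = mins, max = maxs)
}

#' Classify sites as fixed or polymorphic per population
#'
#' Applies the per-population retention filter and assigns every site exactly
#' one class.  A population is \emph{fixed-alt} when every called sample is
#' homozygous for the same single alternate allele, \emph{fixed-ref} when all
#' are homozygous reference, and \emph{polymorphic} when two or more alleles
#' segregate among its called samples.  \code{FIXED_A} requires A fixed-alt
#' and B fixed-ref (i.e. B matches the reference), symmetrically for
#' \code{FIXED_B}.  Two populations fixed for different alternate alleles do
#' not fit either fixed-difference definition and fall into
#' \code{UNINFORMATIVE}, as do sites failing the retention filter.
#'
#' @param sites a [GenotypeSites-class].
#' @param spec a [PopulationSpec-class]; all its samples must be columns of
#'   \code{sites}, and at least one is required.
#' @return A \code{GRanges}, one range per input site, with metadata columns
#'   \code{class} (factor over [siteClassLevels()]), \code{nCalledA},
#'   \code{nCalledB}.
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "sweepHKA")
#' spec <- populationSpec(paste0("A", 1:3), paste0("B", 1:3),
#'                        minCalledA = 2, minCalledB = 2)
#' classifySites(readGenotypeSites(vcf, spec), spec)
#' @export
classifySites <- function(sites, spec) {
    stopifnot(is(sites, "GenotypeSites"), is(spec, "PopulationSpec"))
    samp <- colnames(sites)
    miss <- setdiff(c(spec@samplesA, spec@samplesB), samp)
    if (length(miss) > 0L)
        stop("spec sample(s) absent from genotypes: ",
             paste(miss, collapse = ", "))
    if (length(spec@samplesA) + length(spec@samplesB) == 0L)
        stop("PopulationSpec has no samples")
    a1 <- assay(sites, "allele1")
    a2 <- assay(sites, "allele2")
    A <- .popSummary(a1, a2, match(spec@samplesA, samp))
    B <- .popSummary(a1, a2, match(spec@samplesB, samp))
    n <- nrow(sites)
    cls <- rep("UNINFORMATIVE", n)
    keep <- A$nCalled >= spec@minCalledA & B$nCalled >= spec@minCalledB
    fixA  <- keep & A$min == A$max
    fixB  <- keep & B$min == B$max
    fixAr <- fixA & A$min == 0L; fixAa <- fixA & A$min >= 1L
    fixBr <- fixB & B$min == 0L; fixBa <- fixB & B$min >= 1L
    polyA <- keep & A$min < A$max
    polyB <- keep & B$min < B$max
    cls[polyA & !polyB] <- "POLY_A_ONLY"
    cls[polyB & !polyA] <- "POLY_B_ONLY"
    cls[polyA & polyB]  <- "POLY_BOTH"
    cls[fixAa & fixBr]  <- "FIXED_A"
    cls[fixBa & fixAr]  <- "FIXED_B"
    cls[fixAa & fixBa & A$min == B$min] <- "SHARED_FIXED_ALT"
    cls[fixAr & fixBr]  <- "MONOMORPHIC_REF"
    ## fixAa & fixBa with different alleles stays UNINFORMATIVE
    out <- granges(rowRanges(sites), use.mcols = FALSE)
    mcols(out) <- DataFrame(
        class = factor(cls, levels = .SITE_CLASSES),
        nCalledA = A$nCalled, nCalledB = B$nCalled)
    out
}

#' Tally site classes
#'
#' @param classes the \code{GRanges} returned by [classifySites()], or a
#'   factor/character of classes.
#' @return named integer vector over all of [siteClassLevels()] (zeroes kept);
#'   sums to the number of input sites.
#' @export
siteClassTally <- function(classes) {
    if (is(classes, "GRanges")) classes <- mcols(classes)$class
    table(factor(classes, levels = .SITE_CLASSES))
}

#' Write a site-class table as TSV
#'
#' Columns: chrom, pos (1-based), class.
#' @param classes \code{GRanges} from [classifySites()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSiteClasses <- function(classes, path) {
    df <- data.frame(chrom = as.character(seqnames(classes)),
                     pos = start(classes),
                     class = as.character(mcols(classes)$class))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
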