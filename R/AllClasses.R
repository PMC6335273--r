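#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges assay assays
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#' @importFrom IRanges IRanges CharacterList
NULL

#' Two-population design with call-count retention thresholds
#'
#' Describes which VCF samples belong to each inbred population and how many
#' called genotypes per population a site must have to be retained.  The
#' defaults (10 of 12 in population A, 9 of 11 in population B) mirror a
#' GK-vs-Wistar rat design where a handful of lower-coverage animals are
#' tolerated per site.
#'
#' @slot nameA,nameB single-character population labels.
#' @slot samplesA,samplesB character vectors of sample IDs (disjoint).
#' @slot minCalledA,minCalledB minimum number of samples with a fully called
#'   diploid genotype for the site to be informative.
#' @export
setClass("PopulationSpec", representation(
    nameA = "character", nameB = "character",
    samplesA = "character", samplesB = "character",
    minCalledA = "integer", minCalledB = "integer"
))

setValidity("PopulationSpec", function(object) {
    msg <- NULL
    if (length(intersect(object@samplesA, object@samplesB)) > 0L)
        msg <- c(msg, "samplesA and samplesB must be disjoint")
    if (anyDuplicated(object@samplesA) || anyDuplicated(object@samplesB))
        msg <- c(msg, "duplicated sample IDs within a population")
    if (object@minCalledA < 1L || object@minCalledA > length(object@samplesA))
        msg <- c(msg, "minCalledA must be in [1, length(samplesA)]")
    if (object@minCalledB < 1L || object@minCalledB > length(object@samplesB))
        msg <- c(msg, "minCalledB must be in [1, length(samplesB)]")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PopulationSpec
#'
#' @param samplesA,samplesB sample IDs of the two populations.
#' @param nameA,nameB population labels (default "A"/"B").
#' @param minCalledA,minCalledB per-population retention thresholds: a site is
#'   classified only if at least this many samples have a called (non-missing)
#'   diploid genotype.  Defaults are 10 and 9, matching a 12 + 11 sample
#'   design.
#' @return A [PopulationSpec-class] object.
#' @examples
#' populationSpec(paste0("A", 1:12), paste0("B", 1:11))
#' @export
populationSpec <- function(samplesA, samplesB, nameA = "A", nameB = "B",
                           minCalledA = min(10L, length(samplesA)),
                           minCalledB = min(9L, length(samplesB))) {
    new("PopulationSpec", nameA = nameA, nameB = nameB,
        samplesA = as.character(samplesA), samplesB = as.character(samplesB),
        minCalledA = as.integer(minCalledA), minCalledB = as.integer(minCalledB))
}

#' Swap the two populations of a PopulationSpec
#'
#' Utility for symmetry checks: population B becomes A and vice versa,
#' thresholds travelling with their samples.
#' @param spec a [PopulationSpec-class].
#' @return A [PopulationSpec-class] with A and B exchanged.
#' @export
swapPopulations <- function(spec) {
    new("PopulationSpec", nameA = spec@nameB, nameB = spec@nameA,
        samplesA = spec@samplesB, samplesB = spec@samplesA,
        minCalledA = spec@minCalledB, minCalledB = spec@minCalledA)
}

setMethod("show", "PopulationSpec", function(object) {
    cat("PopulationSpec:", object@nameA, sprintf("(%d samples, min called %d)",
        length(object@samplesA), object@minCalledA),
        "vs", object@nameB, sprintf("(%d samples, min called %d)\n",
        length(object@samplesB), object@minCalledB))
})

#' Multi-sample genotypes at variant sites
#'
#' A \linkS4class{RangedSummarizedExperiment} holding one row per VCF locus
#' and one column per sample, with two integer assays \code{allele1} and
#' \code{allele2} (0 = reference, k = k-th alternate, \code{NA} = missing).
#' Row ranges carry \code{ref}, \code{alt} (a CharacterList) and
#' \code{isSNV}.
#'
#' @export
setClass("GenotypeSites", contains = "RangedSummarizedExperiment")

setValidity("GenotypeSites", function(object) {
    msg <- NULL
    if (!all(c("allele1", "allele2") %in% names(assays(object))))
        msg <- c(msg, "assays must contain 'allele1' and 'allele2'")
    if (!all(c("ref", "alt") %in% names(mcols(rowRanges(object)))))
        msg <- c(msg, "rowRanges mcols must contain 'ref' and 'alt'")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn GenotypeSites number of variant sites.
#' @param x,object a GenotypeSites.
#' @export
setMethod("show", "GenotypeSites", function(object) {
    cat(class(object), "with", nrow(object), "sites x", ncol(object),
        "samples\n")
    callNextMethod()
})

#' Ground truth of a simulated two-population world
#'
#' Bundles the planted sweep intervals, the pre-noise class of every variant
#' site, the planted differentially expressed genes and the per-population
#' planted amino-acid-changing genes, together with the seed and configuration
#' used, so that recovery can be scored exactly.
#'
#' @slot sweeps a \code{GRanges} of planted sweep intervals.
#' @slot siteClass a \code{GRanges} of all simulated sites with the planted
#'   (pre-noise) class in \code{mcols()$class}.
#' @slot deGenes character, planted differentially expressed gene IDs.
#' @slot saacGenesA,saacGenesB character, genes planted with amino-acid
#'   changing fixed variants private to each population.
#' @slot config the \code{list} configuration used.
#' @export
setClass("SweepTruthSet", representation(
    sweeps = "GRanges", siteClass = "GRanges",
    deGenes = "character", saacGenesA = "character", saacGenesB = "character",
    config = "list"
))

setMethod("show", "SweepTruthSet", function(object) {
    cat("SweepTruthSet:", length(object@sweeps), "planted sweeps,",
        length(object@siteClass), "sites,",
        length(object@deGenes), "DE genes\n")
})
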