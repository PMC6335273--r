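## One default simulated world shared across test files (built lazily once).
.worldCache <- new.env(parent = emptyenv())

defaultWorld <- function() {
    if (is.null(.worldCache$w)) {
        dir <- file.path(tempdir(), "sweepHKA-world")
        .worldCache$w <- simulateWorld(simConfig(seed = 1L), dir = dir)
    }
    .worldCache$w
}

## GenotypeSites straight from simulated genotype matrices (no VCF round
## trip), for tests that only need the analysis path.
sitesFromPops <- function(pops) {
    al <- sweepHKA:::.parseGT(pops$gt)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(allele1 = al$a1, allele2 = al$a2),
        rowRanges = pops$sites)
    methods::new("GenotypeSites", se)
}
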