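## Build a GenotypeSites object directly from a character genotype matrix
## ("0/0", "0/1", "1/1", "./.", ...), bypassing VCF I/O.
makeSites <- function(gt, pos = seq_len(nrow(gt)) * 100L, chrom = "chr1",
                      ref = rep("A", nrow(gt)),
                      alt = as.list(rep("G", nrow(gt)))) {
    gt <- as.matrix(gt)
    al <- sweepHKA:::.parseGT(gt)
    gr <- GenomicRanges::GRanges(rep(chrom, length.out = length(pos)),
                                 IRanges::IRanges(pos, pos + nchar(ref) - 1L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        ref = ref, alt = as(alt, "CharacterList"),
        isSNV = nchar(ref) == 1L &
            vapply(alt, function(z) all(nchar(z) == 1L), logical(1)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(allele1 = al$a1, allele2 = al$a2),
        rowRanges = gr)
    methods::new("GenotypeSites", se)
}

## genotype matrix helper: one row per site given as character vector
gtRow <- function(...) matrix(c(...), nrow = 1,
                              dimnames = list(NULL, names(c(...))))

## tiny population design used across unit tests: 3 + 3 samples
toySpec <- function(minA = 2L, minB = 2L)
    populationSpec(paste0("A", 1:3), paste0("B", 1:3),
                   minCalledA = minA, minCalledB = minB)

## Brute-force site classifier: enumerates each population's allele multiset.
## Kept deliberately simple and independent of the vectorized implementation.
bruteClassify <- function(gtVec, samplesA, samplesB, minA, minB) {
    parse1 <- function(g) {
        if (g %in% c("./.", ".|.")) return(NULL)
        as.integer(strsplit(g, "[/|]")[[1]])
    }
    allelesOf <- function(samp) {
        out <- list()
        for (s in samp) {
            a <- parse1(gtVec[[s]])
            if (!is.null(a) && !anyNA(a)) out[[length(out) + 1L]] <- a
        }
        out
    }
    aA <- allelesOf(samplesA); aB <- allelesOf(samplesB)
    if (length(aA) < minA || length(aB) < minB) return("UNINFORMATIVE")
    state <- function(al) {
        u <- unique(unlist(al))
        if (length(u) > 1L) "poly"
        else if (u == 0L) "fixedref"
        else paste0("fixedalt", u)
    }
    sA <- state(aA); sB <- state(aB)
    if (sA == "poly" && sB == "poly") return("POLY_BOTH")
    if (sA == "poly") return("POLY_A_ONLY")
    if (sB == "poly") return("POLY_B_ONLY")
    if (sA == "fixedref" && sB == "fixedref") return("MONOMORPHIC_REF")
    if (startsWith(sA, "fixedalt") && sB == "fixedref") return("FIXED_A")
    if (startsWith(sB, "fixedalt") && sA == "fixedref") return("FIXED_B")
    if (sA == sB) return("SHARED_FIXED_ALT")
    "UNINFORMATIVE"
}

## Exact two-sided Fisher p by full hypergeometric enumeration of all tables
## with the observed margins.
enumFisherP <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    lo <- max(0L, c1 - r2); hi <- min(r1, c1)
    probs <- vapply(lo:hi, function(x)
        exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1)),
        numeric(1))
    pObs <- probs[a - lo + 1L]
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

## Independent whole-protein translate-and-diff effect oracle for CDS SNVs.
translateDiffOracle <- function(model, genome, pos, refB, altB) {
    cdsSeq <- sweepHKA:::.cdsSequence(model, genome)
    gpos <- sweepHKA:::.cdsGenomicPos(model)
    i <- match(pos, gpos)
    if (is.na(i)) return(NA_character_)
    base <- if (model$strand == "-") sweepHKA:::.COMP[[altB]] else altB
    mutated <- cdsSeq
    substr(mutated, i, i) <- base
    tr <- function(s) {
        k <- nchar(s) %/% 3L
        unname(Biostrings::GENETIC_CODE[
            substring(s, 3L * seq_len(k) - 2L, 3L * seq_len(k))])
    }
    p0 <- tr(cdsSeq); p1 <- tr(mutated)
    diffAt <- which(p0 != p1)
    if (length(diffAt) == 0L) return("SYNONYMOUS")
    if (p1[diffAt] == "*") return("STOPGAIN")
    if (p0[diffAt] == "*") return("STOPLOSS")
    "NONSYNONYMOUS"
}

## Two diploid A samples carrying the four haplotypes AAA / AAT / AAT / ATT
## over three positions (the first position is monomorphic so only two
## variant sites exist): sampleA1 = {AAA, AAT}, sampleA2 = {AAT, ATT}.
## Two reference-homozygous B samples satisfy the retention filter without
## touching population A's statistics.
fourHaplotypeSites <- function() {
    gt <- rbind(c("0/1", "0/0", "0/0", "0/0"),   # alt count in A: 1 of 4
                c("0/1", "1/1", "0/0", "0/0"))   # alt count in A: 3 of 4
    colnames(gt) <- c("A1", "A2", "B1", "B2")
    makeSites(gt, pos = c(200L, 300L), ref = c("A", "A"),
              alt = list("T", "T"))
}

fourHapSpec <- function()
    populationSpec(c("A1", "A2"), c("B1", "B2"),
                   minCalledA = 2, minCalledB = 2)
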