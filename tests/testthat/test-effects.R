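## A hand-built two-gene toy: gene gp on the plus strand (single CDS exon),
## gene gm on the minus strand (two CDS exons with a codon split across the
## junction).
toyAnnotation <- function() {
    ## plus-strand CDS at 101..112: ATG GGA TAC TAA
    ## minus-strand gene on a separate chromosome, CDS pieces at
    ## 201..206 + 213..218 (genomic); transcript = revcomp(218..213, 206..201)
    plus <- "ATGGGATACTAA"
    txMinus <- "ATGCCTTGGTAA"                 # what the transcript should be
    segLens <- c(6L, 6L)
    g1 <- paste0(strrep("T", 100), plus, strrep("A", 100))
    ## place minus-strand CDS: transcript piece 1 (first 6 nt) maps to
    ## genomic 213..218 revcomp'd; piece 2 to 201..206
    rc <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
    g2chars <- strsplit(strrep("T", 300), "")[[1]]
    p1 <- rc(substr(txMinus, 1, 6)); p2 <- rc(substr(txMinus, 7, 12))
    g2chars[213:218] <- strsplit(p1, "")[[1]]
    g2chars[201:206] <- strsplit(p2, "")[[1]]
    genome <- Biostrings::DNAStringSet(c(chrP = g1,
                                         chrM = paste(g2chars, collapse = "")))
    models <- list(
        gp = list(gene_id = "gp", transcript_id = "tx_gp", chrom = "chrP",
                  strand = "+",
                  segments = GenomicRanges::GRanges("chrP",
                      IRanges::IRanges(101, 112), strand = "+"),
                  cdsLen = 12L),
        gm = list(gene_id = "gm", transcript_id = "tx_gm", chrom = "chrM",
                  strand = "-",
                  segments = GenomicRanges::GRanges("chrM",
                      IRanges::IRanges(c(213, 201), c(218, 206)),
                      strand = "-"),
                  cdsLen = 12L))
    list(genome = genome, models = models)
}

variantGr <- function(chrom, pos, ref, alt) {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(pos, pos + nchar(ref) - 1L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(ref = ref, alt = alt)
    gr
}

test_that("codon-level SNV classification covers the standard cases", {
    toy <- toyAnnotation()
    ann <- function(pos, ref, alt)
        annotateVariants(variantGr("chrP", pos, ref, alt), toy$models,
                         toy$genome)
    ## GGA -> GGG third-position wobble (codon 2, genomic 104..106)
    e <- ann(106L, "A", "G")
    expect_equal(e$effect, "SYNONYMOUS")
    expect_true(is.na(e$aa_change))
    ## TAC -> TAA stopgain (codon 3, genomic 107..109)
    e <- ann(109L, "C", "A")
    expect_equal(e$effect, "STOPGAIN")
    expect_equal(e$aa_change, "Y3*")
    ## stop codon TAA -> TGA stays synonymous (stop retained)
    e <- ann(111L, "A", "G")
    expect_equal(e$effect, "SYNONYMOUS")
    ## nonsynonymous with Table-3-style notation: GGA -> GAA (G2E)
    e <- ann(105L, "G", "A")
    expect_equal(e$effect, "NONSYNONYMOUS")
    expect_equal(e$aa_change, "G2E")
    ## annotating the reference base against itself changes nothing
    e <- ann(105L, "G", "G")
    expect_equal(e$effect, "SYNONYMOUS")
    ## reference mismatch is a data-integrity error with coordinates
    expect_error(ann(105L, "T", "A"), "chrP:105")
})

test_that("indels in CDS follow the mod-3 rule; flanking SNVs are splice
           region; distant variants are noncoding", {
    toy <- toyAnnotation()
    ## 2-bp insertion inside CDS -> frameshift
    e <- annotateVariants(variantGr("chrP", 104L, "G", "GAT"), toy$models,
                          toy$genome)
    expect_equal(e$effect, "FRAMESHIFT")
    ## 3-bp insertion -> in-frame
    e <- annotateVariants(variantGr("chrP", 104L, "G", "GATT"), toy$models,
                          toy$genome)
    expect_equal(e$effect, "NONFRAMESHIFT_INDEL")
    ## SNV 2 bp outside the CDS edge
    e <- annotateVariants(variantGr("chrP", 99L, "T", "A"), toy$models,
                          toy$genome)
    expect_equal(e$effect, "SPLICE_REGION")
    ## SNV far from any gene
    e <- annotateVariants(variantGr("chrP", 10L, "T", "A"), toy$models,
                          toy$genome)
    expect_equal(e$effect, "NONCODING")
    expect_true(is.na(e$gene_id))
})

test_that("minus-strand annotation equals the whole-protein
           translate-and-diff oracle at every CDS position", {
    toy <- toyAnnotation()
    mo <- toy$models$gm
    gpos <- sweepHKA:::.cdsGenomicPos(mo)
    chrSeq <- as.character(toy$genome[["chrM"]])
    for (p in sort(gpos)) {
        refB <- substr(chrSeq, p, p)
        for (altB in setdiff(c("A", "C", "G", "T"), refB)) {
            e <- annotateVariants(variantGr("chrM", p, refB, altB),
                                  toy$models, toy$genome)
            expect_equal(e$effect,
                         translateDiffOracle(mo, toy$genome, p, refB, altB),
                         info = paste("chrM", p, refB, ">", altB))
        }
    }
})

test_that("random simulated genes: every CDS SNV effect matches the oracle", {
    w <- defaultWorld()
    models <- sweepHKA:::.modelsFromWorld(w$world)
    set.seed(123)
    genome <- w$world$genome
    checked <- 0L
    for (rep in 1:100) {
        mo <- models[[sample(length(models), 1)]]
        gpos <- sweepHKA:::.cdsGenomicPos(mo)
        p <- sample(gpos, 1)
        chrSeq <- as.character(genome[[mo$chrom]])
        refB <- substr(chrSeq, p, p)
        altB <- sample(setdiff(c("A", "C", "G", "T"), refB), 1)
        e <- annotateVariants(variantGr(mo$chrom, p, refB, altB),
                              models, genome)
        e <- e[e$gene_id == mo$gene_id, ]
        expect_equal(e$effect,
                     translateDiffOracle(mo, genome, p, refB, altB),
                     info = paste(mo$gene_id, mo$strand, p, refB, ">", altB))
        checked <- checked + 1L
    }
    expect_equal(checked, 100L)
})

test_that("SAAC sets are set differences over amino-acid-changing genes and
           ignore processing order", {
    effA <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                       effect = c("NONSYNONYMOUS", "FRAMESHIFT",
                                  "STOPGAIN", "SYNONYMOUS"))
    effB <- data.frame(gene_id = c("g2", "g5"),
                       effect = c("NONSYNONYMOUS", "SYNONYMOUS"))
    s <- saacSets(effA, effB)
    expect_equal(s$saacA, c("g1", "g3"))
    expect_equal(s$saacB, character(0))
    expect_length(intersect(s$saacA, s$saacB), 0)
    ## order invariance
    s2 <- saacSets(effA[sample(nrow(effA)), ], effB)
    expect_equal(s2, s)
    ## a gene with only synonymous variants is excluded everywhere
    expect_false("g4" %in% unlist(s))
    ## planted truth on a noise-free world is recovered exactly (checked in
    ## the simulator tests); here check the empty edge
    s0 <- saacSets(effA[0, ], effB[0, ])
    expect_equal(s0$saacA, character(0))
})

test_that("NS/S ratio contrast reproduces the printed genome-wide numbers", {
    ## effects laid out so the PASS stratum holds 1021 NS + 1553 S and the
    ## rest of the genome 2481 NS + 4587 S, as printed
    nIn <- 1021 + 1553; nOut <- 2481 + 4587
    eff <- data.frame(
        chrom = "chr1",
        pos = c(seq_len(nIn), 1000000L + seq_len(nOut)),
        effect = c(rep(c("NONSYNONYMOUS", "SYNONYMOUS"), c(1021, 1553)),
                   rep(c("NONSYNONYMOUS", "SYNONYMOUS"), c(2481, 4587))))
    pass <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500000))
    r <- nsSynRatioTest(eff, pass)
    expect_equal(round(r$ratio_in, 2), 0.66)
    expect_equal(round(r$ratio_out, 2), 0.54)
    expect_equal(r$p, 4.239e-05, tolerance = 1e-3)
    ## equal ratios: p = 1 up to exact-test discreteness
    eff2 <- data.frame(chrom = "chr1",
                       pos = c(seq_len(30), 1000000L + seq_len(60)),
                       effect = c(rep(c("NONSYNONYMOUS", "SYNONYMOUS"),
                                      c(10, 20)),
                                  rep(c("NONSYNONYMOUS", "SYNONYMOUS"),
                                      c(20, 40))))
    expect_gt(nsSynRatioTest(eff2, pass)$p, 0.99)
    ## empty NS class: ratios zero, p = 1
    eff3 <- data.frame(chrom = "chr1",
                       pos = c(seq_len(10), 1000000L + seq_len(10)),
                       effect = "SYNONYMOUS")
    r3 <- nsSynRatioTest(eff3, pass)
    expect_equal(r3$ratio_in, 0); expect_equal(r3$ratio_out, 0)
    expect_equal(r3$p, 1)
})

test_that("gene models read from GFF3 match the simulated models", {
    w <- defaultWorld()
    fromGff <- readGeneModels(w$paths$gff)
    direct <- sweepHKA:::.modelsFromWorld(w$world)
    expect_setequal(names(fromGff), names(direct))
    for (g in names(direct)) {
        expect_equal(GenomicRanges::granges(fromGff[[g]]$segments),
                     GenomicRanges::granges(direct[[g]]$segments), info = g)
        expect_equal(fromGff[[g]]$strand, direct[[g]]$strand, info = g)
    }
})
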