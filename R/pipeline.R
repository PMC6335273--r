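#' @importFrom utils head read.table write.table
#' @importFrom tools md5sum
NULL

#' Run the full sweep-detection pipeline on a set of input files
#'
#' Chains the whole analysis: site classification, the 50-kb/10-kb
#' homogeneity scan with Bonferroni control and PASS-region calling, 10-kb
#' Tajima's D / Fst / fixed-density tracks, codon-level effect annotation and
#' SAAC sets, QTL overlap, paired differential expression, and candidate-gene
#' integration.  All outputs are written under \code{outdir} with fixed names
#' (\code{site_classes.tsv}, \code{windows.tsv}, \code{pass_regions.bed},
#' \code{tajima.tsv}, \code{fst.tsv}, \code{density.tsv}, \code{effects.tsv},
#' \code{saac.tsv}, \code{qtl_overlap.tsv}, \code{de.tsv},
#' \code{candidates.tsv}, \code{manifest.json}).  Given identical inputs and
#' parameters the outputs are byte-identical across reruns; the manifest
#' records parameters and input/output checksums (no timestamps).
#'
#' @param vcf multi-sample VCF path.
#' @param popmap two-column TSV (sample, population) with populations
#'   \code{A} and \code{B}, or a [PopulationSpec-class].
#' @param fasta reference FASTA path.
#' @param gff gene-model GFF3 path.
#' @param qtlBed QTL BED path (optional).
#' @param counts counts TSV (gene, length, sample columns; optional).
#' @param pairing pairing TSV (case, control, stage; optional).
#' @param markedGenes text file of marked gene IDs (optional).
#' @param chromSizes named vector of chromosome sizes, or two-column TSV
#'   path; defaults to the FASTA sequence lengths.
#' @param outdir output directory.
#' @param window,step scan window and step in bp (defaults 50000/10000).
#' @param statWindow tiling window for the statistics tracks (default 10000).
#' @param alpha family-wise significance level (default 0.05).
#' @param test \code{"fisher"} or \code{"chisq"}.
#' @param minCalledA,minCalledB retention thresholds (defaults 10 and 9).
#' @param minFRatio direction-rule fold requirement (default 1).
#' @param v0,deWindow,fdr expression-test parameters.
#' @param snvOnly restrict classification to SNVs (default FALSE).
#' @return (invisibly) list with every intermediate object and the manifest.
#' @export
runSweepPipeline <- function(vcf, popmap, fasta, gff, qtlBed = NULL,
                             counts = NULL, pairing = NULL,
                             markedGenes = NULL, chromSizes = NULL,
                             outdir, window = 50000L, step = 10000L,
                             statWindow = 10000L, alpha = 0.05,
                             test = c("fisher", "chisq"),
                             minCalledA = 10L, minCalledB = 9L,
                             minFRatio = 1, v0 = 10, deWindow = 101,
                             fdr = 0.05, snvOnly = FALSE) {
    test <- match.arg(test)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (f in c(vcf, fasta, gff))
        if (!file.exists(f)) stop("input file not found: ", f)
    spec <- if (is(popmap, "PopulationSpec")) popmap else {
        pm <- utils::read.table(popmap, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
        populationSpec(pm[[1]][pm[[2]] == "A"], pm[[1]][pm[[2]] == "B"],
                       minCalledA = min(minCalledA, sum(pm[[2]] == "A")),
                       minCalledB = min(minCalledB, sum(pm[[2]] == "B")))
    }
    genome <- readDNAStringSet(fasta)
    names(genome) <- sub("\\s.*", "", names(genome))
    if (is.null(chromSizes)) {
        chromSizes <- stats::setNames(Biostrings::width(genome),
                                      names(genome))
    } else if (is.character(chromSizes) && length(chromSizes) == 1L) {
        cs <- utils::read.table(chromSizes, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
        chromSizes <- stats::setNames(cs[[2]], cs[[1]])
    }
    ## classify
    sites <- readGenotypeSites(vcf, spec, snvOnly = snvOnly)
    classes <- classifySites(sites, spec)
    writeSiteClasses(classes, file.path(outdir, "site_classes.tsv"))
    ## scan
    scanW <- makeWindows(chromSizes, window, step)
    scanW <- countWindowSites(classes, scanW)
    scanW <- scanWindows(scanW, method = test, minFRatio = minFRatio)
    writeWindowStats(scanW, file.path(outdir, "windows.tsv"), alpha = alpha)
    pass <- callPassRegions(scanW, alpha = alpha)
    writeRegionsBed(pass, file.path(outdir, "pass_regions.bed"))
    ## popgen tracks
    statW <- makeWindows(chromSizes, statWindow, statWindow)
    tajA <- windowTajimaD(sites, spec, statW, "A")
    tajB <- windowTajimaD(sites, spec, statW, "B")
    mcols(tajA)$D_B <- mcols(tajB)$D
    writeWindowTsv(tajA, file.path(outdir, "tajima.tsv"))
    fst <- windowWcFst(sites, spec, statW)
    writeWindowTsv(fst, file.path(outdir, "fst.tsv"))
    dens <- fixedDensity(classes, statW)
    writeWindowTsv(dens, file.path(outdir, "density.tsv"))
    ## effects + SAAC
    models <- readGeneModels(gff)
    fixedOf <- function(cl) {
        idx <- mcols(classes)$class == cl
        v <- granges(rowRanges(sites))[idx]
        mcols(v)$ref <- mcols(rowRanges(sites))$ref[idx]
        mcols(v)$alt <- vapply(as.list(mcols(rowRanges(sites))$alt[idx]),
                               `[`, character(1), 1L)
        v
    }
    effA <- annotateVariants(fixedOf("FIXED_A"), models, genome)
    effB <- annotateVariants(fixedOf("FIXED_B"), models, genome)
    effA$population <- "A"; effB$population <- "B"
    utils::write.table(rbind(effA, effB), file.path(outdir, "effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    saac <- saacSets(effA, effB)
    saacDf <- data.frame(
        gene = c(saac$saacA, saac$saacB),
        population = c(rep("A", length(saac$saacA)),
                       rep("B", length(saac$saacB))))
    utils::write.table(saacDf, file.path(outdir, "saac.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ## QTL overlap
    qtlSummary <- NULL
    if (!is.null(qtlBed) && file.exists(qtlBed)) {
        qtls <- readRegions(qtlBed)
        qtlSummary <- intersectSummary(pass, qtls)
        utils::write.table(
            data.frame(overlap_bp = qtlSummary$overlap_bp,
                       frac_pass_covered = qtlSummary$frac_a_covered,
                       n_qtl_hit = qtlSummary$n_b_hit,
                       n_qtl = length(qtls)),
            file.path(outdir, "qtl_overlap.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
    }
    ## expression
    de <- NULL
    if (!is.null(counts) && file.exists(counts)) {
        cnt <- utils::read.table(counts, sep = "\t", header = TRUE,
                                 check.names = FALSE,
                                 stringsAsFactors = FALSE)
        mat <- as.matrix(cnt[, -(1:2), drop = FALSE])
        rownames(mat) <- cnt[[1]]
        lens <- stats::setNames(cnt[[2]], cnt[[1]])
        pr <- utils::read.table(pairing, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
        de <- differentialExpression(mat, lens, pr, v0 = v0,
                                     window = deWindow, fdr = fdr)
        deTab <- do.call(rbind, lapply(names(de$perStage), function(st)
            cbind(stage = st, de$perStage[[st]])))
        utils::write.table(deTab, file.path(outdir, "de.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    ## integrate
    geneRanges <- GRanges()
    integration <- NULL
    gffGenes <- rtracklayer::import(gff)
    gffGenes <- gffGenes[gffGenes$type == "gene"]
    if (length(gffGenes) > 0L) {
        geneRanges <- granges(gffGenes)
        mcols(geneRanges)$gene_id <- if (!is.null(gffGenes$ID))
            as.character(gffGenes$ID) else as.character(gffGenes$gene_id)
    }
    marked <- if (!is.null(markedGenes) && file.exists(markedGenes))
        readLines(markedGenes) else character(0)
    integration <- integrateCandidates(
        saac$saacA, pass, geneRanges,
        if (is.null(de)) character(0) else de$deGenes, marked)
    candDf <- data.frame(gene = integration$candidates)
    if (nrow(candDf) > 0L) {
        candDf$in_pass <- candDf$gene %in% integration$passGenes
        candDf$de <- candDf$gene %in%
            (if (is.null(de)) character(0) else de$deGenes)
        candDf$marked <- TRUE
    }
    utils::write.table(candDf, file.path(outdir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ## manifest: parameters + checksums, no timestamps (reruns byte-identical)
    inputs <- Filter(Negate(is.null),
                     list(vcf = vcf, fasta = fasta, gff = gff,
                          qtlBed = qtlBed, counts = counts,
                          pairing = pairing, markedGenes = markedGenes))
    inputs <- Filter(file.exists, inputs)
    outFiles <- list.files(outdir, full.names = TRUE)
    outFiles <- setdiff(outFiles, file.path(outdir, "manifest.json"))
    manifest <- list(
        tool = "sweepHKA",
        version = as.character(utils::packageVersion("sweepHKA")),
        parameters = list(window = window, step = step,
                          statWindow = statWindow, alpha = alpha,
                          test = test, minCalledA = minCalledA,
                          minCalledB = minCalledB, minFRatio = minFRatio,
                          v0 = v0, deWindow = deWindow, fdr = fdr,
                          snvOnly = snvOnly),
        input_md5 = as.list(stats::setNames(
            unname(tools::md5sum(unlist(inputs))),
            basename(unlist(inputs)))),
        output_md5 = as.list(stats::setNames(
            unname(tools::md5sum(outFiles)), basename(outFiles))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(spec = spec, sites = sites, classes = classes,
                   scan = scanW, pass = pass, tajimaA = tajA, tajimaB = tajB,
                   fst = fst, density = dens, effectsA = effA,
                   effectsB = effB, saac = saac, qtl = qtlSummary, de = de,
                   integration = integration, manifest = manifest))
}
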