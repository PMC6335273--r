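#' @importFrom Biostrings writeXStringSet xscat
#' @importFrom stats runif rnbinom rlnorm
NULL

#' Configuration for the synthetic two-population world
#'
#' Defaults describe the study conditions the package is designed around: two
#' diploid inbred populations of 12 and 11 animals derived from a shared
#' founder pool, roughly one founder variant site per kb, per-sample
#' homozygosity in the low nineties (residual heterozygosity plus inbred
#' Hardy-Weinberg draws at polymorphic sites), sweeps planted as intervals
#' where founder-alt sites become fixed in population A with high
#' probability, and a paired beta-cell-style expression matrix with planted
#' differentially expressed genes across three age stages.
#'
#' @param seed integer seed driving every random draw.
#' @param nChroms,chromLength toy genome shape (default 2 x 2 Mb).
#' @param nSamplesA,nSamplesB population sizes (default 12 and 11).
#' @param founderSiteDensity founder variant sites per kb (default 2.5,
#'   matching the per-kb density of the retained variant set in a deeply
#'   resequenced inbred rat pair).
#' @param sweeps \code{GRanges} of planted sweep intervals; default two
#'   200-kb sweeps, one per chromosome.
#' @param sweepFixProb probability a founder site inside a sweep is fixed for
#'   the alternate allele in population A (default 0.9).
#' @param backgroundFixProbA,backgroundFixProbB per-site fixation
#'   probabilities outside sweeps (default 0.02 each).
#' @param hetResidualProb per-sample per-site residual heterozygosity noise
#'   (default 0.04).
#' @param missingProb per-sample per-site missing-genotype probability
#'   (default 0.02).
#' @param indelProb fraction of sites simulated as short indels rather than
#'   SNVs (default 0.05).
#' @param fis inbreeding coefficient used for genotype draws at polymorphic
#'   sites (default 0.85; together with \code{hetResidualProb} this puts
#'   per-sample homozygote rates in the low nineties).
#' @param nGenes,nDeGenes genes on the toy genome and planted DE genes
#'   (defaults 120 and 10; a gene complement much larger than the planted DE
#'   set keeps the compositional bias of TPM renormalization small).
#' @param deLog2fc planted log2 fold change (default 2).
#' @param exprDispersion negative-binomial dispersion (default 0.1,
#'   within-inbred-line biological variability).
#' @param pairsPerStage paired case/control samples per stage (default 3).
#' @param stages stage labels (default 4/6/8 weeks).
#' @return a classed list of configuration values.
#' @export
simConfig <- function(seed = 1L, nChroms = 2L, chromLength = 2e6,
                      nSamplesA = 12L, nSamplesB = 11L,
                      founderSiteDensity = 2.5,
                      sweeps = NULL,
                      sweepFixProb = 0.9,
                      backgroundFixProbA = 0.02, backgroundFixProbB = 0.02,
                      hetResidualProb = 0.04, missingProb = 0.02,
                      indelProb = 0.05, fis = 0.85,
                      nGenes = 120L, nDeGenes = 10L, deLog2fc = 2,
                      exprDispersion = 0.1, pairsPerStage = 3L,
                      stages = c("4wk", "6wk", "8wk")) {
    if (is.null(sweeps)) {
        ch <- character(0); st <- integer(0); en <- integer(0)
        if (nChroms >= 1L && chromLength >= 8e5) {
            ch <- "chr1"; st <- 600001L; en <- 800000L
        }
        if (nChroms >= 2L && chromLength >= 15e5) {
            ch <- c(ch, "chr2"); st <- c(st, 1200001L); en <- c(en, 1400000L)
        }
        sweeps <- GRanges(ch, IRanges(st, en))
    }
    cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
                chromLength = as.integer(chromLength),
                nSamplesA = as.integer(nSamplesA),
                nSamplesB = as.integer(nSamplesB),
                founderSiteDensity = founderSiteDensity, sweeps = sweeps,
                sweepFixProb = sweepFixProb,
                backgroundFixProbA = backgroundFixProbA,
                backgroundFixProbB = backgroundFixProbB,
                hetResidualProb = hetResidualProb, missingProb = missingProb,
                indelProb = indelProb, fis = fis,
                nGenes = as.integer(nGenes),
                nDeGenes = min(as.integer(nDeGenes), as.integer(nGenes)),
                deLog2fc = deLog2fc, exprDispersion = exprDispersion,
                pairsPerStage = as.integer(pairsPerStage), stages = stages)
    probs <- c(sweepFixProb, backgroundFixProbA, backgroundFixProbB,
               hetResidualProb, missingProb, indelProb, fis)
    stopifnot(all(probs >= 0 & probs <= 1))
    class(cfg) <- "simConfig"
    cfg
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.ALL_CODONS <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                     paste0), c("A","C","G","T"), paste0))
.SENSE_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)

#' Simulate a toy genome with CDS gene models
#'
#' Uniform-random reference chromosomes carrying \code{nGenes} protein-coding
#' genes (1-3 CDS exons, both strands, ATG...stop, no internal stops, total
#' CDS length a multiple of 3).  At least one gene is placed inside every
#' planted sweep interval so that sweeps can produce coding fixed variants.
#'
#' @param config a [simConfig()].
#' @return list with \code{genome} (\code{DNAStringSet}), \code{chromSizes}
#'   (named vector), \code{genes} (data.frame of spans), \code{cds}
#'   (\code{GRanges} of CDS segments with \code{gene_id}, \code{Parent},
#'   \code{phase}).
#' @export
simulateGenome <- function(config) {
    set.seed(config$seed)
    chroms <- paste0("chr", seq_len(config$nChroms))
    L <- config$chromLength
    baseRaw <- charToRaw("ACGT")
    seqs <- lapply(chroms, function(ch) baseRaw[sample.int(4L, L, TRUE)])
    names(seqs) <- chroms
    occupied <- lapply(chroms, function(ch) IRanges())
    names(occupied) <- chroms
    geneRows <- list(); cdsList <- list()
    placeGene <- function(gid, chrom, lo, hi) {
        nCodons <- sample(40:120, 1)
        cdsLen <- 3L * nCodons
        nEx <- sample(1:3, 1)
        ## split CDS into nEx pieces of >= 12 nt at arbitrary offsets
        if (nEx > 1L) {
            cuts <- sort(sample(seq(12L, cdsLen - 12L), nEx - 1L))
            exLens <- diff(c(0L, cuts, cdsLen))
        } else exLens <- cdsLen
        intrLens <- if (nEx > 1L) sample(60:200, nEx - 1L, replace = TRUE)
                    else integer(0)
        span <- sum(exLens) + sum(intrLens)
        strandG <- sample(c("+", "-"), 1)
        for (try in seq_len(200)) {
            st <- sample(seq(max(lo, 1L), hi - span), 1)
            cand <- IRanges(st, st + span - 1L)
            if (length(IRanges::findOverlaps(cand, occupied[[chrom]])) == 0L)
                break
            if (try == 200L) stop("gene placement failed on ", chrom)
        }
        occupied[[chrom]] <<- c(occupied[[chrom]], cand)
        cdsSeq <- paste0("ATG",
                         paste(sample(.SENSE_CODONS, nCodons - 2L,
                                      replace = TRUE), collapse = ""),
                         sample(.STOP_CODONS, 1))
        ## genomic exon coordinates (left to right)
        exStarts <- st + cumsum(c(0L, head(exLens, -1L) + intrLens))
        exEnds <- exStarts + exLens - 1L
        ## transcript order: 5'->3'; on minus strand rightmost exon is first
        ord <- if (strandG == "-") rev(seq_len(nEx)) else seq_len(nEx)
        cum <- 0L
        phase <- integer(nEx)
        for (j in seq_len(nEx)) {
            k <- ord[j]
            piece <- substr(cdsSeq, cum + 1L, cum + exLens[k])
            phase[k] <- (3L - cum %% 3L) %% 3L
            gpiece <- if (strandG == "-")
                as.character(reverseComplement(DNAString(piece))) else piece
            seqs[[chrom]][exStarts[k]:exEnds[k]] <<- charToRaw(gpiece)
            cum <- cum + exLens[k]
        }
        tx <- paste0("tx_", gid)
        cdsList[[length(cdsList) + 1L]] <<- GRanges(
            chrom, IRanges(exStarts, exEnds), strand = strandG,
            type = "CDS", gene_id = gid, Parent = tx, phase = phase)
        geneRows[[length(geneRows) + 1L]] <<- data.frame(
            gene_id = gid, transcript_id = tx, chrom = chrom,
            strand = strandG, start = st, end = st + span - 1L,
            cds_len = cdsLen, stringsAsFactors = FALSE)
    }
    gid <- 0L
    nextId <- function() { gid <<- gid + 1L; sprintf("gene%03d", gid) }
    if (config$nGenes > 0L) {
        ## one gene guaranteed inside each sweep
        for (i in seq_along(config$sweeps)) {
            sw <- config$sweeps[i]
            placeGene(nextId(), as.character(seqnames(sw)),
                      start(sw) + 1000L, end(sw) - 1000L)
        }
        while (gid < config$nGenes) {
            ch <- chroms[gid %% length(chroms) + 1L]
            placeGene(nextId(), ch, 1L, L)
        }
    }
    genome <- DNAStringSet(vapply(seqs, rawToChar, character(1)))
    names(genome) <- chroms
    list(genome = genome,
         chromSizes = stats::setNames(rep(L, length(chroms)), chroms),
         genes = if (length(geneRows)) do.call(rbind, geneRows)
                 else data.frame(),
         cds = if (length(cdsList))
             suppressWarnings(do.call(c, unname(cdsList))) else GRanges())
}

## Independent translate-and-diff check used to record amino-acid-change
## truth: applies an SNV to the full CDS and compares whole translated
## proteins.
.translateStr <- function(seq) {
    k <- nchar(seq) %/% 3L
    codons <- substring(seq, 3L * seq_len(k) - 2L, 3L * seq_len(k))
    paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

.aaChangingTruth <- function(cdsSeq, cdsGenomicPos, strand, pos, refB, altB) {
    i <- match(pos, cdsGenomicPos)
    if (is.na(i)) return(FALSE)
    base <- if (strand == "-") .COMP[[altB]] else altB
    mutated <- cdsSeq
    substr(mutated, i, i) <- base
    !identical(.translateStr(cdsSeq), .translateStr(mutated))
}

#' Simulate two-population genotypes with planted sweeps
#'
#' Places founder variant sites at the configured density, assigns each a
#' pre-noise truth class (inside sweeps, sites become fixed-in-A with
#' \code{sweepFixProb} and residual polymorphic sites carry low-frequency
#' alleles, emulating the rare-variant skew left behind by a sweep; outside,
#' sites are fixed in A/B with the background probabilities or drawn from a
#' neutral class mix), then draws per-sample diploid genotypes
#' (Hardy-Weinberg with inbreeding at polymorphic sites) and applies residual
#' heterozygosity and missingness noise.
#'
#' @param config a [simConfig()].
#' @param world output of [simulateGenome()].
#' @return list with \code{gt} (character genotype matrix, sites x samples),
#'   \code{sites} (\code{GRanges} with ref/alt), \code{samples} (list with A
#'   and B sample IDs), and \code{truth} (a [SweepTruthSet-class]).
#' @export
simulatePopulations <- function(config, world) {
    set.seed(config$seed + 1L)
    chroms <- names(world$chromSizes)
    nA <- config$nSamplesA; nB <- config$nSamplesB
    samplesA <- sprintf("A%02d", seq_len(nA))
    samplesB <- sprintf("B%02d", seq_len(nB))
    allRows <- list()
    for (ch in chroms) {
        L <- world$chromSizes[[ch]]
        nSites <- round(L / 1000 * config$founderSiteDensity)
        pos <- sort(sample(seq(2L, L - 5L), nSites))
        pos <- pos[c(TRUE, diff(pos) >= 5L)]
        allRows[[ch]] <- data.frame(chrom = ch, pos = pos,
                                    stringsAsFactors = FALSE)
    }
    sitesDf <- do.call(rbind, allRows)
    n <- nrow(sitesDf)
    chrRaw <- lapply(world$genome, function(s) charToRaw(as.character(s)))
    bases <- c("A", "C", "G", "T")
    baseAt <- function(chrom, pos) {   # vectorized within one chromosome set
        idx <- match(as.integer(chrRaw[[chrom]][pos]),
                     utf8ToInt("ACGT"))
        bases[idx]
    }
    ## alleles: SNVs vectorized, the few indels in a loop
    isIndel <- runif(n) < config$indelProb
    ref <- character(n); alt <- character(n)
    for (ch in chroms) {
        ri <- which(sitesDf$chrom == ch)
        ref[ri] <- baseAt(ch, sitesDf$pos[ri])
    }
    ## alt base: pick uniformly among the three others
    altOff <- sample.int(3L, n, replace = TRUE)
    altMat <- t(vapply(bases, function(b) setdiff(bases, b), character(3)))
    alt <- altMat[cbind(match(ref, bases), altOff)]
    for (i in which(isIndel)) {
        b <- ref[i]
        k <- sample(1:3, 1)
        if (runif(1) < 0.5) {           # insertion
            alt[i] <- paste0(b, paste(sample(bases, k, replace = TRUE),
                                      collapse = ""))
        } else {                        # deletion
            ref[i] <- paste(baseAt(sitesDf$chrom[i],
                                   sitesDf$pos[i]:(sitesDf$pos[i] + k)),
                            collapse = "")
            alt[i] <- b
        }
    }
    ## plant amino-acid-changing fixed coding variants: one FIXED_A SNV in
    ## the CDS of every gene lying inside a sweep, and FIXED_B SNVs in up to
    ## two genes outside sweeps, so SAAC sets are exercised on every world
    models <- .modelsFromWorld(world)
    plantedClass <- character(0)
    if (length(models) > 0L) {
        spans <- GRanges(world$genes$chrom,
                         IRanges(world$genes$start, world$genes$end))
        inSw <- countOverlaps(spans, config$sweeps) > 0L
        sweepGenes <- world$genes$gene_id[inSw]
        bGenes <- head(world$genes$gene_id[!inSw], 2L)
        plantOne <- function(g) {
            mo <- models[[g]]
            cdsSeq <- .cdsSequence(mo, world$genome)
            gpos <- .cdsGenomicPos(mo)
            for (try in seq_len(50L)) {
                p <- sample(gpos, 1L)
                if (any(abs(sitesDf$pos - p) < 5L &
                        sitesDf$chrom == mo$chrom)) next
                b <- baseAt(mo$chrom, p)
                for (a in sample(setdiff(c("A", "C", "G", "T"), b))) {
                    if (.aaChangingTruth(cdsSeq, gpos, mo$strand, p, b, a))
                        return(list(chrom = mo$chrom, pos = p, ref = b,
                                    alt = a))
                }
            }
            NULL
        }
        for (g in sweepGenes) {
            pl <- plantOne(g)
            if (is.null(pl)) next
            sitesDf <- rbind(sitesDf, data.frame(chrom = pl$chrom,
                                                 pos = pl$pos))
            ref <- c(ref, pl$ref); alt <- c(alt, pl$alt)
            plantedClass <- c(plantedClass, "FIXED_A")
        }
        for (g in bGenes) {
            pl <- plantOne(g)
            if (is.null(pl)) next
            sitesDf <- rbind(sitesDf, data.frame(chrom = pl$chrom,
                                                 pos = pl$pos))
            ref <- c(ref, pl$ref); alt <- c(alt, pl$alt)
            plantedClass <- c(plantedClass, "FIXED_B")
        }
    }
    nPlanted <- length(plantedClass)
    n <- nrow(sitesDf)
    siteGr <- GRanges(sitesDf$chrom, IRanges(sitesDf$pos,
                                             sitesDf$pos + nchar(ref) - 1L))
    inSweep <- countOverlaps(siteGr, config$sweeps) > 0L
    ## truth class per site
    cls <- character(n)
    u <- runif(n)
    neutralMix <- function(k) sample(
        c("POLY_A_ONLY", "POLY_B_ONLY", "POLY_BOTH", "SHARED_FIXED_ALT",
          "MONOMORPHIC_REF"), k, replace = TRUE,
        prob = c(0.25, 0.25, 0.30, 0.10, 0.10))
    sweepMix <- function(k) sample(
        c("POLY_A_ONLY", "POLY_B_ONLY", "POLY_BOTH", "MONOMORPHIC_REF"),
        k, replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
    sw <- which(inSweep)
    cls[sw] <- ifelse(u[sw] < config$sweepFixProb, "FIXED_A", NA)
    cls[sw][is.na(cls[sw])] <- sweepMix(sum(is.na(cls[sw])))
    bg <- which(!inSweep)
    ub <- u[bg]
    pA <- config$backgroundFixProbA; pB <- config$backgroundFixProbB
    cls[bg] <- ifelse(ub < pA, "FIXED_A",
                      ifelse(ub < pA + pB, "FIXED_B", NA))
    cls[bg][is.na(cls[bg])] <- neutralMix(sum(is.na(cls[bg])))
    if (nPlanted > 0L)
        cls[(n - nPlanted + 1L):n] <- plantedClass
    ## coordinate order for the emitted VCF
    ord <- order(match(sitesDf$chrom, chroms), sitesDf$pos)
    sitesDf <- sitesDf[ord, ]; ref <- ref[ord]; alt <- alt[ord]
    cls <- cls[ord]; inSweep <- inSweep[ord]
    siteGr <- siteGr[ord]
    ## allele frequencies for polymorphic draws: sweep residual sites carry
    ## rare alleles (post-sweep recovery), background sites intermediate ones
    fA <- ifelse(inSweep, runif(n, 0.04, 0.22), runif(n, 0.2, 0.8))
    fB <- runif(n, 0.2, 0.8)
    ## vectorized genotype draws (0/1/2 alt copies): Hardy-Weinberg with
    ## inbreeding at polymorphic sites, deterministic at fixed/monomorphic
    drawPopRows <- function(rows, f, nSamp, fis) {
        if (length(rows) == 0L) return(NULL)
        pHomAlt <- f^2 + fis * f * (1 - f)
        pHet <- 2 * f * (1 - f) * (1 - fis)
        u <- matrix(runif(length(rows) * nSamp), length(rows), nSamp)
        g <- matrix(0L, length(rows), nSamp)
        g[u < pHomAlt + pHet] <- 1L
        g[u < pHomAlt] <- 2L
        ## guarantee each polymorphic population really segregates
        noSeg <- !(rowSums(g == 1L) > 0L |
                   (rowSums(g == 0L) > 0L & rowSums(g == 2L) > 0L))
        g[noSeg, 1L] <- 0L; g[noSeg, 2L] <- 2L
        g
    }
    gtA <- matrix(0L, n, nA); gtB <- matrix(0L, n, nB)   # 0/1/2 alt copies
    fixArows <- cls %in% c("FIXED_A", "SHARED_FIXED_ALT")
    fixBrows <- cls %in% c("FIXED_B", "SHARED_FIXED_ALT")
    gtA[fixArows, ] <- 2L
    gtB[fixBrows, ] <- 2L
    polyArows <- which(cls %in% c("POLY_A_ONLY", "POLY_BOTH"))
    polyBrows <- which(cls %in% c("POLY_B_ONLY", "POLY_BOTH"))
    gtA[polyArows, ] <- drawPopRows(polyArows, fA[polyArows], nA, config$fis)
    gtB[polyBrows, ] <- drawPopRows(polyBrows, fB[polyBrows], nB, config$fis)
    gt012 <- cbind(gtA, gtB)
    colnames(gt012) <- c(samplesA, samplesB)
    ## residual heterozygosity noise then missingness
    nsamp <- ncol(gt012)
    hetFlip <- matrix(runif(n * nsamp) < config$hetResidualProb, n, nsamp)
    gt012[hetFlip] <- 1L
    gtChar <- matrix(c("0/0", "0/1", "1/1")[gt012 + 1L], n, nsamp,
                     dimnames = dimnames(gt012))
    missing <- matrix(runif(n * nsamp) < config$missingProb, n, nsamp)
    gtChar[missing] <- "./."
    ## truth containers
    truthSites <- siteGr
    mcols(truthSites) <- DataFrame(ref = ref, alt = alt,
                                   class = factor(cls, levels = .SITE_CLASSES),
                                   inSweep = inSweep)
    ## planted amino-acid-changing genes per population (whole-protein
    ## translate-and-diff for SNVs; mod-3 rule for CDS indels)
    changedA <- character(0); changedB <- character(0)
    if (length(models) > 0L) {
        segAll <- suppressWarnings(do.call(c, unname(lapply(models,
            function(mo) {
                g <- mo$segments
                mcols(g)$model <- mo$gene_id
                g
            }))))
        fixedIdx <- which(cls %in% c("FIXED_A", "FIXED_B"))
        ov <- findOverlaps(truthSites[fixedIdx], segAll)
        seqCache <- list(); posCache <- list()
        for (h in seq_along(ov)) {
            i <- fixedIdx[S4Vectors::queryHits(ov)[h]]
            g <- mcols(segAll)$model[S4Vectors::subjectHits(ov)[h]]
            mo <- models[[g]]
            if (is.null(seqCache[[g]])) {
                seqCache[[g]] <- .cdsSequence(mo, world$genome)
                posCache[[g]] <- .cdsGenomicPos(mo)
            }
            changing <- if (nchar(ref[i]) == 1L && nchar(alt[i]) == 1L)
                .aaChangingTruth(seqCache[[g]], posCache[[g]], mo$strand,
                                 start(truthSites)[i], ref[i], alt[i])
            else TRUE   # any CDS-touching indel changes the protein
            if (!changing) next
            if (cls[i] == "FIXED_A") changedA <- c(changedA, g)
            else changedB <- c(changedB, g)
        }
    }
    changedA <- sort(unique(changedA)); changedB <- sort(unique(changedB))
    truth <- new("SweepTruthSet", sweeps = config$sweeps,
                 siteClass = truthSites, deGenes = character(0),
                 saacGenesA = setdiff(changedA, changedB),
                 saacGenesB = setdiff(changedB, changedA),
                 config = unclass(config)["seed"])
    list(gt = gtChar, sites = truthSites,
         samples = list(A = samplesA, B = samplesB), truth = truth)
}

## gene-model list (same shape as readGeneModels()) straight from the
## simulated world, bypassing GFF round-trip
.modelsFromWorld <- function(world) {
    if (length(world$cds) == 0L) return(list())
    byGene <- split(seq_along(world$cds), mcols(world$cds)$gene_id)
    models <- lapply(byGene, function(i) {
        seg <- granges(world$cds[i])
        str <- as.character(strand(seg))[1]
        seg <- if (str == "-") seg[order(-start(seg))]
               else seg[order(start(seg))]
        gid <- mcols(world$cds)$gene_id[i[1]]
        list(gene_id = gid,
             transcript_id = mcols(world$cds)$Parent[i[1]],
             chrom = as.character(seqnames(seg))[1], strand = str,
             segments = seg, cdsLen = sum(width(seg)))
    })
    names(models) <- vapply(models, `[[`, character(1), "gene_id")
    models
}

#' Simulate a paired expression count matrix
#'
#' Negative-binomial counts for paired case/control samples across the
#' configured stages, with a shared per-pair library factor (so pairing is
#' informative) and \code{nDeGenes} planted genes shifted by
#' \code{deLog2fc} in case samples (alternating up/down).
#'
#' @param config a [simConfig()].
#' @param geneIds character vector of gene IDs (rows).
#' @param geneLengths per-gene lengths in bp; default 1 kb each.
#' @return list with \code{counts} (integer matrix), \code{lengths},
#'   \code{pairing} (data.frame case/control/stage) and \code{deGenes}.
#' @export
simulateExpression <- function(config, geneIds,
                               geneLengths = NULL) {
    set.seed(config$seed + 2L)
    ng <- length(geneIds)
    stopifnot(config$nDeGenes <= ng)
    if (is.null(geneLengths))
        geneLengths <- stats::setNames(rep(1000L, ng), geneIds)
    mu <- 2^runif(ng, 4, 10)
    size <- 1 / config$exprDispersion
    deGenes <- if (config$nDeGenes > 0L)
        sort(sample(geneIds, config$nDeGenes)) else character(0)
    fc <- rep(1, ng)
    de <- geneIds %in% deGenes
    sgn <- rep_len(c(1, -1), sum(de))
    fc[de] <- 2^(config$deLog2fc * sgn)
    cols <- list(); cn <- character(0)
    pairing <- list()
    for (st in config$stages) {
        for (p in seq_len(config$pairsPerStage)) {
            lf <- rlnorm(1, 0, 0.15)
            caseName <- sprintf("case_%s_%d", st, p)
            ctrlName <- sprintf("ctrl_%s_%d", st, p)
            cols[[caseName]] <- rnbinom(ng, mu = mu * fc * lf, size = size)
            cols[[ctrlName]] <- rnbinom(ng, mu = mu * lf, size = size)
            pairing[[length(pairing) + 1L]] <- data.frame(
                case = caseName, control = ctrlName, stage = st,
                stringsAsFactors = FALSE)
        }
    }
    counts <- do.call(cbind, cols)
    storage.mode(counts) <- "integer"
    rownames(counts) <- geneIds
    list(counts = counts, lengths = geneLengths,
         pairing = do.call(rbind, pairing), deGenes = deGenes)
}

#' Simulate QTL intervals
#'
#' One QTL generously covering each planted sweep (sweep plus 50-150 kb of
#' flank on each side) and two decoy QTLs per chromosome elsewhere.
#'
#' @param config a [simConfig()].
#' @return \code{GRanges} of QTL intervals with a \code{name} column.
#' @export
simulateQtls <- function(config) {
    set.seed(config$seed + 3L)
    L <- config$chromLength
    ch <- character(0); st <- numeric(0); en <- numeric(0)
    for (i in seq_along(config$sweeps)) {
        sw <- config$sweeps[i]
        ch <- c(ch, as.character(seqnames(sw)))
        st <- c(st, max(1, start(sw) - sample(50000:150000, 1)))
        en <- c(en, min(L, end(sw) + sample(50000:150000, 1)))
    }
    for (chm in paste0("chr", seq_len(config$nChroms))) {
        for (k in 1:2) {
            s0 <- sample(seq(1, L - 250000), 1)
            ch <- c(ch, chm); st <- c(st, s0)
            en <- c(en, s0 + sample(50000:200000, 1))
        }
    }
    out <- GRanges(ch, IRanges(st, en))
    mcols(out)$name <- paste0("QTL_", seq_along(out))
    out
}

#' Simulate and write a complete seeded test world
#'
#' Chains [simulateGenome()], [simulatePopulations()], [simulateQtls()] and
#' [simulateExpression()], and writes reference FASTA, GFF3 gene models,
#' multi-sample VCF 4.2 (with contig headers), sweep-truth BED, QTL BED,
#' counts and pairing TSVs, a marked-gene list (planted DE genes plus all
#' genes inside sweeps plus decoys) and a truth JSON, all under one
#' directory.  Byte-identical across reruns with the same configuration.
#'
#' @param config a [simConfig()].
#' @param dir output directory (created if needed); when \code{NULL} nothing
#'   is written and only objects are returned.
#' @return (invisibly) list with all simulated objects and, when \code{dir}
#'   is given, a \code{paths} element of written files.
#' @export
simulateWorld <- function(config, dir = NULL) {
    world <- simulateGenome(config)
    pops <- simulatePopulations(config, world)
    qtls <- simulateQtls(config)
    expr <- simulateExpression(config, world$genes$gene_id,
                               stats::setNames(world$genes$cds_len,
                                               world$genes$gene_id))
    truth <- pops$truth
    truth@deGenes <- expr$deGenes
    sweepGenes <- world$genes$gene_id[
        countOverlaps(GRanges(world$genes$chrom,
                              IRanges(world$genes$start, world$genes$end)),
                      config$sweeps) > 0L]
    set.seed(config$seed + 4L)
    decoys <- sample(setdiff(world$genes$gene_id,
                             c(expr$deGenes, sweepGenes)),
                     min(4L, max(0L, nrow(world$genes) -
                                 length(expr$deGenes) - length(sweepGenes))))
    marked <- sort(unique(c(expr$deGenes, sweepGenes, decoys)))
    res <- list(world = world, pops = pops, qtls = qtls, expr = expr,
                truth = truth, markedGenes = marked)
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        paths <- list(
            fasta = file.path(dir, "reference.fa"),
            gff = file.path(dir, "genes.gff3"),
            vcf = file.path(dir, "variants.vcf"),
            sweepsBed = file.path(dir, "sweeps_truth.bed"),
            qtlBed = file.path(dir, "qtls.bed"),
            counts = file.path(dir, "counts.tsv"),
            pairing = file.path(dir, "pairing.tsv"),
            marked = file.path(dir, "marked_genes.txt"),
            popmap = file.path(dir, "populations.tsv"),
            chromSizes = file.path(dir, "chrom_sizes.tsv"),
            truth = file.path(dir, "truth.json"))
        writeXStringSet(world$genome, paths$fasta)
        .writeGff3(world, paths$gff)
        .writeVcfText(pops, world$chromSizes, paths$vcf)
        writeRegionsBed(config$sweeps, paths$sweepsBed, namePrefix = "sweep")
        writeRegionsBed(qtls, paths$qtlBed, namePrefix = "QTL")
        cnt <- data.frame(gene = rownames(expr$counts),
                          length = as.integer(expr$lengths[rownames(expr$counts)]),
                          expr$counts, check.names = FALSE)
        utils::write.table(cnt, paths$counts, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(expr$pairing, paths$pairing, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        writeLines(marked, paths$marked)
        popmap <- data.frame(
            sample = c(pops$samples$A, pops$samples$B),
            population = c(rep("A", length(pops$samples$A)),
                           rep("B", length(pops$samples$B))))
        utils::write.table(popmap, paths$popmap, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        utils::write.table(
            data.frame(chrom = names(world$chromSizes),
                       size = as.integer(world$chromSizes)),
            paths$chromSizes, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
        truthJson <- list(
            seed = config$seed,
            sweeps = data.frame(chrom = as.character(seqnames(truth@sweeps)),
                                start = start(truth@sweeps) - 1L,
                                end = end(truth@sweeps)),
            de_genes = truth@deGenes,
            saac_genes_a = truth@saacGenesA,
            saac_genes_b = truth@saacGenesB,
            class_tally = as.list(siteClassTally(truth@siteClass)))
        jsonlite::write_json(truthJson, paths$truth, auto_unbox = TRUE,
                             pretty = TRUE)
        res$paths <- paths
    }
    invisible(res)
}

.writeGff3 <- function(world, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (ch in names(world$chromSizes))
        writeLines(sprintf("##sequence-region %s 1 %d", ch,
                           world$chromSizes[[ch]]), con)
    g <- world$genes
    cds <- world$cds
    for (i in seq_len(nrow(g))) {
        writeLines(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                           g$chrom[i], g$start[i], g$end[i], g$strand[i],
                           g$gene_id[i]), con)
        writeLines(sprintf(
            "%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            g$chrom[i], g$start[i], g$end[i], g$strand[i],
            g$transcript_id[i], g$gene_id[i]), con)
        sel <- which(mcols(cds)$gene_id == g$gene_id[i])
        for (j in sel)
            writeLines(sprintf(
                "%s\tsim\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds:%s;Parent=%s;gene_id=%s",
                g$chrom[i], start(cds)[j], end(cds)[j], g$strand[i],
                mcols(cds)$phase[j], g$transcript_id[i],
                g$transcript_id[i], g$gene_id[i]), con)
    }
    invisible(path)
}

.writeVcfText <- function(pops, chromSizes, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##fileformat=VCFv4.2", con)
    writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               con)
    for (ch in names(chromSizes))
        writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                           chromSizes[[ch]]), con)
    samples <- colnames(pops$gt)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"), con)
    sites <- pops$sites
    body <- paste(as.character(seqnames(sites)), start(sites), ".",
                  mcols(sites)$ref, mcols(sites)$alt, ".", "PASS", ".", "GT",
                  apply(pops$gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
    invisible(path)
}
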