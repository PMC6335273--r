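#' @importFrom Biostrings readDNAStringSet DNAStringSet DNAString subseq
#'   reverseComplement translate GENETIC_CODE
#' @importFrom rtracklayer import export
NULL

.EFFECTS <- c("SYNONYMOUS", "NONSYNONYMOUS", "STOPGAIN", "STOPLOSS",
              "FRAMESHIFT", "NONFRAMESHIFT_INDEL", "NONCODING",
              "SPLICE_REGION")
.AA_CHANGING <- c("NONSYNONYMOUS", "STOPGAIN", "STOPLOSS", "FRAMESHIFT",
                  "NONFRAMESHIFT_INDEL")

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Read CDS gene models from GFF3/GTF
#'
#' Imports CDS features, groups them into transcripts, keeps the single
#' longest-CDS transcript per gene, and drops (with a message) transcripts
#' whose concatenated CDS length is not a multiple of 3.
#'
#' @param gffPath path to a GFF3 or GTF file whose CDS features carry
#'   \code{Parent}/\code{transcript_id} and (directly or via parents)
#'   \code{gene_id}-style attributes.  Files written by
#'   [simulateGenome()] use \code{ID=cds:<tx>;Parent=<tx>;gene_id=<gene>}.
#' @return a named list of gene models; each element has \code{gene_id},
#'   \code{transcript_id}, \code{chrom}, \code{strand}, and \code{segments}
#'   (a \code{GRanges} of CDS exons ordered 5' to 3' in transcript
#'   orientation).
#' @export
readGeneModels <- function(gffPath) {
    gff <- rtracklayer::import(gffPath)
    cds <- gff[gff$type == "CDS"]
    if (length(cds) == 0L) return(list())
    m <- mcols(cds)
    txid <- if (!is.null(m$transcript_id)) as.character(m$transcript_id)
            else vapply(m$Parent, function(p) as.character(p)[1], character(1))
    gid <- if (!is.null(m$gene_id)) as.character(m$gene_id) else txid
    models <- lapply(split(seq_along(cds), txid), function(i) {
        seg <- granges(cds[i])
        str <- as.character(strand(seg))[1]
        seg <- if (str == "-") seg[order(-start(seg))] else seg[order(start(seg))]
        list(gene_id = gid[i[1]], transcript_id = txid[i[1]],
             chrom = as.character(seqnames(seg))[1], strand = str,
             segments = seg, cdsLen = sum(width(seg)))
    })
    bad <- vapply(models, function(mo) mo$cdsLen %% 3L != 0L, logical(1))
    if (any(bad)) {
        message("skipping ", sum(bad),
                " transcript(s) with partial CDS (length not multiple of 3)")
        models <- models[!bad]
    }
    ## longest CDS per gene
    genes <- vapply(models, `[[`, character(1), "gene_id")
    lens <- vapply(models, `[[`, numeric(1), "cdsLen")
    keep <- unlist(lapply(split(seq_along(models), genes), function(i)
        i[which.max(lens[i])]))
    models <- models[sort(keep)]
    names(models) <- vapply(models, `[[`, character(1), "gene_id")
    models
}

## Genomic positions of a model's CDS bases, 5'->3' in transcript orientation.
.cdsGenomicPos <- function(model) {
    unlist(lapply(seq_along(model$segments), function(i) {
        s <- start(model$segments)[i]; e <- end(model$segments)[i]
        if (model$strand == "-") seq.int(e, s) else seq.int(s, e)
    }))
}

## CDS nucleotide sequence of a model from a per-chromosome DNAStringSet.
.cdsSequence <- function(model, genome) {
    chrSeq <- genome[[model$chrom]]
    parts <- lapply(seq_along(model$segments), function(i) {
        x <- subseq(chrSeq, start(model$segments)[i], end(model$segments)[i])
        if (model$strand == "-") reverseComplement(x) else x
    })
    as.character(do.call(Biostrings::xscat, parts))
}

.translateCodon <- function(codon) {
    aa <- Biostrings::GENETIC_CODE[[codon]]
    if (is.null(aa) || is.na(aa)) "X" else aa
}

#' Annotate variants against gene models at codon level
#'
#' Classifies each variant (typically the fixed differences of one
#' population) against every overlapping gene model.  SNVs inside a CDS are
#' translated in transcript orientation (reverse-complemented on the minus
#' strand) with the standard nuclear code and classified as
#' SYNONYMOUS / NONSYNONYMOUS / STOPGAIN / STOPLOSS, with an amino-acid
#' change string like \code{"G86R"} (1-based protein coordinates, \code{*}
#' for stop).  Indels touching a CDS are FRAMESHIFT when the length change is
#' not a multiple of 3, NONFRAMESHIFT_INDEL otherwise.  SNVs within 2 bp of a
#' CDS edge on the non-coding side are SPLICE_REGION; everything else is
#' NONCODING.
#'
#' @param variants \code{GRanges} with metadata columns \code{ref} and
#'   \code{alt} (single chosen alternate allele per variant, VCF-style
#'   anchored representation for indels).
#' @param models gene-model list from [readGeneModels()].
#' @param genome a \code{DNAStringSet} named by chromosome, or a FASTA path.
#' @return \code{data.frame} with one row per (variant, overlapping gene)
#'   pair — plus one NONCODING row for variants hitting no gene — and columns
#'   chrom, pos, ref, alt, gene_id, transcript_id, effect, aa_change.
#'   Reference-mismatch between \code{ref} and the genome is an error.
#' @export
annotateVariants <- function(variants, models, genome) {
    if (is.character(genome)) genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    ref <- as.character(mcols(variants)$ref)
    alt <- as.character(mcols(variants)$alt)
    chrom <- as.character(seqnames(variants))
    pos <- start(variants)
    ## data-integrity: genome base(s) must match the stated ref allele
    for (i in seq_along(variants)) {
        gref <- as.character(subseq(genome[[chrom[i]]], pos[i],
                                    pos[i] + nchar(ref[i]) - 1L))
        if (gref != ref[i])
            stop("reference mismatch at ", chrom[i], ":", pos[i],
                 " (VCF ref ", ref[i], ", genome ", gref, ")")
    }
    ## interval actually affected by the variant
    affected <- GRanges(chrom, IRanges(pos, pos + nchar(ref) - 1L))
    segAll <- suppressWarnings(do.call(c, unname(lapply(models, function(mo) {
        g <- mo$segments
        mcols(g)$model <- mo$gene_id
        g
    }))))
    out <- list()
    emit <- function(i, gene, tx, eff, aac) {
        out[[length(out) + 1L]] <<- data.frame(
            chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt[i],
            gene_id = gene, transcript_id = tx, effect = eff,
            aa_change = aac, stringsAsFactors = FALSE)
    }
    ## per-model caches
    cdsSeqCache <- list(); cdsPosCache <- list()
    near <- if (length(segAll) > 0L)
        findOverlaps(affected, segAll, maxgap = 2L) else NULL
    hitGenes <- if (is.null(near)) rep(list(character(0)), length(variants))
        else split(mcols(segAll)$model[S4Vectors::subjectHits(near)],
                   factor(S4Vectors::queryHits(near),
                          levels = seq_along(variants)))
    for (i in seq_along(variants)) {
        genes <- unique(hitGenes[[i]])
        if (length(genes) == 0L) {
            emit(i, NA_character_, NA_character_, "NONCODING", NA_character_)
            next
        }
        for (g in genes) {
            mo <- models[[g]]
            inCDS <- any(start(mo$segments) <= end(affected)[i] &
                         end(mo$segments) >= pos[i])
            isSNV <- nchar(ref[i]) == 1L && nchar(alt[i]) == 1L
            if (!inCDS) {
                emit(i, mo$gene_id, mo$transcript_id,
                     if (isSNV) "SPLICE_REGION" else "NONCODING",
                     NA_character_)
                next
            }
            if (!isSNV) {
                shift <- nchar(alt[i]) - nchar(ref[i])
                eff <- if (abs(shift) %% 3L != 0L) "FRAMESHIFT"
                       else "NONFRAMESHIFT_INDEL"
                emit(i, mo$gene_id, mo$transcript_id, eff, NA_character_)
                next
            }
            if (is.null(cdsSeqCache[[g]])) {
                cdsSeqCache[[g]] <- .cdsSequence(mo, genome)
                cdsPosCache[[g]] <- .cdsGenomicPos(mo)
            }
            cdsPos <- match(pos[i], cdsPosCache[[g]])
            if (is.na(cdsPos)) {  # inside span but intronic (splice check done)
                emit(i, mo$gene_id, mo$transcript_id, "SPLICE_REGION",
                     NA_character_)
                next
            }
            base <- if (mo$strand == "-") .COMP[[alt[i]]] else alt[i]
            codonIdx <- (cdsPos - 1L) %/% 3L + 1L
            within <- (cdsPos - 1L) %% 3L + 1L
            refCodon <- substr(cdsSeqCache[[g]], (codonIdx - 1L) * 3L + 1L,
                               codonIdx * 3L)
            altCodon <- refCodon
            substr(altCodon, within, within) <- base
            refAA <- .translateCodon(refCodon)
            altAA <- .translateCodon(altCodon)
            eff <- if (refAA == altAA) "SYNONYMOUS"
                   else if (altAA == "*") "STOPGAIN"
                   else if (refAA == "*") "STOPLOSS"
                   else "NONSYNONYMOUS"
            aac <- if (eff == "SYNONYMOUS") NA_character_
                   else paste0(refAA, codonIdx, altAA)
            emit(i, mo$gene_id, mo$transcript_id, eff, aac)
        }
    }
    do.call(rbind, out)
}

#' Specific amino-acid-changed (SAAC) gene sets
#'
#' A gene is "amino acid changed" in a population when it carries at least
#' one NONSYNONYMOUS, STOPGAIN, STOPLOSS, FRAMESHIFT or NONFRAMESHIFT_INDEL
#' fixed variant there.  The SAAC sets are the two set differences: genes
#' changed in exactly one population.
#'
#' @param effectsA,effectsB effect tables from [annotateVariants()] run on
#'   the fixed variants of populations A and B respectively.
#' @return list with \code{changedA}, \code{changedB}, \code{saacA}
#'   (= changedA minus changedB), \code{saacB}.
#' @export
saacSets <- function(effectsA, effectsB) {
    changed <- function(e) {
        if (is.null(e) || nrow(e) == 0L) return(character(0))
        sort(unique(e$gene_id[e$effect %in% .AA_CHANGING & !is.na(e$gene_id)]))
    }
    a <- changed(effectsA); b <- changed(effectsB)
    list(changedA = a, changedB = b,
         saacA = setdiff(a, b), saacB = setdiff(b, a))
}

#' Non-synonymous/synonymous ratio inside vs outside PASS regions
#'
#' Splits the coding SNV effects of one population's fixed variants by
#' whether the site lies in a PASS region, forms the 2x2 table
#' \code{[[NS_in, S_in], [NS_out, S_out]]} and tests it with a two-sided
#' Fisher's exact test.
#'
#' @param effects effect table from [annotateVariants()]; only SYNONYMOUS and
#'   NONSYNONYMOUS rows are used.
#' @param passRegions \code{GRanges} of PASS regions.
#' @return list with \code{ratio_in}, \code{ratio_out} (NaN when the
#'   synonymous stratum is empty), \code{p}, and the 2x2 \code{table}.
#' @export
nsSynRatioTest <- function(effects, passRegions) {
    e <- effects[effects$effect %in% c("SYNONYMOUS", "NONSYNONYMOUS"), ,
                 drop = FALSE]
    gr <- GRanges(e$chrom, IRanges(e$pos, e$pos))
    inside <- countOverlaps(gr, passRegions) > 0L
    ns <- e$effect == "NONSYNONYMOUS"
    tab <- matrix(c(sum(ns & inside), sum(!ns & inside),
                    sum(ns & !inside), sum(!ns & !inside)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("in", "out"), c("NS", "S")))
    p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
        stats::fisher.test(tab)$p.value else 1
    list(ratio_in = tab[1, 1] / tab[1, 2],
         ratio_out = tab[2, 1] / tab[2, 2],
         p = p, table = tab)
}
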