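#' @importFrom GenomicRanges GRanges start end seqnames
#' @importFrom IRanges IRanges
NULL

#' TranscriptModel: exon structure and TIS of one transcript
#'
#' Exons are stored as 1-based inclusive genomic intervals, non-overlapping
#' and ordered 5' to 3' in transcript orientation (ascending genomic
#' coordinates on the plus strand, descending on the minus strand). The TIS
#' is the genomic position of the first nucleotide of the start codon and
#' must fall inside an exon.
#'
#' @slot transcriptId Transcript identifier.
#' @slot chromosome Chromosome name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons An [IRanges::IRanges] of exon intervals (stored ascending).
#' @slot tisGenomicPos 1-based genomic position of the TIS.
#' @export
setClass("TranscriptModel",
    slots = c(
        transcriptId = "character",
        chromosome = "character",
        strand = "character",
        exons = "IRanges",
        tisGenomicPos = "integer"
    )
)

setValidity("TranscriptModel", function(object) {
    ex <- object@exons
    if (length(ex) == 0L) return("no exons")
    if (!object@strand %in% c("+", "-")) return("strand must be + or -")
    s <- IRanges::start(ex)
    e <- IRanges::end(ex)
    if (is.unsorted(s) || any(e[-length(e)] >= s[-1L])) {
        return("exons must be sorted and non-overlapping")
    }
    tis <- object@tisGenomicPos
    if (!any(tis >= s & tis <= e)) {
        return("TIS position not inside an exon")
    }
    TRUE
})

setMethod("show", "TranscriptModel", function(object) {
    cat("TranscriptModel", object@transcriptId, "on",
        object@chromosome, object@strand, "with",
        length(object@exons), "exon(s), TIS at",
        object@tisGenomicPos, "\n")
})

#' @rdname TranscriptModel-class
#' @param transcriptId,chromosome,strand,tisGenomicPos See slots.
#' @param exonStarts,exonEnds Integer vectors of 1-based inclusive exon
#'   bounds (any order; stored sorted ascending).
#' @return A \linkS4class{TranscriptModel}.
#' @export
transcriptModel <- function(transcriptId, chromosome, strand,
                            exonStarts, exonEnds, tisGenomicPos) {
    ord <- order(exonStarts)
    new("TranscriptModel",
        transcriptId = transcriptId,
        chromosome = chromosome,
        strand = strand,
        exons = IRanges::IRanges(start = exonStarts[ord],
                                 end = exonEnds[ord]),
        tisGenomicPos = as.integer(tisGenomicPos))
}

## Genomic positions of the coding nucleotides, in translation order,
## starting at the TIS and walking the spliced exons in transcript
## orientation.
.codingPositions <- function(tm) {
    s <- IRanges::start(tm@exons)
    e <- IRanges::end(tm@exons)
    if (tm@strand == "+") {
        pos <- unlist(lapply(seq_along(s), function(i) s[i]:e[i]))
    } else {
        pos <- unlist(lapply(rev(seq_along(s)), function(i) e[i]:s[i]))
    }
    idx <- match(tm@tisGenomicPos, pos)
    pos[idx:length(pos)]
}

#' Map a peptide to genomic coordinates
#'
#' Protein positions \code{[start, end]} on the proteoform encoded by a
#' transcript map to the spliced nucleotide interval
#' \code{[3(start - 1) + 1, 3 end]} counted from the TIS along the exons,
#' which is then projected back to genomic blocks honouring strand and
#' splice junctions. Blocks are emitted 0-based half-open (BED convention),
#' sorted by ascending genomic start; their lengths sum to three times the
#' peptide length. Partial codons are never emitted.
#'
#' @param start,end 1-based inclusive protein positions of the peptide on
#'   the proteoform encoded by \code{tm} (position 1 = the TIS codon).
#' @param tm A \linkS4class{TranscriptModel}.
#' @param peptide_id Optional identifier carried into the result.
#' @return A data.frame of class \code{"GenomeBlockSet"} with columns
#'   \code{chrom}, \code{chromStart} (0-based), \code{chromEnd}
#'   (exclusive), \code{strand}, \code{peptide_id}.
#' @export
#' @examples
#' tm <- transcriptModel("t1", "chr1", "+", 1001, 1100, 1001)
#' mapPeptideToGenome(1, 3, tm)  # one 9-nt block [1000, 1009)
mapPeptideToGenome <- function(start, end, tm, peptide_id = NA_character_) {
    stopifnot(start >= 1L, end >= start)
    coding <- .codingPositions(tm)
    nt <- (3L * (start - 1L) + 1L):(3L * end)
    if (max(nt) > length(coding)) {
        stop("out of transcript bounds: peptide needs ", max(nt),
             " coding nucleotides but only ", length(coding),
             " are available downstream of the TIS")
    }
    g <- coding[nt]
    ## collapse consecutive runs (ascending on +, descending on -)
    step <- if (tm@strand == "+") 1L else -1L
    breaks <- c(0L, which(diff(g) != step), length(g))
    blocks <- do.call(rbind, lapply(seq_len(length(breaks) - 1L),
        function(i) {
            run <- g[(breaks[i] + 1L):breaks[i + 1L]]
            c(min(run), max(run))
        }))
    out <- data.frame(
        chrom = tm@chromosome,
        chromStart = blocks[, 1L] - 1L,
        chromEnd = blocks[, 2L],
        strand = tm@strand,
        peptide_id = peptide_id,
        stringsAsFactors = FALSE
    )
    out <- out[order(out$chromStart), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("GenomeBlockSet", class(out))
    out
}

#' Write genome-mapped peptides as BED12
#'
#' One record per peptide; the blocks become blockSizes/blockStarts.
#'
#' @param blockSets A list of \code{GenomeBlockSet} data.frames (or one).
#' @param path Output path.
#' @param names Feature names; defaults to the peptide ids.
#' @return The path, invisibly.
#' @export
writeBed12 <- function(blockSets, path, names = NULL) {
    if (is.data.frame(blockSets)) blockSets <- list(blockSets)
    lines <- vapply(seq_along(blockSets), function(i) {
        b <- blockSets[[i]]
        chromStart <- min(b$chromStart)
        chromEnd <- max(b$chromEnd)
        nm <- if (!is.null(names)) names[i] else {
            if (!is.na(b$peptide_id[1L])) b$peptide_id[1L]
            else paste0("peptide", i)
        }
        paste(b$chrom[1L], chromStart, chromEnd, nm, 0L, b$strand[1L],
              chromStart, chromEnd, "0,0,0", nrow(b),
              paste0(paste(b$chromEnd - b$chromStart, collapse = ","), ","),
              paste0(paste(b$chromStart - chromStart, collapse = ","), ","),
              sep = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Read transcript models from a GTF subset
#'
#' Reads exon records (grouped by the \code{transcript_id} attribute) via
#' \pkg{rtracklayer}. TIS positions are taken from \code{start_codon}
#' records when present, or supplied explicitly (e.g. parsed from custom
#' accessions with [parseCustomAccession()]).
#'
#' @param path Path to a GTF file containing exon (and optionally
#'   start_codon) lines.
#' @param tis Optional named integer vector mapping transcript ids to TIS
#'   genomic positions, overriding/supplementing start_codon records.
#' @return A named list of \linkS4class{TranscriptModel}s (transcripts
#'   without a known TIS are dropped).
#' @export
readTranscriptModels <- function(path, tis = NULL) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
        stop("readTranscriptModels requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    sc <- gr[gr$type == "start_codon"]
    tis_map <- if (length(sc) > 0L) {
        stats::setNames(
            ifelse(as.character(GenomicRanges::strand(sc)) == "-",
                   GenomicRanges::end(sc), GenomicRanges::start(sc)),
            sc$transcript_id)
    } else integer(0)
    if (!is.null(tis)) tis_map <- c(tis, tis_map[setdiff(names(tis_map),
                                                         names(tis))])
    models <- list()
    for (tx in unique(ex$transcript_id)) {
        if (!tx %in% names(tis_map)) next
        sub <- ex[ex$transcript_id == tx]
        models[[tx]] <- transcriptModel(
            transcriptId = tx,
            chromosome = as.character(GenomicRanges::seqnames(sub))[1L],
            strand = as.character(GenomicRanges::strand(sub))[1L],
            exonStarts = GenomicRanges::start(sub),
            exonEnds = GenomicRanges::end(sub),
            tisGenomicPos = tis_map[[tx]])
    }
    models
}
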