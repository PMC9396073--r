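#' Source categories of proteoform database entries
#'
#' Every entry in a custom proteoform database carries one source category:
#' curated UniProt canonical entries, UniProt isoforms, or Ribo-Seq-derived
#' proteoforms annotated by the position of their translation initiation site
#' (TIS) relative to the Ensembl transcript annotation: \code{atis} (annotated
#' TIS), \code{cds} (TIS inside the coding sequence), \code{utr5} / \code{utr3}
#' (TIS in an untranslated region) and \code{ntr} (TIS on a noncoding
#' transcript such as a pseudogene or a retained-intron transcript).
#'
#' @return Character vector of the seven recognised category codes.
#' @export
#' @examples
#' sourceCategories()
sourceCategories <- function() {
    c("uniprot", "uniprot_isoform", "atis", "cds", "utr5", "utr3", "ntr")
}

## Accession tokens used in FASTA headers for the Ribo-Seq annotation field.
.annotationTokens <- c(
    atis = "aTIS", cds = "CDS", utr5 = "5UTR", utr3 = "3UTR", ntr = "ntr"
)

.checkCategory <- function(category) {
    bad <- setdiff(unique(category), sourceCategories())
    if (length(bad) > 0L) {
        stop("unknown source category: ", paste(bad, collapse = ", "))
    }
    invisible(category)
}

#' Priority rank of a source category
#'
#' Two distinct priority orders are in use and are kept as named schemes.
#' The \code{peptide_sorting} scheme orders peptide-to-entry matches when one
#' peptide matches several database entries (UniProt before UniProt isoforms
#' before Ribo-Seq proteoforms, and within Ribo-Seq proteoforms
#' aTIS > CDS > 5'UTR > 3'UTR > NTR). The \code{db_main_id} scheme chooses the
#' main identifier when redundant sequences are collapsed at database build
#' time (aTIS, CDS, 5UTR, ntr, 3UTR after UniProt). The two schemes differ in
#' the relative position of \code{ntr} and \code{utr3}.
#'
#' @param category Character vector of category codes (see
#'   [sourceCategories()]).
#' @param scheme Either \code{"peptide_sorting"} or \code{"db_main_id"}.
#' @return Integer vector of ranks; lower rank means higher priority.
#' @export
#' @examples
#' categoryRank("uniprot", "peptide_sorting")  # 0
#' categoryRank("ntr", "peptide_sorting")      # 6
#' categoryRank("ntr", "db_main_id") < categoryRank("utr3", "db_main_id")
categoryRank <- function(category,
                         scheme = c("peptide_sorting", "db_main_id")) {
    scheme <- match.arg(scheme)
    .checkCategory(category)
    order <- switch(scheme,
        peptide_sorting = c("uniprot", "uniprot_isoform", "atis", "cds",
                            "utr5", "utr3", "ntr"),
        db_main_id = c("uniprot", "uniprot_isoform", "atis", "cds",
                       "utr5", "ntr", "utr3")
    )
    match(category, order) - 1L
}

#' Parse a custom proteoform accession
#'
#' Custom accessions are composed of the Ensembl transcript identifier, the
#' chromosome, the genomic position of the TIS, the TIS annotation
#' (\code{aTIS}, \code{CDS}, \code{5UTR}, \code{3UTR} or \code{ntr}) and a
#' final six-character block whose first three characters are binary flags
#' ("bincodes") denoting the Ribo-Seq dataset(s) of origin, followed by a
#' verbatim suffix (e.g. \code{"db1"}) that is stored but never interpreted.
#'
#' @param id Character vector of accessions such as
#'   \code{"ENST00000403258_6_88276364_ntr_101db1"}.
#' @return A data.frame with one row per accession and columns
#'   \code{transcript_id}, \code{chromosome}, \code{tis_genomic_pos},
#'   \code{annotation} (a category code), \code{bincode_flags} and
#'   \code{suffix}. [formatCustomAccession()] on the result reproduces the
#'   input exactly.
#' @export
#' @examples
#' parseCustomAccession("ENST00000403258_6_88276364_ntr_101db1")
parseCustomAccession <- function(id) {
    stopifnot(is.character(id))
    one <- function(x) {
        fields <- strsplit(x, "_", fixed = TRUE)[[1L]]
        n <- length(fields)
        if (n < 5L) {
            stop("malformed accession '", x,
                 "': expected at least 5 underscore-separated fields")
        }
        last <- fields[n]
        if (nchar(last) < 4L ||
            !grepl("^[01]{3}", last)) {
            stop("malformed accession '", x,
                 "': bincode block '", last,
                 "' must start with three 0/1 flags")
        }
        annot_tok <- fields[n - 1L]
        annot <- names(.annotationTokens)[match(annot_tok,
                                                .annotationTokens)]
        if (is.na(annot)) {
            stop("malformed accession '", x, "': unknown TIS annotation '",
                 annot_tok, "'")
        }
        pos <- suppressWarnings(as.integer(fields[n - 2L]))
        if (is.na(pos) || pos <= 0L) {
            stop("malformed accession '", x,
                 "': TIS genomic position '", fields[n - 2L],
                 "' is not a positive integer")
        }
        ## chromosome may itself contain underscores (scaffolds)
        chrom <- paste(fields[2:(n - 3L)], collapse = "_")
        if (!nzchar(chrom)) {
            stop("malformed accession '", x, "': empty chromosome field")
        }
        data.frame(
            transcript_id = fields[1L],
            chromosome = chrom,
            tis_genomic_pos = pos,
            annotation = annot,
            bincode_flags = substr(last, 1L, 3L),
            suffix = substring(last, 4L),
            stringsAsFactors = FALSE
        )
    }
    do.call(rbind, lapply(id, one))
}

#' @rdname parseCustomAccession
#' @param accession A data.frame as returned by [parseCustomAccession()].
#' @export
formatCustomAccession <- function(accession) {
    stopifnot(is.data.frame(accession))
    paste(accession$transcript_id,
          accession$chromosome,
          accession$tis_genomic_pos,
          .annotationTokens[accession$annotation],
          paste0(accession$bincode_flags, accession$suffix),
          sep = "_")
}

#' Is an identifier a custom (Ribo-Seq proteoform) accession?
#'
#' @param id Character vector.
#' @return Logical vector.
#' @export
isCustomAccession <- function(id) {
    vapply(id, function(x) {
        !inherits(try(parseCustomAccession(x), silent = TRUE), "try-error")
    }, logical(1L), USE.NAMES = FALSE)
}

#' Infer the source category of an identifier
#'
#' Custom accessions carry their category in the TIS annotation field.
#' All other identifiers are treated as UniProt accessions; an identifier with
#' a trailing dash-number isoform suffix (e.g. \code{"P14618-2"}) is an
#' isoform.
#'
#' @param id Character vector of identifiers.
#' @return Character vector of category codes.
#' @export
#' @examples
#' inferCategory(c("P14618", "P14618-2", "ENST00000403258_6_88276364_ntr_101db1"))
inferCategory <- function(id) {
    custom <- isCustomAccession(id)
    out <- character(length(id))
    if (any(custom)) {
        out[custom] <- parseCustomAccession(id[custom])$annotation
    }
    iso <- !custom & grepl("-[0-9]+$", id)
    out[iso] <- "uniprot_isoform"
    out[!custom & !iso] <- "uniprot"
    out
}
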