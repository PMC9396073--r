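#' Exact-match scan of a peptide against annotated proteins
#'
#' Finds every occurrence of a peptide as an exact (optionally I/L-folded)
#' substring of the reference entries. By default the reference is
#' restricted to annotated proteins (UniProt canonical and isoform
#' categories), mirroring the homology curation of candidate NTR peptides.
#'
#' @param peptide A single peptide sequence.
#' @param db A \linkS4class{ProteoformDatabase} (or named character vector
#'   of subject sequences).
#' @param ilFold Fold I and L together before comparing?
#' @param categories Categories retained as reference subjects (ignored when
#'   \code{db} is a plain vector).
#' @return A data.frame with columns \code{peptide}, \code{subject_id},
#'   \code{subject_start} (1-based), \code{n_mismatches} (all 0),
#'   \code{mismatch_positions}, \code{peptide_residues},
#'   \code{subject_residues} (all empty).
#' @export
exactMatchScan <- function(peptide, db, ilFold = TRUE,
                           categories = c("uniprot", "uniprot_isoform")) {
    subjects <- .referenceSubjects(db, categories)
    pep <- if (ilFold) foldIL(peptide) else peptide
    rows <- lapply(names(subjects), function(id) {
        s <- if (ilFold) foldIL(subjects[[id]]) else subjects[[id]]
        hits <- gregexpr(pep, s, fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) return(NULL)
        data.frame(peptide = peptide, subject_id = id,
                   subject_start = as.integer(hits),
                   n_mismatches = 0L, mismatch_positions = "",
                   peptide_residues = "", subject_residues = "",
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- .emptyHomologyFrame()
    out
}

.referenceSubjects <- function(db, categories) {
    if (is(db, "ProteoformDatabase")) {
        keep <- db@category %in% categories
        stats::setNames(as.character(db@sequences[keep]),
                        mainIds(db)[keep])
    } else {
        stopifnot(!is.null(names(db)))
        stats::setNames(as.character(db), names(db))
    }
}

.emptyHomologyFrame <- function() {
    data.frame(peptide = character(0), subject_id = character(0),
               subject_start = integer(0), n_mismatches = integer(0),
               mismatch_positions = character(0),
               peptide_residues = character(0),
               subject_residues = character(0),
               stringsAsFactors = FALSE)
}

#' Near-match (bounded-Hamming) scan of a peptide
#'
#' Ungapped sliding-window comparison of a peptide against every window of
#' every reference subject, with I/L folded together. All hits achieving the
#' minimal mismatch count are returned, provided that count does not exceed
#' \code{maxMismatches}. For short peptides against a curated reference this
#' is equivalent to (or stricter than) a protein BLAST with parameters
#' adjusted for short sequences: all reported alignments are ungapped and
#' full peptide length.
#'
#' @param peptide A single peptide sequence.
#' @param db Reference database or named character vector, as in
#'   [exactMatchScan()].
#' @param maxMismatches Maximum number of mismatches reported (>= 1).
#' @param ilFold Fold I/L before comparing (mismatch residues are reported
#'   from the unfolded sequences)?
#' @param categories Reference categories, as in [exactMatchScan()].
#' @return A data.frame as in [exactMatchScan()];
#'   \code{mismatch_positions} holds comma-joined 1-based peptide positions,
#'   \code{peptide_residues} / \code{subject_residues} the differing
#'   residues in the same order.
#' @export
#' @examples
#' ref <- c(RPS2 = "KADDAGAAGGPGGPGGPGMGNRGGFRGGFW")
#' nearMatchScan("ADDAGAAGGPGGPGGPEMGNRGGFRGGF", ref)
nearMatchScan <- function(peptide, db, maxMismatches = 2L, ilFold = TRUE,
                          categories = c("uniprot", "uniprot_isoform")) {
    stopifnot(maxMismatches >= 1L)
    subjects <- .referenceSubjects(db, categories)
    n <- nchar(peptide)
    pep_f <- strsplit(if (ilFold) foldIL(peptide) else peptide, "")[[1L]]
    pep_o <- strsplit(peptide, "")[[1L]]
    best <- maxMismatches + 1L
    hits <- list()
    for (id in names(subjects)) {
        s <- subjects[[id]]
        m <- nchar(s)
        if (m < n) next
        s_f <- strsplit(if (ilFold) foldIL(s) else s, "")[[1L]]
        s_o <- strsplit(s, "")[[1L]]
        for (off in 0:(m - n)) {
            idx <- (off + 1L):(off + n)
            mism <- which(pep_f != s_f[idx])
            k <- length(mism)
            if (k > best || k > maxMismatches) next
            hit <- data.frame(
                peptide = peptide, subject_id = id,
                subject_start = off + 1L, n_mismatches = k,
                mismatch_positions = paste(mism, collapse = ","),
                peptide_residues = paste(pep_o[mism], collapse = ","),
                subject_residues = paste(s_o[idx][mism], collapse = ","),
                stringsAsFactors = FALSE)
            if (k < best) {
                best <- k
                hits <- list(hit)
            } else {
                hits[[length(hits) + 1L]] <- hit
            }
        }
    }
    out <- do.call(rbind, hits)
    if (is.null(out)) out <- .emptyHomologyFrame()
    rownames(out) <- NULL
    out
}

#' Can a residue difference be explained by a single-nucleotide change?
#'
#' Two residues are SNP-plausible when some codon of the first and some
#' codon of the second differ by exactly one base (standard genetic code);
#' the witnessing codon pair is returned. Identical residues are trivially
#' plausible (witnessed by a shared codon at distance 0). The test is
#' symmetric in its arguments.
#'
#' @param ref_residue,var_residue Single amino-acid letters.
#' @return A list with \code{ref_residue}, \code{var_residue},
#'   \code{plausible} (logical) and \code{witness_codon_pair} (character
#'   vector of two codons, or NULL).
#' @export
#' @examples
#' snpPlausible("G", "E")  # GGG -> GAG, plausible
#' snpPlausible("M", "Y")  # not plausible
snpPlausible <- function(ref_residue, var_residue) {
    code <- Biostrings::GENETIC_CODE
    codons <- function(aa) names(code)[code == aa]
    c1 <- codons(ref_residue)
    c2 <- codons(var_residue)
    if (length(c1) == 0L || length(c2) == 0L) {
        stop("no codons for residue(s): ",
             paste(c(ref_residue, var_residue)[
                 c(length(c1) == 0L, length(c2) == 0L)], collapse = ", "))
    }
    if (ref_residue == var_residue) {
        return(list(ref_residue = ref_residue, var_residue = var_residue,
                    plausible = TRUE,
                    witness_codon_pair = c(c1[1L], c1[1L])))
    }
    ham <- function(a, b) {
        sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
    }
    for (a in c1) {
        for (b in c2) {
            if (ham(a, b) == 1L) {
                return(list(ref_residue = ref_residue,
                            var_residue = var_residue,
                            plausible = TRUE,
                            witness_codon_pair = c(a, b)))
            }
        }
    }
    list(ref_residue = ref_residue, var_residue = var_residue,
         plausible = FALSE, witness_codon_pair = NULL)
}

#' Curation report for candidate NTR peptides
#'
#' One row per candidate peptide: whether it has an exact match to an
#' annotated protein, the best near match with its mismatch count, and
#' whether every mismatch is SNP-plausible.
#'
#' @param peptides Character vector of candidate peptide sequences.
#' @param db Reference database (see [exactMatchScan()]).
#' @param maxMismatches Passed to [nearMatchScan()].
#' @return A data.frame with columns \code{peptide}, \code{exact_hit}
#'   (subject id or NA), \code{best_near_hit}, \code{n_mismatches},
#'   \code{snp_plausible_all}.
#' @export
curationReport <- function(peptides, db, maxMismatches = 2L) {
    rows <- lapply(peptides, function(p) {
        ex <- exactMatchScan(p, db)
        near <- nearMatchScan(p, db, maxMismatches = maxMismatches)
        snp_all <- NA
        if (nrow(near) > 0L && near$n_mismatches[1L] > 0L) {
            pr <- strsplit(near$peptide_residues[1L], ",")[[1L]]
            sr <- strsplit(near$subject_residues[1L], ",")[[1L]]
            snp_all <- all(mapply(function(a, b)
                snpPlausible(b, a)$plausible, pr, sr))
        }
        data.frame(
            peptide = p,
            exact_hit = if (nrow(ex) > 0L) ex$subject_id[1L]
                        else NA_character_,
            best_near_hit = if (nrow(near) > 0L) near$subject_id[1L]
                            else NA_character_,
            n_mismatches = if (nrow(near) > 0L) near$n_mismatches[1L]
                           else NA_integer_,
            snp_plausible_all = snp_all,
            stringsAsFactors = FALSE
        )
    })
    do.call(rbind, rows)
}
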