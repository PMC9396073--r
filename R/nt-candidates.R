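#' Initiator-methionine processing rule sets
#'
#' Methionine aminopeptidases (MetAPs) excise the initiator methionine when
#' the second residue has a small gyration radius. Two named follower sets
#' are used in different parts of the analysis: the \code{"detectability"}
#' set \{A, S, G, P, T, V\} (used when generating processed Nt-peptides
#' in silico) and the \code{"metap"} set \{A, C, G, P, S, T, V\} (the full
#' MetAP specificity, used when classifying observed N termini).
#'
#' @param name \code{"detectability"} or \code{"metap"}.
#' @return Character vector of removable-follower residues with a
#'   \code{"set"} attribute.
#' @export
#' @examples
#' imetRuleSet("metap")
imetRuleSet <- function(name = c("detectability", "metap")) {
    name <- match.arg(name)
    sets <- list(
        detectability = c("A", "S", "G", "P", "T", "V"),
        metap = c("A", "C", "G", "P", "S", "T", "V")
    )
    structure(sets[[name]], set = name)
}

#' Generate candidate N-terminal peptides of a protein
#'
#' All digestion peptides starting at position 1 are candidate Nt-peptides.
#' When the sequence starts with methionine followed by a residue in the
#' iMet rule set, the iMet-processed protein is digested as well and its
#' position-1 peptides are reported with start 2 on the original sequence.
#'
#' @param sequence A single protein sequence.
#' @param rule A \linkS4class{ProteaseRule}.
#' @param imet An [imetRuleSet()] follower set.
#' @return A data.frame as from [digestSequence()] restricted to candidate
#'   Nt-peptides; \code{start} is 1 or 2 on the original sequence.
#' @export
#' @examples
#' generateNtCandidates("MAKRTTR", proteaseRule("argc"))
generateNtCandidates <- function(sequence, rule,
                                 imet = imetRuleSet("detectability")) {
    d <- digestSequence(sequence, rule)
    out <- d[d$start == 1L, , drop = FALSE]
    if (nchar(sequence) >= 3L &&
        substr(sequence, 1L, 1L) == "M" &&
        substr(sequence, 2L, 2L) %in% imet) {
        clipped <- substring(sequence, 2L)
        d2 <- digestSequence(clipped, rule)
        d2 <- d2[d2$start == 1L, , drop = FALSE]
        d2$start <- 2L
        d2$end <- d2$end + 1L
        out <- rbind(out, d2)
    }
    rownames(out) <- NULL
    out
}

#' Fold isoleucine onto leucine
#'
#' Leucine and isoleucine are isobaric and indistinguishable by standard MS
#' fragmentation; sequence comparisons for uniqueness and homology fold the
#' two together. The folding is idempotent and length-preserving.
#'
#' @param sequence Character vector.
#' @return Character vector with every I replaced by L.
#' @export
foldIL <- function(sequence) {
    chartr("I", "L", sequence)
}

#' Peptide uniqueness within a proteome
#'
#' Counts, for each peptide, the number of distinct database entries whose
#' sequence contains the peptide as a substring, with I/L folded on both
#' sides. A peptide is unique when the count is 1; a count of 0 flags an
#' inconsistency (the peptide does not occur in the proteome).
#'
#' @param peptides Character vector of peptide sequences.
#' @param db A \linkS4class{ProteoformDatabase} (or character vector of
#'   protein sequences).
#' @return Named integer vector of parent-entry counts.
#' @export
peptideUniqueness <- function(peptides, db) {
    proteome <- if (is(db, "ProteoformDatabase"))
        as.character(entrySequences(db)) else as.character(db)
    folded_prot <- foldIL(proteome)
    folded_pep <- foldIL(peptides)
    counts <- vapply(folded_pep, function(p) {
        sum(vapply(folded_prot, function(s) {
            grepl(p, s, fixed = TRUE)
        }, logical(1L)))
    }, integer(1L), USE.NAMES = FALSE)
    stats::setNames(counts, peptides)
}

#' Per-protein and aggregate MS-detectability summary
#'
#' For each entry and protease, peptides are generated either by full
#' digestion (\code{mode = "shotgun"}) or as candidate N-terminal peptides
#' (\code{mode = "nterm"}), the detectability criteria are applied, and
#' uniqueness of the detectable peptides is evaluated against the whole
#' database with I/L folding.
#'
#' @param db A \linkS4class{ProteoformDatabase}.
#' @param rules A list of \linkS4class{ProteaseRule}s (or one rule).
#' @param criteria A [detectabilityCriteria()] object.
#' @param imet iMet follower set for \code{mode = "nterm"}.
#' @param mode \code{"shotgun"} or \code{"nterm"}.
#' @param blockedAmines Passed to [msDetectable()].
#' @return A list with \code{per_entry} (one row per entry x protease:
#'   \code{n_peptides}, \code{n_detectable}, \code{n_unique_detectable},
#'   \code{has_detectable}, \code{has_unique}) and \code{aggregate} (by
#'   category x protease: entry counts and percent of entries with at least
#'   one detectable / unique detectable peptide).
#' @export
detectabilitySummary <- function(db, rules, criteria = detectabilityCriteria(),
                                 imet = imetRuleSet("detectability"),
                                 mode = c("shotgun", "nterm"),
                                 blockedAmines = FALSE) {
    mode <- match.arg(mode)
    if (is(rules, "ProteaseRule")) rules <- list(rules)
    ids <- mainIds(db)
    seqs <- as.character(entrySequences(db))
    cats <- db@category
    per <- list()
    for (rule in rules) {
        rows <- lapply(seq_along(ids), function(i) {
            peps <- if (mode == "shotgun") {
                digestSequence(seqs[i], rule)
            } else {
                generateNtCandidates(seqs[i], rule, imet)
            }
            det <- msDetectable(unique(peps$sequence), criteria,
                                blockedAmines = blockedAmines)
            detectable <- det$sequence[det$detectable]
            uniq <- if (length(detectable) > 0L)
                peptideUniqueness(detectable, db) else integer(0)
            data.frame(
                main_id = ids[i], category = cats[i], protease = rule@name,
                n_peptides = length(unique(peps$sequence)),
                n_detectable = length(detectable),
                n_unique_detectable = sum(uniq == 1L),
                stringsAsFactors = FALSE
            )
        })
        per[[rule@name]] <- do.call(rbind, rows)
    }
    per_entry <- do.call(rbind, per)
    rownames(per_entry) <- NULL
    per_entry$has_detectable <- per_entry$n_detectable > 0L
    per_entry$has_unique <- per_entry$n_unique_detectable > 0L
    agg <- do.call(rbind, lapply(
        split(per_entry,
              list(per_entry$category, per_entry$protease), drop = TRUE),
        function(g) data.frame(
            category = g$category[1L], protease = g$protease[1L],
            n_entries = nrow(g),
            pct_detectable = 100 * mean(g$has_detectable),
            pct_unique = 100 * mean(g$has_unique),
            stringsAsFactors = FALSE
        )))
    rownames(agg) <- NULL
    list(per_entry = per_entry, aggregate = agg)
}
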