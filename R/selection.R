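#' Remove internal, C-terminal and pyroglutamate peptides
#'
#' Distinct peptides that were only ever seen with a free alpha-amine are
#' internal peptides (the enrichment chemistry acetylates every true N
#' terminus in vivo or in vitro) and are removed. Peptides whose end
#' coincides with the end of their main entry and whose start is beyond
#' position 2 are C-terminal peptides and are removed; a peptide starting at
#' position 1 or 2 that reaches the end of the entry covers the complete
#' (micro)protein and is kept. Peptides seen only with an N-terminal
#' pyroglutamate are coenrichment artifacts: they are diverted to a side
#' table, neither Nt evidence nor internal.
#'
#' @param distinct A distinct-peptide data.frame from [deduplicatePsms()].
#' @param db A \linkS4class{ProteoformDatabase} used to resolve entry
#'   lengths and verify that each peptide occurs at its stated position.
#' @return A list with \code{candidates} (kept Nt-candidates, with an
#'   \code{end} column added), \code{removed} (with a \code{reason} column:
#'   \code{"internal"} or \code{"cterm"}) and \code{pyroglu} (the side
#'   table).
#' @export
filterTerminalClasses <- function(distinct, db) {
    parent <- entrySequence(db, distinct$main_entry)
    if (anyNA(parent)) {
        stop("main entries not in database: ",
             paste(unique(distinct$main_entry[is.na(parent)]),
                   collapse = ", "))
    }
    end <- distinct$main_start + nchar(distinct$peptide) - 1L
    obs <- substr(parent, distinct$main_start, end)
    if (any(obs != distinct$peptide)) {
        bad <- which(obs != distinct$peptide)[1L]
        stop("peptide ", distinct$peptide[bad],
             " is not a substring of entry ", distinct$main_entry[bad],
             " at position ", distinct$main_start[bad])
    }
    distinct$end <- end
    forms <- strsplit(distinct$forms_seen, ",", fixed = TRUE)
    pyro_only <- vapply(forms, function(f) all(f == "pyroglu"), logical(1L))
    free_only <- vapply(forms, function(f) all(f == "free"), logical(1L))
    cterm <- !pyro_only & !free_only &
        end == nchar(parent) & distinct$main_start > 2L
    keep <- !pyro_only & !free_only & !cterm
    removed <- distinct[free_only | cterm, , drop = FALSE]
    removed$reason <- ifelse(free_only[free_only | cterm],
                             "internal", "cterm")
    list(candidates = distinct[keep, , drop = FALSE],
         removed = removed,
         pyroglu = distinct[pyro_only, , drop = FALSE])
}

#' Collapse C-terminally ragged peptides
#'
#' Ragged peptides are an enrichment artifact: several peptides share the
#' same start position on the same database entry but are C-terminally
#' shorter. Within each (main entry, start) group the peptide with the
#' highest-priority N-terminal modification is kept (in vivo acetyl beats
#' heavy acetyl, even on a shorter form); among equals the longest sequence
#' wins. All shorter members are recorded, and PSM counts are aggregated
#' over the group so acetylation percentages remain PSM-count based.
#'
#' @param candidates A candidate data.frame from [filterTerminalClasses()].
#' @return The collapsed data.frame with a \code{shorter_variants} column
#'   (comma-joined peptide sequences, empty for singleton groups).
#' @export
collapseRagged <- function(candidates) {
    if (nrow(candidates) == 0L) {
        candidates$shorter_variants <- character(0)
        return(candidates)
    }
    key <- paste(candidates$main_entry, candidates$main_start, sep = "\r")
    groups <- split(seq_len(nrow(candidates)), key)
    rows <- lapply(groups, function(i) {
        g <- candidates[i, , drop = FALSE]
        ord <- order(-.modPriority(g$best_mod), -nchar(g$peptide),
                     g$peptide)
        g <- g[ord, , drop = FALSE]
        keep <- g[1L, , drop = FALSE]
        keep$shorter_variants <- paste(g$peptide[-1L], collapse = ",")
        keep$psm_count <- sum(g$psm_count)
        keep$n_invivo <- sum(g$n_invivo)
        keep$n_heavy <- sum(g$n_heavy)
        keep$acetylation_pct <- if (keep$n_invivo + keep$n_heavy > 0L)
            .roundAway(100 * keep$n_invivo /
                       (keep$n_invivo + keep$n_heavy), 0L) else NA_real_
        keep$forms_seen <- paste(
            sort(unique(unlist(strsplit(g$forms_seen, ",")))),
            collapse = ",")
        keep
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$main_entry, out$main_start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify candidate N-terminal peptides
#'
#' Decision tree, first match wins:
#' \enumerate{
#'   \item start at position 1 or 2 of any matched entry: database-annotated
#'     N terminus, high confidence (regardless of MetAP-rule compliance; the
#'     modification may be in vivo or heavy acetyl).
#'   \item start beyond 2 with a Ribo-Seq-called TIS at the matched
#'     (entry, start): alternative N terminus, high confidence.
#'   \item start beyond 2, in vivo acetylated, with initiator-methionine
#'     evidence (the peptide starts with Met, or is preceded by Met with a
#'     first residue in the MetAP follower set): alternative, high.
#'   \item start beyond 2, in vivo acetylated, no Met evidence, and the
#'     preceding residue is not a cleavage site of the protease used:
#'     alternative, low.
#'   \item start beyond 2, heavy acetylated, Met evidence as above, and not
#'     preceded by a cleavage site: alternative, low.
#'   \item otherwise removed, with a reason code
#'     (\code{"blocked_no_met"}, \code{"acetyl_follows_cleavage_site"} or
#'     \code{"blocked_follows_cleavage_site"}).
#' }
#'
#' @param candidates A data.frame from [collapseRagged()].
#' @param db A \linkS4class{ProteoformDatabase}.
#' @param riboseqTis Optional data.frame of Ribo-Seq-supported initiation
#'   sites with columns \code{entry_id} and \code{pos} (1-based protein
#'   position of the initiation on that entry).
#' @param rule The \linkS4class{ProteaseRule} of the dataset (used for the
#'   preceding-residue cleavage-site test).
#' @param imet iMet follower set; defaults to the full MetAP specificity.
#' @return The input with columns \code{category}
#'   (\code{"database_annotated"} / \code{"alternative"}), \code{confidence}
#'   (\code{"high"} / \code{"low"} / \code{"removed"}), \code{reason} and
#'   \code{preceding_residue} added.
#' @export
classifyNtPeptides <- function(candidates, db, riboseqTis = NULL, rule,
                               imet = imetRuleSet("metap")) {
    n <- nrow(candidates)
    category <- character(n)
    confidence <- character(n)
    reason <- character(n)
    preceding <- rep(NA_character_, n)
    tis_key <- if (!is.null(riboseqTis) && nrow(riboseqTis) > 0L) {
        paste(riboseqTis$entry_id, riboseqTis$pos, sep = "\r")
    } else character(0)
    for (i in seq_len(n)) {
        m <- .parseMatches(candidates$matches[i])
        start <- candidates$main_start[i]
        pep <- candidates$peptide[i]
        mod <- candidates$best_mod[i]
        if (start > 1L) {
            par <- entrySequence(db, candidates$main_entry[i])
            preceding[i] <- substr(par, start - 1L, start - 1L)
        }
        if (any(m$start <= 2L)) {
            category[i] <- "database_annotated"
            confidence[i] <- "high"
            reason[i] <- "annotated_start"
            next
        }
        if (length(tis_key) > 0L &&
            any(paste(m$entry_id, m$start, sep = "\r") %in% tis_key)) {
            category[i] <- "alternative"
            confidence[i] <- "high"
            reason[i] <- "riboseq_tis"
            next
        }
        met_evidence <- substr(pep, 1L, 1L) == "M" ||
            (!is.na(preceding[i]) && preceding[i] == "M" &&
             substr(pep, 1L, 1L) %in% imet)
        at_cleavage <- !is.na(preceding[i]) &&
            preceding[i] %in% rule@cleaveAfter
        if (mod == "invivo_ac" && met_evidence) {
            category[i] <- "alternative"
            confidence[i] <- "high"
            reason[i] <- "cotranslational_acetyl_met"
        } else if (mod == "invivo_ac" && !at_cleavage) {
            category[i] <- "alternative"
            confidence[i] <- "low"
            reason[i] <- "cotranslational_acetyl_no_cleavage"
        } else if (mod == "invivo_ac") {
            category[i] <- "removed"
            confidence[i] <- "removed"
            reason[i] <- "acetyl_follows_cleavage_site"
        } else if (mod == "heavy_ac" && met_evidence && !at_cleavage) {
            category[i] <- "alternative"
            confidence[i] <- "low"
            reason[i] <- "blocked_met_no_cleavage"
        } else if (mod == "heavy_ac" && met_evidence) {
            category[i] <- "removed"
            confidence[i] <- "removed"
            reason[i] <- "blocked_follows_cleavage_site"
        } else {
            category[i] <- "removed"
            confidence[i] <- "removed"
            reason[i] <- "blocked_no_met"
        }
    }
    candidates$preceding_residue <- preceding
    candidates$category <- category
    candidates$confidence <- confidence
    candidates$reason <- reason
    candidates
}

#' Run the full single-protease selection pipeline
#'
#' Orchestrates [sortMatches()], [deduplicatePsms()],
#' [filterTerminalClasses()], [collapseRagged()] and
#' [classifyNtPeptides()], recording a snapshot at every named stage for
#' funnel accounting.
#'
#' @param psms A PSM data.frame for one protease.
#' @param db A \linkS4class{ProteoformDatabase}.
#' @param riboseqTis Optional Ribo-Seq TIS table (see
#'   [classifyNtPeptides()]).
#' @param rule The dataset's \linkS4class{ProteaseRule}; defaults to the
#'   preset named like the PSMs' protease.
#' @param imet iMet follower set for classification.
#' @return A list with \code{final} (kept, classified Nt-peptides with a
#'   \code{datasets} column), \code{removed} (all removed records with
#'   reasons), \code{pyroglu} (side table), \code{funnel} (a
#'   [computeFunnel()] table) and \code{stages} (the raw snapshots).
#' @export
selectNTermini <- function(psms, db, riboseqTis = NULL, rule = NULL,
                           imet = imetRuleSet("metap")) {
    protease <- unique(psms$protease)
    if (length(protease) != 1L) {
        stop("selectNTermini expects PSMs from a single protease; got: ",
             paste(protease, collapse = ", "))
    }
    if (is.null(rule)) rule <- proteaseRule(protease)
    stages <- list()
    sorted <- sortMatches(psms, db)
    stages$start <- sorted
    stages$after_accession_sorting <- sorted
    distinct <- deduplicatePsms(sorted)
    stages$distinct_peptides <- distinct
    ft <- filterTerminalClasses(distinct, db)
    stages$nt_peptides <- ft$candidates
    ragged <- collapseRagged(ft$candidates)
    stages$after_ragged <- ragged
    classified <- classifyNtPeptides(ragged, db, riboseqTis, rule, imet)
    stages$database_annotated <-
        classified[classified$category == "database_annotated", ,
                   drop = FALSE]
    stages$high_conf_alternative <-
        classified[classified$category == "alternative" &
                   classified$confidence == "high", , drop = FALSE]
    stages$low_conf_alternative <-
        classified[classified$category == "alternative" &
                   classified$confidence == "low", , drop = FALSE]
    final <- classified[classified$confidence != "removed", , drop = FALSE]
    stages$final <- final
    removed_cls <- classified[classified$confidence == "removed", ,
                              drop = FALSE]
    removed_all <- .bindRows(ft$removed, removed_cls)
    final$datasets <- rep(protease, nrow(final))
    list(final = final, removed = removed_all, pyroglu = ft$pyroglu,
         funnel = computeFunnel(stages), stages = stages)
}

## rbind data.frames with differing columns (union, NA-filled)
.bindRows <- function(...) {
    dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0L, list(...))
    if (length(dfs) == 0L) return(NULL)
    cols <- Reduce(union, lapply(dfs, names))
    do.call(rbind, lapply(dfs, function(d) {
        for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
        d[, cols, drop = FALSE]
    }))
}

#' Funnel accounting over the selection stages
#'
#' For every named pipeline stage, the total number of records and the
#' number whose main match (after accession sorting) is an NTR entry.
#' Totals are non-increasing along the funnel.
#'
#' @param stages A named list of stage snapshots (data.frames with a
#'   \code{main_category} column), as produced by [selectNTermini()].
#' @return A data.frame with columns \code{stage}, \code{total},
#'   \code{ntr_matched}.
#' @export
computeFunnel <- function(stages) {
    rows <- lapply(names(stages), function(nm) {
        s <- stages[[nm]]
        data.frame(
            stage = nm,
            total = nrow(s),
            ntr_matched = if (nrow(s) > 0L)
                sum(s$main_category == "ntr") else 0L,
            stringsAsFactors = FALSE
        )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Merge classified N-terminal peptides across proteases
#'
#' Different proteases generate different C-terminal ends at the same N
#' terminus, so merging is keyed on (main entry, start): the longest
#' sequence is retained, the contributing datasets are unioned, the in vivo
#' acetylation percentage is recomputed over all contributing PSM counts,
#' and the best confidence (high over low) is kept. A category conflict
#' within a group resolves to database-annotated (with a warning).
#'
#' @param tables A list of classified tables (the \code{final} element of
#'   [selectNTermini()] results), each internally deduplicated.
#' @return One merged data.frame keyed by (main entry, start).
#' @export
mergeAcrossProteases <- function(tables) {
    all <- .bindRows2(tables)
    if (is.null(all) || nrow(all) == 0L) return(all)
    all <- unique(all)      # identical records never contribute twice
    key <- paste(all$main_entry, all$main_start, sep = "\r")
    groups <- split(seq_len(nrow(all)), key)
    rows <- lapply(groups, function(i) {
        g <- all[i, , drop = FALSE]
        ord <- order(-nchar(g$peptide), -.modPriority(g$best_mod),
                     g$peptide, g$datasets)
        g <- g[ord, , drop = FALSE]
        keep <- g[1L, , drop = FALSE]
        keep$datasets <- paste(
            sort(unique(unlist(strsplit(g$datasets, ",")))),
            collapse = ",")
        keep$psm_count <- sum(g$psm_count)
        keep$n_invivo <- sum(g$n_invivo)
        keep$n_heavy <- sum(g$n_heavy)
        keep$acetylation_pct <- if (keep$n_invivo + keep$n_heavy > 0L)
            .roundAway(100 * keep$n_invivo /
                       (keep$n_invivo + keep$n_heavy), 0L) else NA_real_
        keep$best_mod <- g$best_mod[which.max(.modPriority(g$best_mod))]
        if (any(g$confidence == "high")) keep$confidence <- "high"
        if (length(unique(g$category)) > 1L) {
            warning("category conflict at ", keep$main_entry, ":",
                    keep$main_start, "; keeping database_annotated")
            keep$category <- "database_annotated"
        }
        sv <- unique(unlist(strsplit(g$shorter_variants, ",")))
        sv <- setdiff(sv, c("", keep$peptide))
        sv <- unique(c(sv, setdiff(g$peptide, keep$peptide)))
        keep$shorter_variants <- paste(sv, collapse = ",")
        keep
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$main_entry, out$main_start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.bindRows2 <- function(tables) {
    do.call(.bindRows, unname(tables))
}

#' Overlap of final N-termini between datasets
#'
#' Pairwise and (when three or more datasets are given) three-way overlap
#' counts, computed both by main entry and by (main entry, start).
#'
#' @param tables A named list of classified final tables (one per dataset).
#' @return A data.frame with columns \code{keying} (\code{"entry"} or
#'   \code{"entry_start"}), \code{sets} (comma-joined dataset names) and
#'   \code{count} (size of the intersection; singleton rows give set
#'   sizes).
#' @export
overlapSummary <- function(tables) {
    keysets <- list(
        entry = lapply(tables, function(t) unique(t$main_entry)),
        entry_start = lapply(tables, function(t)
            unique(paste(t$main_entry, t$main_start, sep = ":")))
    )
    rows <- list()
    for (keying in names(keysets)) {
        ks <- keysets[[keying]]
        nms <- names(ks)
        combos <- unlist(lapply(seq_along(nms), function(k) {
            utils::combn(nms, k, simplify = FALSE)
        }), recursive = FALSE)
        for (combo in combos) {
            inter <- Reduce(intersect, ks[combo])
            rows[[length(rows) + 1L]] <- data.frame(
                keying = keying,
                sets = paste(combo, collapse = ","),
                count = length(inter),
                stringsAsFactors = FALSE
            )
        }
    }
    do.call(rbind, rows)
}
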