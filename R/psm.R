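## N-terminal modification codes and their deduplication priority.
## In vivo (cotranslational) acetylation outranks in vitro heavy acetylation,
## which outranks a free alpha-amine; pyroglutamate is handled separately
## (diverted to a side table, never counted as Nt evidence).
.NT_MODS <- c("invivo_ac", "heavy_ac", "free", "pyroglu")

.modPriority <- function(mod) {
    match(mod, c("pyroglu", "free", "heavy_ac", "invivo_ac"))
}

.checkNtMod <- function(mod) {
    bad <- setdiff(unique(mod), .NT_MODS)
    if (length(bad) > 0L) {
        stop("unknown nt_mod value(s): ", paste(bad, collapse = ", "),
             " (expected ", paste(.NT_MODS, collapse = "/"), ")")
    }
    invisible(mod)
}

#' Read a PSM (peptide-to-spectrum match) table
#'
#' Expected tab-separated columns: \code{peptide}, \code{nt_mod} (one of
#' \code{invivo_ac}, \code{heavy_ac}, \code{free}, \code{pyroglu}),
#' \code{score}, \code{protease}, \code{sample_id} and \code{matches}, a
#' semicolon-separated list of \code{entry_id:start} tokens giving every
#' database entry the peptide matches and the 1-based start position of the
#' match.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of PSMs.
#' @export
readPsmTable <- function(path) {
    psms <- utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = "character")
    required <- c("peptide", "nt_mod", "score", "protease", "sample_id",
                  "matches")
    missing <- setdiff(required, names(psms))
    if (length(missing) > 0L) {
        stop("PSM table ", path, " lacks column(s): ",
             paste(missing, collapse = ", "))
    }
    psms$score <- as.numeric(psms$score)
    .checkNtMod(psms$nt_mod)
    if (any(!nzchar(psms$matches))) {
        stop("PSM table ", path, ": empty matches at row(s) ",
             paste(which(!nzchar(psms$matches)), collapse = ","))
    }
    psms
}

#' @rdname readPsmTable
#' @param psms A PSM data.frame.
#' @export
writePsmTable <- function(psms, path) {
    utils::write.table(psms, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## "id:start;id:start" -> data.frame(entry_id, start)
.parseMatches <- function(x) {
    toks <- strsplit(x, ";", fixed = TRUE)[[1L]]
    toks <- toks[nzchar(toks)]
    pos <- regexpr(":[0-9]+$", toks)
    if (any(pos < 0L)) {
        stop("malformed match token(s): ",
             paste(toks[pos < 0L], collapse = ", "))
    }
    data.frame(
        entry_id = substr(toks, 1L, pos - 1L),
        start = as.integer(substring(toks, pos + 1L)),
        stringsAsFactors = FALSE
    )
}

.formatMatches <- function(m) {
    paste(paste0(m$entry_id, ":", m$start), collapse = ";")
}

#' Sort the entry matches of each PSM
#'
#' One peptide often matches several database entries; search engines pick
#' one at random. Matches are reordered by a stable sort on (category
#' priority under the \code{peptide_sorting} scheme, start position,
#' lexicographic entry id), so that the first match -- the main match -- is
#' the most plausible origin: annotated proteins beat Ribo-Seq proteoforms,
#' and within a category the most N-terminal match wins. No match is
#' removed.
#'
#' @param psms A PSM data.frame (see [readPsmTable()]).
#' @param db Optional \linkS4class{ProteoformDatabase}; when supplied, the
#'   category of each matched entry is taken from the database, otherwise it
#'   is inferred from the identifier.
#' @return The PSM data.frame with \code{matches} reordered and columns
#'   \code{main_entry}, \code{main_start}, \code{main_category} added.
#' @export
sortMatches <- function(psms, db = NULL) {
    sorted <- lapply(psms$matches, function(x) {
        m <- .parseMatches(x)
        cat <- if (!is.null(db)) {
            idx <- entryIndex(db, m$entry_id)
            ifelse(is.na(idx), inferCategory(m$entry_id),
                   db@category[idx])
        } else {
            inferCategory(m$entry_id)
        }
        ord <- order(categoryRank(cat, "peptide_sorting"), m$start,
                     m$entry_id)
        list(m = m[ord, , drop = FALSE], cat = cat[ord])
    })
    psms$matches <- vapply(sorted, function(s) .formatMatches(s$m), "")
    psms$main_entry <- vapply(sorted, function(s) s$m$entry_id[1L], "")
    psms$main_start <- vapply(sorted, function(s) s$m$start[1L], 1L)
    psms$main_category <- vapply(sorted, function(s) s$cat[1L], "")
    psms
}

#' Collapse PSMs to distinct peptides
#'
#' PSMs of one protease are grouped by exact peptide sequence. Within a
#' group the representative PSM is the highest-scoring one among those with
#' the highest-priority N-terminal modification (in vivo acetyl > heavy
#' acetyl > free). The acetylation percentage is computed from PSM counts as
#' 100 * n(in vivo) / (n(in vivo) + n(heavy)), rounded to the nearest
#' integer (half away from zero); it is undefined (NA) when no acetylated
#' form was seen.
#'
#' @param psms A PSM data.frame, already passed through [sortMatches()].
#' @return A data.frame of distinct peptides with columns \code{peptide},
#'   \code{best_mod}, \code{psm_count}, \code{n_invivo}, \code{n_heavy},
#'   \code{acetylation_pct}, \code{forms_seen} (comma-joined), \code{score},
#'   \code{main_entry}, \code{main_start}, \code{main_category},
#'   \code{matches}, \code{protease}.
#' @export
deduplicatePsms <- function(psms) {
    .checkNtMod(psms$nt_mod)
    if (length(unique(psms$protease)) > 1L) {
        stop("deduplicatePsms expects PSMs from a single protease")
    }
    groups <- split(seq_len(nrow(psms)), psms$peptide)
    rows <- lapply(groups, function(i) {
        g <- psms[i, , drop = FALSE]
        pri <- .modPriority(g$nt_mod)
        best <- which(pri == max(pri))
        rep_i <- best[which.max(g$score[best])]
        n_iv <- sum(g$nt_mod == "invivo_ac")
        n_hv <- sum(g$nt_mod == "heavy_ac")
        pct <- if (n_iv + n_hv > 0L)
            .roundAway(100 * n_iv / (n_iv + n_hv), 0L) else NA_real_
        data.frame(
            peptide = g$peptide[1L],
            best_mod = g$nt_mod[rep_i],
            psm_count = nrow(g),
            n_invivo = n_iv, n_heavy = n_hv,
            acetylation_pct = pct,
            forms_seen = paste(sort(unique(g$nt_mod)), collapse = ","),
            score = g$score[rep_i],
            main_entry = g$main_entry[rep_i],
            main_start = g$main_start[rep_i],
            main_category = g$main_category[rep_i],
            matches = g$matches[rep_i],
            protease = g$protease[1L],
            stringsAsFactors = FALSE
        )
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$peptide), , drop = FALSE]
    rownames(out) <- NULL
    out
}
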