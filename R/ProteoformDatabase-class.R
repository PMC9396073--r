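#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges CharacterList
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom IRanges CharacterList IRanges
#' @importFrom stats setNames
NULL

.AA_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "U")

#' ProteoformDatabase: a nonredundant custom proteoform sequence database
#'
#' Container for a merged protein sequence database in which byte-identical
#' sequences have been collapsed to a single entry carrying one main
#' identifier; all other identifiers sharing the sequence are kept as
#' alternative identifiers. Sequences use the 20 standard amino acids plus
#' selenocysteine (U).
#'
#' @slot sequences An [Biostrings::AAStringSet] named by main identifier.
#' @slot category Character vector of source categories, one per entry.
#' @slot altIds A [IRanges::CharacterList] of alternative identifiers.
#' @slot description Character vector of free-text descriptions.
#'
#' @seealso [mergeDatabases()], [loadDatabase()], [writeDatabase()]
#' @export
setClass("ProteoformDatabase",
    slots = c(
        sequences = "AAStringSet",
        category = "character",
        altIds = "CharacterList",
        description = "character"
    )
)

setValidity("ProteoformDatabase", function(object) {
    n <- length(object@sequences)
    msgs <- character(0)
    if (length(object@category) != n || length(object@altIds) != n ||
        length(object@description) != n) {
        msgs <- c(msgs, "slot lengths differ")
    }
    ids <- names(object@sequences)
    if (is.null(ids) && n > 0L) {
        msgs <- c(msgs, "sequences must be named by main id")
    } else if (anyDuplicated(ids)) {
        msgs <- c(msgs, "duplicated main ids")
    }
    if (n > 0L && any(Biostrings::width(object@sequences) == 0L)) {
        msgs <- c(msgs, "empty sequences are not allowed")
    }
    if (n > 0L && anyDuplicated(as.character(object@sequences))) {
        msgs <- c(msgs, "duplicate sequences: database is not merged")
    }
    alt <- unlist(object@altIds, use.names = FALSE)
    if (length(alt) > 0L && any(alt %in% ids)) {
        msgs <- c(msgs, "alt ids must not duplicate main ids")
    }
    bad <- setdiff(unique(object@category), sourceCategories())
    if (length(bad) > 0L) {
        msgs <- c(msgs, paste("unknown categories:",
                              paste(bad, collapse = ", ")))
    }
    if (length(msgs) > 0L) msgs else TRUE
})

#' Construct a ProteoformDatabase
#'
#' Low-level constructor; sequences must already be nonredundant. Use
#' [mergeDatabases()] to build a database from possibly redundant sources.
#'
#' @param main_id Character vector of unique main identifiers.
#' @param sequence Character vector (or AAStringSet) of amino-acid sequences.
#' @param category Source category per entry; inferred from \code{main_id}
#'   when missing.
#' @param alt_ids List (or CharacterList) of alternative identifiers.
#' @param description Character vector of descriptions.
#' @return A \linkS4class{ProteoformDatabase}.
#' @export
ProteoformDatabase <- function(main_id, sequence,
                               category = inferCategory(main_id),
                               alt_ids = NULL, description = NULL) {
    n <- length(main_id)
    seqs <- if (is(sequence, "AAStringSet")) sequence else {
        .checkResidues(toupper(sequence), main_id)
        AAStringSet(toupper(sequence))
    }
    names(seqs) <- main_id
    if (is.null(alt_ids)) alt_ids <- vector("list", n)
    if (is.null(description)) description <- character(n)
    description[is.na(description)] <- ""
    new("ProteoformDatabase",
        sequences = seqs,
        category = as.character(category),
        altIds = as(alt_ids, "CharacterList"),
        description = as.character(description))
}

.checkResidues <- function(sequence, ids) {
    offending <- lapply(strsplit(sequence, ""), setdiff, y = .AA_RESIDUES)
    bad <- lengths(offending) > 0L
    if (any(bad)) {
        stop("non-amino-acid characters in ",
             paste0(ids[bad], " (",
                    vapply(offending[bad], paste, "", collapse = ","),
                    ")", collapse = "; "))
    }
    invisible(sequence)
}

#' @describeIn ProteoformDatabase-class Number of entries.
#' @param x,object A ProteoformDatabase.
#' @export
setMethod("length", "ProteoformDatabase", function(x) length(x@sequences))

setMethod("show", "ProteoformDatabase", function(object) {
    cat("ProteoformDatabase with", length(object), "entries\n")
    tab <- table(factor(object@category, levels = sourceCategories()))
    tab <- tab[tab > 0L]
    if (length(tab) > 0L) {
        cat("  categories:",
            paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    }
    nalt <- sum(lengths(object@altIds))
    cat("  alternative ids:", nalt, "\n")
})

#' Accessors for ProteoformDatabase
#'
#' @param db A \linkS4class{ProteoformDatabase}.
#' @return \code{mainIds}: character vector of main identifiers;
#'   \code{entryCategories}: named character vector of categories;
#'   \code{entrySequences}: named AAStringSet; \code{entryAltIds}: named
#'   CharacterList; \code{entryLengths}: named integer vector.
#' @export
mainIds <- function(db) names(db@sequences)

#' @rdname mainIds
#' @export
entryCategories <- function(db) {
    stats::setNames(db@category, mainIds(db))
}

#' @rdname mainIds
#' @export
entrySequences <- function(db) db@sequences

#' @rdname mainIds
#' @export
entryAltIds <- function(db) stats::setNames(db@altIds, mainIds(db))

#' @rdname mainIds
#' @export
entryLengths <- function(db) {
    stats::setNames(Biostrings::width(db@sequences), mainIds(db))
}

#' Look up a database entry by any of its identifiers
#'
#' The index covers main and alternative identifiers alike.
#'
#' @param db A \linkS4class{ProteoformDatabase}.
#' @param id Character vector of identifiers (main or alternative).
#' @return Integer vector of entry positions (NA where unknown).
#' @export
entryIndex <- function(db, id) {
    main <- match(id, mainIds(db))
    miss <- is.na(main)
    if (any(miss)) {
        alt <- db@altIds
        flat <- unlist(alt, use.names = FALSE)
        owner <- rep(seq_along(alt), lengths(alt))
        main[miss] <- owner[match(id[miss], flat)]
    }
    main
}

#' @rdname entryIndex
#' @return \code{entrySequence}: character vector of sequences for the
#'   entries owning each identifier (NA where unknown).
#' @export
entrySequence <- function(db, id) {
    idx <- entryIndex(db, id)
    out <- rep(NA_character_, length(id))
    ok <- !is.na(idx)
    out[ok] <- as.character(db@sequences[idx[ok]])
    out
}

#' Merge possibly redundant proteoform sources into one database
#'
#' Entries with byte-identical sequences are reduced to a single entry with
#' one main identifier; all other identifiers are kept as alternative
#' identifiers. The main identifier is the one whose category ranks highest
#' under the \code{db_main_id} scheme (UniProt preferred, then aTIS, CDS,
#' 5UTR, ntr, 3UTR), ties broken by the lexicographically smallest
#' identifier. Sequence identity is exact string equality; I/L equivalence
#' plays no role at this stage.
#'
#' @param sources A data.frame with columns \code{id}, \code{sequence} and
#'   optionally \code{category} and \code{description}, a
#'   \linkS4class{ProteoformDatabase}, or a list mixing the two.
#' @return A \linkS4class{ProteoformDatabase}. Merging is idempotent.
#' @export
#' @examples
#' src <- data.frame(id = c("P11111", "ENST00000001_1_10_ntr_100db1"),
#'                   sequence = c("MKVLAG", "MKVLAG"))
#' db <- mergeDatabases(src)
#' mainIds(db)  # UniProt id wins
mergeDatabases <- function(sources) {
    if (is.data.frame(sources) || is(sources, "ProteoformDatabase")) {
        sources <- list(sources)
    }
    sources <- lapply(sources, function(s) {
        if (is(s, "ProteoformDatabase")) entryFrame(s) else s
    })
    src <- do.call(rbind, lapply(sources, function(s) {
        stopifnot(all(c("id", "sequence") %in% names(s)))
        data.frame(
            id = as.character(s$id),
            sequence = toupper(as.character(s$sequence)),
            category = if ("category" %in% names(s))
                as.character(s$category) else inferCategory(s$id),
            description = if ("description" %in% names(s))
                as.character(s$description) else "",
            stringsAsFactors = FALSE
        )
    }))
    if (is.null(src) || nrow(src) == 0L) {
        return(ProteoformDatabase(character(0), character(0),
                                  category = character(0)))
    }
    .checkCategory(src$category)
    groups <- split(seq_len(nrow(src)), src$sequence)
    built <- lapply(groups, function(i) {
        g <- src[i, , drop = FALSE]
        ## expand entries that already carry alt ids (idempotence)
        ord <- order(categoryRank(g$category, "db_main_id"), g$id)
        g <- g[ord, , drop = FALSE]
        g <- g[!duplicated(g$id), , drop = FALSE]
        list(main_id = g$id[1L], sequence = g$sequence[1L],
             category = g$category[1L],
             alt_ids = g$id[-1L],
             description = g$description[1L])
    })
    ## restore input-independent deterministic order: by main id
    built <- built[order(vapply(built, `[[`, "", "main_id"))]
    db <- ProteoformDatabase(
        main_id = vapply(built, `[[`, "", "main_id"),
        sequence = vapply(built, `[[`, "", "sequence"),
        category = vapply(built, `[[`, "", "category"),
        alt_ids = lapply(built, `[[`, "alt_ids"),
        description = vapply(built, `[[`, "", "description")
    )
    db
}

#' Read / write a proteoform database as FASTA
#'
#' The header grammar is \code{">MAIN_ID [ALT1][ALT2] free-text"}: the first
#' whitespace-separated token is the main identifier, square-bracketed tokens
#' are alternative identifiers sharing the identical sequence, and the
#' remainder is the description. Sequences are uppercased on input; trailing
#' stop characters (\code{*}) are stripped with a warning; any other
#' non-amino-acid character is an error.
#'
#' @param path Path to a FASTA file.
#' @return \code{loadDatabase}: a \linkS4class{ProteoformDatabase}.
#' @export
loadDatabase <- function(path) {
    ## read as raw strings: invalid residues must be reported, not dropped
    seqs <- Biostrings::readBStringSet(path)
    headers <- names(seqs)
    main <- sub("\\s.*$", "", headers)
    if (anyDuplicated(main)) {
        stop("duplicate main ids in ", path, ": ",
             paste(unique(main[duplicated(main)]), collapse = ", "))
    }
    rest <- sub("^\\S+\\s*", "", headers)
    alt <- lapply(regmatches(rest, gregexpr("\\[[^]]*\\]", rest)),
                  function(x) gsub("\\[|\\]", "", x))
    desc <- trimws(gsub("\\[[^]]*\\]", "", rest))
    chr <- toupper(as.character(seqs))
    if (any(grepl("*", chr, fixed = TRUE))) {
        warning("stripping '*' stop characters from ",
                sum(grepl("*", chr, fixed = TRUE)), " sequence(s)")
        chr <- gsub("*", "", chr, fixed = TRUE)
    }
    .checkResidues(chr, main)
    ProteoformDatabase(main, chr, category = inferCategory(main),
                       alt_ids = alt, description = desc)
}

#' @rdname loadDatabase
#' @param db A \linkS4class{ProteoformDatabase}.
#' @export
writeDatabase <- function(db, path) {
    alt <- vapply(as.list(db@altIds), function(a) {
        if (length(a) == 0L) "" else paste0(" ",
            paste0("[", a, "]", collapse = ""))
    }, "")
    desc <- ifelse(nzchar(db@description), paste0(" ", db@description), "")
    out <- db@sequences
    names(out) <- paste0(mainIds(db), alt, desc)
    writeXStringSet(out, path, width = 70L)
    invisible(path)
}

#' Flatten a database to one row per identifier
#'
#' Each entry contributes one row for its main identifier and one per
#' alternative identifier, all sharing the sequence. Useful for re-merging
#' and for checking what an identifier originally carried.
#'
#' @param db A \linkS4class{ProteoformDatabase}.
#' @return A data.frame with columns \code{id}, \code{sequence},
#'   \code{category}, \code{description}.
#' @export
entryFrame <- function(db) {
    alt <- as.list(db@altIds)
    n_alt <- lengths(alt)
    main_rows <- data.frame(
        id = mainIds(db),
        sequence = as.character(db@sequences),
        category = db@category,
        description = db@description,
        stringsAsFactors = FALSE
    )
    if (sum(n_alt) == 0L) return(main_rows)
    owner <- rep(seq_along(alt), n_alt)
    alt_ids <- unlist(alt, use.names = FALSE)
    alt_rows <- data.frame(
        id = alt_ids,
        sequence = as.character(db@sequences)[owner],
        category = inferCategory(alt_ids),
        description = db@description[owner],
        stringsAsFactors = FALSE
    )
    rbind(main_rows, alt_rows)
}

#' Database manifest report
#'
#' One row per entry: main identifier, category, sequence length and the
#' number of alternative identifiers.
#'
#' @param db A \linkS4class{ProteoformDatabase}.
#' @param path Optional path; when given the manifest is also written as TSV.
#' @return A data.frame.
#' @export
databaseManifest <- function(db, path = NULL) {
    m <- data.frame(
        main_id = mainIds(db),
        category = db@category,
        length = unname(entryLengths(db)),
        n_alt_ids = lengths(db@altIds),
        stringsAsFactors = FALSE
    )
    if (!is.null(path)) {
        utils::write.table(m, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    m
}
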