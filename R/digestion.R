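#' ProteaseRule: cleavage specificity of a protease
#'
#' Cleavage occurs C-terminal to any residue in \code{cleaveAfter}, optionally
#' suppressed when the next residue is proline. Three presets mirror the
#' common N-terminomics setup: \code{"argc"} (R, 2 missed cleavages; trypsin
#' acts as ArgC when lysines are blocked by acetylation, so \code{"trypsin"}
#' is an alias), \code{"chymotrypsin"} (F/L/M/W/Y, 2 missed cleavages) and
#' \code{"gluc"} (D/E including before proline, 4 missed cleavages).
#'
#' @slot name Protease name.
#' @slot cleaveAfter Residues after which the backbone is cleaved.
#' @slot suppressBeforeProline Suppress cleavage when followed by proline?
#' @slot maxMissedCleavages Maximum number of missed cleavages.
#' @export
setClass("ProteaseRule",
    slots = c(
        name = "character",
        cleaveAfter = "character",
        suppressBeforeProline = "logical",
        maxMissedCleavages = "integer"
    )
)

setValidity("ProteaseRule", function(object) {
    if (length(object@cleaveAfter) == 0L) return("cleaveAfter is empty")
    if (object@maxMissedCleavages < 0L) return("negative missed cleavages")
    TRUE
})

setMethod("show", "ProteaseRule", function(object) {
    cat("ProteaseRule", object@name, "- cleave after",
        paste(object@cleaveAfter, collapse = ""),
        if (object@suppressBeforeProline) "(not before P)" else "",
        "MC <=", object@maxMissedCleavages, "\n")
})

#' @rdname ProteaseRule-class
#' @param name A preset name (\code{"argc"}, \code{"trypsin"},
#'   \code{"chymotrypsin"}, \code{"chymo"}, \code{"gluc"}) or a custom name
#'   when \code{cleaveAfter} is supplied.
#' @param cleaveAfter,suppressBeforeProline,maxMissedCleavages Override the
#'   preset (or define a custom rule).
#' @return A \linkS4class{ProteaseRule}.
#' @export
#' @examples
#' proteaseRule("argc")
#' proteaseRule("gluc", maxMissedCleavages = 2)
proteaseRule <- function(name, cleaveAfter = NULL,
                         suppressBeforeProline = NULL,
                         maxMissedCleavages = NULL) {
    presets <- list(
        argc = list(c("R"), FALSE, 2L),
        trypsin = list(c("R"), FALSE, 2L),
        chymotrypsin = list(c("F", "L", "M", "W", "Y"), FALSE, 2L),
        chymo = list(c("F", "L", "M", "W", "Y"), FALSE, 2L),
        gluc = list(c("D", "E"), FALSE, 4L)
    )
    p <- presets[[tolower(name)]]
    if (is.null(p) && is.null(cleaveAfter)) {
        stop("unknown protease preset '", name,
             "'; supply cleaveAfter for a custom rule")
    }
    new("ProteaseRule",
        name = tolower(name),
        cleaveAfter = if (is.null(cleaveAfter)) p[[1L]] else
            toupper(cleaveAfter),
        suppressBeforeProline = if (is.null(suppressBeforeProline))
            (if (is.null(p)) FALSE else p[[2L]]) else suppressBeforeProline,
        maxMissedCleavages = as.integer(
            if (is.null(maxMissedCleavages))
                (if (is.null(p)) 2L else p[[3L]]) else maxMissedCleavages))
}

.cleavageBoundaries <- function(residues, rule) {
    n <- length(residues)
    if (n == 0L) return(integer(0))
    hit <- residues %in% rule@cleaveAfter
    if (rule@suppressBeforeProline) {
        nxt <- c(residues[-1L], "")
        hit <- hit & nxt != "P"
    }
    hit[n] <- FALSE                     # C-terminus is always a boundary
    which(hit)
}

#' In-silico protease digestion
#'
#' Enumerates all digestion peptides of a protein sequence under a cleavage
#' rule, up to the rule's maximum number of missed cleavages. Peptides with
#' zero missed cleavages partition the sequence; a peptide with k missed
#' cleavages is the concatenation of k + 1 consecutive fully cleaved
#' fragments.
#'
#' @param sequence A single amino-acid string.
#' @param rule A \linkS4class{ProteaseRule}.
#' @param maxMissedCleavages Override of the rule's maximum.
#' @return A data.frame sorted by (start, end) with columns \code{sequence},
#'   \code{start}, \code{end} (1-based inclusive) and
#'   \code{missed_cleavages}.
#' @export
#' @examples
#' digestSequence("MKAARAGRPK", proteaseRule("argc"), maxMissedCleavages = 1)
digestSequence <- function(sequence, rule,
                           maxMissedCleavages = rule@maxMissedCleavages) {
    stopifnot(length(sequence) == 1L, nchar(sequence) > 0L)
    residues <- strsplit(sequence, "")[[1L]]
    n <- length(residues)
    cuts <- .cleavageBoundaries(residues, rule)
    starts0 <- c(1L, cuts + 1L)
    ends0 <- c(cuts, n)
    k0 <- length(starts0)
    mc <- as.integer(maxMissedCleavages)
    out <- vector("list", mc + 1L)
    for (m in 0:min(mc, k0 - 1L)) {
        i <- seq_len(k0 - m)
        out[[m + 1L]] <- data.frame(
            start = starts0[i], end = ends0[i + m],
            missed_cleavages = m
        )
    }
    res <- do.call(rbind, out)
    res <- res[order(res$start, res$end), , drop = FALSE]
    res$sequence <- substring(sequence, res$start, res$end)
    rownames(res) <- NULL
    res[, c("sequence", "start", "end", "missed_cleavages")]
}
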