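#' Theoretical b/y fragment ions of a peptide
#'
#' Singly protonated b and y ions: b_i is the sum of the first i residue
#' masses (plus modifications on positions 1..i) plus one proton; y_i is the
#' sum of the last i residue masses (plus their modifications) plus water
#' plus one proton. A peptide of length n yields 2(n - 1) ions.
#'
#' @param peptide A single peptide sequence.
#' @param modifications Optional data.frame with columns \code{position}
#'   (1-based residue index) and \code{delta} (Da).
#' @param ionTypes Subset of \code{c("b", "y")}.
#' @param charge Fragment charge (default 1).
#' @return A data.frame with columns \code{ion} (e.g. \code{"b3"}),
#'   \code{series}, \code{index}, \code{mz}.
#' @export
#' @examples
#' theoreticalFragments("AG")
theoreticalFragments <- function(peptide, modifications = NULL,
                                 ionTypes = c("b", "y"), charge = 1L) {
    r <- strsplit(peptide, "")[[1L]]
    n <- length(r)
    stopifnot(n >= 2L)
    masses <- .RESIDUE_MASS[r]
    if (anyNA(masses)) {
        stop("unknown residue(s) in '", peptide, "'")
    }
    moddelta <- numeric(n)
    if (!is.null(modifications) && nrow(modifications) > 0L) {
        moddelta[modifications$position] <-
            moddelta[modifications$position] + modifications$delta
    }
    masses <- unname(masses) + moddelta
    out <- list()
    if ("b" %in% ionTypes) {
        i <- seq_len(n - 1L)
        bmz <- (cumsum(masses)[i] + charge * .PROTON_MASS) / charge
        out$b <- data.frame(ion = paste0("b", i), series = "b", index = i,
                            mz = bmz, stringsAsFactors = FALSE)
    }
    if ("y" %in% ionTypes) {
        i <- seq_len(n - 1L)
        ymz <- (cumsum(rev(masses))[i] + .WATER_MASS +
                charge * .PROTON_MASS) / charge
        out$y <- data.frame(ion = paste0("y", i), series = "y", index = i,
                            mz = ymz, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Read / write a spectrum peak list
#'
#' Two-column tab-separated format: \code{mz} (Th) and \code{intensity}
#' (arbitrary units), sorted by m/z.
#'
#' @param path Path to a TSV file.
#' @return \code{readPeakList}: a data.frame sorted by m/z.
#' @export
readPeakList <- function(path) {
    p <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("mz", "intensity") %in% names(p)))
    p <- p[order(p$mz), , drop = FALSE]
    rownames(p) <- NULL
    p
}

#' @rdname readPeakList
#' @param peaks A data.frame with \code{mz} and \code{intensity} columns.
#' @export
writePeakList <- function(peaks, path) {
    utils::write.table(peaks[order(peaks$mz), c("mz", "intensity")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## Most intense peak within mzTol of each target m/z; NA when absent.
.matchFragmentIntensity <- function(peaks, mz, mzTol) {
    vapply(mz, function(target) {
        sel <- abs(peaks$mz - target) <= mzTol
        if (!any(sel)) NA_real_ else max(peaks$intensity[sel])
    }, numeric(1L))
}

#' Fragment-ion rank concordance between two spectra of one peptide
#'
#' Mirrors the manual comparison of an identified spectrum against the
#' spectrum of the corresponding synthetic peptide: the \code{topN} most
#' intense annotated b/y fragments of the reference spectrum are selected,
#' the same fragments are looked up in the query spectrum (within
#' \code{mzTol}), and the Spearman rank correlation of the intensity ranks
#' is computed; fragments missing from the query are assigned rank
#' \code{topN + 1}. The score is invariant to uniform intensity scaling of
#' either spectrum.
#'
#' @param reference,query Peak lists (data.frames with \code{mz},
#'   \code{intensity}).
#' @param peptide The peptide sequence both spectra are assumed to derive
#'   from.
#' @param modifications Passed to [theoreticalFragments()].
#' @param topN Number of reference fragments compared (default 10).
#' @param mzTol Fragment matching tolerance in Th (default 0.5).
#' @param threshold Verdict threshold on the score (default 0.6).
#' @return A list with \code{score} (Spearman rho in [-1, 1] or NA),
#'   \code{verdict} (\code{"matching"}, \code{"not_matching"} or
#'   \code{"insufficient"} when fewer than 3 fragments are common),
#'   \code{n_common} and the per-fragment \code{table}.
#' @export
rankConcordance <- function(reference, query, peptide,
                            modifications = NULL, topN = 10L, mzTol = 0.5,
                            threshold = 0.6) {
    frags <- theoreticalFragments(peptide, modifications)
    ref_int <- .matchFragmentIntensity(reference, frags$mz, mzTol)
    frags <- frags[!is.na(ref_int), , drop = FALSE]
    ref_int <- ref_int[!is.na(ref_int)]
    ord <- order(-ref_int)
    take <- utils::head(ord, topN)
    frags <- frags[take, , drop = FALSE]
    ref_int <- ref_int[take]
    k <- nrow(frags)
    qry_int <- .matchFragmentIntensity(query, frags$mz, mzTol)
    n_common <- sum(!is.na(qry_int))
    ref_rank <- rank(-ref_int, ties.method = "average")
    qry_rank <- rep(topN + 1, k)
    found <- !is.na(qry_int)
    qry_rank[found] <- rank(-qry_int[found], ties.method = "average")
    tab <- data.frame(ion = frags$ion, mz = frags$mz,
                      ref_intensity = ref_int, query_intensity = qry_int,
                      ref_rank = ref_rank, query_rank = qry_rank,
                      stringsAsFactors = FALSE)
    if (n_common < 3L) {
        return(list(score = NA_real_, verdict = "insufficient",
                    n_common = n_common, table = tab))
    }
    score <- suppressWarnings(
        stats::cor(ref_rank, qry_rank, method = "spearman"))
    if (is.na(score)) score <- 0
    list(score = score,
         verdict = if (score >= threshold) "matching" else "not_matching",
         n_common = n_common, table = tab)
}
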