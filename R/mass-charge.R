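## Monoisotopic residue masses (Da), standard 20 amino acids plus
## selenocysteine (U). Water and proton masses to 6+ decimals.
.RESIDUE_MASS <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    U = 150.95364, R = 156.10111, Y = 163.06333, W = 186.07931
)
.WATER_MASS <- 18.0105646863
.PROTON_MASS <- 1.007276466812

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus any modification
#' delta masses.
#'
#' @param sequence Character vector of peptide sequences.
#' @param modifications Optional data.frame with columns \code{position}
#'   (1-based residue index; only used for bookkeeping) and \code{delta}
#'   (mass shift in Da), applied to every sequence, or a numeric vector of
#'   deltas.
#' @return Numeric vector of monoisotopic masses in Da.
#' @export
#' @examples
#' peptideMass("G")                       # 75.03203
#' peptideMass("GG") - peptideMass("G")   # one glycine residue, 57.02146
peptideMass <- function(sequence, modifications = NULL) {
    delta <- 0
    if (!is.null(modifications)) {
        delta <- if (is.data.frame(modifications))
            sum(modifications$delta) else sum(modifications)
    }
    vapply(sequence, function(s) {
        r <- strsplit(s, "")[[1L]]
        m <- .RESIDUE_MASS[r]
        if (anyNA(m)) {
            stop("unknown residue(s) in '", s, "': ",
                 paste(unique(r[is.na(m)]), collapse = ","))
        }
        sum(m) + .WATER_MASS + delta
    }, numeric(1L), USE.NAMES = FALSE)
}

#' Named pKa sets for peptide charge calculation
#'
#' Nine ionizable groups are modelled: the free alpha-amine (N-terminus), the
#' alpha-carboxyl (C-terminus) and the side chains of R, K, H (basic) and
#' D, E, C, Y (acidic). Three literature sets are provided; \code{"emboss"}
#' is the default used throughout the package.
#'
#' @param name One of \code{"emboss"}, \code{"lehninger"},
#'   \code{"bjellqvist"}.
#' @return Named numeric vector with names \code{Nterm}, \code{Cterm},
#'   \code{R}, \code{K}, \code{H}, \code{D}, \code{E}, \code{C}, \code{Y}
#'   and a \code{"set"} attribute.
#' @export
pkaSet <- function(name = c("emboss", "lehninger", "bjellqvist")) {
    name <- match.arg(name)
    sets <- list(
        emboss = c(Nterm = 8.6, Cterm = 3.6, R = 12.5, K = 10.8, H = 6.5,
                   D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
        lehninger = c(Nterm = 9.69, Cterm = 2.34, R = 12.48, K = 10.53,
                      H = 6.0, D = 3.65, E = 4.25, C = 8.18, Y = 10.07),
        bjellqvist = c(Nterm = 7.5, Cterm = 3.55, R = 12.0, K = 10.0,
                       H = 5.98, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
    )
    structure(sets[[name]], set = name)
}

#' Fractional net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch summation: each basic group contributes
#' \eqn{1/(1+10^{pH-pKa})}, each acidic group \eqn{-1/(1+10^{pKa-pH})}.
#' When amines are blocked (e.g. by acetylation of the alpha-amine and of
#' lysine side chains, as in COFRADIC samples) the N-terminus and lysines do
#' not ionize.
#'
#' @param sequence Character vector of peptide sequences.
#' @param ph pH (default 2, the condition used for the detectability model).
#' @param pka A pKa set from [pkaSet()].
#' @param blockedAmines If TRUE, skip the N-terminal amine and lysines.
#' @return Numeric vector of fractional net charges.
#' @export
#' @examples
#' chargeAtPh("AAAAAAR", ph = 2)  # ~ +2 (alpha-amine + Arg)
chargeAtPh <- function(sequence, ph = 2, pka = pkaSet(),
                       blockedAmines = FALSE) {
    basic <- function(pk) 1 / (1 + 10^(ph - pk))
    acidic <- function(pk) -1 / (1 + 10^(pk - ph))
    vapply(sequence, function(s) {
        r <- strsplit(s, "")[[1L]]
        q <- acidic(pka[["Cterm"]])
        if (!blockedAmines) q <- q + basic(pka[["Nterm"]])
        counts <- table(factor(r, levels = c("R", "K", "H", "D", "E",
                                             "C", "Y")))
        q <- q + counts[["R"]] * basic(pka[["R"]]) +
            counts[["H"]] * basic(pka[["H"]]) +
            counts[["D"]] * acidic(pka[["D"]]) +
            counts[["E"]] * acidic(pka[["E"]]) +
            counts[["C"]] * acidic(pka[["C"]]) +
            counts[["Y"]] * acidic(pka[["Y"]])
        if (!blockedAmines) q <- q + counts[["K"]] * basic(pka[["K"]])
        q
    }, numeric(1L), USE.NAMES = FALSE)
}

#' MS detectability criteria
#'
#' A peptide is considered MS-detectable when it is longer than
#' \code{minLengthExclusive} residues, its integerized charge at
#' \code{ph} is at most \code{maxCharge} (inclusive), and its m/z at that
#' charge is at most \code{maxMz} Th.
#'
#' @param minLengthExclusive Peptides must be strictly longer than this
#'   (default 6 residues).
#' @param maxCharge Maximum allowed charge state (default +4, inclusive).
#' @param maxMz Maximum m/z in Th (default 1500).
#' @param ph pH at which charge is evaluated (default 2).
#' @return A classed list of criteria.
#' @export
detectabilityCriteria <- function(minLengthExclusive = 6L, maxCharge = 4L,
                                  maxMz = 1500, ph = 2) {
    stopifnot(minLengthExclusive > 0L, maxCharge > 0L, maxMz > 0, ph > 0)
    structure(list(minLengthExclusive = as.integer(minLengthExclusive),
                   maxCharge = as.integer(maxCharge),
                   maxMz = maxMz, ph = ph),
              class = "DetectabilityCriteria")
}

.integerizeCharge <- function(q, how = c("round", "floor", "ceiling")) {
    how <- match.arg(how)
    z <- switch(how,
        round = sign(q) * floor(abs(q) + 0.5),  # half away from zero
        floor = floor(q),
        ceiling = ceiling(q))
    pmax(1, z)
}

#' Is a peptide MS-detectable?
#'
#' Applies the length, charge and m/z criteria. The fractional charge at the
#' criteria's pH is integerized (by default rounded, half away from zero, and
#' floored at +1) to give the assumed charge state z; the m/z test uses
#' (mass + z * proton) / z.
#'
#' @param sequence Character vector of peptide sequences.
#' @param criteria A [detectabilityCriteria()] object.
#' @param pka A pKa set from [pkaSet()].
#' @param blockedAmines Passed to [chargeAtPh()].
#' @param chargeRounding How the fractional charge is integerized.
#' @return A data.frame with columns \code{sequence}, \code{detectable},
#'   \code{reason} (\code{"ok"}, \code{"length"}, \code{"charge"} or
#'   \code{"mz"}; the first failing criterion), \code{charge}, \code{z},
#'   \code{mz}.
#' @export
#' @examples
#' msDetectable(c("AAAAAA", "AAAAAAR"))
msDetectable <- function(sequence, criteria = detectabilityCriteria(),
                         pka = pkaSet(), blockedAmines = FALSE,
                         chargeRounding = "round") {
    len <- nchar(sequence)
    q <- chargeAtPh(sequence, ph = criteria$ph, pka = pka,
                    blockedAmines = blockedAmines)
    z <- .integerizeCharge(q, chargeRounding)
    mass <- peptideMass(sequence)
    mz <- (mass + z * .PROTON_MASS) / z
    reason <- rep("ok", length(sequence))
    reason[mz > criteria$maxMz] <- "mz"
    reason[z > criteria$maxCharge] <- "charge"
    reason[len <= criteria$minLengthExclusive] <- "length"
    data.frame(sequence = sequence, detectable = reason == "ok",
               reason = reason, charge = q, z = z, mz = mz,
               stringsAsFactors = FALSE)
}
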