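#' Configuration for the synthetic-data generator
#'
#' The generator emulates the salient features of an N-terminomics
#' (COFRADIC) study built on a Ribo-Seq-derived custom database: NTR
#' proteoforms are short (median length 40 residues versus 414 for annotated
#' proteins), a fraction of them are pseudogene-like near-duplicates (0-2
#' substitutions) of an annotated parent, true N termini are cotranslationally
#' acetylated with high probability (80-90 percent of cytosolic proteins),
#' initiator methionines are excised per MetAP specificity, and the peptide
#' pool is contaminated with internal, C-terminal, ragged and
#' pyroglutamate-starting peptides with semi-specific ends.
#'
#' @param n_annotated,n_ntr Entry counts of the two database compartments.
#' @param ntr_length_median,annotated_length_median Median protein lengths
#'   (log-normal length model; only the medians are constrained).
#' @param pseudogene_fraction Fraction of NTR entries cloned from an
#'   annotated parent with 0-2 substitutions.
#' @param acetylation_prob Probability that a true N terminus is
#'   cotranslationally (in vivo) acetylated (default 0.85).
#' @param imet_rule iMet follower set used both to generate processed
#'   termini and to compute expected labels.
#' @param proteases Character vector of protease preset names.
#' @param planted_counts Named integer vector of planted record counts per
#'   protease; names are the ground-truth classes.
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return A classed list.
#' @export
simulationConfig <- function(n_annotated = 60L, n_ntr = 60L,
                             ntr_length_median = 40L,
                             annotated_length_median = 414L,
                             pseudogene_fraction = 0.3,
                             acetylation_prob = 0.85,
                             imet_rule = imetRuleSet("metap"),
                             proteases = c("trypsin", "chymotrypsin",
                                           "gluc"),
                             planted_counts = c(
                                 true_nterm_pos1 = 18L,
                                 true_nterm_pos2 = 14L,
                                 alt_high_met = 10L,
                                 alt_high_riboseq = 8L,
                                 alt_low = 10L,
                                 internal = 18L,
                                 cterm = 8L,
                                 ragged_group = 5L,
                                 pyroglu = 8L,
                                 full_coverage_micro = 1L),
                             seed = 1L) {
    stopifnot(all(planted_counts >= 0L),
              pseudogene_fraction >= 0, pseudogene_fraction <= 1,
              acetylation_prob >= 0, acetylation_prob <= 1)
    structure(list(
        n_annotated = as.integer(n_annotated),
        n_ntr = as.integer(n_ntr),
        ntr_length_median = as.integer(ntr_length_median),
        annotated_length_median = as.integer(annotated_length_median),
        pseudogene_fraction = pseudogene_fraction,
        acetylation_prob = acetylation_prob,
        imet_rule = imet_rule,
        proteases = proteases,
        planted_counts = planted_counts,
        seed = as.integer(seed)
    ), class = "SimulationConfig")
}

.AA20 <- setdiff(.AA_RESIDUES, "U")

## Random protein: starts with Met; second residue is a MetAP-removable
## follower with probability 0.6 (so processed termini are well represented).
.randomProtein <- function(len, imet) {
    second <- if (stats::runif(1) < 0.6) sample(imet, 1L) else
        sample(setdiff(.AA20, imet), 1L)
    paste0("M", second,
           paste(sample(.AA20, len - 2L, replace = TRUE), collapse = ""))
}

.lengthDraw <- function(n, median, sdlog, min_len = 12L) {
    pmax(min_len, round(stats::rlnorm(n, meanlog = log(median),
                                      sdlog = sdlog)))
}

.randomAccession <- function(i) {
    sprintf("ENST%011d_%d_%d_ntr_%sdb1", i, sample(1:22, 1L),
            sample(1e6:2e8, 1L),
            sample(c("100", "010", "001", "110", "101", "011", "111"), 1L))
}

#' Generate a synthetic proteoform database with planted parents
#'
#' Annotated (UniProt-like) entries and NTR proteoform entries are drawn
#' with log-normal lengths calibrated to the configured medians. A fraction
#' of NTR entries are pseudogene-like: a window of an annotated parent
#' cloned with 0-2 residue substitutions. When full-coverage microprotein
#' records are planted, a few NTR entries are forced to microprotein length.
#' Deterministic given \code{cfg$seed}.
#'
#' @param cfg A [simulationConfig()].
#' @return A list with \code{db} (a \linkS4class{ProteoformDatabase}) and
#'   \code{parents} (data.frame: \code{ntr_id}, \code{parent_id},
#'   \code{parent_start}, \code{n_substitutions},
#'   \code{substitution_positions}).
#' @export
generateProteome <- function(cfg) {
    set.seed(cfg$seed)
    imet <- cfg$imet_rule
    ann_len <- .lengthDraw(cfg$n_annotated, cfg$annotated_length_median,
                           sdlog = 0.55, min_len = 40L)
    ann_id <- sprintf("P%05d", 10000L + seq_len(cfg$n_annotated))
    ann_seq <- vapply(ann_len, .randomProtein, "", imet = imet)
    n_pseudo <- round(cfg$pseudogene_fraction * cfg$n_ntr)
    ntr_len <- .lengthDraw(cfg$n_ntr, cfg$ntr_length_median, sdlog = 0.45,
                           min_len = 12L)
    n_micro <- sum(cfg$planted_counts["full_coverage_micro"],
                   na.rm = TRUE) * length(cfg$proteases)
    if (n_micro > 0L) {
        micro_idx <- utils::tail(seq_len(cfg$n_ntr), min(n_micro + 2L,
                                                         cfg$n_ntr))
        ntr_len[micro_idx] <- sample(12:18, length(micro_idx),
                                     replace = TRUE)
    }
    ntr_id <- vapply(seq_len(cfg$n_ntr), .randomAccession, "")
    ntr_seq <- character(cfg$n_ntr)
    parents <- list()
    seen <- ann_seq
    for (i in seq_len(cfg$n_ntr)) {
        if (i <= n_pseudo) {
            parent <- sample(cfg$n_annotated, 1L)
            plen <- nchar(ann_seq[parent])
            wlen <- min(ntr_len[i], plen)
            wstart <- sample(seq_len(plen - wlen + 1L), 1L)
            s <- substr(ann_seq[parent], wstart, wstart + wlen - 1L)
            nsub <- sample(0:2, 1L)
            if (nsub == 0L && s %in% seen) nsub <- 1L
            pos <- if (nsub > 0L) sort(sample(seq_len(wlen), nsub)) else
                integer(0)
            for (p in pos) {
                old <- substr(s, p, p)
                substr(s, p, p) <- sample(setdiff(.AA20, old), 1L)
            }
            ntr_seq[i] <- s
            parents[[length(parents) + 1L]] <- data.frame(
                ntr_id = ntr_id[i], parent_id = ann_id[parent],
                parent_start = wstart, n_substitutions = length(pos),
                substitution_positions = paste(pos, collapse = ","),
                stringsAsFactors = FALSE)
        } else {
            repeat {
                s <- .randomProtein(ntr_len[i], imet)
                if (!s %in% seen) break
            }
            ntr_seq[i] <- s
        }
        seen <- c(seen, ntr_seq[i])
    }
    src <- data.frame(
        id = c(ann_id, ntr_id),
        sequence = c(ann_seq, ntr_seq),
        category = c(rep("uniprot", cfg$n_annotated),
                     rep("ntr", cfg$n_ntr)),
        stringsAsFactors = FALSE
    )
    db <- mergeDatabases(src)
    parents <- if (length(parents) > 0L) do.call(rbind, parents) else
        data.frame(ntr_id = character(0), parent_id = character(0),
                   parent_start = integer(0), n_substitutions = integer(0),
                   substitution_positions = character(0))
    list(db = db, parents = parents)
}

## All exact occurrences of a peptide across database entries.
.occurrences <- function(peptide, ids, seqs) {
    rows <- lapply(seq_along(ids), function(i) {
        hits <- gregexpr(peptide, seqs[i], fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) return(NULL)
        data.frame(entry_id = ids[i], start = as.integer(hits),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

## Peptide end: prefer a specific C-terminal cleavage site, else a
## semi-specific end; always strictly inside the protein.
.chooseEnd <- function(seq, start, rule, min_len = 8L, max_len = 18L) {
    n <- nchar(seq)
    residues <- strsplit(seq, "")[[1L]]
    cuts <- .cleavageBoundaries(residues, rule)
    ok <- cuts[cuts >= start + min_len - 1L & cuts <= start + max_len - 1L &
               cuts < n]
    if (length(ok) > 0L) return(ok[1L])
    end <- min(start + max_len - 1L, n - 1L)
    if (end - start + 1L < min_len) return(NA_integer_)
    end
}

## Standalone expected-label evaluation used at generation time.  Mirrors
## the documented classification rules but is written independently of the
## pipeline code path.
.expectedLabel <- function(matches, best_mod, db_seqs, rule, imet,
                           riboseq_key) {
    cat <- inferCategory(matches$entry_id)
    ord <- order(categoryRank(cat, "peptide_sorting"), matches$start,
                 matches$entry_id)
    main <- matches[ord[1L], ]
    pep_first <- substr(main$peptide, 1L, 1L)
    prec <- if (main$start > 1L)
        substr(db_seqs[[main$entry_id]], main$start - 1L, main$start - 1L)
        else NA_character_
    if (any(matches$start <= 2L)) {
        return(c("database_annotated", "high"))
    }
    if (any(paste(matches$entry_id, matches$start) %in% riboseq_key)) {
        return(c("alternative", "high"))
    }
    met <- pep_first == "M" ||
        (!is.na(prec) && prec == "M" && pep_first %in% imet)
    at_cut <- !is.na(prec) && prec %in% rule@cleaveAfter
    if (best_mod == "invivo_ac" && met) return(c("alternative", "high"))
    if (best_mod == "invivo_ac" && !at_cut) return(c("alternative", "low"))
    if (best_mod == "heavy_ac" && met && !at_cut)
        return(c("alternative", "low"))
    c("removed", "removed")
}

## Main (entry, start) after accession sorting, computed independently of
## the pipeline: category priority, then start, then lexicographic id.
.mainKey <- function(matches) {
    cat <- inferCategory(matches$entry_id)
    ord <- order(categoryRank(cat, "peptide_sorting"), matches$start,
                 matches$entry_id)
    paste(matches$entry_id[ord[1L]], matches$start[ord[1L]])
}

.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

## Attempt to plant one ground-truth record; NULL signals an unsuitable
## random draw (the caller retries with fresh randomness).
.plantOne <- function(class, db, ids, seqs, lens, rule, imet, cfg,
                      used_peps, protease) {
    pep_key <- function(p) paste0(protease, "\r", p)
    grp_key <- function(k) paste0(protease, "\rgrp\r", k)
    fresh <- function(p) !exists(pep_key(p), envir = used_peps)
    truth_row <- function(peptide, matches, best_mod, bucket,
                          category = NA_character_,
                          confidence = NA_character_,
                          reason = NA_character_, entry, start) {
        data.frame(peptide = peptide, protease = protease,
                   true_class = class, expected_bucket = bucket,
                   expected_category = category,
                   expected_confidence = confidence,
                   expected_reason = reason,
                   best_mod = best_mod,
                   matches = .formatMatches(matches),
                   entry_id = entry, start = start,
                   stringsAsFactors = FALSE)
    }
    nterm_mods <- function() {
        if (stats::runif(1) < cfg$acetylation_prob) {
            n <- .sample1(2:3)
            c("invivo_ac", sample(c("invivo_ac", "heavy_ac"), n - 1L,
                                  replace = TRUE, prob = c(0.7, 0.3)))
        } else {
            rep("heavy_ac", .sample1(1:2))
        }
    }
    register_group <- function(matches) {
        k <- grp_key(.mainKey(matches))
        if (exists(k, envir = used_peps)) return(FALSE)
        assign(k, TRUE, envir = used_peps)
        TRUE
    }

    if (class %in% c("true_nterm_pos1", "true_nterm_pos2")) {
        pos2 <- class == "true_nterm_pos2"
        eligible <- which(lens >= 14L &
            (!pos2 | (substr(seqs, 1L, 1L) == "M" &
                      substr(seqs, 2L, 2L) %in% imet)))
        if (length(eligible) == 0L) return(NULL)
        i <- .sample1(eligible)
        start <- if (pos2) 2L else 1L
        end <- .chooseEnd(seqs[i], start, rule)
        if (is.na(end) || end >= lens[i]) return(NULL)
        pep <- substr(seqs[i], start, end)
        if (!fresh(pep)) return(NULL)
        matches <- .occurrences(pep, ids, seqs)
        if (!register_group(matches)) return(NULL)
        mods <- nterm_mods()
        best <- if (any(mods == "invivo_ac")) "invivo_ac" else "heavy_ac"
        return(list(key = pep_key(pep), peptide = pep, mods = mods,
                    matches = matches,
                    truth = truth_row(pep, matches, best, "final",
                                      entry = ids[i], start = start)))
    }

    if (class == "full_coverage_micro") {
        eligible <- which(lens >= 8L & lens <= 20L)
        if (length(eligible) == 0L) return(NULL)
        i <- .sample1(eligible)
        pep <- seqs[i]
        if (!fresh(pep)) return(NULL)
        matches <- .occurrences(pep, ids, seqs)
        if (nrow(matches) != 1L) return(NULL)
        if (!register_group(matches)) return(NULL)
        mods <- rep("heavy_ac", .sample1(1:2))
        return(list(key = pep_key(pep), peptide = pep, mods = mods,
                    matches = matches,
                    truth = truth_row(pep, matches, "heavy_ac", "final",
                                      entry = ids[i], start = 1L)))
    }

    if (class %in% c("alt_high_met", "alt_high_riboseq", "alt_low")) {
        i <- .sample1(which(lens >= 24L))
        n <- lens[i]
        s_cand <- 4:(n - 9L)
        if (length(s_cand) == 0L) return(NULL)
        if (class == "alt_high_met") {
            mpos <- which(strsplit(seqs[i], "")[[1L]] == "M")
            s_cand <- intersect(s_cand, mpos)
            if (length(s_cand) == 0L) return(NULL)
        }
        s <- .sample1(s_cand)
        first <- substr(seqs[i], s, s)
        prec <- substr(seqs[i], s - 1L, s - 1L)
        if (class != "alt_high_met") {
            if (first == "M" || prec == "M") return(NULL)
            if (class == "alt_low" && prec %in% rule@cleaveAfter) {
                return(NULL)
            }
        }
        end <- .chooseEnd(seqs[i], s, rule)
        if (is.na(end) || end >= n) return(NULL)
        pep <- substr(seqs[i], s, end)
        if (!fresh(pep)) return(NULL)
        matches <- .occurrences(pep, ids, seqs)
        if (any(matches$start <= 2L)) return(NULL)
        ## class conditions must hold at every occurrence so the main
        ## match cannot subvert the planted label
        occ_ok <- vapply(seq_len(nrow(matches)), function(j) {
            e <- matches$entry_id[j]
            st <- matches$start[j]
            es <- seqs[match(e, ids)]
            pj <- substr(es, st - 1L, st - 1L)
            if (class == "alt_high_met") TRUE
            else pj != "M" && !(class == "alt_low" &&
                                pj %in% rule@cleaveAfter)
        }, logical(1L))
        if (!all(occ_ok)) return(NULL)
        ## the peptide must not end at any occurrence's protein C terminus
        at_cterm <- vapply(seq_len(nrow(matches)), function(j) {
            es <- seqs[match(matches$entry_id[j], ids)]
            matches$start[j] + nchar(pep) - 1L >= nchar(es)
        }, logical(1L))
        if (any(at_cterm)) return(NULL)
        if (!register_group(matches)) return(NULL)
        mods <- switch(class,
            alt_high_met = rep("invivo_ac", .sample1(1:2)),
            alt_high_riboseq = rep("heavy_ac", .sample1(1:2)),
            alt_low = rep("invivo_ac", .sample1(1:2)))
        best <- mods[1L]
        rb <- if (class == "alt_high_riboseq") {
            data.frame(entry_id = ids[i], pos = s,
                       stringsAsFactors = FALSE)
        } else NULL
        return(list(key = pep_key(pep), peptide = pep, mods = mods,
                    matches = matches, riboseq = rb,
                    truth = truth_row(pep, matches, best, "final",
                                      entry = ids[i], start = s)))
    }

    if (class == "internal") {
        i <- .sample1(which(lens >= 24L))
        n <- lens[i]
        s <- .sample1(4:(n - 9L))
        end <- .chooseEnd(seqs[i], s, rule)
        if (is.na(end) || end >= n) return(NULL)
        pep <- substr(seqs[i], s, end)
        if (!fresh(pep)) return(NULL)
        matches <- .occurrences(pep, ids, seqs)
        if (any(matches$start <= 2L)) return(NULL)
        mods <- rep("free", .sample1(1:3))
        return(list(key = pep_key(pep), peptide = pep, mods = mods,
                    matches = matches,
                    truth = truth_row(pep, matches, "free", "removed",
                                      reason = "internal",
                                      entry = ids[i], start = s)))
    }

    if (class == "cterm") {
        i <- .sample1(which(lens >= 20L))
        n <- lens[i]
        plen <- .sample1(8:15)
        s <- n - plen + 1L
        if (s <= 3L) return(NULL)
        pep <- substr(seqs[i], s, n)
        if (!fresh(pep)) return(NULL)
        matches <- .occurrences(pep, ids, seqs)
        if (nrow(matches) != 1L) return(NULL)
        mods <- rep("heavy_ac", .sample1(1:2))
        return(list(key = pep_key(pep), peptide = pep, mods = mods,
                    matches = matches,
                    truth = truth_row(pep, matches, "heavy_ac", "removed",
                                      reason = "cterm",
                                      entry = ids[i], start = s)))
    }

    if (class == "ragged_group") {
        i <- .sample1(which(lens >= 28L))
        end <- .chooseEnd(seqs[i], 1L, rule, min_len = 15L, max_len = 22L)
        if (is.na(end) || end >= lens[i]) return(NULL)
        ends <- c(end, end - 4L, end - 8L)
        if (min(ends) < 7L) return(NULL)
        peps <- substr(rep(seqs[i], 3L), 1L, ends)
        if (!all(vapply(peps, fresh, logical(1L)))) return(NULL)
        match_list <- lapply(peps, .occurrences, ids = ids, seqs = seqs)
        if (any(vapply(match_list, nrow, 0L) != 1L)) return(NULL)
        if (!register_group(match_list[[1L]])) return(NULL)
        mods <- lapply(1:3, function(j) rep("invivo_ac", .sample1(1:2)))
        truth <- rbind(
            truth_row(peps[1L], match_list[[1L]], "invivo_ac", "final",
                      entry = ids[i], start = 1L),
            truth_row(peps[2L], match_list[[2L]], "invivo_ac",
                      "collapsed", entry = ids[i], start = 1L),
            truth_row(peps[3L], match_list[[3L]], "invivo_ac",
                      "collapsed", entry = ids[i], start = 1L))
        return(list(key = pep_key(peps[1L]), peptide = peps[1L],
                    mods = mods[[1L]], matches = match_list[[1L]],
                    truth = truth,
                    extra = list(
                        list(peptide = peps[2L], mods = mods[[2L]],
                             matches = match_list[[2L]]),
                        list(peptide = peps[3L], mods = mods[[3L]],
                             matches = match_list[[3L]]))))
    }

    if (class == "pyroglu") {
        i <- .sample1(which(lens >= 24L))
        n <- lens[i]
        qpos <- which(strsplit(seqs[i], "")[[1L]] == "Q")
        qpos <- qpos[qpos >= 4L & qpos <= n - 9L]
        if (length(qpos) == 0L) return(NULL)
        s <- .sample1(qpos)
        end <- .chooseEnd(seqs[i], s, rule)
        if (is.na(end) || end >= n) return(NULL)
        pep <- substr(seqs[i], s, end)
        if (!fresh(pep)) return(NULL)
        matches <- .occurrences(pep, ids, seqs)
        mods <- rep("pyroglu", .sample1(1:2))
        return(list(key = pep_key(pep), peptide = pep, mods = mods,
                    matches = matches,
                    truth = truth_row(pep, matches, "pyroglu", "pyroglu",
                                      entry = ids[i], start = s)))
    }

    stop("unknown planted class: ", class)
}

#' Generate a PSM table with planted ground truth
#'
#' For every planted class and protease, peptides are cut from the database
#' honouring the protease specificity (semi-specific ends for alternative
#' starts), N-terminal modifications are assigned (in vivo acetyl with
#' probability \code{acetylation_prob} at true N termini, heavy acetyl for
#' termini free in the cell, free alpha-amines for internal peptides,
#' pyroglutamate for Q-starting artifacts), ragged groups share a start
#' position, and identification scores are drawn uniformly from [30, 120].
#' The match list of every PSM is an honest substring scan of the whole
#' database, so pseudogene clones produce genuine multi-matches. Expected
#' category and confidence are evaluated at generation time by a standalone
#' implementation of the classification rules. Deterministic given
#' \code{cfg$seed}.
#'
#' @param proteome A list from [generateProteome()].
#' @param cfg The [simulationConfig()] used to generate it.
#' @return A list with \code{psms} (PSM data.frame across all proteases),
#'   \code{truth} (one row per planted peptide: \code{true_class},
#'   \code{expected_bucket} in final/removed/pyroglu/collapsed,
#'   \code{expected_category}, \code{expected_confidence}) and
#'   \code{riboseq_tis} (the planted TIS evidence table).
#' @export
generatePsmTable <- function(proteome, cfg) {
    set.seed(cfg$seed + 1L)
    db <- proteome$db
    ids <- mainIds(db)
    seqs <- unname(as.character(entrySequences(db)))
    db_seqs <- stats::setNames(as.list(seqs), ids)
    lens <- nchar(seqs)
    imet <- cfg$imet_rule
    riboseq <- list()
    psms <- list()
    truth <- list()
    used_peps <- new.env(parent = emptyenv())
    samples <- sprintf("B%d", 1:12)

    emit_psms <- function(peptide, mods, protease, matches) {
        n <- length(mods)
        data.frame(
            peptide = peptide, nt_mod = mods,
            score = .roundAway(stats::runif(n, 30, 120), 2L),
            protease = protease,
            sample_id = sample(samples, n, replace = TRUE),
            matches = .formatMatches(matches),
            stringsAsFactors = FALSE)
    }

    for (protease in cfg$proteases) {
        rule <- proteaseRule(protease)
        counts <- cfg$planted_counts
        for (class in names(counts)) {
            k <- counts[[class]]
            planted <- 0L
            attempts <- 0L
            while (planted < k) {
                attempts <- attempts + 1L
                if (attempts > 400L) {
                    stop("could not plant class ", class, " for ",
                         protease)
                }
                rec <- .plantOne(class, db, ids, seqs, lens, rule, imet,
                                 cfg, used_peps, protease)
                if (is.null(rec)) next
                planted <- planted + 1L
                assign(rec$key, TRUE, envir = used_peps)
                psms[[length(psms) + 1L]] <- emit_psms(
                    rec$peptide, rec$mods, protease, rec$matches)
                if (!is.null(rec$extra)) {
                    for (ex in rec$extra) {
                        assign(paste0(protease, "\r", ex$peptide), TRUE,
                               envir = used_peps)
                        psms[[length(psms) + 1L]] <- emit_psms(
                            ex$peptide, ex$mods, protease, ex$matches)
                    }
                }
                if (!is.null(rec$riboseq)) {
                    riboseq[[length(riboseq) + 1L]] <- rec$riboseq
                }
                truth[[length(truth) + 1L]] <- rec$truth
            }
        }
    }
    psms <- do.call(rbind, psms)
    truth <- do.call(rbind, truth)
    riboseq_tis <- if (length(riboseq) > 0L) {
        unique(do.call(rbind, riboseq))
    } else {
        data.frame(entry_id = character(0), pos = integer(0))
    }
    ## finalize expected labels now that the full TIS set is known
    riboseq_key <- paste(riboseq_tis$entry_id, riboseq_tis$pos)
    for (i in seq_len(nrow(truth))) {
        if (!truth$expected_bucket[i] %in% c("final")) next
        m <- .parseMatches(truth$matches[i])
        m$peptide <- truth$peptide[i]
        lab <- .expectedLabel(m, truth$best_mod[i], db_seqs,
                              proteaseRule(truth$protease[i]), imet,
                              riboseq_key)
        truth$expected_category[i] <- lab[1L]
        truth$expected_confidence[i] <- lab[2L]
    }
    list(psms = psms, truth = truth, riboseq_tis = riboseq_tis)
}

#' Generate a reference/query spectrum pair for concordance testing
#'
#' Builds the theoretical b/y fragment m/z values of a peptide and assigns
#' synthetic intensities. When \code{concordant}, the query intensities are
#' the reference intensities with at most one adjacent rank swap (emulating
#' the same peptide measured twice); otherwise the intensities are randomly
#' permuted over the fragments (a different underlying spectrum).
#' Deterministic given \code{seed}.
#'
#' @param peptide A peptide of length >= 4.
#' @param concordant Should the pair emulate matching spectra?
#' @param seed Integer seed.
#' @return A list with \code{reference} and \code{query} peak lists
#'   (data.frames with \code{mz}, \code{intensity}).
#' @export
generateSpectrumPair <- function(peptide, concordant = TRUE, seed = 1L) {
    stopifnot(nchar(peptide) >= 4L)
    set.seed(seed)
    frags <- theoreticalFragments(peptide)
    k <- nrow(frags)
    ref_int <- stats::runif(k, 50, 1000)
    qry_int <- if (concordant) {
        out <- ref_int
        if (stats::runif(1) < 0.5 && k >= 2L) {
            ord <- order(-out)
            j <- sample(k - 1L, 1L)
            tmp <- out[ord[j]]
            out[ord[j]] <- out[ord[j + 1L]]
            out[ord[j + 1L]] <- tmp
        }
        out * stats::runif(1, 0.5, 2)   # uniform scaling is irrelevant
    } else {
        sample(ref_int)
    }
    list(
        reference = data.frame(mz = frags$mz, intensity = ref_int)[
            order(frags$mz), ],
        query = data.frame(mz = frags$mz, intensity = qry_int)[
            order(frags$mz), ]
    )
}

.NT_BASES <- c("A", "C", "G", "T")

.reverseComplement <- function(x) {
    chartr("ACGT", "TGCA",
           vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]),
                                       collapse = ""), ""))
}

#' Generate a toy genomic locus encoding a protein
#'
#' Reverse-translates a protein through randomly chosen codons, splits the
#' coding sequence over \code{nExons} exons separated by random introns,
#' embeds it in a random chromosome sequence (with 5' UTR nucleotides before
#' the TIS inside the first coding exon), and returns the corresponding
#' \linkS4class{TranscriptModel} plus the chromosome sequence. On the minus
#' strand the coding sequence is placed reverse-complemented with exons in
#' descending genomic order. Deterministic given \code{seed}.
#'
#' @param protein Protein sequence (no selenocysteine).
#' @param strand \code{"+"} or \code{"-"}.
#' @param nExons Number of exons carrying coding sequence.
#' @param transcriptId,chromosome Identifiers for the model.
#' @param seed Integer seed.
#' @return A list with \code{model} (TranscriptModel), \code{genome} (named
#'   character vector of one chromosome sequence) and \code{protein}.
#' @export
generateToyLocus <- function(protein, strand = "+", nExons = 2L,
                             transcriptId = "TX1", chromosome = "chrT",
                             seed = 1L) {
    set.seed(seed)
    code <- Biostrings::GENETIC_CODE
    cds <- paste(vapply(strsplit(protein, "")[[1L]], function(aa) {
        cands <- names(code)[code == aa]
        if (length(cands) == 0L) stop("no codon for residue ", aa)
        .sample1(cands)
    }, ""), collapse = "")
    n_nt <- nchar(cds)
    nExons <- max(1L, min(nExons, n_nt))
    ## split the CDS into nExons non-empty chunks
    cuts <- if (nExons > 1L)
        sort(sample(seq_len(n_nt - 1L), nExons - 1L)) else integer(0)
    chunk_bounds <- cbind(c(1L, cuts + 1L), c(cuts, n_nt))
    utr5 <- sample(3:12, 1L)            # 5' UTR inside the first exon
    introns <- if (nExons > 1L) sample(20:60, nExons - 1L,
                                       replace = TRUE) else integer(0)
    offset <- sample(30:80, 1L)         # upstream flank
    ## lay out exons on a forward template
    starts <- integer(nExons)
    ends <- integer(nExons)
    pos <- offset + 1L
    for (i in seq_len(nExons)) {
        exon_len <- (chunk_bounds[i, 2L] - chunk_bounds[i, 1L] + 1L) +
            if (i == 1L) utr5 else 0L
        starts[i] <- pos
        ends[i] <- pos + exon_len - 1L
        pos <- ends[i] + 1L + (if (i < nExons) introns[i] else
                               sample(20:50, 1L))
    }
    glen <- pos + 30L
    template <- sample(.NT_BASES, glen, replace = TRUE)
    ## write the spliced exonic sequence (UTR then CDS) onto the template
    exonic <- c(sample(.NT_BASES, utr5, replace = TRUE),
                strsplit(cds, "")[[1L]])
    cursor <- 1L
    for (i in seq_len(nExons)) {
        w <- ends[i] - starts[i] + 1L
        template[starts[i]:ends[i]] <- exonic[cursor:(cursor + w - 1L)]
        cursor <- cursor + w
    }
    fwd <- paste(template, collapse = "")
    tis_fwd <- starts[1L] + utr5        # first CDS nucleotide, forward axis
    if (strand == "+") {
        genome <- fwd
        model <- transcriptModel(transcriptId, chromosome, "+",
                                 starts, ends, tis_fwd)
    } else {
        ## mirror the layout: genomic coordinate g -> glen - g + 1
        genome <- .reverseComplement(fwd)
        model <- transcriptModel(transcriptId, chromosome, "-",
                                 glen - ends + 1L, glen - starts + 1L,
                                 glen - tis_fwd + 1L)
    }
    list(model = model,
         genome = stats::setNames(genome, chromosome),
         protein = protein)
}

#' Extract and translate the spliced sequence of mapped genome blocks
#'
#' Support utility for validating [mapPeptideToGenome()]: given a toy
#' genome, concatenates the block nucleotides in translation order
#' (ascending genomic order on the plus strand, descending with reverse
#' complement on the minus strand) and translates them with the standard
#' genetic code.
#'
#' @param blockSet A \code{GenomeBlockSet} from [mapPeptideToGenome()].
#' @param genome Named character vector of chromosome sequences.
#' @return A list with \code{nucleotides} and \code{peptide}.
#' @export
translateBlockSet <- function(blockSet, genome) {
    chrom <- genome[[blockSet$chrom[1L]]]
    pieces <- substring(chrom, blockSet$chromStart + 1L,
                        blockSet$chromEnd)
    nt <- if (blockSet$strand[1L] == "+") {
        paste(pieces, collapse = "")
    } else {
        paste(.reverseComplement(rev(pieces)), collapse = "")
    }
    code <- Biostrings::GENETIC_CODE
    codons <- substring(nt, seq(1L, nchar(nt), 3L),
                        pmin(seq(3L, nchar(nt) + 2L, 3L), nchar(nt)))
    list(nucleotides = nt,
         peptide = paste(code[codons], collapse = ""))
}
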