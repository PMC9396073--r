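#' Enrichment metrics of an N-terminal peptidome
#'
#' Distinct peptides fall in four classes: free Nt-peptides (N termini free
#' in the cell, hence heavy-acetylated in vitro), cotranslationally (in
#' vivo) acetylated Nt-peptides, pyroglutamyl-starting peptides (coenriched
#' artifacts) and internal peptides (free alpha-amine at analysis). The
#' fraction of Nt-peptides is the share of the first two classes; the
#' enrichment efficiency additionally counts pyroglutamyl peptides, since
#' the enrichment chemistry coenriches them. Percentages are rounded half
#' away from zero to one decimal.
#'
#' @param x Either a distinct-peptide data.frame (from
#'   [deduplicatePsms()]; classes are derived from \code{best_mod} and
#'   \code{forms_seen}) or the count of free Nt-peptides.
#' @param n_cotransl,n_pyroglu,n_internal Class counts when \code{x} is a
#'   count.
#' @return A list with the four counts, \code{total},
#'   \code{fraction_nt_pct} and \code{efficiency_pct}.
#' @export
#' @examples
#' enrichmentMetrics(3820, 2192, 1418, 2717)  # fraction 59.2, efficiency 73.2
enrichmentMetrics <- function(x, n_cotransl = NULL, n_pyroglu = NULL,
                              n_internal = NULL) {
    if (is.data.frame(x)) {
        forms <- strsplit(x$forms_seen, ",", fixed = TRUE)
        pyro_only <- vapply(forms, function(f) all(f == "pyroglu"),
                            logical(1L))
        free_only <- vapply(forms, function(f) all(f == "free"),
                            logical(1L))
        n_free_nt <- sum(!pyro_only & !free_only &
                         x$best_mod == "heavy_ac")
        n_cotransl <- sum(!pyro_only & !free_only &
                          x$best_mod == "invivo_ac")
        n_pyroglu <- sum(pyro_only)
        n_internal <- sum(free_only)
    } else {
        n_free_nt <- x
    }
    counts <- c(n_free_nt, n_cotransl, n_pyroglu, n_internal)
    stopifnot(all(counts >= 0))
    total <- sum(counts)
    if (total == 0) stop("no peptides: total count is zero")
    list(
        n_free_nt = n_free_nt, n_cotransl = n_cotransl,
        n_pyroglu = n_pyroglu, n_internal = n_internal, total = total,
        fraction_nt_pct = .roundAway(100 * (n_free_nt + n_cotransl) /
                                     total, 1L),
        efficiency_pct = .roundAway(
            100 * (n_free_nt + n_cotransl + n_pyroglu) / total, 1L)
    )
}

#' Percentage share of NTR-matched peptides
#'
#' @param numerator,denominator Counts (denominator > 0).
#' @param decimals Decimal places (default 2), rounded half away from zero.
#' @return The percentage 100 * numerator / denominator.
#' @export
#' @examples
#' ntrShare(22, 3854)  # 0.57
ntrShare <- function(numerator, denominator, decimals = 2L) {
    stopifnot(denominator > 0)
    .roundAway(100 * numerator / denominator, decimals)
}

#' Run the end-to-end pipeline on synthetic or supplied data
#'
#' Simulates a proteoform database and PSM tables (or loads supplied ones),
#' runs the per-protease selection pipeline, merges across proteases,
#' computes enrichment metrics, funnel counts, dataset overlaps and a
#' homology curation report for the final alternative NTR peptides, and
#' writes all artifacts plus a machine-readable JSON summary into a run
#' directory.
#'
#' @param config A [simulationConfig()] (synthetic mode), or a list with
#'   elements \code{db} (a \linkS4class{ProteoformDatabase}), \code{psms}
#'   (PSM data.frame covering one or more proteases) and optionally
#'   \code{riboseq_tis}.
#' @param outDir Output directory (created if missing).
#' @param imet iMet follower set for classification.
#' @return Invisibly, a list with \code{final} (merged table),
#'   \code{per_protease} results, \code{enrichment}, \code{overlap},
#'   \code{curation}, \code{truth} (synthetic mode) and \code{summary}.
#' @export
runPipeline <- function(config, outDir = tempfile("ntermrun"),
                        imet = imetRuleSet("metap")) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    truth <- NULL
    if (inherits(config, "SimulationConfig")) {
        proteome <- generateProteome(config)
        db <- proteome$db
        sim <- generatePsmTable(proteome, config)
        psms <- sim$psms
        riboseq_tis <- sim$riboseq_tis
        truth <- sim$truth
        writeDatabase(db, file.path(outDir, "db.fasta"))
        utils::write.table(truth, file.path(outDir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        db <- config$db
        psms <- config$psms
        riboseq_tis <- config$riboseq_tis
        if (is.null(db) || is.null(psms)) {
            stop("config must provide 'db' and 'psms'")
        }
    }
    per <- list()
    enrichment <- list()
    for (protease in unique(psms$protease)) {
        sub <- psms[psms$protease == protease, , drop = FALSE]
        writePsmTable(sub, file.path(outDir,
                                     paste0("psms_", protease, ".tsv")))
        res <- selectNTermini(sub, db, riboseq_tis,
                              rule = proteaseRule(protease), imet = imet)
        per[[protease]] <- res
        enrichment[[protease]] <-
            enrichmentMetrics(res$stages$distinct_peptides)
    }
    final <- mergeAcrossProteases(lapply(per, `[[`, "final"))
    funnel <- do.call(rbind, lapply(names(per), function(p) {
        cbind(protease = p, per[[p]]$funnel)
    }))
    overlap <- overlapSummary(lapply(per, `[[`, "final"))
    ntr_final <- final[final$main_category == "ntr" &
                       final$category == "alternative", , drop = FALSE]
    curation <- if (nrow(ntr_final) > 0L) {
        curationReport(ntr_final$peptide, db)
    } else NULL
    utils::write.table(final, file.path(outDir, "final_nterm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    removed <- .bindRows2(lapply(per, `[[`, "removed"))
    if (!is.null(removed)) {
        utils::write.table(removed, file.path(outDir, "removal_log.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(funnel, file.path(outDir, "funnel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(overlap, file.path(outDir, "overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(curation)) {
        utils::write.table(curation, file.path(outDir, "curation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    n_ntr <- sum(final$main_category == "ntr")
    summary <- list(
        n_psms = nrow(psms),
        n_final_nterm = nrow(final),
        n_database_annotated = sum(final$category ==
                                   "database_annotated"),
        n_alternative_high = sum(final$category == "alternative" &
                                 final$confidence == "high"),
        n_alternative_low = sum(final$category == "alternative" &
                                final$confidence == "low"),
        n_ntr_final = n_ntr,
        ntr_share_pct = ntrShare(n_ntr, nrow(final)),
        enrichment = enrichment,
        files = list.files(outDir)
    )
    jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(final = final, per_protease = per,
                   enrichment = enrichment, funnel = funnel,
                   overlap = overlap, curation = curation, truth = truth,
                   summary = summary, outDir = outDir))
}
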