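ntrId1 <- "ENST00000000001_1_1000_ntr_100db1"
ntrId2 <- "ENST00000000002_2_2000_ntr_010db1"

test_that("match sorting prioritizes category, then start, then id", {
    db <- tinyDb()
    ## annotated entry beats an NTR match even at a later start
    psm <- makePsm("MKEET", "heavy_ac", 50, "trypsin",
                   paste0(ntrId1, ":1;P10001:5"))
    s <- sortMatches(psm, db)
    expect_equal(s$main_entry, "P10001")
    expect_equal(s$main_start, 5L)
    ## within a category the lowest start wins
    psm2 <- makePsm("X", "free", 10, "trypsin", "P10002:7;P10001:2")
    s2 <- sortMatches(psm2, db)
    expect_equal(s2$main_entry, "P10001")
    expect_equal(s2$main_start, 2L)
    ## same category and start: alphabetical id
    psm3 <- makePsm("X", "free", 10, "trypsin",
                    paste0(ntrId2, ":3;", ntrId1, ":3"))
    s3 <- sortMatches(psm3, db)
    expect_equal(s3$main_entry, ntrId1)
    ## no match is removed
    expect_equal(length(strsplit(s3$matches, ";")[[1L]]), 2L)
})

test_that("deduplication keeps the top PSM and computes acetylation %", {
    psms <- rbind(
        makePsm(rep("MKEETKEDAEEK", 7L),
                c(rep("invivo_ac", 5L), rep("heavy_ac", 2L)),
                c(60, 95, 70, 55, 80, 99, 40), "trypsin",
                paste0(ntrId1, ":1")),
        makePsm("AVNVYSTS", "free", 33, "trypsin", "P10001:2"))
    psms <- sortMatches(psms, tinyDb())
    d <- deduplicatePsms(psms)
    expect_equal(nrow(d), 2L)
    grp <- d[d$peptide == "MKEETKEDAEEK", ]
    expect_equal(grp$best_mod, "invivo_ac")
    expect_equal(grp$psm_count, 7L)
    ## 100 * 5/7 = 71.4 rounds to 71
    expect_equal(grp$acetylation_pct, 71)
    ## representative is the highest-scoring in vivo PSM, not the heavy 99
    expect_equal(grp$score, 95)
    ## free-only peptide: undefined percentage
    expect_true(is.na(d$acetylation_pct[d$peptide == "AVNVYSTS"]))
})

test_that("peptides found in several fractions collapse to one record", {
    psms <- sortMatches(rbind(
        makePsm("KSAPSTGG", "heavy_ac", 50, "chymotrypsin",
                "P10001:3", sample_id = "B6"),
        makePsm("KSAPSTGG", "heavy_ac", 61, "chymotrypsin",
                "P10001:3", sample_id = "B9")), NULL)
    d <- deduplicatePsms(psms)
    expect_equal(nrow(d), 1L)
    expect_equal(d$psm_count, 2L)
})

test_that("internal, C-terminal and pyroglutamate peptides are diverted", {
    db <- mergeDatabases(data.frame(
        id = c("P1", "P2", ntrId1),
        sequence = c("MKVLAGWYDPET", "MAAAAKWWQETFGHKL", "MKEETKEDAEEKQ")))
    psms <- sortMatches(rbind(
        makePsm("LAGWYD", "free", 40, "trypsin", "P1:4"),       # internal
        makePsm("ETFGHKL", "heavy_ac", 50, "trypsin", "P2:10"), # C-terminal
        makePsm("QETFGH", "pyroglu", 45, "trypsin", "P2:9"),    # artifact
        makePsm("MKEETKEDAEEKQ", "heavy_ac", 66, "trypsin",
                paste0(ntrId1, ":1"))), db)                     # full cover
    ft <- filterTerminalClasses(deduplicatePsms(psms), db)
    expect_equal(sort(ft$removed$peptide), c("ETFGHKL", "LAGWYD"))
    expect_equal(ft$removed$reason[ft$removed$peptide == "LAGWYD"],
                 "internal")
    expect_equal(ft$removed$reason[ft$removed$peptide == "ETFGHKL"],
                 "cterm")
    expect_equal(ft$pyroglu$peptide, "QETFGH")
    ## start 1 spanning the complete microprotein is kept
    expect_equal(ft$candidates$peptide, "MKEETKEDAEEKQ")
    ## inconsistent position is a hard error
    bad <- deduplicatePsms(sortMatches(
        makePsm("WRONGPEP", "free", 1, "trypsin", "P1:2"), db))
    expect_error(filterTerminalClasses(bad, db), "not a substring")
})

test_that("ragged groups collapse to the longest, acetyl-first member", {
    base <- "MEKKEVVEEAENGRDAPADKKQKTDE"
    db <- mergeDatabases(data.frame(id = "P9", sequence = base))
    peps <- c("EKKEVVEEAENGRDAPAD", "EKKEVVEEAENGRDAP",
              "EKKEVVEEAENGR", "EKKEVVEEAEN")
    psms <- sortMatches(makePsm(peps, "heavy_ac", c(10, 20, 30, 40),
                                "trypsin", "P9:2"), db)
    ft <- filterTerminalClasses(deduplicatePsms(psms), db)
    collapsed <- collapseRagged(ft$candidates)
    expect_equal(nrow(collapsed), 1L)
    expect_equal(collapsed$peptide, "EKKEVVEEAENGRDAPAD")
    expect_setequal(strsplit(collapsed$shorter_variants, ",")[[1L]],
                    peps[-1L])
    expect_equal(collapsed$psm_count, 4L)

    ## a shorter in vivo acetylated member beats a longer heavy one
    psms2 <- sortMatches(makePsm(peps[1:2], c("heavy_ac", "invivo_ac"),
                                 c(90, 10), "trypsin", "P9:2"), db)
    collapsed2 <- collapseRagged(
        filterTerminalClasses(deduplicatePsms(psms2), db)$candidates)
    expect_equal(collapsed2$peptide, "EKKEVVEEAENGRDAP")
    expect_equal(collapsed2$best_mod, "invivo_ac")

    ## singleton groups pass through unchanged
    one <- filterTerminalClasses(deduplicatePsms(sortMatches(
        makePsm("EKKEVVEEAENGRDAPAD", "heavy_ac", 5, "trypsin", "P9:2"),
        db)), db)$candidates
    c1 <- collapseRagged(one)
    expect_equal(c1$peptide, one$peptide)
    expect_equal(c1$shorter_variants, "")
})

test_that("the classification decision tree matches the documented rules", {
    db <- mergeDatabases(data.frame(
        id = c("E1", "E2", "E3", "E4"),
        sequence = c(
            standInEntry("MASAASSSSLE", 12L, "E", 30L),
            standInEntry("GDVVPKDANAAIATIKTKR", 70L, "H", 124L),
            standInEntry("MKEETKEDAEEKQ", 1L, "", 13L),
            standInEntry("AVGVIKAVDKKAAGAGKVT", 27L, "L", 60L)),
        category = "ntr"))
    cand <- function(pep, entry, start, mod) {
        data.frame(peptide = pep, best_mod = mod, psm_count = 1L,
                   n_invivo = as.integer(mod == "invivo_ac"),
                   n_heavy = as.integer(mod == "heavy_ac"),
                   acetylation_pct = NA_real_, forms_seen = mod,
                   score = 50, main_entry = entry, main_start = start,
                   main_category = "ntr",
                   matches = paste0(entry, ":", start),
                   protease = "x", end = start + nchar(pep) - 1L,
                   shorter_variants = "", stringsAsFactors = FALSE)
    }
    ## in vivo acetylated, starts with Met, no Ribo-Seq: alternative high
    r1 <- classifyNtPeptides(cand("MASAASSSSLE", "E1", 12L, "invivo_ac"),
                             db, NULL, proteaseRule("gluc"))
    expect_equal(c(r1$category, r1$confidence),
                 c("alternative", "high"))
    ## in vivo, no Met, preceded by H (not an ArgC site): alternative low
    r2 <- classifyNtPeptides(
        cand("GDVVPKDANAAIATIKTKR", "E2", 70L, "invivo_ac"),
        db, NULL, proteaseRule("trypsin"))
    expect_equal(c(r2$category, r2$confidence), c("alternative", "low"))
    ## start 1, heavy acetylated: database annotated high
    r3 <- classifyNtPeptides(cand("MKEETKEDAEEKQ", "E3", 1L, "heavy_ac"),
                             db, NULL, proteaseRule("trypsin"))
    expect_equal(c(r3$category, r3$confidence),
                 c("database_annotated", "high"))
    ## heavy acetylated, no Met evidence: removed
    r4 <- classifyNtPeptides(
        cand("AVGVIKAVDKKAAGAGKVT", "E4", 27L, "heavy_ac"),
        db, NULL, proteaseRule("chymotrypsin"))
    expect_equal(r4$confidence, "removed")
    expect_equal(r4$reason, "blocked_no_met")
    ## Ribo-Seq evidence upgrades a blocked peptide to alternative high
    r5 <- classifyNtPeptides(
        cand("AVGVIKAVDKKAAGAGKVT", "E4", 27L, "heavy_ac"),
        db, data.frame(entry_id = "E4", pos = 27L),
        proteaseRule("chymotrypsin"))
    expect_equal(c(r5$category, r5$confidence), c("alternative", "high"))
})

test_that("cross-protease merging keeps the longest peptide per terminus", {
    db <- mergeDatabases(data.frame(
        id = "P9", sequence = "MEKKEVVEEAENGRDAPADKKQKTDEWW"))
    run1 <- selectNTermini(sortMatches(
        makePsm("EKKEVVEEAENGR", "invivo_ac", 44, "trypsin", "P9:2"),
        db), db)
    run2 <- selectNTermini(sortMatches(
        makePsm("EKKEVVEEAENGRDAPAD", "invivo_ac", 61, "chymotrypsin",
                "P9:2"), db), db)
    merged <- mergeAcrossProteases(list(run1$final, run2$final))
    expect_equal(nrow(merged), 1L)
    expect_equal(merged$peptide, "EKKEVVEEAENGRDAPAD")
    expect_setequal(strsplit(merged$datasets, ",")[[1L]],
                    c("trypsin", "chymotrypsin"))
    expect_equal(merged$psm_count, 2L)

    ## different starts stay distinct records
    run3 <- selectNTermini(sortMatches(
        makePsm("KKEVVEEAENGRDAPAD", "invivo_ac", 50, "argc", "P9:3"),
        db), db)
    merged2 <- mergeAcrossProteases(list(run1$final, run3$final))
    expect_equal(nrow(merged2), 2L)

    ## merging a table with itself changes nothing
    self1 <- mergeAcrossProteases(list(run1$final))
    self2 <- mergeAcrossProteases(list(run1$final, run1$final))
    expect_identical(self1, self2)
})

test_that("funnel totals reconcile and the output is order-invariant", {
    db <- tinyDb()
    psms <- rbind(
        makePsm("MAVNVYSTSVTSDNLSR", "invivo_ac", 80, "trypsin",
                "P10001:1"),
        makePsm("AVNVYSTSVTSDNLSR", "invivo_ac", 70, "trypsin",
                paste0("P10001:2;", ntrId2, ":5")),
        makePsm("TTSEQPLK", "free", 30, "trypsin", "P10002:5"),
        makePsm("MKEETKEDAEEKQ", "heavy_ac", 55, "trypsin",
                paste0(ntrId1, ":1")),
        makePsm("QPLKVR", "pyroglu", 22, "trypsin", "P10002:9"))
    res <- selectNTermini(psms, db)
    n_removed <- if (is.null(res$removed)) 0L else nrow(res$removed)
    ## totality: every distinct peptide lands in exactly one bucket
    expect_equal(nrow(res$stages$distinct_peptides),
                 nrow(res$final) + n_removed + nrow(res$pyroglu))
    f <- res$funnel
    expect_true(all(diff(f$total[f$stage %in%
        c("start", "distinct_peptides", "nt_peptides", "after_ragged",
          "final")]) <= 0L))
    expect_true(all(f$ntr_matched <= f$total))

    ## shuffling the input rows leaves every output identical
    set.seed(9)
    res2 <- selectNTermini(psms[sample(nrow(psms)), ], db)
    expect_identical(res$final, res2$final)
    expect_identical(res$funnel, res2$funnel)

    ## a peptide counts as NTR only when its sorted main match is NTR
    sorted <- res$stages$start
    avn <- sorted[sorted$peptide == "AVNVYSTSVTSDNLSR", ]
    expect_equal(avn$main_category, "uniprot")
})

test_that("acetylation percentages stay within bounds", {
    set.seed(31)
    db <- mergeDatabases(data.frame(
        id = "P9", sequence = "MEKKEVVEEAENGRDAPADKKQKTDEWW"))
    for (rep in 1:20) {
        n_iv <- sample(0:4, 1L)
        n_hv <- sample(0:4, 1L)
        if (n_iv + n_hv == 0L) next
        mods <- c(rep("invivo_ac", n_iv), rep("heavy_ac", n_hv))
        psms <- sortMatches(makePsm(rep("EKKEVVEEAENGR", length(mods)),
                                    mods, seq_along(mods), "trypsin",
                                    "P9:2"), db)
        d <- deduplicatePsms(psms)
        expect_gte(d$acetylation_pct, 0)
        expect_lte(d$acetylation_pct, 100)
        expect_equal(d$acetylation_pct == 100, n_hv == 0L)
    }
})

test_that("dataset overlaps equal brute-force set intersections", {
    t1 <- data.frame(main_entry = c("A", "B", "C"),
                     main_start = c(1L, 1L, 2L))
    t2 <- data.frame(main_entry = c("B", "C", "D"),
                     main_start = c(1L, 2L, 1L))
    t3 <- data.frame(main_entry = c("C", "E"), main_start = c(2L, 1L))
    ov <- overlapSummary(list(x = t1, y = t2, z = t3))
    get <- function(keying, sets) {
        ov$count[ov$keying == keying & ov$sets == sets]
    }
    expect_equal(get("entry", "x"), 3L)
    expect_equal(get("entry", "x,y"), 2L)
    expect_equal(get("entry", "x,y,z"), 1L)
    expect_equal(get("entry_start", "x,y,z"),
                 length(Reduce(intersect, list(
                     c("A:1", "B:1", "C:2"), c("B:1", "C:2", "D:1"),
                     c("C:2", "E:1")))))
})
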