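test_that("exact matches report every occurrence, with I/L folding", {
    ref <- c(R1 = "MMFGHKLWW", R2 = "AAFGHKLCCFGHKLDD")
    hits <- exactMatchScan("FGHKL", ref)
    expect_equal(hits$subject_start[hits$subject_id == "R1"], 3L)
    expect_equal(hits$subject_start[hits$subject_id == "R2"], c(3L, 10L))
    ## isobaric leucine/isoleucine fold together
    hits_il <- exactMatchScan("FGHKI", ref)
    expect_equal(nrow(hits_il), 3L)
    expect_equal(nrow(exactMatchScan("FGHKI", ref, ilFold = FALSE)), 0L)
})

test_that("near-match scan finds minimal-mismatch ungapped alignments", {
    ref <- c(RPS2 = "KKADDAGAAGGPGGPGGPGMGNRGGFRGGFWW")
    hit <- nearMatchScan("ADDAGAAGGPGGPGGPEMGNRGGFRGGF", ref)
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$n_mismatches, 1L)
    expect_equal(hit$mismatch_positions, "17")
    expect_equal(hit$peptide_residues, "E")
    expect_equal(hit$subject_residues, "G")
    expect_equal(hit$subject_start, 3L)
    ## zero-mismatch windows delegate to exact behaviour
    hit0 <- nearMatchScan("GMGNRGGF", ref)
    expect_equal(hit0$n_mismatches, 0L)
})

test_that("near-match scan equals the brute-force Hamming comparator", {
    set.seed(77)
    for (rep in 1:15) {
        subjects <- stats::setNames(
            vapply(1:8, function(i) randomPeptide(sample(20:60, 1L)), ""),
            paste0("S", 1:8))
        ## half the time, plant a mutated copy of a window
        pep <- if (rep %% 2 == 0) {
            randomPeptide(sample(8:15, 1L))
        } else {
            src <- sample(subjects, 1L)
            off <- sample(nchar(src) - 12L, 1L)
            p <- substr(src, off, off + 11L)
            pos <- sample(12L, 1L)
            substr(p, pos, pos) <- sample(AA20, 1L)
            p
        }
        got <- nearMatchScan(pep, subjects, maxMismatches = 2L)
        want <- bruteHammingScan(pep, as.list(subjects), 2L)
        if (is.null(want)) {
            expect_equal(nrow(got), 0L)
        } else {
            expect_equal(
                got[order(got$subject_id, got$subject_start),
                    c("subject_id", "subject_start", "n_mismatches")],
                want[order(want$subject_id, want$subject_start), ],
                ignore_attr = TRUE)
        }
    }
})

test_that("SNP plausibility reflects single-base codon neighbourhoods", {
    ge <- snpPlausible("G", "E")
    expect_true(ge$plausible)
    w <- ge$witness_codon_pair
    expect_equal(sum(strsplit(w[1], "")[[1]] != strsplit(w[2], "")[[1]]),
                 1L)
    expect_equal(unname(Biostrings::GENETIC_CODE[w[1]]), "G")
    expect_equal(unname(Biostrings::GENETIC_CODE[w[2]]), "E")
    ## GGG -> GAG is itself a valid witness
    expect_equal(sum(strsplit("GGG", "")[[1]] != strsplit("GAG", "")[[1]]),
                 1L)
    nd <- snpPlausible("N", "D")
    expect_true(nd$plausible)
    expect_false(snpPlausible("M", "Y")$plausible)
})

test_that("SNP plausibility is symmetric and reflexive-true", {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    for (a in aas) {
        expect_true(snpPlausible(a, a)$plausible)
        for (b in sample(aas, 5L)) {
            expect_equal(snpPlausible(a, b)$plausible,
                         snpPlausible(b, a)$plausible)
        }
    }
})

test_that("theoretical b/y fragments obey mass bookkeeping", {
    fr <- theoreticalFragments("AG")
    expect_equal(nrow(fr), 2L)
    expect_equal(fr$mz[fr$ion == "b1"], 72.044, tolerance = 1e-4)
    expect_equal(fr$mz[fr$ion == "y1"], 76.039, tolerance = 1e-4)
    ## 2(n - 1) ions and b/y complementarity
    pep <- "MKVLAGWYD"
    fr2 <- theoreticalFragments(pep)
    n <- nchar(pep)
    expect_equal(nrow(fr2), 2L * (n - 1L))
    b <- fr2[fr2$series == "b", ]
    y <- fr2[fr2$series == "y", ]
    neutral <- peptideMass(pep)
    for (i in seq_len(n - 1L)) {
        expect_equal(b$mz[b$index == i] + y$mz[y$index == n - i],
                     neutral + 2 * 1.007276466812, tolerance = 1e-9)
    }
})

test_that("rank concordance scores identity, reversal and permutations", {
    pep <- "MKVLAGWYDE"
    pair <- generateSpectrumPair(pep, concordant = TRUE, seed = 5)
    ## identical lists are perfectly concordant
    same <- rankConcordance(pair$reference, pair$reference, pep)
    expect_equal(same$score, 1)
    expect_equal(same$verdict, "matching")
    ## exactly reversed intensity ranks anti-correlate
    rev_q <- pair$reference
    rev_q$intensity <- max(rev_q$intensity) + min(rev_q$intensity) -
        rev_q$intensity
    rev_res <- rankConcordance(pair$reference, rev_q, pep)
    expect_equal(rev_res$score, -1)
    expect_equal(rev_res$verdict, "not_matching")
    ## invariant to uniform intensity scaling
    scaled <- pair$query
    scaled$intensity <- scaled$intensity * 1e3
    expect_equal(rankConcordance(pair$reference, scaled, pep)$score,
                 rankConcordance(pair$reference, pair$query, pep)$score)
    ## too few common fragments is flagged, not scored
    tiny <- pair$reference[1:2, ]
    expect_equal(rankConcordance(pair$reference, tiny, pep)$verdict,
                 "insufficient")
})

test_that("random rank permutations score near zero on average", {
    pep <- "MKVLAGWYDEKR"
    scores <- vapply(1:200, function(i) {
        pair <- generateSpectrumPair(pep, concordant = FALSE, seed = i)
        rankConcordance(pair$reference, pair$query, pep)$score
    }, numeric(1L))
    expect_lt(abs(mean(scores)), 0.15)
})

test_that("genome mapping converts protein to spliced 0-based blocks", {
    ## single exon, plus strand: protein 1-3 covers 9 nt from the TIS
    tm <- transcriptModel("t1", "chr1", "+", 1001L, 1100L, 1001L)
    b <- mapPeptideToGenome(1L, 3L, tm)
    expect_equal(nrow(b), 1L)
    expect_equal(c(b$chromStart, b$chromEnd), c(1000L, 1009L))
    ## exon boundary 4 nt after the TIS splits the codons 4 + 5
    tm2 <- transcriptModel("t2", "chr1", "+", c(1001L, 2001L),
                           c(1004L, 2100L), 1001L)
    b2 <- mapPeptideToGenome(1L, 3L, tm2)
    expect_equal(b2$chromEnd - b2$chromStart, c(4L, 5L))
    ## running past the transcript end is an error
    expect_error(mapPeptideToGenome(1L, 40L, tm2), "out of transcript")
    ## minus strand: blocks still ascend and lengths sum to 3 x peptide
    tm3 <- transcriptModel("t3", "chr1", "-", c(501L, 601L),
                           c(560L, 650L), 650L)
    b3 <- mapPeptideToGenome(2L, 11L, tm3)
    expect_equal(sum(b3$chromEnd - b3$chromStart), 30L)
    expect_true(!is.unsorted(b3$chromStart))
})

test_that("translating mapped blocks recovers the peptide (round trip)", {
    set.seed(88)
    for (rep in 1:60) {
        strand <- sample(c("+", "-"), 1L)
        protein <- randomPeptide(sample(12:30, 1L))
        locus <- generateToyLocus(protein, strand = strand,
                                  nExons = sample(1:4, 1L),
                                  seed = sample.int(1e6, 1L))
        s <- sample(nchar(protein) - 4L, 1L)
        e <- min(nchar(protein), s + sample(3:8, 1L))
        blocks <- mapPeptideToGenome(s, e, locus$model)
        expect_equal(sum(blocks$chromEnd - blocks$chromStart),
                     3L * (e - s + 1L))
        got <- translateBlockSet(blocks, locus$genome)
        expect_equal(got$peptide, substr(protein, s, e))
    }
})

test_that("BED12 output and GTF transcript models round-trip", {
    skip_if_not_installed("rtracklayer")
    tm <- transcriptModel("tx1", "chr2", "+", c(101L, 301L),
                          c(150L, 400L), 121L)
    b <- mapPeptideToGenome(1L, 12L, tm, peptide_id = "pep1")
    bed <- withr::local_tempfile(fileext = ".bed")
    writeBed12(b, bed)
    fields <- strsplit(readLines(bed), "\t")[[1L]]
    expect_equal(fields[1L], "chr2")
    expect_equal(as.integer(fields[10L]), nrow(b))
    sizes <- as.integer(strsplit(fields[11L], ",")[[1L]])
    expect_equal(sum(sizes), 36L)

    gtf <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
        paste("chr2", "test", "exon", 101, 150, ".", "+", ".",
              "transcript_id \"tx1\";", sep = "\t"),
        paste("chr2", "test", "exon", 301, 400, ".", "+", ".",
              "transcript_id \"tx1\";", sep = "\t"),
        paste("chr2", "test", "start_codon", 121, 123, ".", "+", ".",
              "transcript_id \"tx1\";", sep = "\t")), gtf)
    models <- readTranscriptModels(gtf)
    expect_equal(names(models), "tx1")
    expect_equal(models$tx1@tisGenomicPos, 121L)
    b2 <- mapPeptideToGenome(1L, 12L, models$tx1, peptide_id = "pep1")
    expect_equal(b2$chromStart, b$chromStart)
    expect_equal(b2$chromEnd, b$chromEnd)
})

test_that("the curation report flags exact hits and SNP-plausible variants", {
    ref <- c(P1 = "KKADDAGAAGGPGGPGGPGMGNRGGFRGGFWW",
             P2 = "MMFGHKLWW")
    rep <- curationReport(c("FGHKL", "ADDAGAAGGPGGPGGPEMGNRGGFRGGF"), ref)
    expect_equal(rep$exact_hit[1L], "P2")
    expect_equal(rep$best_near_hit[2L], "P1")
    expect_equal(rep$n_mismatches[2L], 1L)
    expect_true(rep$snp_plausible_all[2L])    # E vs G: GAG vs GGG
})
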