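test_that("zero-missed-cleavage digestion partitions the sequence", {
    d <- digestSequence("MKAARAGRPK", proteaseRule("argc"), 0L)
    expect_equal(d$sequence, c("MKAAR", "AGR", "PK"))
    expect_equal(d$start, c(1L, 6L, 9L))
    expect_equal(d$end, c(5L, 8L, 10L))
    expect_equal(paste(d$sequence, collapse = ""), "MKAARAGRPK")

    ## GluC cleaves after D/E including before proline
    d2 <- digestSequence("AEDPG", proteaseRule("gluc"), 0L)
    expect_equal(d2$sequence, c("AE", "D", "PG"))
})

test_that("missed cleavages concatenate consecutive fragments", {
    d <- digestSequence("MKAARAGRPK", proteaseRule("argc"), 1L)
    expect_true(all(c("MKAARAGR", "AGRPK") %in% d$sequence))
    one <- d[d$sequence == "MKAARAGR", ]
    expect_equal(c(one$start, one$end, one$missed_cleavages), c(1L, 8L, 1L))
})

test_that("digestion equals the brute-force oracle on random sequences", {
    set.seed(402)
    rules <- list(argc = proteaseRule("argc"),
                  chymo = proteaseRule("chymotrypsin"),
                  gluc = proteaseRule("gluc"))
    for (rep in 1:40) {
        s <- randomPeptide(sample(5:60, 1L))
        for (nm in names(rules)) {
            mc <- sample(0:4, 1L)
            got <- digestSequence(s, rules[[nm]], mc)
            want <- bruteDigest(s, rules[[nm]]@cleaveAfter, mc)
            expect_equal(got, want, ignore_attr = TRUE)
            ## reconstruction: 0-MC peptides reproduce the input
            zero <- got[got$missed_cleavages == 0L, ]
            expect_equal(paste(zero$sequence, collapse = ""), s)
        }
    }
})

test_that("peptide masses match independent monoisotopic arithmetic", {
    expect_equal(peptideMass("G"), 75.03203, tolerance = 1e-6)
    expect_equal(peptideMass("GG") - peptideMass("G"), 57.02146,
                 tolerance = 1e-6)
    ## additivity of modification deltas
    expect_equal(peptideMass("MKV", modifications = data.frame(
        position = 1L, delta = 42.010565)) - peptideMass("MKV"),
        42.010565)
    ## selenocysteine is in the mass table
    expect_gt(peptideMass("U"), peptideMass("C"))
    expect_error(peptideMass("GBZ"), "unknown residue")
})

test_that("charge at acidic pH follows the closed form", {
    ## blocked amines, no ionizable side chains: only the C-terminus
    expect_lt(abs(chargeAtPh("GG", ph = 2, blockedAmines = TRUE)), 0.1)
    ## free alpha-amine plus one arginine at pH 2 is close to +2
    q <- chargeAtPh("AAAAAAR", ph = 2)
    expect_gt(q, 1.9); expect_lt(q, 2.1)
    ## monotone non-increasing in pH
    phs <- seq(0, 14, by = 0.5)
    qs <- vapply(phs, function(p) chargeAtPh("MRKDHECY", ph = p),
                 numeric(1L))
    expect_true(all(diff(qs) <= 1e-9))
})

test_that("detectability applies length, charge and m/z criteria", {
    res <- msDetectable(c("AAAAAA", "AAAAAAR", "RARARARR"))
    expect_false(res$detectable[1L])
    expect_equal(res$reason[1L], "length")
    expect_true(res$detectable[2L])
    expect_equal(res$z[2L], 2)
    expect_equal(res$mz[2L], 301.2, tolerance = 1e-3)
    ## five arginines and a free N-terminus exceed the +4 bound
    pep5r <- "ARARARARAR"
    res5 <- msDetectable(pep5r)
    expect_false(res5$detectable)
    expect_equal(res5$reason, "charge")
})

test_that("relaxing any criterion never decreases the detectable count", {
    set.seed(71)
    peps <- vapply(1:80, function(i) randomPeptide(sample(4:40, 1L)), "")
    base <- detectabilityCriteria()
    n0 <- sum(msDetectable(peps, base)$detectable)
    relaxed <- list(
        detectabilityCriteria(minLengthExclusive = 4L),
        detectabilityCriteria(maxCharge = 6L),
        detectabilityCriteria(maxMz = 2500)
    )
    for (cr in relaxed) {
        expect_gte(sum(msDetectable(peps, cr)$detectable), n0)
    }
})

test_that("Nt-candidates include iMet-processed forms only when allowed", {
    cand <- generateNtCandidates("MAKRTTR", proteaseRule("argc"))
    expect_true(all(cand$start %in% c(1L, 2L)))
    expect_true("MAKR" %in% cand$sequence[cand$start == 1L])
    expect_true("AKR" %in% cand$sequence[cand$start == 2L])
    akr <- cand[cand$sequence == "AKR", ]
    expect_equal(akr$end, 4L)

    ## D is not a removable follower under the detectability set
    cand2 <- generateNtCandidates("MDKRTTR", proteaseRule("argc"))
    expect_true(all(cand2$start == 1L))

    ## no iMet, no position-2 forms
    cand3 <- generateNtCandidates("AKRTTR", proteaseRule("argc"))
    expect_true(all(cand3$start == 1L))
})

test_that("I/L folding drives uniqueness counting", {
    expect_equal(foldIL("SAMPLE"), "SAMPLE")
    expect_equal(foldIL(foldIL("ILLIA")), foldIL("ILLIA"))
    expect_equal(nchar(foldIL("ILLIA")), 5L)

    proteome <- c(A = "WWSAMPLEWW", B = "KKSAMPIEKK", C = "MKVLAG")
    u <- peptideUniqueness("SAMPLE", proteome)
    expect_equal(unname(u), 2L)           # I = L, so both entries match
    expect_equal(unname(peptideUniqueness("NOTTHERE", proteome)), 0L)
})

test_that("adding proteome entries never increases uniqueness", {
    set.seed(15)
    proteome <- vapply(1:10, function(i) randomPeptide(30L), "")
    names(proteome) <- paste0("E", 1:10)
    peps <- substr(proteome[1:5], 3, 12)
    before <- peptideUniqueness(peps, proteome)
    extended <- c(proteome, X1 = paste0("AA", proteome[[1]]))
    after <- peptideUniqueness(peps, extended)
    expect_true(all(after >= before))
})

test_that("detectability summary aggregates per-entry booleans", {
    db <- tinyDb()
    s <- detectabilitySummary(db, proteaseRule("argc"), mode = "shotgun")
    expect_equal(nrow(s$per_entry), length(db))
    ## aggregate percentages are means of the per-entry booleans
    for (i in seq_len(nrow(s$aggregate))) {
        g <- s$per_entry[s$per_entry$category == s$aggregate$category[i], ]
        expect_equal(s$aggregate$pct_detectable[i],
                     100 * mean(g$has_detectable))
        expect_equal(s$aggregate$pct_unique[i], 100 * mean(g$has_unique))
    }
    ## nterm mode only considers candidate Nt-peptides: at most
    ## (maxMC + 1) position-1 forms plus as many iMet-processed forms
    sn <- detectabilitySummary(db, proteaseRule("argc"), mode = "nterm")
    expect_true(all(sn$per_entry$n_peptides <= 6L))
})
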