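## Shared fixtures and independent brute-force oracles.

AA20 <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], character(0))

randomPeptide <- function(len) {
    paste(sample(AA20, len, replace = TRUE), collapse = "")
}

## A tiny merged database used across selection tests.
tinyDb <- function() {
    mergeDatabases(data.frame(
        id = c("P10001", "P10002",
               "ENST00000000001_1_1000_ntr_100db1",
               "ENST00000000002_2_2000_ntr_010db1"),
        sequence = c(
            "MAVNVYSTSVTSDNLSRHDMLAWINESLQLNLTK",   # annotated, Nt after iMet
            "MDKRTTSEQPLKVRKEWFPLY",                # annotated
            "MKEETKEDAEEKQ",                        # NTR microprotein
            "MGLSDGEWQLVLNVWGKVEADIPGHGQEVLIR"),    # NTR
        stringsAsFactors = FALSE))
}

makePsm <- function(peptide, nt_mod, score, protease, matches,
                    sample_id = "B1") {
    data.frame(peptide = peptide, nt_mod = nt_mod, score = score,
               protease = protease, sample_id = sample_id,
               matches = matches, stringsAsFactors = FALSE)
}

## Brute-force digestion oracle: enumerate all substrings bounded by
## cleavage sites with at most mc internal cleavage sites.  Written
## independently of digestSequence().
bruteDigest <- function(sequence, cleave_after, mc,
                        suppress_before_p = FALSE) {
    r <- strsplit(sequence, "")[[1L]]
    n <- length(r)
    is_cut <- logical(n)
    for (i in seq_len(n - 1L)) {
        if (r[i] %in% cleave_after &&
            !(suppress_before_p && r[i + 1L] == "P")) {
            is_cut[i] <- TRUE
        }
    }
    bounds <- c(0L, which(is_cut), n)     # peptide bounds (after position)
    out <- list()
    for (a in seq_len(length(bounds) - 1L)) {
        for (b in (a + 1L):length(bounds)) {
            internal <- b - a - 1L
            if (internal > mc) next
            out[[length(out) + 1L]] <- data.frame(
                sequence = substr(sequence, bounds[a] + 1L, bounds[b]),
                start = bounds[a] + 1L, end = bounds[b],
                missed_cleavages = internal)
        }
    }
    res <- do.call(rbind, out)
    res <- res[order(res$start, res$end), , drop = FALSE]
    rownames(res) <- NULL
    res
}

## Brute-force all-window Hamming comparator (I/L folded).
bruteHammingScan <- function(peptide, subjects, max_mm) {
    fold <- function(x) chartr("I", "L", x)
    p <- strsplit(fold(peptide), "")[[1L]]
    n <- length(p)
    rows <- list()
    for (id in names(subjects)) {
        s <- strsplit(fold(subjects[[id]]), "")[[1L]]
        if (length(s) < n) next
        for (off in 0:(length(s) - n)) {
            mm <- sum(p != s[(off + 1L):(off + n)])
            if (mm <= max_mm) {
                rows[[length(rows) + 1L]] <- data.frame(
                    subject_id = id, subject_start = off + 1L,
                    n_mismatches = mm, stringsAsFactors = FALSE)
            }
        }
    }
    res <- do.call(rbind, rows)
    if (is.null(res)) return(res)
    best <- min(res$n_mismatches)
    res <- res[res$n_mismatches == best, , drop = FALSE]
    rownames(res) <- NULL
    res
}

## Check every planted truth record against the per-protease pipeline
## results; returns the per-record agreement as a logical vector.
checkRecovery <- function(run) {
    truth <- run$truth
    ok <- logical(nrow(truth))
    for (i in seq_len(nrow(truth))) {
        row <- truth[i, ]
        pp <- run$per_protease[[row$protease]]
        ok[i] <- switch(row$expected_bucket,
            final = {
                hit <- pp$final[pp$final$peptide == row$peptide, ]
                nrow(hit) == 1L &&
                    hit$category == row$expected_category &&
                    hit$confidence == row$expected_confidence
            },
            removed = {
                hit <- pp$removed[pp$removed$peptide == row$peptide, ]
                nrow(hit) == 1L && hit$reason == row$expected_reason
            },
            pyroglu = row$peptide %in% pp$pyroglu$peptide,
            collapsed = {
                sv <- unlist(strsplit(pp$final$shorter_variants, ","))
                row$peptide %in% sv && !row$peptide %in% pp$final$peptide
            },
            FALSE)
    }
    ok
}

## The 19 published NTR Nt-peptide records: sequence, start position on the
## matched entry, protease, N-terminal modification, preceding residue,
## entry length and the reported confidence.  Entries are reconstructed as
## synthetic stand-ins: the true residues outside the peptide are unknown,
## so padding residues are used (they never affect the classification
## inputs: start, modification, preceding residue, first residue).
ntrPeptideTable <- function() {
    t4 <- read.delim(text = paste(
        "accession\tstart\tsequence\tprotease\tmod\tprec\tlen\tconf",
        "ENST00000543961_12_25803373_ntr_100db1\t1\tMAEAPNMAVVNEQQMPEEVPAPAPAQEPVQEAPKGR\tchymotrypsin\theavy_ac\t\t82\thigh",
        "ENST00000439303_10_10174230_ntr_100db1\t1\tMDGEEKTCGGCEGPDAMYVKLISSDGHEFIVKR\ttrypsin\theavy_ac\t\t115\thigh",
        "ENST00000486575_22_20127011_ntr_100db1\t1\tMKEETKEDAEEKQ\ttrypsin\theavy_ac\t\t13\thigh",
        "ENST00000458332_17_19446852_ntr_111db1\t2\tADDAGAAGGPGGPGGPEMGNRGGFRGGF\tgluc\tinvivo_ac\tM\t88\thigh",
        "ENST00000454707_6_5972475_ntr_100db1\t2\tADTFLEHM\ttrypsin\tinvivo_ac\tM\t157\thigh",
        "ENST00000216019_22_38506168_ntr_100db1\t2\tASATGDSASERESAAPAAAPTAEAPPPSVVTRPEPQ\tchymotrypsin\tinvivo_ac\tM\t463\thigh",
        "ENST00000556323_14_92026617_ntr_100db1\t2\tEKKEVVEEAENGRDAPAD\tchymotrypsin\theavy_ac\tM\t56\thigh",
        "ENST00000498385_22_23894847_ntr_001db3\t2\tHSIGKIGGAQNRSYS\tgluc\theavy_ac\tM\t54\thigh",
        "ENST00000415278_1_96448241_ntr_001db3\t2\tKAVDKKAAGAGK\tgluc\theavy_ac\tM\t25\thigh",
        "ENST00000586518_17_75779096_ntr_010db2\t2\tKSAPSTGGVKKPH\tchymotrypsin\theavy_ac\tM\t17\thigh",
        "ENST00000478033_1_159918889_ntr_100db1\t2\tNVIGLQMGTNRGASQAGMTGYG\tgluc\tinvivo_ac\tM\t29\thigh",
        "ENST00000569492_16_35803171_ntr_100db1\t2\tRKAEGDAKGDKAKVKDEPQR\tchymotrypsin\theavy_ac\tM\t81\thigh",
        "ENST00000555320_14_80822530_ntr_010db2\t2\tRKAEGDAKGDKAKVKD\tchymotrypsin\theavy_ac\tM\t88\thigh",
        "ENST00000556323_14_92026566_ntr_100db1\t2\tSDAAVDTSSEITTKDLKEKKEVVEEAENGRDAPAD\tchymotrypsin\tinvivo_ac\tM\t73\thigh",
        "ENST00000582213_17_7572835_ntr_100db1\t9\tFPSNWNEIVDSFDDMNLSESLLR\ttrypsin\tinvivo_ac\tG\t148\tlow",
        "ENST00000403258_6_88276364_ntr_101db1\t12\tMASAASSSSLE\tgluc\tinvivo_ac\tE\t146\thigh",
        "ENST00000402643_6_166064725_ntr_111db1\t64\tASTGTAKAVGKVIPELNGKL\tchymotrypsin\tinvivo_ac\tP\t125\tlow",
        "ENST00000530835_11_90283408_ntr_011db2\t70\tGDVVPKDANAAIATIKTKR\ttrypsin\tinvivo_ac\tH\t124\tlow",
        "ENST00000530835_11_90283409_ntr_011db2\t74\tPKDANAAIATIKTKR\ttrypsin\tinvivo_ac\tF\t124\tlow",
        sep = "\n"), stringsAsFactors = FALSE)
    t4$prec[is.na(t4$prec)] <- ""
    t4
}

## Build a stand-in database entry holding a peptide at a given start with
## a given preceding residue and total length (padding residue G).
standInEntry <- function(peptide, start, prec, len) {
    pre <- if (start == 1L) "" else {
        paste0(strrep("G", start - 2L), prec)
    }
    post_len <- len - (start + nchar(peptide) - 1L)
    paste0(pre, peptide, strrep("G", max(0L, post_len)))
}
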