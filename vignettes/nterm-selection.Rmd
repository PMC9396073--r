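---
title: "Selecting N-terminal peptides as translational evidence: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting N-terminal peptides as translational evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NTermFinder)
```

## The problem

Ribosome profiling predicts thousands of proteoforms translated from
regions annotated as noncoding — pseudogenes, retained introns, lncRNAs
(collectively "NTRs" here). Mass-spectrometry evidence for these proteins
is scarce and error-prone: NTR proteoforms are short (median around 40
residues versus around 414 for annotated proteins) and are often
near-identical copies of an annotated parent gene, so a peptide that seems
to support an NTR usually also matches — or almost matches — a canonical
protein. `NTermFinder` implements a deliberately stringent workflow that
asks a narrower question than shotgun proteomics: does a peptide mark a
protein *N terminus* created by translation initiation?

The N terminus carries translational signals that internal peptides lack:
cotranslational N-terminal acetylation (80–90 % of cytosolic proteins),
initiator-methionine (iMet) excision restricted by methionine
aminopeptidase (MetAP) specificity (second residue in A, C, G, P, S, T,
V), and, independently, initiation sites called from initiating-ribosome
footprints (Ribo-Seq TIS). N-terminomics by COFRADIC enriches exactly
these peptides: free amines are blocked in vitro with an isotope-coded
heavy acetyl group before digestion, so after enrichment a peptide's
N-terminal modification state distinguishes in vivo acetylated termini,
termini free in the cell (heavy acetyl), internal peptides (free
alpha-amine) and coenriched pyroglutamate artifacts.

## The custom database and its conventions

MS/MS spectra are searched against a merged database of UniProt canonical
and isoform sequences plus Ribo-Seq-derived proteoforms whose accessions
encode transcript, chromosome, TIS genomic position, TIS annotation
(aTIS/CDS/5UTR/3UTR/ntr) and a three-flag "bincode" naming the supporting
Ribo-Seq datasets (`parseCustomAccession()`). Redundant sequences collapse
to one entry whose main identifier follows a fixed category priority
(`mergeDatabases()`); the identifiers displaced into the description line
are retained and indexed.

Two different category orders are in use and both are kept
(`categoryRank()`): database construction prefers `ntr` over `utr3`, while
peptide-to-entry match sorting prefers `utr3` over `ntr`. We did not
reconcile them — each is used where its convention applies. Merging uses
exact string equality; I/L equivalence applies only to peptide-level
matching, never to database merging.

## Detectability model

In-silico digestion (`digestSequence()`) supports ArgC (cleave after R —
trypsin acts as ArgC when lysines are acetylated), chymotrypsin (F/L/M/W/Y)
and GluC (D/E, including before proline), with missed-cleavage defaults of
2, 2 and 4. A peptide is considered MS-detectable when it is longer than
six residues, its charge at pH 2 is at most +4 and its m/z at that charge
is at most 1500 Th (`msDetectable()`).

The charge model is a Henderson–Hasselbalch summation over nine ionizable
groups. Because the literature offers several pKa scales, the scale is
configuration, not code (`pkaSet()`): the default is the EMBOSS set
(C-terminus 3.6, N-terminus 8.6), chosen because it reproduces the
behaviour the workflow relies on — an amine-blocked peptide is essentially
neutral at pH 2 (|q| < 0.1), and a free N-terminus plus one arginine give
roughly +2. The classical Lehninger free-amino-acid constants (C-terminus
2.34) would leave a residual −0.3 charge on blocked peptides at pH 2,
which is inconsistent with that working assumption; the Lehninger and
Bjellqvist sets remain selectable. The fractional charge is integerized
for the m/z test by rounding half away from zero and flooring at +1; the
+4 bound is treated as inclusive. Both choices are exposed as options
(`chargeRounding`, `detectabilityCriteria()`).

Candidate N-terminal peptides are the digestion peptides starting at
position 1, plus — when the protein starts with Met followed by a
removable residue — the position-2 peptides of the iMet-clipped sequence
(`generateNtCandidates()`). Two follower sets are kept deliberately:
{A,S,G,P,T,V} for detectability-style candidate generation and the full
MetAP set {A,C,G,P,S,T,V} for classifying observed termini, matching how
each is used. Uniqueness counts distinct parent entries containing the
peptide with I and L folded together (`peptideUniqueness()`); position-2
candidates are generated identically for near-cognate starts decoded to
Met.

## The selection pipeline

Per protease, `selectNTermini()` chains five stages:

1. **Accession sorting** (`sortMatches()`): one peptide often matches many
   entries; matches are stably ordered by category priority, then lowest
   start position, then lexicographic identifier, and the first match
   becomes the peptide's main entry. No match is discarded.
2. **Deduplication** (`deduplicatePsms()`): PSMs group by exact sequence;
   in vivo acetyl outranks heavy acetyl outranks free; the representative
   is the highest-scoring PSM of the best modification. The acetylation
   percentage is `100 * n(in vivo) / (n(in vivo) + n(heavy))` over PSM
   counts, rounded to the nearest integer (half away from zero); free PSMs
   are excluded from the denominator, which is what makes the workflow's
   worked ratio of 5 in vivo to 2 heavy PSMs come out at 71 %.
3. **Terminal-class filtering** (`filterTerminalClasses()`): free-only
   peptides are internal; peptides ending at their main entry's C terminus
   with start beyond 2 are C-terminal; a start-1/2 peptide spanning the
   whole sequence is kept as a full-coverage microprotein.
   Pyroglutamate-only peptides go to a side table: they are counted in
   enrichment efficiency but are never classified as N termini.
4. **Ragged collapsing** (`collapseRagged()`): peptides sharing (entry,
   start) but C-terminally truncated collapse to the best-modified, then
   longest member; shorter variants and pooled PSM counts are kept so the
   acetylation percentage stays PSM-count based after merging.
5. **Classification** (`classifyNtPeptides()`), first match wins:
   start at 1 or 2 of *any* matched entry is a database-annotated,
   high-confidence terminus — deliberately without requiring MetAP-rule
   compliance, since observed position-2 termini include non-canonical
   excisions; a Ribo-Seq TIS at the matched (entry, start) makes a
   high-confidence alternative terminus (exact coordinate match — the
   supplied TIS table can be pre-expanded when a tolerance is wanted);
   in vivo acetylation plus iMet evidence
   (starts with Met, or preceded by Met with a removable first residue)
   is alternative/high; in vivo acetylation without Met evidence and not
   preceded by a cleavage site of the protease used is alternative/low, as
   is heavy acetylation with Met evidence away from a cleavage site;
   everything else is removed with a reason code.

Datasets merge on (main entry, start), keeping the longest peptide, the
union of datasets and the best confidence, and recomputing acetylation
over all contributing PSM counts (`mergeAcrossProteases()`). Funnel
accounting (`computeFunnel()`) records totals and NTR-matched counts at
every stage; every input PSM ends in exactly one of final table, removal
log or pyroglutamate side table.

Ties between matched entries sharing both category and start fall back to
the lexicographically smallest identifier, making the whole pipeline
invariant to input row order. A single in vivo PSM suffices for
"partially cotranslationally acetylated" status.

## Curation of surviving NTR candidates

Short peptides against a curated reference need no heuristic alignment:
`exactMatchScan()` and `nearMatchScan()` perform exhaustive ungapped
scanning with I/L folding and report all minimal-mismatch hits with their
mismatch positions — for 8–36-residue peptides this is equivalent to or
stricter than a short-sequence protein BLAST, and no gapped alignment or
E-value is needed (every curated alignment in this workflow is ungapped).
`snpPlausible()` asks whether a residue difference could arise from a
single nucleotide change: some codon of one residue within Hamming
distance 1 of some codon of the other. Identical residues are trivially
plausible (a shared codon, distance 0); note Met and Trp have single
codons, so a strict distance-1 witness cannot exist for them. A
transcript-aware check against actual codons can replace the generic test
when nucleotide sequences are available; database lookups of known SNPs
are out of scope, and a free-text annotation slot carries external
evidence.

Spectrum comparison mirrors the manual synthetic-peptide check: the ten
most intense annotated b/y fragments of the reference spectrum are ranked,
the same fragments are located in the query within a 0.5 Th tolerance, and
the Spearman correlation of the intensity ranks is the concordance score
(`rankConcordance()`; missing fragments get rank 11, fewer than three
common fragments is "insufficient"). The "matching" threshold of 0.6 is
this package's own quantification of an otherwise qualitative judgement
and is configurable.

`mapPeptideToGenome()` projects protein positions [start, end] to the
spliced nucleotide interval [3(start−1)+1, 3·end] counted from the TIS
along the exons and emits 0-based half-open genomic blocks (BED
convention; BED12 writer included). Partial codons are never emitted; on
the minus strand the first codon has the highest genomic coordinate.

## What the synthetic data emulate — and what they do not

`generateProteome()` / `generatePsmTable()` build the study conditions the
pipeline is validated under: log-normal protein lengths with medians 414
(annotated) and 40 (NTR) — the only length features the study constrains —
pseudogene-like NTR entries cloned from an annotated parent with 0–2
substitutions, cotranslational acetylation probability 0.85 (the middle of
the cited 80–90 % range), MetAP-compliant iMet removal, and planted
internal, C-terminal, ragged, pyroglutamate and semi-specific
contaminants. Matches attached to each synthetic PSM come from an honest
substring scan of the generated database, so clones genuinely produce
multi-matched peptides; expected labels are computed at generation time by
a compact standalone evaluation of the documented rules, separate from the
pipeline code path. Scores (uniform on [30, 120]) and fraction labels are
invented plumbing. Amino-acid composition is uniform over the 20 standard
residues.

The defaults plant roughly 110 labelled distinct peptides per protease
(over 500 PSMs across the three proteases), a scale at which the whole
validation runs in seconds on one CPU while exercising every rule; the
generator is deterministic given its seed.

What passing on these data shows: the selection logic implements its rules
exactly and recovers every planted label on noise-free input. What it does
not show: robustness to search-engine error (false PSMs, wrong
modification calls), score-dependent FDR behaviour, real spectral noise,
non-uniform sequence composition, or the true abundance distribution of
NTR proteins — none of which the generator models. The published absolute
dataset counts (thousands of N termini from three proteases) require the
original raw data and search results and are not reproducible here; the
package instead reproduces the workflow's printed worked examples exactly
and validates the machinery property-by-property (digestion against a
brute-force enumerator, homology scanning against an all-window
comparator, genome mapping by translate-back round trips on 1000 random
transcript models on both strands).

## Numerical and degenerate-input choices

- All percentage rounding is half away from zero (R's `round()` is
  banker's rounding and would turn 0.575 into 0.57 or 0.58 depending on
  binary representation).
- Empty databases, empty PSM tables and singleton ragged groups pass
  through unchanged; a peptide that does not occur at its stated position
  in its main entry is a hard consistency error, not a removal.
- Stop characters (`*`) in FASTA input are stripped with a warning; any
  other non-residue character is an error naming the offenders.
  Selenocysteine (U) is a valid residue with its own monoisotopic mass.
- The trailing `dbN` token of custom accessions is stored verbatim and
  never interpreted.

## A small worked example

```{r example}
db <- mergeDatabases(data.frame(
    id = c("P10001", "ENST00000000001_1_1000_ntr_100db1"),
    sequence = c("MAVNVYSTSVTSDNLSRHDMLAWINESLQLNLTK", "MKEETKEDAEEKQ")))
psms <- data.frame(
    peptide = c("AVNVYSTSVTSDNLSR", "MKEETKEDAEEKQ"),
    nt_mod = c("invivo_ac", "heavy_ac"),
    score = c(80, 55), protease = "trypsin", sample_id = "B1",
    matches = c("P10001:2", "ENST00000000001_1_1000_ntr_100db1:1"))
res <- selectNTermini(psms, db)
res$final[, c("peptide", "main_entry", "category", "confidence")]
```

Both peptides are database-annotated, high-confidence N termini: the
first sits at position 2 after a canonically removable iMet of an
annotated protein, the second covers a complete NTR microprotein from
position 1.

## Limitations

The pipeline classifies; it does not re-score identifications, estimate
FDR, or integrate quantification. Ribo-Seq evidence enters only as a set
of (entry, position) initiation sites — read-level processing is upstream
of this package. The BLAST surrogate does not model gapped homology (by
design) and the SNP test is necessary, not sufficient, evidence for a
variant explanation.
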