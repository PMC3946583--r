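---
title: "Methods: transcriptome-based TE discovery, expression profiling and copy-number estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome-based TE discovery, expression profiling and copy-number estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`tescan` implements a transcriptome-first strategy for studying
transposable elements (TEs) in a crop without a reference genome.
Instead of annotating a genome assembly, it screens an assembled
transcript set for TE-derived transcripts — the transcriptionally
*active* fraction of the mobilome — classifies them under the
Wicker-style class/order/superfamily taxonomy, quantifies their
expression across libraries and tissues, and estimates genomic copy
number of selected transposase genes by real-time-PCR absolute
quantification. A seeded synthetic-data generator produces every input
with known ground truth, so each stage is verifiable at desk scale.

Out of scope by design: de novo assembly itself, GO annotation,
phylogenetics, genome-scale repeat masking, LTR/TSD structural
annotation, and edgeR-style dispersion modelling.

# Discovery

Three screening routes run independently and their results are merged:

1. **Keyword screening** of per-transcript functional annotations. The
   default vocabulary holds fifteen terms: generic transposon
   terminology (transposon, retrotransposon, transposase, reverse
   transcriptase, transposable element, retroelement) and
   order/superfamily names (hAT, En/spm, Mutator, MULE, Non-LTR, PIF,
   Copia, Gypsy, Mariner). Matching is case-insensitive substring
   matching; *hAT* alone requires word boundaries, because otherwise
   every description containing "that" or "phosphatase" would match.
   All matching keywords are reported, and superfamily-specific
   keywords carry a classification hint.

2. **Homology screening** against a labelled reference TE library.
   Candidate query/reference pairs are selected by exact shared words
   of length 12 on both strands, requiring at least two distinct
   shared words (the classic two-hit heuristic); candidates are then
   aligned with an optimal affine-gap local (Smith–Waterman)
   alignment. Scoring is match +2 / mismatch −3, gap open 5 / extend 2.
   The break-even identity of this system is 60%, so alignments can
   extend through the 60–100% identity range that cross-species TE
   homology occupies; a +1/−3 system (break-even 75%) would be unable
   to report the 70%-identity hits this screen is specified to accept.
   Significance uses the Karlin–Altschul E-value
   `E = K * m * n * exp(-lambda * S)` with the database-size
   correction (`n` = total reference length). `lambda` is solved
   numerically from the score system at uniform base composition;
   `K = 0.41` is the standard constant for this scoring regime. A hit
   requires `E <= 1e-10` *and* percent identity (matches over aligned
   columns, N columns excluded) at or above 70%. Both thresholds are
   exposed.

3. **Sub-terminal motif screening.** Each conserved sub-terminal motif
   (8–60 bp) is aligned glocally — motif global, window local — inside
   the first and last 250 bp of every transcript, on both strands; a
   hit requires at least 70% identity over the aligned columns. The
   250 bp window reflects where sub-terminal family signatures sit in
   full-length elements while tolerating ragged transcript ends.

**Redundancy removal** is greedy longest-first clustering: sequences
are visited in deterministic order (length descending, then id
ascending) and join the first representative with global identity at
or above 0.95 on either strand; representatives inherit the union of
the members' route evidence. 95% mirrors common transcript-clustering
practice (CD-HIT-EST's default neighbourhood) and the observed
assembly-versus-clone similarity of this kind of data.

**Virus exclusion.** Candidates whose annotation matches a
retrovirus-like term (virus, viral, retrovirus, polyprotein) are
dropped *unless* they also carry superfamily-level evidence (a
homology or sub-terminal hit, or a superfamily-specific keyword) —
encoding the manual curation step that separates retroelements from
reverse-transcribing viruses.

**Hairpin criterion.** Rolling-circle (Helitron) elements are
recognisable by a 3′-terminal CTAG immediately preceded by an 18 bp
palindromic block able to form a hairpin. `hairpin_scan()` reports
every position in the 3′-terminal window (default 50 bp) where CTAG is
preceded by an 18-mer whose first half reverse-complements its second
half with at most one mismatch (perfect palindromes are rare in
diverged copies; one mismatch in nine pairings keeps the stem stable).

**Classification** follows evidence precedence homology >
sub-terminal > hairpin > keyword. A hairpin signature alone implies
Helitron. Superfamily-specific keywords map through a fixed table
(Copia→Ty1/Copia, Gypsy→Ty3/Gypsy, Non-LTR / retroelement / reverse
transcriptase→Non-LTR retrotransposon, En/spm→CACTA, MULE→Mutator,
Mariner→Tc1/Mariner, PIF→PIF-harbinger); generic DNA-transposon
keywords alone give class II Unclassified (code DU) and
"retrotransposon" alone class I Unclassified (RU). Names are
`Ib_<code>_<n>` with the standard three-letter codes (RLC, RLG, RN,
RU, DTT, DTH, DTM, DTP, DTC, DTX, DHH, DIS, DU) and deterministic
numbering within each code.

**ORFs.** The six-frame finder defines an ORF as ATG to the next
in-frame stop (stop included in the length), taking the first ATG
after the previous stop in each frame; open-ended runs without a stop
are not reported. The "long ORF" census applies a strict `> 1000` nt
filter.

# Expression profiling

Read-based profiling maps each read by unique best local alignment
(same scoring as the homology screen, identity ≥ 0.95); reads whose
best score ties between targets are discarded as ambiguous rather than
fractionally assigned — multi-mapping rescue is out of scope.
Normalisation is RPKM, `count * 1e9 / (library_total * length_bp)`.

Tag-based profiling emulates NlaIII digital gene expression: every
CATG on the sense strand with at least 17 downstream bases yields one
21 bp tag. All CATG sites are used, not only the 3′-most one — a
deliberate divergence from canonical NlaIII DGE, which maximises the
detectable fraction of TEs at the cost of intra-transcript tag
multiplicity (a both-strands toggle is not provided; assembled strands
are taken at face value). TEs without any valid site are flagged
undetectable. TE expression is the sum of its tag counts in tags per
million (TPM).

Differential expression between two libraries uses the two-sided
exact hypergeometric (Fisher) probability of the 2×2 table
`[a, A−a; b, B−b]`; a TE is called differentially expressed at
`p <= 0.05` and `|log2FC| >= 1`, with the fold change
pseudocount-shrunk as `log2((a+0.5)/A) − log2((b+0.5)/B)` so zeros are
finite. Specific expression (SETE) requires a count of at least 1 in
one library and exactly 0 in the other. Expression breadth counts the
tissues where a TE is detected (count ≥ 1); percentages are reported
over all detected TEs, rounded half-up to two decimals. Half-up
rounding is used for every printed percentage and for the copy-number
ratio; it is the convention that reproduces the reference values this
package validates against, and `round()`'s banker's rounding is
avoided deliberately.

# qPCR absolute quantification

Plasmid standards are converted to copies/µl with the double-stranded
DNA formula `conc * 6.022e23 / (length * 1e9 * 650)` (650 g/mol per
bp). Replicate Ct values are averaged per dilution level, and mean Ct
is regressed on log10(copies) by ordinary least squares; the
amplification efficiency is `E = 10^(−1/slope) − 1` (slope −3.3219 is
perfect doubling, E = 1). Unknown samples are quantified by inverting
the fitted line, and gene copy number is the ratio of the gene's
absolute abundance to that of a single-copy reference gene (S8e by
default), rounded half-up with a floor of one — a genomic ratio below
one physically means one copy measured with error.

# The synthetic-data generator

The generator is first-class, tested code. It emulates:

* an annotated transcript mixture: planted TEs across eight
  superfamilies carrying their structural signatures — identical
  150–300 bp long terminal repeats for Ty1/Copia and Ty3/Gypsy,
  10–30 bp terminal inverted repeats for Tc1/Mariner, hAT, Mutator,
  PIF-harbinger and CACTA, and the 18 bp palindrome + CTAG signature
  for Helitrons — each with an internal ATG→stop segment and at least
  one CATG tag site, diverged ~10% from a pristine per-superfamily
  reference element (which doubles as the homology screen's labelled
  library); sub-terminal motifs are the 45 bp just inside the 5′
  terminus of each reference, long enough that the 70% similarity
  threshold is discriminative against the best chance alignment in a
  250 bp window;
* background transcripts with non-TE annotations, to measure the
  false-positive rate of the screens;
* negative-binomial read and tag counts with configurable per-library
  means and dispersion (default 0.1; 0 gives Poisson), tag counts
  allocated multinomially across each TE's extractable tags; raw reads
  are exact substrings at uniform positions;
* qPCR plates with Ct = slope·log10(copies) + intercept + Gaussian
  noise (default sd 0.1) over a four-point tenfold dilution
  (10^6–10^9 copies/µl); standards and the unknown sample are run in
  duplicate wells alike.

Default study size: 60 planted TEs (8/8/8/8/7/7/7/7 across the eight
superfamilies) among 200 background transcripts, TE lengths
800–3000 bp, four read libraries and seven tissues at 2×10^5
reads/tags nominal depth. These sizes keep a full pipeline run at
desk scale (single CPU, ~2 minutes) while leaving each validation
statistic enough resolution.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real data: assembly artefacts
(chimeras, fragmentation, redundant isoforms), sequencing errors and
quality structure, hexaploid genome complexity, biased base
composition, and correlated expression between related TE copies.

# Validation design and numerical choices

* Alignment operators are cross-checked against independently written
  quadratic dynamic-programming oracles (local and global, affine
  gaps, gap of length L costing open + L·ext); tag extraction, ORF,
  hairpin and clustering operators against exhaustive position scans
  and all-pairs greedy clustering on small instances.
* The DE null calibration generates two libraries with identical
  per-TE means under Poisson sampling — the exact test's own sampling
  model — and checks the fraction of p ≤ 0.05 stays below 0.08; under
  strong over-dispersion the exact test is anticonservative by
  construction, which is precisely why dispersion-modelling methods
  exist (out of scope here). Sensitivity is measured on planted 4–8×
  fold changes at mean ≥ 50 under the default dispersion 0.1.
* Copy-number recovery is validated over 100 noisy replicates per true
  copy number 1–3 at Ct noise sd 0.1.
* Intron inference reports transcript-side gap runs of at least 40 bp
  (the intron/indel boundary; typical plant introns are ≥ 70–100 bp,
  alignment indels an order of magnitude shorter). Gap *lengths* are
  recovered exactly on clean instances; gap *positions* can slide by a
  few bases when intron boundaries are homologous to the flanking
  exon, a known ambiguity of alignment-based splicing inference.
* `validate_config()` range-checks every threshold and reports all
  problems at once; all randomness flows from the single config seed
  through fixed per-stage offsets, so whole-pipeline runs are
  byte-identical under a fixed seed.

# Known limitations

MITEs enter only through homology or keyword evidence (no structural
MITE discovery); the IS family is recognised only via homology;
ambiguous multi-keyword annotations are resolved by fixed precedence
rather than a probabilistic model; the exact DE test ignores
biological over-dispersion; and the sub-terminal screen's sensitivity
depends directly on how well the motif set represents the local TE
families.
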