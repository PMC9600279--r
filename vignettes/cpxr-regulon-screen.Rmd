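---
title: "Screening a bacterial genome for CpxR boxes and calling the regulon"
author: "cpxscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a bacterial genome for CpxR boxes and calling the regulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpxscreen)
```

## The problem

The CpxRA two-component system lets Gram-negative bacteria sense envelope
stress: the membrane kinase CpxA phosphorylates the response regulator
CpxR, and CpxR-P binds a bipartite DNA box — two conserved pentamers,
consensus `GTAAA`, separated by a 5- or 6-bp spacer — in the promoters of
its target genes. `cpxscreen` turns a curated collection of such boxes
into a position-specific scoring matrix (PSSM), scans a genome with it,
maps the surviving windows into promoter regions, classifies candidate
genes by where their boxes sit, and finally calls regulation from
qRT-PCR fold-change tables. A seeded synthetic-data layer generates
training sites, genomes with planted boxes and Ct tables with known
truth, so every stage is testable without any external download.

## The scoring model

From $n$ aligned sites of length $L$ (here 15 bp, or 16 bp after spacer
expansion), the per-position base probabilities are estimated with
additive smoothing,

$$p_{i,b} = \frac{n_{i,b} + \beta}{n + 4\beta},$$

with pseudocount $\beta = 0.5$ by default, allocated uniformly across
the four bases. An option allocates the pseudocount proportionally to
the background instead ($n_{i,b} + 4\beta q_b$); with a uniform
background the two coincide. Scores are log-odds in bits against a
background model $q$,

$$s_{i,b} = \log_2 \frac{p_{i,b}}{q_b}, \qquad
  S(w) = \sum_{i=1}^{L} s_{i,\,w_i},$$

so the consensus string attains the matrix's maximum achievable score
and a score of 0 marks the point where a window is equally likely under
motif and background. The default background is uniform
($q_b = 0.25$); `genome_background()` estimates a strand-symmetric
composition from the scanned sequence instead. Bits (log base 2) are
the field convention and match the magnitude of published per-box
scores (double-digit positive values for near-consensus boxes).

Curated 16-bp boxes are scarce, so the 16-bp training set is derived
from the 15-bp one: the middle base of the 5-bp spacer (the 8th base of
the site) is duplicated, `expand_spacer("GTAAACCGCCGTAAA")` →
`"GTAAACCGGCCGTAAA"`. Column 8 of the 16-bp count matrix therefore
duplicates column 8 of the 15-bp matrix, and the flanking columns are
shared — a property the test suite checks directly.

## Scanning and the adaptive threshold

Every window of matrix length is scored on both strands by default;
minus-strand windows are scored as their reverse complement
(equivalently, against the reverse-complemented matrix) and reported at
forward-strand coordinates. Windows containing any non-ACGT base are
skipped and counted, never imputed. Circular scanning (windows wrapping
the origin) is available but off by default.

The cutoff is adaptive: $\tau = \mu - \sigma$, the mean of the score
population minus its standard deviation, with the population divisor
$n$ (the window population is enumerated, not sampled). Retention uses
a strict inequality ($S > \tau$). Three score populations are
supported:

* `"genome"` (default): all scoreable windows of the scan;
* `"training"`: the scores of the training sites themselves;
* `"manual"`: a user-supplied cutoff in bits.

A practical note on the default: log-odds scores of background windows
are strongly left-skewed (a single mismatch at a conserved position
costs several bits), so the genome-wide mean minus one SD lies far into
the left tail and retains the large majority of windows. On a uniform
50-kb background with a near-consensus matrix, roughly 80% of windows
survive it. The rule is implemented exactly as stated, but analyses
that need a selective cutoff should use the training population or a
manual value; the natural choices are 0 bits (motif-vs-background
decision boundary) or a fraction of the maximum achievable score
(the end-to-end tests use 70%, which cleanly separates planted
consensus boxes from the best background windows). The 15-bp and 16-bp
scans are always calibrated independently, each against its own
population, and their hit lists are kept separate; overlapping 15/16-bp
hits at one locus are both reported and only collapsed downstream.

## Promoter windows and the four location groups

The screened region per gene runs 700 bp upstream through 100 bp
downstream of the start codon, oriented by strand, with the start-codon
base counted as the first downstream base: on 0-based half-open forward
coordinates a `+` gene with start codon at $S$ gets $[S-700,\,S+100)$
and a `-` gene the exact mirror $[S-99,\,S+701)$, both of width 800
unless clipped at a contig end. A hit is assigned to a gene only when
its interval lies fully inside the window — partial overlaps are
excluded so box counts stay unambiguous — and one hit may serve several
genes, which is precisely how divergent gene pairs share a box.

Candidate genes are classified into four location groups, decided in
priority order A > B > C > D:

* **A** — the gene belongs to a multi-gene cluster (same-strand
  adjacent genes with intergenic gaps ≤ 50 bp, a configurable operon
  heuristic) and the distinct boxes assigned across the cluster number
  at least two;
* **B** — a single gene's window holds at least two distinct boxes;
* **C** — the gene's single box lies in the intergenic span shared
  with a divergently transcribed neighbour, inside both windows (both
  partners are reported, cross-referenced);
* **D** — a single box in a single gene's window.

"Distinct boxes" are non-overlapping intervals: overlapping or nested
hits collapse to one box represented by the highest-scoring member
(ties: leftmost). The priority order resolves genes satisfying several
descriptions — the multi-box layouts subsume the single-box ones. Note
that group C is intrinsically pairwise: one shared box makes both
divergent genes candidates, so a bundle with one exemplar of each
layout yields five candidate genes, two of them class C. Within a gene,
boxes are ranked by score (ties by coordinate), and the top-ranked
"best box" mirrors the experimental observation that the regulator
prefers the higher-scoring of two candidate boxes.

## Regulation calls from Ct tables

Relative expression uses the standard comparative-Ct quantification
with a constitutively transcribed reference gene (rpoD by default):

$$\Delta\Delta C_T = (\bar{C_T}^{gene} - \bar{C_T}^{ref})_{cond}
                   - (\bar{C_T}^{gene} - \bar{C_T}^{ref})_{ctrl},
  \qquad \text{fold} = 2^{-\Delta\Delta C_T},$$

with replicate Cts averaged arithmetically before differencing. Fold
changes are invariant to plate-wide Ct offsets. A fold is called
positive at ≥ 2, negative at ≤ 0.5 (both bounds inclusive; only
strictly-between values are insignificant), matching published tables
in which every reported down-regulation (0.42, 0.08, …) counts as
significant. A gene is regulated in an activation group when *either*
of the group's two comparison columns meets the rule — the unique
reading that reproduces all three published counts (42 genes for the
cpxA24/ΔcpxA group, 64 for the NlpE-overexpression group, 73 in the
union) from the bundled table. When a group's two columns disagree in
direction, the verdict takes the first significant column in the
group's stated order; the count is unaffected. Statistical testing and
amplification-efficiency correction are deliberately out of scope —
calls are threshold-only, as in the source tables.

## What the synthetic generators emulate

`sample_sites()` draws training sites as two consensus pentamers around
an i.i.d. uniform spacer; each pentamer base is retained with
probability $\pi$ (default 0.9, a typical conservation level for
curated bacterial TFBS collections) and otherwise substituted uniformly
among the other three bases — the simplest symmetric variability model.
`plant_genome()` writes an i.i.d. background genome (uniform by
default; an E. coli-like GC of 0.508 can be supplied), places
non-overlapping gene models on both strands in 5-kb slots, and plants
one exemplar of each requested layout class inside the appropriate
promoter window(s); class-C boxes are planted on the minus strand to
exercise strand handling. `simulate_ct()` shifts a gene's baseline Ct
by minus the true log2 effect plus Gaussian replicate noise, with the
reference gene flat in expectation. All three are pure functions of
their spec and seed; repeated runs are byte-identical, including the
emitted FASTA/GFF3/BED files.

What passing tests on this material do **not** show: real genomes are
not i.i.d. (repeats, skewed composition, codon structure), real
binding-site collections are not independent draws from one product
distribution, and real operon structure is not a 50-bp gap rule.
Recovery and classification results on synthetic bundles validate the
machinery, not genome-scale hit counts; reproducing published
genome-wide counts additionally depends on the genome sequence, the
curated site set, and unstated conventions (strand set, background,
score population) that the configuration exposes as options.

## Numerical choices and degenerate inputs

* Matrix math is exact to 1e-9 in the tests; scores round-trip to
  probabilities by exponentiation.
* Consensus ties break by the fixed base order A < C < G < T.
* A zero pseudocount is allowed at the probability stage (the
  maximum-likelihood limit) but a zero probability is rejected at
  log-odds time with an instruction to use β > 0.
* Threshold calibration requires at least two scores; an all-equal
  population yields σ = 0 and, with the strict inequality, zero hits.
* Ambiguity codes: rejected in training sites, skipped (and counted)
  in genome windows.
* Hit files are sorted by (contig, start, strand); reruns on identical
  inputs are byte-identical. BED output is 0-based half-open with the
  bit score scaled by 50 and clamped to 0–1000 (the lossless score
  lives in the companion TSV); human-readable candidate tables are
  1-based inclusive and say so in a header line.
* Problem sizes in the test suite were chosen to keep the full run at
  about half a minute: 50-kb planted genomes (10 seeds for recovery),
  5-kb oracle-equivalence genomes, 200-bp genomes for the 100-seed
  symmetry/monotonicity sweep, and 10,000-site draws for parameter
  recovery.

## Known limitations

* No p-value calibration of scores: the mean−SD rule is the threshold
  semantics, and its genome-population default is permissive (see
  above).
* The operon heuristic is adjacency plus a gap cutoff; no
  transcription-start-site or expression-based operon inference.
* No motif discovery: the matrix always comes from supplied aligned
  sites, and no mixture or higher-order dependencies are modelled.
* Fold-change calls ignore replicate dispersion; the simulation layer
  exposes how the false-positive rate of the plain 2-fold rule falls
  with replicate number, but calls remain threshold-only by design.
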