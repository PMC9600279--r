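# cpxscreen

Genome-wide screening of CpxR binding sites and regulon prediction for
the bacterial CpxRA envelope-stress two-component system.

CpxR, the response regulator of the CpxRA system, binds a bipartite DNA
box — consensus `GTAAA-N5-6-GTAAA`, two conserved pentamers around a 5-
or 6-bp spacer — in the promoters of its target genes. `cpxscreen` is
for microbiologists who have a curated collection of such boxes and want
to predict, genome-wide, which genes the regulator controls, then
confirm candidates with qRT-PCR. The pipeline:

1. **Matrix build** — from aligned 15-bp sites, per-position
   probabilities `p(i,b) = (n(i,b) + β) / (n + 4β)` with pseudocount
   β = 0.5, and log-odds scores in bits `s(i,b) = log2(p(i,b)/q(b))`
   against a uniform (default) or genome-composition background. A
   window scores `S(w) = Σᵢ s(i, wᵢ)`. The 16-bp training set is
   derived by duplicating the middle spacer base of each 15-bp site.
2. **Genome scan** — every 15-bp and 16-bp window, both strands, with
   the adaptive cutoff τ = μ − σ (mean minus population SD of the score
   population); windows scoring strictly above τ are putative CpxR
   boxes.
3. **Promoter annotation** — strand-aware windows 700 bp upstream to
   100 bp downstream of each start codon; hits assigned by full
   containment; candidate genes classified into four box-location
   groups (A: multiple boxes across a gene cluster; B: multiple boxes
   at one gene; C: one box shared by divergent genes; D: one box at one
   gene).
4. **Regulation calls** — ΔΔCt fold changes (`fold = 2^(−ΔΔCt)`, rpoD
   reference) and a 2-fold rule (≥ 2 up, ≤ 0.5 down, bounds inclusive)
   per activation-condition group.
5. **Synthetic data** — seeded generators for training sites, genomes
   with planted boxes plus matching GFF3 and truth BED, and Ct tables,
   so the whole screen is testable offline against known truth.

## Worked example

```r
library(cpxscreen)

# 41 training sites around the bipartite consensus (90% flank identity)
sites <- sample_sites(motif_spec(identity = 0.9, seed = 1), 41)
pssm  <- sites_to_pssm(sites)
consensus_sequence(pssm)   # "GTAAACGTGAGTAAA"
max_score(pssm)            # 19.92 bits

# a 50-kb genome with one planted exemplar of each location group
pl <- plant_genome(motif_spec(identity = 1, seed = 1), seed = 1)
pl
#> Planted genome: 50000 bp, 6 genes, 6 planted boxes (classes A,B,C,D), seed 1

scan_genome(pssm, pl$genome)
#> Genome scan (15-bp matrix, strands +-):
#>   99972 windows scored (0 skipped), mu = -16.8180, sigma = 6.7832, threshold = -23.6012
#>   83781 hits above threshold
```

The scan reports the score population (99,972 windows: both strands of
50 kb), the calibrated cutoff μ − σ, and the retained hits. Note the
mean−SD rule is deliberately permissive — background log-odds scores
are left-skewed, so τ sits deep in the left tail; the planted consensus
boxes score ~19 bits here, far above it. `threshold_population =
"training"` or `"manual"` give selective cutoffs (see the vignette).

Calling regulation on the bundled fold-change table of the 73
experimentally tested candidate genes:

```r
folds <- read_fold_table(cpx_extdata("table2_fold_changes.tsv"),
                         groups = cpx_fold_groups())
count_regulated(folds, "cpxA24_dcpxA")  # 42
count_regulated(folds, "pnlpE")         # 64
count_union(folds)                      # 73
```

42 genes respond (≥ 2-fold either way) under constitutive kinase
activation (cpxA24) or kinase deletion, 64 under NlpE overexpression,
and all 73 genes in the table respond under at least one condition.

For a full run — matrix build, paired 15/16-bp scan, annotation,
classification, track export — see `run_pipeline()` and `run_config()`,
or the thin command-line front end `inst/scripts/cpxscreen.R`
(`simulate` and `run` subcommands).

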