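---
title: "HLA-based sample-identity QC for RNA-seq: models and methods"
author: "hlaqc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HLA-based sample-identity QC for RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the typing model and its assumptions, the tunable parameters and their
defaults, what the simulator does and does not emulate, the numerical
choices, and the known limitations. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The problem

Cohort RNA-seq studies carry several samples per participant, and a
mislabeled sample silently corrupts every downstream contrast. The HLA
class I and II genes (*A, B, C, DPB1, DQB1, DRB1*) are polymorphic enough
that the twelve allele slots of an individual (two per gene) act as a
built-in barcode readable from the reads themselves. `hlaqc` types every
sample at four-digit resolution — the `GENE*XX:YY` level that identifies a
distinct protein; deeper nomenclature fields are synonymous or non-coding
and are collapsed at reference load time — and cross-compares the typed
alleles across the whole study.

## Typing model

**Alignment.** Reads are placed end-to-end, ungapped, on the cDNA
sequences of the allele reference, on both strands, allowing at most
`max_mismatches` substitutions (default 2; `N` never matches). cDNA
references make gapped or spliced placement unnecessary for typing, and an
ungapped model keeps the aligner exact and testable: the compiled
implementation is seed-and-verify with a pigeonhole guarantee, and the test
suite holds it to *exact* agreement with a brute-force Hamming scan over
every window of every allele. Reads are multi-mapped on purpose: a read
supports every four-digit group in which it hits at least one allele, at
most once per group, because within-gene relative counts are what the
caller consumes. For paired-end samples a *pair* supports a group only
when both mates hit it — this mate-concordance rule, rather than an
insert-size model, is what makes paired-end typing cleaner than single-end
(cDNA fragment lengths are unreliable, so no insert constraint is used).

**Calling.** Per gene, the group with the highest count becomes allele 1
(ties broken to the lexicographically smallest name, and logged). Its
confidence is a one-sided outlier z-test against all competing groups of
the same gene, zero-count groups included:

$$p = 1 - \Phi\!\left(\frac{c_{\text{cand}} - \mu_{\text{others}}}
{\sigma_{\text{others}}}\right)$$

with the conventions: $\sigma = 0$ gives $p = 0$ when the candidate
exceeds the background mean and $p = 1$ otherwise, and a gene with a
single reference group gives $p = 0$. The original tool this design
follows inherits its confidence p-values from an earlier typing program
without printing the formula, so the statistic above is this package's own
definition — chosen because it is monotone in the candidate count,
cheap, and isolated behind `outlier_pvalue()` so a rank-based alternative
could be swapped in. One practical property worth knowing: with very few
competing groups (toy references), the second true allele of a
heterozygote dominates the "background" and inflates $p_1$; real
references carry hundreds of groups per gene, where the background is
essentially the zero-count mass and confident calls get vanishingly small
p-values. $\sigma$ is the sample standard deviation (n−1).

**Second allele.** Every read that hit any allele of allele 1's group is
removed and the gene recounted; the new argmax is allele 2. The locus is
homozygous when nothing remains or when the second count falls below
`hom_ratio` × first count. `hom_ratio` defaults to 0.05 — tolerant of
allelic expression imbalance, which is common for HLA; no homozygosity
rule is inherited from the literature, so the ratio is an explicit,
configurable parameter.

**Expression.** RPKM = $10^9 c_{\text{locus}} / (L \cdot N)$ with
$c_{\text{locus}}$ the pass-1 counts of the called group(s), $L$ the mean
cDNA length of those groups' reference alleles and $N$ the sample's total
reads (pairs, for paired-end). It is a sanity signal — low-expression
genes type poorly — not a calibrated expression estimate.

## Cohort comparison

Alleles enter the comparison only below the confidence threshold
(`-c`, default 0.05). Paired-end evidence is stronger, hence the stricter
default; for single-end cohorts 0.5 is recommended — the p-values are
computed identically but from single-mate evidence, so the same cut-off
would discard correct calls rather than wrong ones. A homozygous call
contributes its allele twice, so a fully confident sample has 10 slots
under the default five-gene panel and 12 with all six genes.

For two samples, over the genes where *both* have at least one confident
slot: `shared` sums per-gene multiset intersections, `comparable` sums
per-gene minimum slot counts, and the reported identity is
`100·shared/comparable`. The `min` denominator is a deliberate choice the
source material leaves open: a locus that failed the filter in one sample
does not penalize the pair, and `shared ≤ comparable` is provable, so the
percentage is always well-defined. A hom-vs-het locus sharing one allele
scores 1 of 2 comparable slots. Samples with zero confident alleles stay
in the matrix with `comparable = 0` cells and are flagged in the log.

Grouping is single-linkage: connected components of the graph with an
edge wherever identity ≥ threshold (80% for paired-end cohorts, 70% for
single-end — between-individual pairs essentially never reach 50%, so
both defaults sit in a wide safe margin). Label evaluation sweeps the
threshold over every observed identity value plus 0 and 100, scores each
as a binary classifier over unordered sample pairs (same subject =
positive) and reports the F1-maximizing threshold; ties resolve to the
*largest* threshold, the most conservative pairing. A sample is flagged
as a candidate mislabel when its highest-identity partner at the chosen
threshold carries a different declared subject.

`check_diversity()` counts distinct four-digit alleles across the cohort
and warns below 50 — in populations that restricted, between-individual
identity rises, homozygosity increases and identity QC loses resolution
(the typing itself remains usable).

## The simulator: a stated world

The generator reproduces the benchmarking protocol of the method it
reimplements; its defaults are that protocol, not knobs:

* `X = 10` individuals, each with `0 < n < X` samples (the acceptance
  benchmark draws 2–5);
* 50,000–100,000 HLA-mapped reads per sample, read length 75 or 100 bp —
  the HLA yield of a medium-depth RNA-seq library;
* genotypes drawn per gene as two independent categorical draws from
  population allele frequencies (Hardy–Weinberg, no linkage
  disequilibrium between genes);
* reference alleles absent from a population table are added at frequency
  0.001 — population studies enumerate well under 1000 participants, so
  unseen alleles are rare, not impossible — and the gene is renormalized
  to sum exactly to 1;
* wgsim-style reads: uniform start, i.i.d. substitution errors (default
  1%; the acceptance cohort uses 0.5%), constant quality, no indels —
  typing is ungapped, so indel realism would only exercise code that
  ignores it. Paired fragments are Gaussian (200 ± 20 bp) with mate 2 the
  reverse complement of the far end and random fragment strand;
* per-gene expression weights A 1.0, B 1.0, C 0.8, DRB1 0.6, DPB1 0.3,
  DQB1 0.15 — plumbing values reflecting that DQB1 is the weakest
  expressed of the six (the reason it is excluded from the default
  panel), configurable.

`reads_range` counts *reads*; a paired-end sample of 50,000 reads contains
25,000 pairs. Everything is driven by the R RNG from a single seed, and
cohorts are byte-reproducible.

Synthetic references derive each gene's groups from a common ancestral
sequence at 6% substitution divergence, so groups of a gene are mutually
similar (as real HLA alleles are) yet pairwise distinct; sequences are
500 bp by default. What the simulator does **not** emulate — and what a
green test therefore does not establish robustness against — includes:
intron/UTR carry-over and splicing artifacts, base-quality-correlated
errors and indels, linkage disequilibrium between HLA loci, reference
alleles missing from the database, and the full sequence complexity of
the real IMGT/HLA catalogue (synthetic groups are more uniformly spaced
than real allele families).

## Numerical and interface choices

* Mate pairing in folders follows `_R1/_R2`, `_1/_2`, `.1/.2` filename
  tokens; an orphan token demotes to single-end with a warning. This
  convention is this package's contract, the source material fixes none.
* Compression is detected from gzip magic bytes, not extensions.
* FASTQ parsing is strict: truncated records, malformed separators and
  mate files of unequal length are fatal with the record index; mate
  files are consumed in lockstep.
* Reports print percentages with one decimal and p-values in scientific
  notation with three significant digits, so report diffs are bit-exact
  in tests; the round-trip test recomputes the identity matrix from the
  published per-sample genotype files.
* Typing is deterministic, so the worker count (`-p`) cannot change any
  analysis output byte; the run log records the differing configuration.
* Degenerate inputs: empty gene → `nocall` with RPKM 0; count ties →
  lexicographic, logged; fragment longer than the allele → shrunk with a
  warning; allele shorter than the read → fatal at simulation time.

## Limitations

Four-digit resolution is the design point — six/eight-digit typing would
need a different counting unit and a genomic reference. Known HLA linkage
disequilibrium is ignored by both the simulator and the gene panel; a
user studying a population with strong LD should restrict the panel via
the custom gene list. Low-diversity cohorts (< 50 alleles) are flagged
but not rescued. The aligner is substitution-only; reads spanning indels
relative to the reference allele are lost to typing, which real
short-read aligners would also largely discard at these settings.
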