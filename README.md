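# hlaqc — study-wide HLA typing and sample-identity QC for RNA-seq

RNA-seq studies routinely contain several samples per participant (time
points, conditions, technical replicates), and samples get mislabeled:
during collection, library preparation, sequencing or data transfer. Because
the classical HLA genes are the most polymorphic loci in the human genome,
the combination of HLA alleles is close to unique per individual and can be
read directly out of the RNA-seq reads. `hlaqc` exploits this: it types the
six most variable HLA genes (*HLA-A, -B, -C, -DPB1, -DQB1, -DRB1*) at
four-digit resolution (`GENE*XX:YY`, the protein level) from raw FASTQ, then
cross-compares all samples of a study so that samples from the same person
group together and swapped or mislabeled samples stand out.

It is aimed at anyone running cohort RNA-seq — clinical trials, vaccine
challenge studies, longitudinal designs — as a first-line QC step ahead of
the usual genome alignment, and doubles as a convenient study-wide
HLA-typing tool.

## Method in brief

For each sample, reads are aligned end-to-end and ungapped (≤ 2
substitutions, both strands) against a cDNA reference of known HLA alleles
collapsed to four-digit groups. Per gene, the group with the highest read
count becomes the first allele; its confidence is a one-sided outlier
z-test against the counts of all competing groups of the same gene,

> p = 1 − Φ((c_cand − μ_others) / σ_others),

reads supporting the first allele are removed, and the recount yields the
second allele (or a homozygous call when fewer than 5% of the top count
remains). Expression is reported as RPKM = 10⁹·c/(L·N). Alleles passing a
confidence threshold (default p < 0.05 for paired-end, 0.5 recommended for
single-end) enter the pairwise identity

> percent(i, j) = 100 · Σ_g |multiset ∩| / Σ_g min(slots),

reported for every couple of samples in a squared matrix. Samples are
grouped by single-linkage at an identity threshold (80% paired-end / 70%
single-end); declared sample→subject labels can be scored by an
F1-maximizing threshold sweep over all sample pairs, flagging samples whose
closest HLA match contradicts their label. Samples from different
individuals essentially never exceed 50% identity, so the grouping is
robust.

A built-in simulator (Hardy–Weinberg genotype draws from population allele
frequencies, wgsim-style substitution-only reads, 50,000–100,000 HLA reads
per sample at 75/100 bp) makes the entire pipeline testable without any
external data; low-diversity populations (< 50 distinct alleles) are
detected and flagged as unsuitable for identity QC.

## Worked example

Simulate a cohort of 3 individuals × 2 paired-end samples from a synthetic
reference and population, then run the full QC:

```r
library(hlaqc)

ref    <- synthetic_reference(n_groups = 30, seq_length = 500, seed = 100)
freq   <- synthetic_frequency_table(ref, seed = 101)
params <- sim_params(n_individuals = 3, samples_range = c(2, 2),
                     reads_range = c(20000L, 20000L), error_rate = 0.005,
                     seed = 102)
dir <- file.path(tempdir(), "demo")
sim <- simulate_cohort(params, freq, ref, dir)

reffa <- file.path(tempdir(), "ref.fasta")
write_reference_fasta(ref, reffa)
run <- run_pipeline(run_config(dir, reffa,
                               output_folder = file.path(tempdir(), "demo_out")))
print(run$typings[[1]])
print(run$matrix)
```

which prints (abridged):

```
HLA typing of 'sample001' (paired, 10000 pairs)
  A     A*01:17      p=3.71e-08  A*01:06      p=0         het    rpkm=507600.0
  B     B*01:25      p=5.51e-09  B*01:07      p=0         het    rpkm=521800.0
  C     C*01:19      p=7.76e-08  C*01:14      p=0         het    rpkm=415800.0
  DPB1  DPB1*01:30   p=4.42e-09  DPB1*01:13   p=0         het    rpkm=147600.0
  DRB1  DRB1*01:04   p=6.78e-08  DRB1*01:13   p=0         het    rpkm=303200.0

HLA identity matrix: 6 samples
          sample001 sample002 sample003 sample004 sample005 sample006
sample001       100       100        10        10        10        10
sample002       100       100        10        10        10        10
sample003        10        10       100       100        20        20
sample004        10        10       100       100        20        20
sample005        10        10        20        20       100       100
sample006        10        10        20        20       100       100
```

Each sample's ten confident allele slots (2 per gene × 5 default genes) are
fully recovered; the two samples of each individual share 100% of alleles
while between-individual pairs sit at 10–20%, far below the 80% grouping
threshold, so `run$groups` reproduces the three individuals exactly. The
reports land in the output folder: per-sample `*.genotype.tsv`, the
`identity_percent.tsv` / `identity_counts.tsv` matrices,
`alleles_total.tsv`, `groups.tsv`, a heat-map-ready `identity_long.tsv`
and, when `labels` is given, `eval.tsv` + `mislabels.tsv`.

A command-line front end ships in the installed package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hla-cohort-qc.R", package = "hlaqc"))')
Rscript $CLI INPUT_DIR -r REF.fasta -c 0.05 -p 4 -g 5 -o OUTDIR --labels labels.tsv
Rscript $CLI simulate -r REF.fasta -f FREQ.tsv -o SIMDIR --individuals 10
```

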