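# Shared fixtures and the independent brute-force alignment oracle.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc_str <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Build an allele_reference directly from name/sequence vectors.
make_ref <- function(allele_names, sequences) {
  hlaqc:::.new_allele_reference(data.frame(
    gene = sub("\\*.*$", "", allele_names),
    allele_name = allele_names,
    group4 = reduce_to_group(allele_names),
    sequence = sequences,
    stringsAsFactors = FALSE))
}

write_fasta <- function(path, headers, seqs) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

write_fastq_file <- function(path, seqs, ids = NULL, gz = FALSE) {
  if (is.null(ids)) ids <- paste0("r", seq_along(seqs))
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  lines <- if (length(seqs)) {
    as.vector(rbind(paste0("@", ids), seqs, "+", strrep("I", nchar(seqs))))
  } else character(0)
  writeLines(lines, con)
  path
}

# Brute-force oracle: every window of every reference sequence, both
# strands, mismatch = differing chars or a read char outside ACGT.
# Independent of the packaged aligner (no k-mer index, no pigeonhole) and
# must agree with it exactly.
brute_hamming <- function(read, window) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(window, "")[[1]]
  sum(a != b | !(a %in% BASES))
}

brute_align <- function(read, ref, max_mm) {
  L <- nchar(read)
  oris <- unique(c(read, rc_str(read)))
  hit <- vapply(seq_len(nrow(ref$records)), function(i) {
    S <- ref$records$sequence[i]
    n <- nchar(S)
    if (L > n || L == 0) return(FALSE)
    chars <- strsplit(S, "")[[1]]
    idx <- outer(0:(L - 1), seq_len(n - L + 1), "+")  # L x W position matrix
    wm <- matrix(chars[idx], nrow = L)
    for (ori in oris) {
      a <- strsplit(ori, "")[[1]]
      mm <- colSums((wm != a) | !(a %in% BASES))
      if (any(mm <= max_mm)) return(TRUE)
    }
    FALSE
  }, logical(1))
  sort(ref$records$allele_name[hit])
}

# Minimal hand-built typing objects for the QC-layer tests.
mk_call <- function(gene, a1, p1, a2 = NA_character_, p2 = NA_real_,
                    zyg = if (is.na(a2)) "hom" else "het",
                    c1 = 100L, c2 = 50L, rpkm = 0) {
  structure(list(gene = gene, allele1 = a1, p1 = p1, allele2 = a2, p2 = p2,
                 zygosity = zyg, c1 = c1, c2 = c2, rpkm = rpkm),
            class = "locus_call")
}

mk_typing <- function(sample_id, calls, layout = "paired") {
  structure(list(sample_id = sample_id, layout = layout,
                 total_reads = 1000L, n_skipped = 0L,
                 calls = setNames(calls, vapply(calls, `[[`, "", "gene"))),
            class = "sample_typing")
}

mk_profile <- function(sample_id, alleles) {
  structure(list(sample_id = sample_id, alleles = alleles,
                 n_confident = sum(lengths(alleles))),
            class = "allele_profile")
}

# Small simulated cohort used by several test files.
small_cohort <- function(dir, n_ind = 3, samples_range = c(1, 2),
                         reads = 3000, n_groups = 12, seed = 421,
                         layout = "paired", error_rate = 0.005) {
  ref <- synthetic_reference(n_groups = n_groups, seq_length = 400,
                             seed = seed)
  freq <- synthetic_frequency_table(ref, seed = seed + 1)
  params <- sim_params(n_individuals = n_ind, samples_range = samples_range,
                       reads_range = c(reads, reads), layout = layout,
                       error_rate = error_rate, seed = seed + 2)
  sim <- simulate_cohort(params, freq, ref, dir)
  list(ref = ref, freq = freq, params = params, sim = sim)
}
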