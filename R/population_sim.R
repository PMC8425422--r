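#' Simulation parameters
#'
#' Defaults reproduce the stated benchmarking protocol: X = 10 individuals,
#' 0 < n < X samples per individual, 50,000-100,000 HLA-mapped reads per
#' sample at 75 or 100 bp. `reads_range` counts individual reads; a
#' paired-end sample therefore contains half as many read pairs.
#' Expression weights reflect the relative RNA-seq coverage of the six
#' genes, with DQB1 lowest (its weak expression is why the default gene
#' panel leaves it out).
#'
#' @param n_individuals Number of individuals X (default 10).
#' @param samples_range Inclusive range the per-individual sample count is
#'   drawn from, default `c(1, n_individuals - 1)`.
#' @param read_length Read length in bp, 75 or 100.
#' @param layout `"paired"` or `"single"`.
#' @param reads_range Inclusive range of total HLA reads per sample.
#' @param error_rate Per-base substitution error rate in `[0, 0.2]`.
#' @param frag_mean,frag_sd Fragment length model for paired-end reads.
#' @param expr_weights Named positive weights, one per gene.
#' @param seed Optional RNG seed for full reproducibility.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_individuals = 10L,
                       samples_range = c(1L, n_individuals - 1L),
                       read_length = 75L,
                       layout = c("paired", "single"),
                       reads_range = c(50000L, 100000L),
                       error_rate = 0.01,
                       frag_mean = 200, frag_sd = 20,
                       expr_weights = c(A = 1.0, B = 1.0, C = 0.8,
                                        DRB1 = 0.6, DPB1 = 0.3, DQB1 = 0.15),
                       seed = NULL) {
  layout <- match.arg(layout)
  stopifnot(n_individuals >= 1,
            samples_range[1] >= 1, samples_range[2] < n_individuals ||
              n_individuals == 1,
            read_length %in% c(75L, 100L),
            reads_range[1] <= reads_range[2],
            error_rate >= 0, error_rate <= 0.2,
            all(expr_weights > 0))
  structure(list(n_individuals = as.integer(n_individuals),
                 samples_range = as.integer(samples_range),
                 read_length = as.integer(read_length),
                 layout = layout,
                 reads_range = as.integer(reads_range),
                 error_rate = error_rate,
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 expr_weights = expr_weights, seed = seed),
            class = "sim_params")
}

#' Load a population allele-frequency table
#'
#' TSV with columns `gene`, `allele`, `frequency`. Allele names are reduced
#' to four-digit groups; per-gene frequency sums must be within 0.01 of 1
#' and are then renormalized to sum exactly to 1.
#'
#' @param path Path to the TSV file.
#' @return A `frequency_table`: per gene, a named numeric vector of
#'   four-digit group frequencies summing to 1.
#' @export
load_frequency_table <- function(path) {
  if (!file.exists(path)) stop("frequency table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "allele", "frequency")
  if (!all(need %in% names(df))) {
    stop("frequency table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!df$gene %in% hla_genes())) {
    stop("unknown gene(s) in frequency table: ",
         paste(setdiff(unique(df$gene), hla_genes()), collapse = ", "))
  }
  if (any(!is.finite(df$frequency) | df$frequency <= 0)) {
    stop("frequencies must be finite and > 0")
  }
  # allele may be fully qualified ("A*01:01") or gene-relative ("01:01")
  full <- ifelse(grepl("\\*", df$allele), df$allele,
                 paste0(df$gene, "*", df$allele))
  df$group4 <- reduce_to_group(full)
  if (any(.gene_of_allele(df$group4) != df$gene)) {
    stop("allele name(s) disagree with the gene column")
  }
  freq <- lapply(split(df, df$gene), function(d) {
    if (anyDuplicated(d$group4)) {
      stop("duplicate allele group(s) for gene ", d$gene[1], ": ",
           paste(unique(d$group4[duplicated(d$group4)]), collapse = ", "))
    }
    s <- sum(d$frequency)
    if (abs(s - 1) > 0.01) {
      stop("frequencies of gene ", d$gene[1], " sum to ", signif(s, 4),
           " (must be within 0.01 of 1)")
    }
    setNames(d$frequency / s, d$group4)
  })
  structure(list(freq = freq[intersect(hla_genes(), names(freq))]),
            class = "frequency_table")
}

#' Fill in reference alleles missing from a population table
#'
#' Population studies enumerate well under 1000 participants, so reference
#' alleles absent from the table are not impossible, merely unobserved.
#' Each reference four-digit group missing from the table is added with
#' frequency 0.001 and all frequencies of the gene are then renormalized so
#' they again sum exactly to 1.
#'
#' @param table A `frequency_table`.
#' @param ref An `allele_reference`; its genes must cover the table's.
#' @return The adjusted `frequency_table`.
#' @export
adjust_frequencies <- function(table, ref) {
  stopifnot(inherits(table, "frequency_table"),
            inherits(ref, "allele_reference"))
  if (!all(names(table$freq) %in% ref$genes)) {
    stop("frequency table gene(s) absent from reference: ",
         paste(setdiff(names(table$freq), ref$genes), collapse = ", "))
  }
  freq <- lapply(setNames(names(table$freq), names(table$freq)), function(g) {
    f <- table$freq[[g]]
    missing <- setdiff(ref$groups_by_gene[[g]], names(f))
    if (length(missing)) {
      f <- c(f, setNames(rep(0.001, length(missing)), missing))
    }
    f / sum(f)
  })
  structure(list(freq = freq), class = "frequency_table")
}

#' Draw a diploid genotype under Hardy-Weinberg sampling
#'
#' Two independent categorical draws per gene from the (adjusted) allele
#' frequencies, no linkage between genes. For each drawn group a concrete
#' full-resolution allele is chosen uniformly among the group's reference
#' alleles. Uses the current R RNG stream; `set.seed()` beforehand for
#' reproducibility.
#'
#' @param table An adjusted `frequency_table`.
#' @param ref An `allele_reference`.
#' @return A `genotype`: per gene, a 2-row data frame with columns `group4`
#'   and `allele_name`.
#' @export
sample_genotype <- function(table, ref) {
  stopifnot(inherits(table, "frequency_table"),
            inherits(ref, "allele_reference"))
  genes <- intersect(ref$genes, names(table$freq))
  gt <- lapply(setNames(genes, genes), function(g) {
    f <- table$freq[[g]]
    grp <- names(f)[sample.int(length(f), 2L, replace = TRUE, prob = f)]
    allele <- vapply(grp, function(gr) {
      cand <- ref$records$allele_name[ref$records$group4 == gr]
      cand[sample.int(length(cand), 1L)]
    }, character(1))
    data.frame(group4 = grp, allele_name = unname(allele),
               stringsAsFactors = FALSE)
  })
  structure(gt, class = "genotype")
}

# uniform integer draw on [lo, hi]; safe when lo == hi (unlike sample())
.runifint <- function(n, lo, hi) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

.rc_strings <- function(x) {
  if (!length(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Extract windows [start, start+L-1] from per-copy source sequences, with
# one vectorized substring() call per source sequence.
.extract_windows <- function(seq_by_copy, copy_idx, start, L) {
  out <- character(length(copy_idx))
  for (kv in unique(copy_idx)) {
    i <- which(copy_idx == kv)
    out[i] <- substring(seq_by_copy[kv], start[i], start[i] + L - 1L)
  }
  out
}

# i.i.d. substitution errors at rate e; positions/replacements drawn from
# the R RNG, applied in C++.
.apply_errors <- function(reads, L, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  nerr <- stats::rbinom(length(reads), L, error_rate)
  which_err <- which(nerr > 0)
  if (!length(which_err)) return(reads)
  pos_list <- lapply(which_err, function(i) sample.int(L, nerr[i]))
  flat_read <- rep(which_err, lengths(pos_list))
  flat_pos <- unlist(pos_list, use.names = FALSE)
  orig <- substring(reads[flat_read], flat_pos, flat_pos)
  bases <- c("A", "C", "G", "T")
  o <- match(orig, bases)
  shift <- sample.int(3L, length(flat_pos), replace = TRUE)
  newb <- bases[((o - 1L + shift) %% 4L) + 1L]
  newb[is.na(o)] <- orig[is.na(o)]  # leave N untouched
  substitute_bases_cpp(reads, flat_read, flat_pos, newb)
}

.write_fastq <- function(path, ids, seqs, compress = FALSE) {
  qual <- strrep("I", nchar(seqs))
  con <- if (compress) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), con)
  invisible(path)
}

#' Simulate the RNA-seq reads of one sample
#'
#' wgsim-style read generation restricted to what ungapped typing sees:
#' for every read (pair), a gene is chosen proportionally to the expression
#' weights, one of the two allele copies uniformly, a start position
#' uniformly along the allele cDNA, and i.i.d. substitution errors are
#' applied at the stated rate (no indels, constant quality `I`). Paired-end
#' fragments have Gaussian length; mate 2 is the reverse complement of the
#' fragment's other end, and the fragment strand is random so both mate
#' orientations occur. Fragments longer than the allele are shrunk with a
#' warning. Uses the current R RNG stream.
#'
#' @param genotype A `genotype`.
#' @param params A `sim_params`.
#' @param ref An `allele_reference` carrying the allele sequences.
#' @param dir Output directory (created if needed).
#' @param sample_id Sample name; paired-end files are
#'   `<id>_R1.fastq[.gz]` / `<id>_R2.fastq[.gz]`.
#' @param n_reads Total reads for this sample (pairs count as 2).
#' @param compress Write gzip-compressed FASTQ.
#' @return List with `files`, `layout`, `read_length`, `reads_generated`.
#' @export
simulate_sample <- function(genotype, params, ref, dir, sample_id,
                            n_reads = NULL, compress = FALSE) {
  stopifnot(inherits(genotype, "genotype"), inherits(params, "sim_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(n_reads)) {
    n_reads <- .runifint(1L, params$reads_range[1], params$reads_range[2])
  }
  genes <- names(genotype)
  L <- params$read_length
  paired <- params$layout == "paired"
  n_units <- if (paired) n_reads %/% 2L else n_reads

  seq_of <- setNames(ref$records$sequence, ref$records$allele_name)
  seq_by_copy <- unlist(lapply(genes, function(g) seq_of[genotype[[g]]$allele_name]),
                        use.names = FALSE)
  copy_gene <- rep(seq_along(genes), each = 2L)
  copy_len <- nchar(seq_by_copy)
  if (any(copy_len < L)) {
    stop("allele(s) shorter than the read length (", L, " bp)")
  }

  w <- params$expr_weights[genes]
  gene_idx <- sample.int(length(genes), n_units, replace = TRUE,
                         prob = w / sum(w))
  copy_idx <- (gene_idx - 1L) * 2L + sample.int(2L, n_units, replace = TRUE)
  len <- copy_len[copy_idx]

  if (!paired) {
    start <- floor(stats::runif(n_units) * (len - L + 1)) + 1L
    reads <- .extract_windows(seq_by_copy, copy_idx, start, L)
    minus <- stats::runif(n_units) < 0.5
    reads[minus] <- .rc_strings(reads[minus])
    reads <- .apply_errors(reads, L, params$error_rate)
    ids <- paste0(sample_id, ":", seq_len(n_units))
    f <- file.path(dir, paste0(sample_id, ".fastq", if (compress) ".gz"))
    .write_fastq(f, ids, reads, compress)
    files <- f
  } else {
    frag <- round(stats::rnorm(n_units, params$frag_mean, params$frag_sd))
    frag <- pmax(frag, L)
    if (any(frag > len)) {
      warning("fragment(s) longer than the source allele; shrunk to allele length")
      frag <- pmin(frag, len)
    }
    start <- floor(stats::runif(n_units) * (len - frag + 1)) + 1L
    m1 <- .extract_windows(seq_by_copy, copy_idx, start, L)
    m2 <- .rc_strings(.extract_windows(seq_by_copy, copy_idx,
                                       start + frag - L, L))
    minus <- stats::runif(n_units) < 0.5
    tmp <- m1[minus]; m1[minus] <- m2[minus]; m2[minus] <- tmp
    m1 <- .apply_errors(m1, L, params$error_rate)
    m2 <- .apply_errors(m2, L, params$error_rate)
    ids <- paste0(sample_id, ":", seq_len(n_units))
    f1 <- file.path(dir, paste0(sample_id, "_R1.fastq", if (compress) ".gz"))
    f2 <- file.path(dir, paste0(sample_id, "_R2.fastq", if (compress) ".gz"))
    .write_fastq(f1, paste0(ids, "/1"), m1, compress)
    .write_fastq(f2, paste0(ids, "/2"), m2, compress)
    files <- c(f1, f2)
  }
  list(files = files, layout = params$layout, read_length = L,
       reads_generated = if (paired) 2L * n_units else n_units)
}

#' Simulate a whole RNA-seq cohort with ground truth
#'
#' Draws `n_individuals` genotypes under Hardy-Weinberg sampling from the
#' (internally adjusted) frequency table, gives each individual a uniform
#' number of samples in `samples_range`, simulates each sample's reads and
#' writes a `truth.tsv` (sample-to-individual map) and `genotypes.tsv`
#' next to the FASTQ files. Byte-identical across runs for a fixed
#' `params$seed`.
#'
#' @param params A `sim_params`.
#' @param freq_table A `frequency_table` (adjustment to the reference is
#'   applied internally).
#' @param ref An `allele_reference`.
#' @param outdir Output folder for the FASTQ files and truth tables.
#' @param compress Write gzip-compressed FASTQ.
#' @return List with `folder`, `truth` (data frame: `sample_id`,
#'   `individual_id`, `layout`, `read_length`, `reads_generated`),
#'   `genotypes` (per individual), `truth_file`, `genotype_file`.
#' @export
simulate_cohort <- function(params, freq_table, ref, outdir,
                            compress = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  adj <- adjust_frequencies(freq_table, ref)
  X <- params$n_individuals
  ind_ids <- sprintf("ind%02d", seq_len(X))
  genotypes <- setNames(lapply(seq_len(X), function(i) {
    sample_genotype(adj, ref)
  }), ind_ids)

  n_samples <- .runifint(X, params$samples_range[1], params$samples_range[2])
  rows <- list()
  k <- 0L
  for (i in seq_len(X)) {
    for (r in seq_len(n_samples[i])) {
      k <- k + 1L
      sid <- sprintf("sample%03d", k)
      n_reads <- .runifint(1L, params$reads_range[1], params$reads_range[2])
      sim <- simulate_sample(genotypes[[i]], params, ref, outdir, sid,
                             n_reads = n_reads, compress = compress)
      rows[[k]] <- data.frame(sample_id = sid, individual_id = ind_ids[i],
                              layout = sim$layout,
                              read_length = sim$read_length,
                              reads_generated = sim$reads_generated,
                              stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  truth_file <- file.path(outdir, "truth.tsv")
  write.table(truth, truth_file, sep = "\t", quote = FALSE, row.names = FALSE)

  gt_rows <- do.call(rbind, lapply(ind_ids, function(id) {
    do.call(rbind, lapply(names(genotypes[[id]]), function(g) {
      data.frame(individual_id = id, gene = g, copy = 1:2,
                 group4 = genotypes[[id]][[g]]$group4,
                 allele_name = genotypes[[id]][[g]]$allele_name,
                 stringsAsFactors = FALSE)
    }))
  }))
  genotype_file <- file.path(outdir, "genotypes.tsv")
  write.table(gt_rows, genotype_file, sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(folder = outdir, truth = truth, genotypes = genotypes,
       truth_file = truth_file, genotype_file = genotype_file)
}

#' Generate a synthetic HLA allele reference
#'
#' Builds, per gene, an ancestral cDNA sequence and derives each four-digit
#' group from it by random substitutions at the given divergence, so groups
#' of one gene are mutually similar (like real HLA alleles) yet pairwise
#' distinct; additional alleles within a group differ by a couple of
#' synonymous-style substitutions. Names follow the `GENE*XX:YY[:ZZ]`
#' nomenclature. Purely synthetic: no real IMGT/HLA sequence is shipped or
#' reproduced.
#'
#' @param n_groups Four-digit groups per gene.
#' @param genes Genes to include.
#' @param seq_length cDNA length in bp (must exceed fragment lengths).
#' @param alleles_per_group Full-resolution alleles per group.
#' @param divergence Per-base substitution rate from the gene ancestor.
#' @param seed Optional RNG seed.
#' @return An `allele_reference`.
#' @export
synthetic_reference <- function(n_groups = 100L, genes = hla_genes(),
                                seq_length = 500L, alleles_per_group = 1L,
                                divergence = 0.06, seed = NULL) {
  stopifnot(n_groups >= 1, seq_length >= 50, alleles_per_group >= 1,
            divergence > 0, divergence < 0.5,
            all(genes %in% hla_genes()))
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mutate <- function(v, n_mut) {
    pos <- sample.int(length(v), n_mut)
    o <- match(v[pos], bases)
    v[pos] <- bases[((o - 1L + sample.int(3L, n_mut, replace = TRUE)) %% 4L) + 1L]
    v
  }
  recs <- list()
  for (g in genes) {
    anc <- sample(bases, seq_length, replace = TRUE)
    n_mut <- max(1L, round(divergence * seq_length))
    group_seqs <- character(n_groups)
    for (i in seq_len(n_groups)) {
      repeat {
        s <- paste0(mutate(anc, n_mut), collapse = "")
        if (!s %in% group_seqs[seq_len(i - 1L)]) break
      }
      group_seqs[i] <- s
    }
    f1 <- (seq_len(n_groups) - 1L) %/% 50L + 1L
    f2 <- (seq_len(n_groups) - 1L) %% 50L + 1L
    group_names <- sprintf("%s*%02d:%02d", g, f1, f2)
    for (i in seq_len(n_groups)) {
      for (a in seq_len(alleles_per_group)) {
        v <- strsplit(group_seqs[i], "")[[1L]]
        if (a > 1L) v <- mutate(v, 2L)
        recs[[length(recs) + 1L]] <- data.frame(
          gene = g,
          allele_name = if (alleles_per_group == 1L) group_names[i] else
            sprintf("%s:%02d", group_names[i], a),
          group4 = group_names[i],
          sequence = paste0(v, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  .new_allele_reference(do.call(rbind, recs))
}

#' Generate a synthetic population frequency table for a reference
#'
#' Per gene, frequencies are drawn from a symmetric Dirichlet(`alpha`)
#' (via normalized gamma draws) over the reference's four-digit groups.
#' `alpha = 1` gives a fairly even, high-diversity population; small
#' `alpha` concentrates mass on few alleles.
#'
#' @param ref An `allele_reference`.
#' @param alpha Dirichlet concentration parameter.
#' @param seed Optional RNG seed.
#' @return A `frequency_table`.
#' @export
synthetic_frequency_table <- function(ref, alpha = 1, seed = NULL) {
  stopifnot(inherits(ref, "allele_reference"), alpha > 0)
  if (!is.null(seed)) set.seed(seed)
  freq <- lapply(setNames(ref$genes, ref$genes), function(g) {
    grp <- ref$groups_by_gene[[g]]
    x <- stats::rgamma(length(grp), shape = alpha)
    x <- pmax(x, 1e-12)
    setNames(x / sum(x), grp)
  })
  structure(list(freq = freq), class = "frequency_table")
}

#' Write a frequency table to TSV
#'
#' Long format with columns `gene`, `allele`, `frequency`, round-trippable
#' through [load_frequency_table()].
#'
#' @param table A `frequency_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) {
  stopifnot(inherits(table, "frequency_table"))
  df <- do.call(rbind, lapply(names(table$freq), function(g) {
    data.frame(gene = g, allele = names(table$freq[[g]]),
               frequency = unname(table$freq[[g]]), stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
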