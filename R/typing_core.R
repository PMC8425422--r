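#' Typing parameters
#'
#' @param max_mismatches Maximum substitutions allowed for an end-to-end,
#'   ungapped read placement (both strands are searched). Default 2.
#' @param hom_ratio A locus is called homozygous when the best second-pass
#'   count falls below `hom_ratio` times the first-pass top count. Default
#'   0.05, tolerant to allelic expression imbalance.
#' @return List of typing parameters.
#' @export
typing_params <- function(max_mismatches = 2L, hom_ratio = 0.05) {
  stopifnot(max_mismatches >= 0, hom_ratio >= 0, hom_ratio < 1)
  list(max_mismatches = as.integer(max_mismatches), hom_ratio = hom_ratio)
}

# seed length for the k-mer index: must not exceed read_len / (max_mm + 1)
# for the pigeonhole guarantee; shorter reads fall back to a window scan
# inside the C++ code.
.choose_k <- function(min_read_len, max_mm) {
  if (!is.finite(min_read_len) || min_read_len < 1) return(8L)
  max(4L, min(16L, min_read_len %/% (max_mm + 1L)))
}

# Ordered table of four-digit groups in a reference; group ids are row
# indices and are stable for a given reference.
.ref_group_table <- function(ref) {
  u <- unique(ref$records[, c("group4", "gene")])
  u <- u[order(match(u$gene, hla_genes()), u$group4, method = "radix"), ,
         drop = FALSE]
  rownames(u) <- NULL
  u
}

#' Align a single read against an allele reference
#'
#' Reports every allele whose cDNA sequence contains an end-to-end, ungapped
#' occurrence of the read or of its reverse complement with at most
#' `max_mismatches` substitutions. `N` never matches. Multi-allele and
#' multi-gene hits are all reported; a read containing characters outside
#' `ACGTN` yields no hits.
#'
#' @param read Nucleotide string.
#' @param ref An `allele_reference`.
#' @param max_mismatches Maximum substitutions (default 2).
#' @return Character vector of hit allele names (possibly empty).
#' @export
align_read <- function(read, ref, max_mismatches = 2L) {
  stopifnot(inherits(ref, "allele_reference"), length(read) == 1L)
  res <- align_reads_cpp(toupper(read), ref$records$sequence,
                         as.integer(max_mismatches),
                         .choose_k(nchar(read), max_mismatches))
  ref$records$allele_name[res$allele]
}

# Vectorized alignment of many reads; returns flat (read, allele) hit pairs
# plus the number of reads skipped for invalid characters.
.align_hits <- function(reads, ref, max_mismatches) {
  k <- .choose_k(suppressWarnings(min(nchar(reads))), max_mismatches)
  res <- align_reads_cpp(reads, ref$records$sequence,
                         as.integer(max_mismatches), k)
  list(read = res$read, allele = res$allele, n_skipped = sum(res$skipped))
}

# Core counting over in-memory reads. reads2 = NULL for single-end.
# Returns per-gene group counts plus the flat per-read group hits that the
# two-pass caller needs (paired-end hits are mate-concordant pairs).
.count_hits_for_reads <- function(reads1, reads2, ref, max_mismatches) {
  groups <- .ref_group_table(ref)
  K <- nrow(groups)
  gid_of_allele <- match(ref$records$group4, groups$group4)

  dedupe <- function(h) {
    if (!length(h$read)) return(list(read = integer(0), group = integer(0)))
    gid <- gid_of_allele[h$allele]
    key <- (as.numeric(h$read) - 1) * K + gid
    keep <- !duplicated(key)
    list(read = h$read[keep], group = gid[keep])
  }

  a1 <- .align_hits(reads1, ref, max_mismatches)
  h1 <- dedupe(a1)
  n_skipped <- a1$n_skipped
  if (is.null(reads2)) {
    hits <- h1
    n_units <- length(reads1)
  } else {
    if (length(reads1) != length(reads2)) stop("mate vectors differ in length")
    a2 <- .align_hits(reads2, ref, max_mismatches)
    h2 <- dedupe(a2)
    n_skipped <- n_skipped + a2$n_skipped
    # a pair supports a group only when BOTH mates hit >= 1 allele of it
    key1 <- (as.numeric(h1$read) - 1) * K + h1$group
    key2 <- (as.numeric(h2$read) - 1) * K + h2$group
    keep <- key1 %in% key2
    hits <- list(read = h1$read[keep], group = h1$group[keep])
    n_units <- length(reads1)
  }

  tab <- tabulate(hits$group, nbins = K)
  gene_counts <- lapply(setNames(unique(groups$gene), unique(groups$gene)),
                        function(g) {
                          i <- which(groups$gene == g)
                          setNames(tab[i], groups$group4[i])
                        })

  structure(list(gene_counts = gene_counts,
                 hits = hits,
                 groups = groups,
                 total_sample_reads = n_units,
                 n_skipped = n_skipped),
            class = "group_counts")
}

#' Count read support per four-digit allele group
#'
#' Aligns every read (or read pair) of a sample against the reference and
#' accumulates, per gene, the number of reads supporting each four-digit
#' group. Single-end: a read adds 1 to every group containing at least one
#' hit allele (at most once per group). Paired-end: a pair adds 1 to a
#' group only when both mates hit at least one allele of that group.
#'
#' @param spec A `sample_spec`.
#' @param ref An `allele_reference`.
#' @param max_mismatches Maximum substitutions per read placement.
#' @return A `group_counts` object: `gene_counts` (per gene, named integer
#'   vector over all reference groups of that gene), `hits` (flat per-read
#'   group support used by the two-pass caller), `total_sample_reads`
#'   (reads for single-end, pairs for paired-end) and `n_skipped`.
#' @export
count_group_hits <- function(spec, ref, max_mismatches = 2L) {
  stopifnot(inherits(spec, "sample_spec"), inherits(ref, "allele_reference"))
  rd <- stream_reads(spec)
  if (spec$layout == "single") {
    .count_hits_for_reads(rd$reads, NULL, ref, max_mismatches)
  } else {
    .count_hits_for_reads(rd$reads1, rd$reads2, ref, max_mismatches)
  }
}

#' Outlier confidence p-value of a candidate allele group
#'
#' One-sided z-score outlier test: the candidate's read count is compared
#' against the mean and standard deviation of the counts of all \emph{other}
#' groups of the same gene (zero-count groups included);
#' `p = 1 - pnorm(z)`. Smaller p means the candidate stands out more
#' clearly from the background of competing groups. Degenerate cases: with
#' zero spread, `p = 0` when the candidate exceeds the background mean and
#' `1` otherwise; a gene with a single reference group gives `p = 0` (no
#' competitors).
#'
#' @param counts Named numeric vector of read counts over all reference
#'   groups of one gene.
#' @param candidate Name of the candidate group (must be in `counts`).
#' @return p-value in `[0, 1]`.
#' @export
outlier_pvalue <- function(counts, candidate) {
  if (!candidate %in% names(counts)) stop("candidate '", candidate,
                                          "' not among the counted groups")
  others <- counts[names(counts) != candidate]
  if (!length(others)) return(0)
  mu <- mean(others)
  sg <- stats::sd(others)
  if (!is.finite(sg) || sg == 0) {
    return(if (counts[[candidate]] > mu) 0 else 1)
  }
  stats::pnorm((counts[[candidate]] - mu) / sg, lower.tail = FALSE)
}

.nocall <- function(gene) {
  structure(list(gene = gene, allele1 = NA_character_, p1 = NA_real_,
                 allele2 = NA_character_, p2 = NA_real_,
                 zygosity = "nocall", c1 = 0L, c2 = 0L, rpkm = 0),
            class = "locus_call")
}

# argmax with deterministic lexicographic tie-break (smallest name wins)
.argmax_group <- function(counts) {
  top <- max(counts)
  cand <- sort(names(counts)[counts == top], method = "radix")
  if (length(cand) > 1L) {
    message("count tie between groups ", paste(cand, collapse = ", "),
            "; taking ", cand[1L])
  }
  cand[1L]
}

# Two-pass locus call on a precomputed group_counts object.
.call_locus_counts <- function(gc, ref, gene, hom_ratio = 0.05) {
  cnt <- gc$gene_counts[[gene]]
  if (is.null(cnt) || !length(cnt) || max(cnt) == 0L) return(.nocall(gene))

  g1 <- .argmax_group(cnt)
  c1 <- cnt[[g1]]
  p1 <- outlier_pvalue(cnt, g1)

  # pass 2: drop every read that hit any allele of g1's group, recount
  gene_gids <- which(gc$groups$gene == gene)
  gid1 <- which(gc$groups$group4 == g1 & gc$groups$gene == gene)
  reads_g1 <- gc$hits$read[gc$hits$group == gid1]
  keep <- gc$hits$group %in% gene_gids & !(gc$hits$read %in% reads_g1)
  re_tab <- tabulate(match(gc$hits$group[keep], gene_gids),
                     nbins = length(gene_gids))
  recnt <- setNames(re_tab, gc$groups$group4[gene_gids])

  if (max(recnt) == 0L) {
    zyg <- "hom"; g2 <- NA_character_; p2 <- NA_real_; c2 <- 0L
  } else {
    g2 <- .argmax_group(recnt)
    c2 <- recnt[[g2]]
    if (c2 < hom_ratio * c1) {
      zyg <- "hom"; g2 <- NA_character_; p2 <- NA_real_
    } else {
      zyg <- "het"; p2 <- outlier_pvalue(recnt, g2)
    }
  }

  call <- structure(list(gene = gene, allele1 = g1, p1 = p1,
                         allele2 = g2, p2 = p2, zygosity = zyg,
                         c1 = c1, c2 = c2, rpkm = 0),
                    class = "locus_call")
  call$rpkm <- compute_expression(call, cnt, gc$total_sample_reads, ref)
  call
}

#' Call the genotype of one HLA locus
#'
#' Two-pass call. Pass 1: the group with the highest read count becomes
#' `allele1` (ties broken lexicographically and logged) with its outlier
#' p-value. Pass 2: every read that hit any allele of `allele1`'s group is
#' removed, the remaining reads are recounted, and the new argmax becomes
#' `allele2`. The locus is homozygous when no reads remain or the
#' second-pass count falls below `hom_ratio` times the pass-1 top count;
#' `nocall` when the gene received no reads at all.
#'
#' @param spec A `sample_spec`.
#' @param ref An `allele_reference`.
#' @param gene Gene symbol to call.
#' @param max_mismatches,hom_ratio See [typing_params()].
#' @param counts Optional precomputed `group_counts` (skips re-alignment).
#' @return A `locus_call`: `gene`, `allele1`, `p1`, `allele2`, `p2`,
#'   `zygosity` (`"het"`, `"hom"` or `"nocall"`), supporting counts
#'   `c1`/`c2` and `rpkm`.
#' @export
call_locus <- function(spec, ref, gene, max_mismatches = 2L, hom_ratio = 0.05,
                       counts = NULL) {
  stopifnot(gene %in% ref$genes)
  if (is.null(counts)) counts <- count_group_hits(spec, ref, max_mismatches)
  .call_locus_counts(counts, ref, gene, hom_ratio)
}

#' RPKM expression estimate for a called locus
#'
#' `rpkm = 1e9 * c_locus / (L * total_reads)` where `c_locus` sums the
#' pass-1 read counts of the called group(s) and `L` is the mean cDNA
#' length of the reference alleles of those groups. A `nocall` locus has
#' expression 0.
#'
#' @param call A `locus_call`.
#' @param counts Named pass-1 count vector for the gene.
#' @param total_reads Total reads (single-end) or pairs (paired-end)
#'   processed in the sample.
#' @param ref An `allele_reference`.
#' @return Non-negative RPKM value.
#' @export
compute_expression <- function(call, counts, total_reads, ref) {
  if (call$zygosity == "nocall" || total_reads <= 0) return(0)
  grp <- unique(c(call$allele1,
                  if (call$zygosity == "het") call$allele2))
  c_locus <- sum(counts[grp])
  L <- mean(nchar(ref$records$sequence[ref$records$group4 %in% grp]))
  1e9 * c_locus / (L * total_reads)
}

#' Type one sample across all selected genes
#'
#' Aligns the sample once and performs the two-pass locus call for every
#' gene of the reference. Deterministic given identical inputs; the single-
#' versus paired-end code path is dispatched automatically from the sample
#' layout.
#'
#' @param spec A `sample_spec`.
#' @param ref An `allele_reference` (already gene-selected).
#' @param params See [typing_params()].
#' @return A `sample_typing`: `sample_id`, `layout`, `total_reads`,
#'   `n_skipped` and `calls`, one `locus_call` per gene.
#' @export
type_sample <- function(spec, ref, params = typing_params()) {
  gc <- count_group_hits(spec, ref, params$max_mismatches)
  calls <- lapply(setNames(ref$genes, ref$genes), function(g) {
    .call_locus_counts(gc, ref, g, params$hom_ratio)
  })
  structure(list(sample_id = spec$sample_id, layout = spec$layout,
                 total_reads = gc$total_sample_reads,
                 n_skipped = gc$n_skipped, calls = calls),
            class = "sample_typing")
}

#' @export
print.sample_typing <- function(x, ...) {
  cat(sprintf("HLA typing of '%s' (%s, %d %s)\n", x$sample_id, x$layout,
              x$total_reads, if (x$layout == "paired") "pairs" else "reads"))
  for (cl in x$calls) {
    cat(sprintf("  %-5s %-12s p=%-9.3g %-12s p=%-9.3g %-6s rpkm=%.1f\n",
                cl$gene,
                ifelse(is.na(cl$allele1), "-", cl$allele1), cl$p1,
                ifelse(is.na(cl$allele2), "-", cl$allele2), cl$p2,
                cl$zygosity, cl$rpkm))
  }
  invisible(x)
}
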