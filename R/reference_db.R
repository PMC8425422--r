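#' Supported HLA genes
#'
#' The six classical HLA genes with the highest allelic variability: class I
#' \emph{HLA-A, -B, -C} and class II \emph{HLA-DPB1, -DQB1, -DRB1}. All
#' typing, comparison and simulation in this package operates on (a subset
#' of) these genes; alleles of any other gene found in a reference FASTA are
#' dropped at load time.
#'
#' @return Character vector of the six gene symbols, in canonical order.
#' @export
hla_genes <- function() c("A", "B", "C", "DPB1", "DQB1", "DRB1")

# Full allele name: optional "HLA-" prefix, gene, "*", >= 2 numeric fields,
# optional expression-status suffix letter (e.g. "A*24:09N").
.allele_name_pattern <- "^(HLA-)?[A-Z]+[0-9]*\\*[0-9]+:[0-9]+(:[0-9]+)*[NLSCAQ]?$"

#' Reduce an HLA allele name to its four-digit group
#'
#' Four-digit resolution (`GENE*XX:YY`) identifies a specific HLA protein;
#' deeper fields denote synonymous or non-coding variation. The reduction
#' keeps the gene and the first two colon-separated numeric fields and is
#' idempotent.
#'
#' @param allele_name Character vector of allele names such as
#'   `"A*01:01:01:01"`; an optional `"HLA-"` prefix and a trailing
#'   expression-status letter are tolerated.
#' @return Character vector of four-digit group names, e.g. `"A*01:01"`.
#' @examples
#' reduce_to_group(c("A*01:01:01:01", "B*07:02", "DRB1*15:01:01"))
#' @export
reduce_to_group <- function(allele_name) {
  if (!length(allele_name)) return(character(0))
  ok <- grepl(.allele_name_pattern, allele_name)
  if (any(!ok)) {
    stop("malformed HLA allele name(s): ",
         paste(utils::head(allele_name[!ok], 3), collapse = ", "))
  }
  x <- sub("^HLA-", "", allele_name)
  sub("^([A-Z]+[0-9]*\\*[0-9]+:[0-9]+).*$", "\\1", x)
}

.gene_of_allele <- function(allele_name) {
  sub("\\*.*$", "", sub("^HLA-", "", allele_name))
}

# Scan whitespace-separated header tokens for the first allele-name token.
# Accepts both bare headers (">A*01:01:01:01") and IMGT-style headers
# (">HLA:HLA00001 A*01:01:01:01 1098 bp").
.extract_allele_token <- function(headers) {
  vapply(strsplit(trimws(headers), "\\s+"), function(toks) {
    hit <- toks[grepl(.allele_name_pattern, toks)]
    if (length(hit)) sub("^HLA-", "", hit[[1L]]) else NA_character_
  }, character(1))
}

.new_allele_reference <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("gene", "allele_name", "group4", "sequence") %in% names(records)))
  genes <- intersect(hla_genes(), unique(records$gene))
  structure(
    list(records = records,
         genes = genes,
         groups_by_gene = lapply(setNames(genes, genes), function(g) {
           sort(unique(records$group4[records$gene == g]))
         })),
    class = "allele_reference")
}

#' Parse an HLA allele reference FASTA
#'
#' Reads cDNA sequences of known HLA alleles from a FASTA file (plain or
#' gzip-compressed), extracts the allele name from each header, reduces it
#' to its four-digit group and keeps only alleles of the supported genes
#' (see [hla_genes()]). Sequences are uppercased and must contain only
#' `A`, `C`, `G`, `T` or `N`.
#'
#' @param path Path to a FASTA file, optionally `.gz`.
#' @return An `allele_reference` object: a list with `records` (data frame
#'   with columns `gene`, `allele_name`, `group4`, `sequence`), `genes`
#'   (ordered character vector) and `groups_by_gene`.
#' @export
parse_allele_fasta <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  # read as raw strings: DNAStringSet would silently drop invalid letters,
  # and we want them to be a loud format error instead
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("cannot read FASTA '", path, "': ",
                                            conditionMessage(e)))
  if (!length(seqs)) stop("no parsable allele headers in '", path, "'")

  allele <- .extract_allele_token(names(seqs))
  if (all(is.na(allele))) stop("no parsable allele headers in '", path, "'")
  if (any(is.na(allele))) {
    warning(sum(is.na(allele)), " FASTA record(s) without a recognizable ",
            "allele name dropped")
    seqs <- seqs[!is.na(allele)]
    allele <- allele[!is.na(allele)]
  }

  gene <- .gene_of_allele(allele)
  supported <- gene %in% hla_genes()
  if (any(!supported)) {
    message("dropping ", sum(!supported), " allele(s) of unsupported gene(s): ",
            paste(unique(gene[!supported]), collapse = ", "))
    seqs <- seqs[supported]; allele <- allele[supported]; gene <- gene[supported]
  }
  if (!length(allele)) stop("no alleles of supported HLA genes in '", path, "'")

  if (anyDuplicated(allele)) {
    warning("duplicate allele name(s) in reference, keeping first occurrence: ",
            paste(unique(allele[duplicated(allele)]), collapse = ", "))
    keep <- !duplicated(allele)
    seqs <- seqs[keep]; allele <- allele[keep]; gene <- gene[keep]
  }

  sequence <- toupper(as.character(seqs))
  badchar <- grepl("[^ACGTN]", sequence)
  if (any(badchar)) {
    stop("non-ACGTN characters in reference sequence(s): ",
         paste(utils::head(allele[badchar], 3), collapse = ", "))
  }
  if (any(nchar(sequence) == 0)) stop("empty sequence in reference")

  .new_allele_reference(data.frame(
    gene = gene,
    allele_name = allele,
    group4 = reduce_to_group(allele),
    sequence = unname(sequence),
    stringsAsFactors = FALSE))
}

#' Write an allele reference back to FASTA
#'
#' Headers are the full allele names; a `.gz` suffix triggers gzip
#' compression. Mainly used to materialize synthetic references for the
#' pipeline, which takes a FASTA path as input.
#'
#' @param ref An `allele_reference`.
#' @param path Output path (`.fasta` or `.fasta.gz`).
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "allele_reference"))
  x <- Biostrings::DNAStringSet(setNames(ref$records$sequence,
                                         ref$records$allele_name))
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Subset an allele reference by gene
#'
#' The default gene panel excludes \emph{DQB1} (five genes): it has the
#' lowest expression of the six in typical RNA-seq libraries, which hurts
#' the confidence of its typing. `gene_count = 6` adds it back; an explicit
#' `custom` gene list overrides both.
#'
#' @param ref An `allele_reference`.
#' @param gene_count 5 (drop DQB1) or 6 (all genes). Ignored when `custom`
#'   is given.
#' @param custom Optional character vector, a non-empty subset of
#'   [hla_genes()].
#' @return An `allele_reference` restricted to the selected genes.
#' @export
select_genes <- function(ref, gene_count = 5, custom = NULL) {
  stopifnot(inherits(ref, "allele_reference"))
  if (!is.null(custom)) {
    if (!length(custom) || !all(custom %in% hla_genes())) {
      stop("custom gene list must be a non-empty subset of: ",
           paste(hla_genes(), collapse = ", "))
    }
    keep <- custom
  } else {
    if (!gene_count %in% c(5, 6)) stop("gene_count must be 5 or 6")
    keep <- if (gene_count == 5) setdiff(hla_genes(), "DQB1") else hla_genes()
  }
  .new_allele_reference(ref$records[ref$records$gene %in% keep, , drop = FALSE])
}

#' @export
print.allele_reference <- function(x, ...) {
  cat("HLA allele reference:", nrow(x$records), "alleles,",
      length(unique(x$records$group4)), "four-digit groups\n")
  for (g in x$genes) {
    n <- sum(x$records$gene == g)
    cat(sprintf("  %-5s %4d alleles, %4d groups\n", g, n,
                length(x$groups_by_gene[[g]])))
  }
  invisible(x)
}
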