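#' Filter a sample typing by confidence
#'
#' Keeps an allele slot iff its p-value is strictly below `p_threshold`.
#' A homozygous call contributes the allele twice (two slots) when `p1`
#' passes; a heterozygous call contributes each allele independently. The
#' default `0.05` suits paired-end cohorts; `0.5` is recommended for
#' single-end layouts, whose p-values are computed the same way but from
#' noisier single-mate evidence.
#'
#' @param typing A `sample_typing`.
#' @param p_threshold Confidence threshold in `(0, 1]`.
#' @return An `allele_profile`: `sample_id`, `alleles` (per gene, a
#'   character multiset of 0-2 four-digit groups) and `n_confident`.
#' @export
filter_alleles <- function(typing, p_threshold = 0.05) {
  stopifnot(inherits(typing, "sample_typing"),
            p_threshold > 0, p_threshold <= 1)
  alleles <- lapply(typing$calls, function(cl) {
    if (cl$zygosity == "nocall") return(character(0))
    if (cl$zygosity == "hom") {
      return(if (cl$p1 < p_threshold) c(cl$allele1, cl$allele1) else character(0))
    }
    c(if (cl$p1 < p_threshold) cl$allele1,
      if (cl$p2 < p_threshold) cl$allele2)
  })
  structure(list(sample_id = typing$sample_id, alleles = alleles,
                 n_confident = sum(lengths(alleles))),
            class = "allele_profile")
}

# size of the multiset intersection of two character vectors
.multiset_shared <- function(x, y) {
  u <- union(x, y)
  sum(pmin(tabulate(match(x, u), length(u)),
           tabulate(match(y, u), length(u))))
}

#' Pairwise HLA identity between two allele profiles
#'
#' Over the genes where both profiles carry at least one confident slot:
#' `shared` sums the per-gene multiset intersections and `comparable` the
#' per-gene minimum slot counts, so a locus that failed the confidence
#' filter in one sample does not penalize the pair and `shared <=
#' comparable` always holds. `percent = 100 * shared / comparable` (0 when
#' nothing is comparable).
#'
#' @param a,b `allele_profile` objects built from the same gene selection.
#' @return An `identity_cell` list: `shared`, `comparable`, `percent`.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(inherits(a, "allele_profile"), inherits(b, "allele_profile"))
  genes <- intersect(names(a$alleles)[lengths(a$alleles) > 0],
                     names(b$alleles)[lengths(b$alleles) > 0])
  shared <- 0L
  comparable <- 0L
  for (g in genes) {
    shared <- shared + .multiset_shared(a$alleles[[g]], b$alleles[[g]])
    comparable <- comparable + min(length(a$alleles[[g]]),
                                   length(b$alleles[[g]]))
  }
  structure(list(shared = shared, comparable = comparable,
                 percent = if (comparable > 0) 100 * shared / comparable else 0),
            class = "identity_cell")
}

#' Build the squared study-wide identity matrix
#'
#' Cross-compares every couple of samples. The matrix is symmetric and the
#' diagonal is 100 for every sample with at least one confident allele.
#' Samples with zero confident alleles are retained (their cells have
#' `comparable = 0` and percent 0) and reported via a message.
#'
#' @param profiles List of `allele_profile` objects.
#' @return An `identity_matrix`: `sample_ids`, numeric `percent` matrix,
#'   integer `shared` and `comparable` matrices, and per-sample `totals`
#'   of confident allele slots.
#' @export
build_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids in cohort")
  n <- length(ids)
  pct <- matrix(0, n, n, dimnames = list(ids, ids))
  shr <- cmp <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      cell <- pairwise_identity(profiles[[i]], profiles[[j]])
      pct[i, j] <- pct[j, i] <- cell$percent
      shr[i, j] <- shr[j, i] <- cell$shared
      cmp[i, j] <- cmp[j, i] <- cell$comparable
    }
  }
  totals <- vapply(profiles, `[[`, numeric(1), "n_confident")
  names(totals) <- ids
  if (any(totals == 0)) {
    message("sample(s) with zero confident alleles: ",
            paste(ids[totals == 0], collapse = ", "))
  }
  structure(list(sample_ids = ids, percent = pct, shared = shr,
                 comparable = cmp, totals = totals),
            class = "identity_matrix")
}

#' Group samples by identity threshold
#'
#' Single-linkage clustering: clusters are the connected components of the
#' graph that joins two samples whenever their pairwise identity reaches
#' `threshold_pct`. Recommended thresholds: 80 for paired-end cohorts, 70
#' for single-end.
#'
#' @param matrix An `identity_matrix`.
#' @param threshold_pct Identity threshold in percent.
#' @return List of character vectors (sample ids), ordered by first sample.
#' @export
group_samples <- function(matrix, threshold_pct = 80) {
  stopifnot(inherits(matrix, "identity_matrix"))
  n <- length(matrix$sample_ids)
  adj <- matrix$percent >= threshold_pct
  diag(adj) <- TRUE
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lapply(split(matrix$sample_ids, comp), unname)
}

.check_labels <- function(truth, ids) {
  if (is.data.frame(truth)) {
    cols <- intersect(c("sample_id", "subject"), names(truth))
    if (length(cols) != 2) stop("labels need 'sample_id' and 'subject' columns")
    truth <- setNames(as.character(truth$subject), truth$sample_id)
  }
  missing <- setdiff(ids, names(truth))
  if (length(missing)) {
    stop("missing subject label for sample(s): ",
         paste(missing, collapse = ", "))
  }
  truth[ids]
}

#' Evaluate declared sample labels against the identity matrix
#'
#' Treats each unordered sample pair as predicted same-source when its
#' identity reaches a threshold `t`, sweeps `t` over every observed percent
#' value plus 0 and 100, and picks the `t` maximizing the F1 score
#' (harmonic mean of precision and recall over pairs; ties resolved to the
#' largest, most conservative, threshold). Samples whose highest-identity
#' partner at the chosen threshold belongs to a different declared subject
#' are flagged as candidate mislabels.
#'
#' @param matrix An `identity_matrix`.
#' @param truth Named character vector (`sample_id -> subject`) or a data
#'   frame with columns `sample_id` and `subject`; every matrix sample must
#'   be labeled.
#' @return An `eval_result`: chosen `threshold_pct`, `precision`, `recall`,
#'   `f1`, `confusion` (TP, FP, FN, TN), the full `sweep` data frame and
#'   `mislabel_flags` (data frame `sample_id`, `declared_subject`,
#'   `best_matching_group`).
#' @export
evaluate_labels <- function(matrix, truth) {
  stopifnot(inherits(matrix, "identity_matrix"))
  ids <- matrix$sample_ids
  truth <- .check_labels(truth, ids)
  n <- length(ids)
  if (n < 2) stop("need at least two samples to evaluate labels")

  iu <- which(upper.tri(matrix$percent), arr.ind = TRUE)
  pct <- matrix$percent[iu]
  same <- truth[iu[, 1]] == truth[iu[, 2]]

  thresholds <- sort(unique(c(0, 100, pct)))
  sweep <- do.call(rbind, lapply(thresholds, function(t) {
    pred <- pct >= t
    tp <- sum(pred & same); fp <- sum(pred & !same)
    fn <- sum(!pred & same); tn <- sum(!pred & !same)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(threshold = t, precision = prec, recall = rec, f1 = f1,
               TP = tp, FP = fp, FN = fn, TN = tn)
  }))

  best <- max(sweep$f1)
  chosen <- sweep[sweep$f1 == best, , drop = FALSE]
  chosen <- chosen[which.max(chosen$threshold), , drop = FALSE]

  flags <- list()
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    j <- others[order(-matrix$percent[i, others], ids[others],
                      method = "radix")][1]
    if (matrix$percent[i, j] >= chosen$threshold && truth[i] != truth[j]) {
      flags[[length(flags) + 1L]] <- data.frame(
        sample_id = ids[i], declared_subject = unname(truth[i]),
        best_matching_group = unname(truth[j]), stringsAsFactors = FALSE)
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(sample_id = character(0), declared_subject = character(0),
               best_matching_group = character(0), stringsAsFactors = FALSE)

  structure(list(threshold_pct = chosen$threshold,
                 precision = chosen$precision, recall = chosen$recall,
                 f1 = chosen$f1,
                 confusion = c(TP = chosen$TP, FP = chosen$FP,
                               FN = chosen$FN, TN = chosen$TN),
                 sweep = sweep, mislabel_flags = flags),
            class = "eval_result")
}

#' Check the HLA allele diversity of a cohort
#'
#' Counts the distinct four-digit alleles across all confident slots.
#' Cohorts drawn from populations with fewer than 50 distinct alleles are
#' of low diversity: between-individual identity rises and the QC grouping
#' loses resolution, so a warning is raised.
#'
#' @param profiles List of `allele_profile` objects.
#' @return A `diversity_report`: `n_alleles`, `low_diversity`, `threshold`.
#' @export
check_diversity <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  alleles <- unique(unlist(lapply(profiles, function(p) unlist(p$alleles)),
                           use.names = FALSE))
  n <- length(alleles)
  low <- n < 50L
  if (low) {
    warning("low HLA diversity: only ", n, " distinct alleles in the cohort ",
            "(< 50); sample-identity QC may be unreliable")
  }
  structure(list(n_alleles = n, low_diversity = low, threshold = 50L),
            class = "diversity_report")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat("HLA identity matrix:", length(x$sample_ids), "samples\n")
  print(round(x$percent, 1))
  invisible(x)
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("label evaluation: threshold %.1f%%, precision %.3f, recall %.3f, F1 %.3f\n",
              x$threshold_pct, x$precision, x$recall, x$f1))
  if (nrow(x$mislabel_flags)) {
    cat("candidate mislabels:\n")
    print(x$mislabel_flags, row.names = FALSE)
  } else cat("no mislabels flagged\n")
  invisible(x)
}
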