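test_that("load_frequency_table validates genes, sums and positivity", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tallele\tfrequency",
               "A\tA*01:01\t0.6",
               "A\tA*02:01\t0.4"), f)
  tab <- load_frequency_table(f)
  expect_equal(tab$freq$A, c("A*01:01" = 0.6, "A*02:01" = 0.4))

  writeLines(c("gene\tallele\tfrequency", "A\tA*01:01\t0.7"), f)
  expect_error(load_frequency_table(f), "sum to")

  writeLines(c("gene\tallele\tfrequency", "A\tA*01:01\t-0.2",
               "A\tA*02:01\t1.2"), f)
  expect_error(load_frequency_table(f), "finite and > 0")

  writeLines(c("gene\tallele\tfrequency", "DRA\tDRA*01:01\t1.0"), f)
  expect_error(load_frequency_table(f), "unknown gene")

  # gene-relative allele names are accepted
  writeLines(c("gene\tallele\tfrequency", "B\t07:02\t1.0"), f)
  expect_equal(names(load_frequency_table(f)$freq$B), "B*07:02")
})

test_that("adjust_frequencies fills missing alleles at 0.001 and renormalizes", {
  set.seed(51)
  ref <- make_ref(sprintf("A*%02d:01", 1:4), replicate(4, rand_seq(100)))
  tab <- structure(list(freq = list(A = c("A*01:01" = 0.6, "A*02:01" = 0.4))),
                   class = "frequency_table")
  adj <- adjust_frequencies(tab, ref)
  # oracle: direct arithmetic on the stated rule
  raw <- c("A*01:01" = 0.6, "A*02:01" = 0.4, "A*03:01" = 0.001,
           "A*04:01" = 0.001)
  expect_equal(adj$freq$A[names(raw)], raw / sum(raw), tolerance = 1e-12)
  expect_equal(sum(adj$freq$A), 1, tolerance = 1e-9)

  # no missing alleles -> unchanged
  full <- structure(list(freq = list(A = setNames(rep(0.25, 4),
                                                  sprintf("A*%02d:01", 1:4)))),
                    class = "frequency_table")
  expect_equal(adjust_frequencies(full, ref)$freq$A, full$freq$A)

  # conservation property across random tables
  for (i in 1:10) {
    x <- runif(2) + 0.1
    t2 <- structure(list(freq = list(A = setNames(x / sum(x),
                                                  sprintf("A*%02d:01", 1:2)))),
                    class = "frequency_table")
    expect_equal(sum(adjust_frequencies(t2, ref)$freq$A), 1, tolerance = 1e-9)
  }
})

test_that("sample_genotype performs Hardy-Weinberg draws at the table frequencies", {
  set.seed(52)
  ref <- make_ref(c("A*01:01", "A*02:01"), replicate(2, rand_seq(100)))
  tab <- structure(list(freq = list(A = c("A*01:01" = 0.7, "A*02:01" = 0.3))),
                   class = "frequency_table")
  draws <- unlist(lapply(1:10000, function(i) sample_genotype(tab, ref)$A$group4))
  expect_equal(mean(draws == "A*01:01"), 0.7, tolerance = 0.02)

  # degenerate table: always homozygous
  tab1 <- structure(list(freq = list(A = c("A*01:01" = 1))),
                    class = "frequency_table")
  gt <- sample_genotype(tab1, ref)
  expect_equal(gt$A$group4, c("A*01:01", "A*01:01"))

  # determinism under a fixed seed
  set.seed(99); g1 <- sample_genotype(tab, ref)
  set.seed(99); g2 <- sample_genotype(tab, ref)
  expect_identical(g1, g2)
})

test_that("error-free simulated reads are exact substrings of truth alleles", {
  dir <- withr::local_tempdir()
  set.seed(53)
  ref <- make_ref(c("A*01:01", "A*02:01"), replicate(2, rand_seq(400)))
  gt <- structure(list(A = data.frame(group4 = c("A*01:01", "A*02:01"),
                                      allele_name = c("A*01:01", "A*02:01"))),
                  class = "genotype")
  p <- sim_params(n_individuals = 2, read_length = 75, layout = "single",
                  error_rate = 0, expr_weights = c(A = 1))
  sim <- simulate_sample(gt, p, ref, dir, "clean", n_reads = 200)
  reads <- read_fastq(sim$files[1])$seq
  expect_length(reads, 200)
  ok <- vapply(reads, function(rd) {
    any(vapply(ref$records$sequence, function(S) {
      grepl(rd, S, fixed = TRUE) || grepl(rc_str(rd), S, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("substitution errors occur at the stated rate", {
  dir <- withr::local_tempdir()
  set.seed(54)
  S <- rand_seq(400)
  ref <- make_ref("A*01:01", S)
  gt <- structure(list(A = data.frame(group4 = rep("A*01:01", 2),
                                      allele_name = rep("A*01:01", 2))),
                  class = "genotype")
  p <- sim_params(n_individuals = 2, read_length = 75, layout = "single",
                  error_rate = 0.01, expr_weights = c(A = 1))
  sim <- simulate_sample(gt, p, ref, dir, "noisy", n_reads = 500)
  reads <- read_fastq(sim$files[1])$seq

  # independent measurement: minimum Hamming distance over every window
  # and both strands of the single source allele
  chars <- strsplit(S, "")[[1]]
  win <- t(vapply(seq_len(400 - 75 + 1),
                  function(st) chars[st:(st + 74)], character(75)))
  min_mm <- vapply(reads, function(rd) {
    m <- Inf
    for (ori in c(rd, rc_str(rd))) {
      v <- strsplit(ori, "")[[1]]
      m <- min(m, min(rowSums(sweep(win, 2, v, "!="))))
    }
    m
  }, numeric(1))
  expect_lt(abs(mean(min_mm) / 75 - 0.01), 0.002)
})

test_that("paired-end simulation writes proper mates at both read lengths", {
  dir <- withr::local_tempdir()
  set.seed(55)
  ref <- make_ref("B*01:01", rand_seq(500))
  gt <- structure(list(B = data.frame(group4 = rep("B*01:01", 2),
                                      allele_name = rep("B*01:01", 2))),
                  class = "genotype")
  for (L in c(75L, 100L)) {
    p <- sim_params(n_individuals = 2, read_length = L, layout = "paired",
                    error_rate = 0, expr_weights = c(B = 1))
    sim <- simulate_sample(gt, p, ref, dir, paste0("pe", L), n_reads = 100)
    expect_length(sim$files, 2)
    r1 <- read_fastq(sim$files[1])$seq
    r2 <- read_fastq(sim$files[2])$seq
    expect_true(all(nchar(c(r1, r2)) == L))
    expect_equal(sim$reads_generated, 100)
  }

  # fragments longer than the allele are shrunk with a warning
  shortref <- make_ref("B*01:01", rand_seq(150))
  p <- sim_params(n_individuals = 2, read_length = 75, layout = "paired",
                  error_rate = 0, expr_weights = c(B = 1),
                  frag_mean = 200, frag_sd = 10)
  expect_warning(simulate_sample(gt, p, shortref, dir, "short", n_reads = 20),
                 "shrunk")
})

test_that("simulate_cohort respects ranges and is byte-reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  ref <- synthetic_reference(n_groups = 5, seq_length = 400, seed = 56)
  freq <- synthetic_frequency_table(ref, seed = 57)
  p <- sim_params(n_individuals = 3, samples_range = c(1, 2),
                  reads_range = c(1000, 2000), error_rate = 0.005, seed = 58)
  s1 <- simulate_cohort(p, freq, ref, dir1)
  s2 <- simulate_cohort(p, freq, ref, dir2)

  expect_true(all(s1$truth$reads_generated >= 999 &
                    s1$truth$reads_generated <= 2000))
  tab <- table(s1$truth$individual_id)
  expect_true(all(tab >= 1 & tab <= 2))
  expect_identical(s1$truth, s2$truth)

  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("synthetic references have pairwise-distinct, parseable alleles", {
  ref <- synthetic_reference(n_groups = 20, genes = c("A", "B"),
                             seq_length = 300, seed = 59)
  expect_equal(nrow(ref$records), 40)
  expect_false(anyDuplicated(ref$records$sequence) > 0)
  expect_equal(unique(nchar(ref$records$sequence)), 300)
  # names round-trip through the nomenclature reducer
  expect_identical(reduce_to_group(ref$records$allele_name), ref$records$group4)
  # frequency table over it is a valid distribution
  ft <- synthetic_frequency_table(ref, seed = 60)
  expect_equal(unname(vapply(ft$freq, sum, 1)), c(1, 1), tolerance = 1e-9)
  # round-trip through the TSV loader
  f <- tempfile(fileext = ".tsv")
  write_frequency_table(ft, f)
  back <- load_frequency_table(f)
  expect_equal(back$freq$A, ft$freq$A, tolerance = 1e-6)
})

test_that("low allele diversity degrades between-individual separation", {
  # diverse world: 40 groups/gene over 3 genes; restricted world: 4/gene
  # (24 alleles in total, well under the 50-allele guidance)
  run_cohort <- function(n_groups, seed) {
    dir <- tempfile("cohort")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    ref <- synthetic_reference(n_groups = n_groups, genes = c("A", "B", "C"),
                               seq_length = 400, seed = seed)
    freq <- synthetic_frequency_table(ref, seed = seed + 1)
    p <- sim_params(n_individuals = 4, samples_range = c(1, 2),
                    reads_range = c(3000, 3000), error_rate = 0.005,
                    seed = seed + 2,
                    expr_weights = c(A = 1, B = 1, C = 0.8))
    sim <- simulate_cohort(p, freq, ref, dir)
    specs <- discover_samples(dir)
    profs <- lapply(specs, function(s) filter_alleles(type_sample(s, ref), 0.05))
    m <- build_matrix(profs)
    truth <- setNames(sim$truth$individual_id, sim$truth$sample_id)
    iu <- which(upper.tri(m$percent), arr.ind = TRUE)
    between <- truth[m$sample_ids[iu[, 1]]] != truth[m$sample_ids[iu[, 2]]]
    mean(m$percent[iu][between])
  }
  diverse <- run_cohort(40, seed = 61)
  restricted <- run_cohort(4, seed = 61)
  expect_gt(restricted, diverse)
})
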