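#' @keywords internal
.is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# Compression is detected from magic bytes, not the file extension.
.fastq_connection <- function(path) {
  if (.is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a FASTQ file
#'
#' Strict 4-line-record parser. Quality strings are validated for length but
#' otherwise ignored: typing uses alignment mismatch counts only.
#'
#' @param path FASTQ file, plain or gzip-compressed (detected by content).
#' @return List with `id` (read names, up to the first whitespace) and
#'   `seq` (uppercased sequences).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- .fastq_connection(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record at end of '", path, "' (", n, " lines)")
  }
  if (n == 0L) return(list(id = character(0), seq = character(0)))
  ids  <- lines[seq(1L, n, 4L)]
  seqs <- lines[seq(2L, n, 4L)]
  plus <- lines[seq(3L, n, 4L)]
  qual <- lines[seq(4L, n, 4L)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+") |
                 nchar(qual) != nchar(seqs))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], " in '", path, "'")
  }
  list(id = sub("\\s.*$", "", substring(ids, 2L)), seq = toupper(seqs))
}

.strip_fastq_ext <- function(x) sub("\\.(fastq|fq)(\\.gz)?$", "", x, ignore.case = TRUE)

.probe_read_length <- function(path) {
  con <- .fastq_connection(path)
  on.exit(close(con))
  rec <- readLines(con, n = 2L, warn = FALSE)
  if (length(rec) < 2L) return(NA_integer_)
  nchar(rec[2L])
}

.new_sample_spec <- function(sample_id, layout, files, read_length) {
  structure(list(sample_id = sample_id, layout = layout,
                 files = files, read_length = read_length),
            class = "sample_spec")
}

#' Discover RNA-seq samples in a folder
#'
#' Finds `.fastq`/`.fq` files (optionally `.gz`), pairs mates by filename
#' stem plus a trailing mate token (`_R1`/`_R2`, `_1`/`_2` or `.1`/`.2`) and
#' auto-detects single- versus paired-end layout per sample. A mate token
#' without its partner is demoted to single-end with a warning. Samples are
#' returned in lexicographic order of their id; file contents are not read
#' beyond a first-record read-length probe.
#'
#' @param folder Directory containing raw FASTQ files.
#' @return List of `sample_spec` objects (`sample_id`, `layout`, `files`,
#'   `read_length`).
#' @export
discover_samples <- function(folder) {
  if (!dir.exists(folder)) stop("input folder not found: ", folder)
  files <- list.files(folder, pattern = "\\.(fastq|fq)(\\.gz)?$",
                      full.names = TRUE, ignore.case = TRUE)
  if (!length(files)) stop("no samples found: no FASTQ files in '", folder, "'")

  stem <- .strip_fastq_ext(basename(files))
  mate_pat <- "^(.*)(_R[12]|_[12]|\\.[12])$"
  has_tok <- grepl(mate_pat, stem)
  base <- stem
  mate <- rep(NA_integer_, length(stem))
  base[has_tok] <- sub(mate_pat, "\\1", stem[has_tok])
  tok <- sub(mate_pat, "\\2", stem[has_tok])
  mate[has_tok] <- ifelse(grepl("1$", tok), 1L, 2L)

  specs <- list()
  for (b in unique(base)) {
    idx <- which(base == b)
    m1 <- idx[!is.na(mate[idx]) & mate[idx] == 1L]
    m2 <- idx[!is.na(mate[idx]) & mate[idx] == 2L]
    if (length(m1) == 1L && length(m2) == 1L && length(idx) == 2L) {
      specs[[b]] <- .new_sample_spec(b, "paired", c(files[m1], files[m2]),
                                     .probe_read_length(files[m1]))
    } else {
      if (any(!is.na(mate[idx]))) {
        warning("unpaired mate token for stem '", b,
                "'; treating file(s) as single-end")
      }
      for (i in idx) {
        specs[[stem[i]]] <- .new_sample_spec(stem[i], "single", files[i],
                                             .probe_read_length(files[i]))
      }
    }
  }
  specs[order(names(specs), method = "radix")]
}

#' Load the reads of a sample
#'
#' Materializes the read sequences of a sample. For paired-end samples the
#' two mate files are consumed in lockstep and must contain the same number
#' of records.
#'
#' @param spec A `sample_spec` from [discover_samples()].
#' @return For single-end: list with `ids` and `reads`. For paired-end:
#'   list with `ids`, `reads1` and `reads2`.
#' @export
stream_reads <- function(spec) {
  stopifnot(inherits(spec, "sample_spec"))
  if (spec$layout == "single") {
    r <- read_fastq(spec$files[[1L]])
    list(ids = r$id, reads = r$seq)
  } else {
    r1 <- read_fastq(spec$files[[1L]])
    r2 <- read_fastq(spec$files[[2L]])
    if (length(r1$seq) != length(r2$seq)) {
      stop("mate files of sample '", spec$sample_id,
           "' differ in record count (", length(r1$seq), " vs ",
           length(r2$seq), ")")
    }
    list(ids = r1$id, reads1 = r1$seq, reads2 = r2$seq)
  }
}

#' @export
print.sample_spec <- function(x, ...) {
  cat(sprintf("sample '%s' [%s, %s bp]: %s\n", x$sample_id, x$layout,
              ifelse(is.na(x$read_length), "?", x$read_length),
              paste(basename(x$files), collapse = " + ")))
  invisible(x)
}
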