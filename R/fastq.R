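#' Read a FASTQ file
#'
#' Minimal strict FASTQ reader (phred+33, gzip-transparent).  Records must
#' be four lines; sequence and quality must have equal length.  Files that
#' look phred+64-encoded (a majority of quality characters above `'J'`,
#' i.e. Q > 41 under phred+33) are rejected rather than silently
#' converted.
#'
#' @param path Path to a FASTQ file (`.gz` accepted).
#' @return A data.frame with columns `read_id` (header line without the
#'   leading `@`), `seq`, `qual` (phred+33 string).
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4",
                 path, n))
  if (n == 0L)
    return(data.frame(read_id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  hdr <- lines[seq(1L, n, by = 4L)]
  seq <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': line %d does not start with '@'",
                 path, (bad[1] - 1L) * 4L + 1L))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': line %d does not start with '+'",
                 path, (bad[1] - 1L) * 4L + 3L))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop(sprintf(
      "malformed FASTQ '%s': sequence/quality length mismatch at line %d",
      path, (bad[1] - 1L) * 4L + 2L))
  qr <- range(utf8ToInt(paste(qual[seq_len(min(1000L, n %/% 4L))],
                              collapse = "")))
  if (qr[1] < 33L)
    stop(sprintf("'%s': quality character below '!' is not valid phred+33",
                 path))
  qc <- utf8ToInt(paste(qual[seq_len(min(1000L, n %/% 4L))], collapse = ""))
  if (mean(qc > 74L) > 0.5)
    stop(sprintf(
      "'%s' looks phred+64 encoded (most quality characters above 'J'); %s",
      path, "re-encode to phred+33 before use"))
  data.frame(read_id = substring(hdr, 2L), seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

#' Load paired FASTQ files as read pairs
#'
#' Reads two FASTQ files record by record and pairs them positionally,
#' verifying that the identifiers match after stripping a trailing `/1`,
#' `/2` or anything from the first whitespace on.
#'
#' @param path1,path2 Paths to the R1 and R2 FASTQ files.
#' @return A data.frame with columns `read_id` (the shared stem), `seq1`,
#'   `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  if (nrow(r1) != nrow(r2))
    stop(sprintf(
      "unequal record counts: '%s' has %d records, '%s' has %d (first missing record at position %d)",
      path1, nrow(r1), path2, nrow(r2), min(nrow(r1), nrow(r2)) + 1L))
  id1 <- strip_pair_suffix(r1$read_id)
  id2 <- strip_pair_suffix(r2$read_id)
  bad <- which(id1 != id2)
  if (length(bad))
    stop(sprintf("read ID mismatch at record %d: '%s' vs '%s'",
                 bad[1], id1[bad[1]], id2[bad[1]]))
  data.frame(read_id = id1, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

strip_pair_suffix <- function(ids) {
  ids <- sub("[ \t].*$", "", ids)
  sub("/[12]$", "", ids)
}

#' Write a FASTQ file
#'
#' @param x A data.frame with columns `read_id`, `seq`, `qual` (phred+33).
#' @param path Output path; a `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(x)))
  rec <- paste0("@", x$read_id, "\n", x$seq, "\n+\n", x$qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Write paired reads to two FASTQ files
#'
#' @param pairs A data.frame as returned by [read_fastq_pairs()] or
#'   [simulate_reads()].
#' @param path1,path2 Output paths for R1 and R2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_fastq(data.frame(read_id = paste0(pairs$read_id, "/1"),
                         seq = pairs$seq1, qual = pairs$qual1,
                         stringsAsFactors = FALSE), path1)
  write_fastq(data.frame(read_id = paste0(pairs$read_id, "/2"),
                         seq = pairs$seq2, qual = pairs$qual2,
                         stringsAsFactors = FALSE), path2)
  invisible(c(path1, path2))
}
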