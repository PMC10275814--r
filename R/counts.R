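#' Per-sample barcode count table
#'
#' The unit of all downstream assessment: one row per distinct barcode
#' with its read count and within-sample frequency, optionally a UMI
#' (molecule) count.  Rows are ordered by decreasing count, ties broken by
#' barcode string.
#'
#' @param barcode Character vector of distinct barcode sequences.
#' @param count Positive integer read counts, same length.
#' @param sample_id Sample label stored as an attribute.
#' @param umi_count Optional integer molecule counts.
#' @return A data.frame of class `count_table` with columns `barcode`,
#'   `count`, (`umi_count`,) `frequency`.
#' @export
count_table <- function(barcode, count, sample_id = "sample",
                        umi_count = NULL) {
  barcode <- as.character(barcode)
  count <- as.integer(count)
  if (anyDuplicated(barcode)) stop("barcodes must be unique within a sample")
  if (length(count) != length(barcode)) stop("barcode/count length mismatch")
  if (length(count) && any(count < 1L)) stop("counts must be >= 1")
  df <- data.frame(barcode = barcode, count = count,
                   stringsAsFactors = FALSE)
  if (!is.null(umi_count)) {
    stopifnot(length(umi_count) == length(barcode))
    df$umi_count <- as.integer(umi_count)
  }
  df$frequency <- if (nrow(df)) df$count / sum(df$count) else numeric()
  ord <- order(-df$count, df$barcode)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "sample_id") <- as.character(sample_id)
  class(df) <- c("count_table", "data.frame")
  df
}

#' @export
print.count_table <- function(x, n = 10L, ...) {
  cat(sprintf("<count_table> sample '%s': %d barcodes, %d reads\n",
              sample_id(x), nrow(x), sum(x$count)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("  ... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Sample label of a count table
#' @param x A [count_table()].
#' @return The sample id string.
#' @export
sample_id <- function(x) attr(x, "sample_id") %||% "sample"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a count table as TSV
#'
#' Tab-separated columns `barcode`, `count`, (`umi_count`,) `frequency`,
#' preceded by a `# sample_id:` comment line.  Frequencies are written at
#' full precision so that `read_count_table(write_count_table(x))`
#' reproduces `x` (counts exactly, frequencies to well below 1e-9).
#'
#' @param table A [count_table()].
#' @param path Output TSV path.
#' @return `write_count_table` returns `path` invisibly;
#'   `read_count_table` returns a [count_table()].
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# sample_id: %s", sample_id(table)), con)
  df <- as.data.frame(table)
  if ("frequency" %in% names(df))
    df$frequency <- sprintf("%.17g", df$frequency)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1L)
  sid <- if (startsWith(first, "# sample_id:"))
    trimws(sub("^# sample_id:", "", first)) else "sample"
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c(barcode = "character"),
                          stringsAsFactors = FALSE)
  if (!all(c("barcode", "count") %in% names(df)))
    stop(sprintf("'%s' is not a count table (need barcode/count columns)",
                 path))
  if (anyDuplicated(df$barcode))
    stop(sprintf("duplicate barcode rows in '%s': %s", path,
                 df$barcode[anyDuplicated(df$barcode)]))
  count_table(df$barcode, df$count, sample_id = sid,
              umi_count = df[["umi_count"]])
}
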