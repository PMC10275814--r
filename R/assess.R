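#' Barcode set intersections across replicates (UpSet-style)
#'
#' Assigns every barcode in the union to the exact subset of replicates
#' containing it and counts each non-empty subset, the tabulation behind
#' an UpSet plot.
#'
#' @param tables A list of two or more [count_table()]s; names (or sample
#'   ids) label the replicates.
#' @return A data.frame with columns `subset` (e.g. `"R1&R3"`), `degree`
#'   and `n_barcodes`, covering every non-empty subset (zeros included).
#'   The counts sum to the size of the barcode union.
#' @export
replicate_intersections <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need at least two count tables to intersect")
  labels <- replicate_labels(tables)
  sets <- lapply(tables, function(t) t$barcode)
  union_bc <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) union_bc %in% s,
                   logical(length(union_bc)))
  if (length(union_bc) == 1L) member <- matrix(member, nrow = 1L)
  key <- apply(member, 1L, function(m) paste(labels[m], collapse = "&"))
  k <- length(labels)
  subsets <- unlist(lapply(seq_len(k), function(d)
    utils::combn(labels, d, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  cnt <- table(factor(key, levels = subsets))
  data.frame(subset = subsets,
             degree = lengths(strsplit(subsets, "&", fixed = TRUE)),
             n_barcodes = as.integer(cnt[subsets]),
             stringsAsFactors = FALSE)
}

replicate_labels <- function(tables) {
  labels <- names(tables)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(tables, sample_id, character(1))
  if (anyDuplicated(labels))
    labels <- paste0("R", seq_along(tables))
  labels
}

#' Pearson correlation of barcode frequencies between two samples
#'
#' Correlates the frequency vectors of two count tables, either over the
#' barcodes shared by both samples (`scope = "shared"`, the default) or
#' over the union with absent barcodes entered as frequency 0
#' (`"union_with_zeros"`).  The scope and number of points are always
#' part of the result; a zero-variance vector yields a result flagged
#' undefined rather than `NaN`.
#'
#' @param a,b Two [count_table()]s.
#' @param scope `"shared"` or `"union_with_zeros"`.
#' @return A list with `r`, `n`, `scope` and `defined`.
#' @export
pairwise_frequency_correlation <- function(a, b,
                                           scope = c("shared",
                                                     "union_with_zeros")) {
  scope <- match.arg(scope)
  fa <- stats::setNames(a$frequency, a$barcode)
  fb <- stats::setNames(b$frequency, b$barcode)
  bcs <- if (scope == "shared") intersect(a$barcode, b$barcode)
  else union(a$barcode, b$barcode)
  x <- ifelse(is.na(fa[bcs]), 0, fa[bcs])
  y <- ifelse(is.na(fb[bcs]), 0, fb[bcs])
  n <- length(bcs)
  if (n < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = n, scope = scope, defined = FALSE))
  list(r = stats::cor(x, y), n = n, scope = scope, defined = TRUE)
}

#' Diversity and evenness of a barcode library
#'
#' Shannon entropy (nats) of the frequency distribution, evenness
#' (entropy over its maximum `ln(unique_count)`, defined for more than
#' one barcode), and the largest single-barcode frequency.
#'
#' @param table A non-empty [count_table()].
#' @return A list with `unique_count`, `shannon_entropy`, `evenness`,
#'   `max_frequency`.
#' @export
diversity_metrics <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (!nrow(table)) stop("diversity of an empty table is undefined")
  f <- table$frequency
  h <- -sum(f * log(f))
  n <- nrow(table)
  list(unique_count = n, shannon_entropy = h,
       evenness = if (n > 1L) h / log(n) else NA_real_,
       max_frequency = max(f))
}

#' Barcode length spectrum
#'
#' Normalised histogram of observed barcode lengths with the fraction
#' inside the accepted window (`barcode_len` &plusmn; `len_tol`, i.e.
#' 23--27 bp at defaults) -- the length-threshold analysis applied before
#' counting.
#'
#' @param x A `barcode_observations` data.frame (all observations with a
#'   barcode are used, including `bad_length`) or an integer vector of
#'   barcode lengths.
#' @param construct A [barcode_construct()] providing the window.
#' @return A list with `histogram` (data.frame `length`/`n`/`frequency`),
#'   `within_tolerance` and `window`.
#' @export
length_spectrum <- function(x, construct = example_construct()) {
  stopifnot(inherits(construct, "barcode_construct"))
  lens <- if (is.numeric(x)) as.integer(x)
  else nchar(x$barcode[!is.na(x$barcode)])
  w <- barcode_length_window(construct)
  if (!length(lens)) {
    return(list(histogram = data.frame(length = integer(), n = integer(),
                                       frequency = numeric()),
                within_tolerance = NA_real_, window = w))
  }
  tab <- table(lens)
  hist <- data.frame(length = as.integer(names(tab)),
                     n = as.integer(tab),
                     frequency = as.integer(tab) / length(lens))
  list(histogram = hist,
       within_tolerance = mean(lens >= w[1] & lens <= w[2]),
       window = w)
}

#' Barcode frequency trajectories across ordered samples
#'
#' Builds the union-of-barcodes by time-point frequency matrix from a
#' time-ordered list of count tables (absent barcodes have frequency 0)
#' and returns it in long format, ready to write as TSV for downstream
#' lineage-dynamics inference.
#'
#' @param tables Time-ordered list of two or more [count_table()]s.
#' @return A data.frame with columns `barcode`, `time` (1-based index, or
#'   the list names), `frequency`.
#' @export
frequency_trajectories <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need at least two time points")
  times <- if (!is.null(names(tables)) && all(nzchar(names(tables))))
    names(tables) else as.character(seq_along(tables))
  union_bc <- unique(unlist(lapply(tables, function(t) t$barcode),
                            use.names = FALSE))
  out <- do.call(rbind, lapply(seq_along(tables), function(i) {
    f <- stats::setNames(tables[[i]]$frequency, tables[[i]]$barcode)
    v <- f[union_bc]
    data.frame(barcode = union_bc, time = times[i],
               frequency = ifelse(is.na(v), 0, v),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Replicate quality-assessment report
#'
#' Runs the full assessment battery over two or more replicate count
#' tables: per-replicate unique counts and diversity, all pairwise
#' Pearson frequency correlations (shared scope, with union-with-zeros
#' also reported whenever it differs by more than 0.01), and UpSet-style
#' subset intersections.  Length spectra can be attached by passing the
#' extraction observations.
#'
#' @param tables List of two or more [count_table()]s.
#' @param observations Optional list of `barcode_observations` matching
#'   `tables`, used for length spectra.
#' @param construct A [barcode_construct()] for the length window.
#' @return An object of class `replicate_report`.
#' @export
assess_replicates <- function(tables, observations = NULL,
                              construct = example_construct()) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need at least two replicates")
  labels <- replicate_labels(tables)
  names(tables) <- labels
  k <- length(tables)
  div <- lapply(tables, diversity_metrics)
  rmat <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(rmat) <- 1
  pair_details <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sh <- pairwise_frequency_correlation(tables[[i]], tables[[j]],
                                         "shared")
    un <- pairwise_frequency_correlation(tables[[i]], tables[[j]],
                                         "union_with_zeros")
    rmat[i, j] <- rmat[j, i] <- sh$r
    pair_details[[paste(labels[i], labels[j], sep = "~")]] <-
      list(shared = sh,
           union_with_zeros =
             if (!sh$defined || !un$defined ||
                 abs(sh$r - un$r) > 0.01) un else NULL)
  }
  spectra <- if (!is.null(observations))
    lapply(observations, length_spectrum, construct = construct)
  report <- list(
    labels = labels,
    unique_counts = vapply(tables, nrow, integer(1)),
    diversity = div,
    correlations = rmat,
    correlation_details = pair_details,
    intersections = replicate_intersections(tables),
    length_spectra = spectra)
  class(report) <- "replicate_report"
  report
}

#' @export
print.replicate_report <- function(x, ...) {
  cat(sprintf("<replicate_report> %d replicates\n", length(x$labels)))
  cat("unique barcodes:\n")
  print(x$unique_counts)
  ev <- vapply(x$diversity, function(d) d$evenness, numeric(1))
  cat(sprintf("evenness: %s\n",
              paste(sprintf("%s=%.3f", x$labels, ev), collapse = "  ")))
  cat("pairwise Pearson r (shared barcodes):\n")
  print(round(x$correlations, 4))
  full <- x$intersections[x$intersections$degree == length(x$labels), ]
  cat(sprintf("barcodes in all replicates: %d of %d (%.1f%%)\n",
              full$n_barcodes, sum(x$intersections$n_barcodes),
              100 * full$n_barcodes / sum(x$intersections$n_barcodes)))
  invisible(x)
}

#' Plot a replicate report
#'
#' Base-graphics panels: UpSet-style intersection bars, and (when length
#' spectra are attached) the barcode length spectrum with the tolerance
#' window marked.
#'
#' @param x A `replicate_report`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.replicate_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$length_spectra)) 1 else 2),
                      mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  ints <- x$intersections
  graphics::barplot(ints$n_barcodes, names.arg = ints$subset, las = 2,
                    ylab = "barcodes", main = "replicate intersections",
                    cex.names = 0.7)
  if (!is.null(x$length_spectra)) {
    sp <- x$length_spectra[[1]]
    graphics::plot(sp$histogram$length, sp$histogram$frequency,
                   type = "h", lwd = 4, xlab = "barcode length (bp)",
                   ylab = "frequency", main = "length spectrum")
    graphics::abline(v = sp$window + c(-0.5, 0.5), lty = 3)
  }
  invisible(x)
}
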