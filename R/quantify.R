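#' Count barcodes into a per-sample table
#'
#' Tallies identical barcode strings among length-filtered observations;
#' frequency is count over total kept reads.
#'
#' @param observations A `barcode_observations` data.frame (only
#'   status-`ok` rows are counted) or a character vector of barcodes.
#' @param sample_id Sample label for the resulting table.
#' @return A [count_table()]; empty input gives an empty table.
#' @export
count_barcodes <- function(observations, sample_id = "sample") {
  bcs <- if (is.character(observations)) observations
  else observations$barcode[observations$status == "ok"]
  bcs <- bcs[!is.na(bcs)]
  if (!length(bcs))
    return(count_table(character(), integer(), sample_id = sample_id))
  tab <- table(bcs)
  count_table(names(tab), as.integer(tab), sample_id = sample_id)
}

#' Collapse reads to molecules by UMI
#'
#' Counts, per barcode, the number of distinct UMIs (exact match) among
#' its reads -- an estimate of the number of founder molecules, since
#' UMIs attach before amplification.  The per-barcode read/molecule ratio
#' distribution (the amplification-bias report) is attached as attribute
#' `"umi_bias"`.  Reads without an intact UMI contribute to read counts
#' but not to molecule counts.
#'
#' @param observations A `barcode_observations` data.frame with `barcode`
#'   and `umi` columns (status-`ok` rows are used).
#' @param sample_id Sample label.
#' @return A [count_table()] with an extra `umi_count` column.
#' @export
umi_collapse <- function(observations, sample_id = "sample") {
  ok <- observations[observations$status == "ok" &
                       !is.na(observations$barcode), , drop = FALSE]
  if (nrow(ok) && all(is.na(ok$umi)))
    stop("no observation carries a UMI; use count_barcodes() for raw counts")
  tab <- table(ok$barcode)
  has_umi <- !is.na(ok$umi)
  mol <- tapply(ok$umi[has_umi], ok$barcode[has_umi],
                function(u) length(unique(u)))
  umi_count <- as.integer(mol[names(tab)])
  umi_count[is.na(umi_count)] <- 0L
  out <- count_table(names(tab), as.integer(tab), sample_id = sample_id,
                     umi_count = umi_count)
  bias <- data.frame(barcode = out$barcode, count = out$count,
                     umi_count = out$umi_count,
                     ratio = ifelse(out$umi_count > 0,
                                    out$count / out$umi_count, NA_real_),
                     stringsAsFactors = FALSE)
  attr(out, "umi_bias") <- bias
  out
}

#' Cluster sequencing-error barcodes into their parents
#'
#' Directional merging: a barcode `b` is absorbed into a cluster when some
#' cluster member is within `max_dist` edit distance of `b` and the
#' cluster's accumulated count is at least `count_ratio` times `count(b)`.
#' Barcodes are processed in decreasing count order (ties broken
#' lexicographically); absorbed counts add to the absorber, so error
#' chains collapse onto the true barcode.  Passes repeat until the table
#' is stable, which makes the operation idempotent.  This is an extension
#' beyond raw-barcode analysis: counting defaults to no clustering.
#'
#' @param table A [count_table()].
#' @param max_dist Maximum edit (Levenshtein) distance to a cluster
#'   member (default 2).
#' @param count_ratio Required absorber/absorbed count ratio (default 5).
#' @return A [count_table()] of cluster seeds; total counts are conserved
#'   and frequencies recomputed.
#' @export
cluster_barcodes <- function(table, max_dist = 2L, count_ratio = 5) {
  stopifnot(inherits(table, "count_table"))
  max_dist <- as.integer(max_dist)
  if (max_dist < 1L) stop("max_dist must be >= 1")
  has_umi <- "umi_count" %in% names(table)
  repeat {
    new <- cluster_pass(table, max_dist, count_ratio, has_umi)
    if (nrow(new) == nrow(table)) break
    table <- new
  }
  new
}

cluster_pass <- function(table, max_dist, count_ratio, has_umi) {
  n <- nrow(table)
  if (n <= 1L) return(table)
  ord <- order(-table$count, table$barcode)
  bcs <- table$barcode[ord]
  cnt <- as.numeric(table$count[ord])
  umi <- if (has_umi) as.numeric(table$umi_count[ord])
  D <- utils::adist(bcs)
  members <- vector("list", n)   # per cluster: indices into ord-space
  totals <- numeric(n)
  seed <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    target <- 0L
    if (k > 0L) {
      best_d <- max_dist + 1L
      best_total <- -1
      for (cl in seq_len(k)) {
        if (totals[cl] < count_ratio * cnt[i]) next
        d <- min(D[i, members[[cl]]])
        if (d < best_d || (d == best_d && totals[cl] > best_total)) {
          best_d <- d
          best_total <- totals[cl]
          target <- cl
        }
      }
      if (best_d > max_dist) target <- 0L
    }
    if (target == 0L) {
      k <- k + 1L
      members[[k]] <- i
      totals[k] <- cnt[i]
      seed[k] <- i
    } else {
      members[[target]] <- c(members[[target]], i)
      totals[target] <- totals[target] + cnt[i]
    }
  }
  cl_seed <- seed[seq_len(k)]
  cl_count <- vapply(members[seq_len(k)], function(m) sum(cnt[m]),
                     numeric(1))
  cl_umi <- if (has_umi)
    vapply(members[seq_len(k)], function(m) sum(umi[m]), numeric(1))
  count_table(bcs[cl_seed], as.integer(cl_count),
              sample_id = sample_id(table),
              umi_count = if (has_umi) as.integer(cl_umi))
}
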