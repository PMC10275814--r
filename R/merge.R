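#' Merge paired-end reads by quality-aware overlap consensus
#'
#' Read 2 is reverse-complemented into template orientation, every
#' suffix-prefix overlap of length at least `min_overlap` is scored by its
#' number of matching bases (`N` never matches), and among candidates
#' whose mismatch fraction is at most `max_mismatch_frac` the
#' highest-scoring overlap is chosen (ties: the longest overlap, which at
#' fixed read lengths is also the smallest offset).  The consensus keeps
#' the higher-quality base at each overlap disagreement and assigns that
#' quality; at equal quality read 1's base is kept with quality
#' `max(q1, q2) - 3`.  Outside the overlap, bases and qualities are copied
#' from their source read.  Pairs with no acceptable overlap are rejected
#' with reason `"no_overlap"`; merged sequences shorter than
#' `min_merged_len` are rejected with `"too_short_after_merge"`.
#'
#' @param pairs A data.frame with columns `read_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2` (phred+33), as from [read_fastq_pairs()] or
#'   [simulate_reads()].
#' @param min_overlap Minimum overlap length in bp (default 20).
#' @param max_mismatch_frac Maximum mismatches/overlap (default 0.1).
#' @param min_merged_len Minimum merged length (default 0 = off).
#' @return A data.frame of class `merged_reads`: `read_id`, `seq`, `qual`,
#'   `overlap_len`, `n_mismatches`, `status`
#'   (`"merged"`/`"no_overlap"`/`"too_short_after_merge"`).  `seq` is `NA`
#'   for rejected pairs; every input pair appears exactly once.
#' @export
merge_pairs <- function(pairs, min_overlap = 20L, max_mismatch_frac = 0.1,
                        min_merged_len = 0L) {
  stopifnot(all(c("read_id", "seq1", "qual1", "seq2", "qual2") %in%
                  names(pairs)))
  res <- cpp_merge_pairs(pairs$seq1, pairs$qual1, pairs$seq2, pairs$qual2,
                         as.integer(min_overlap), max_mismatch_frac,
                         as.integer(min_merged_len))
  out <- data.frame(
    read_id = pairs$read_id, seq = res$seq, qual = res$qual,
    overlap_len = res$overlap_len, n_mismatches = res$n_mismatches,
    status = c("merged", "no_overlap", "too_short_after_merge")[
      res$status + 1L],
    stringsAsFactors = FALSE)
  class(out) <- c("merged_reads", "data.frame")
  out
}

#' Merge a single read pair
#'
#' Scalar convenience wrapper around [merge_pairs()].
#'
#' @param seq1,qual1,seq2,qual2 Read 1 / read 2 sequence and phred+33
#'   quality strings.
#' @inheritParams merge_pairs
#' @return A one-row list with `seq`, `qual`, `overlap_len`,
#'   `n_mismatches`, `status`.
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2, min_overlap = 20L,
                       max_mismatch_frac = 0.1, min_merged_len = 0L) {
  df <- merge_pairs(
    data.frame(read_id = "pair", seq1 = seq1, qual1 = qual1, seq2 = seq2,
               qual2 = qual2, stringsAsFactors = FALSE),
    min_overlap = min_overlap, max_mismatch_frac = max_mismatch_frac,
    min_merged_len = min_merged_len)
  as.list(df[1L, c("seq", "qual", "overlap_len", "n_mismatches",
                   "status")])
}

#' Summarise a merge run
#'
#' @param merged A `merged_reads` data.frame from [merge_pairs()].
#' @return A data.frame with one row per outcome (`merged`, rejection
#'   reasons) and its count.
#' @export
merge_summary <- function(merged) {
  tab <- table(factor(merged$status,
                      levels = c("merged", "no_overlap",
                                 "too_short_after_merge")))
  data.frame(outcome = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
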