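#' Orient reads by the left flank anchor
#'
#' Searches each sequence and its reverse complement for the left anchor
#' (the last `anchor_len` bases of the left flank) allowing up to
#' `max_flank_mismatches` mismatches, and returns the orientation in which
#' the anchor is found.  If both strands contain the anchor at the same
#' best score, the right anchor is consulted as a tie-break; a read tied
#' on both anchors is reported `ambiguous` and must be discarded, never
#' guessed.
#'
#' @param seqs Character vector of merged (or single-end) read sequences.
#' @param construct A [barcode_construct()].
#' @param max_flank_mismatches Anchor mismatch budget (default 1).
#' @return A data.frame with columns `seq` (oriented forward; `NA` when no
#'   anchor was found or the strand is ambiguous) and `strand`
#'   (`"forward"`, `"reverse"`, `"ambiguous"`, `"none"`).
#' @export
orient_reads <- function(seqs, construct, max_flank_mismatches = 1L) {
  stopifnot(inherits(construct, "barcode_construct"))
  seqs <- as.character(seqs)
  max_mm <- as.integer(max_flank_mismatches)
  la <- left_anchor(construct)
  rc <- cpp_revcomp(seqs)
  f <- cpp_scan_anchor(seqs, la, 1L, -1L)
  r <- cpp_scan_anchor(rc, la, 1L, -1L)
  fmm <- f[, 2]
  rmm <- r[, 2]
  strand <- rep("none", length(seqs))
  strand[fmm <= max_mm & fmm < rmm] <- "forward"
  strand[rmm <= max_mm & rmm < fmm] <- "reverse"
  tie <- which(fmm <= max_mm & rmm <= max_mm & fmm == rmm)
  if (length(tie)) {
    ra <- right_anchor(construct)
    ft <- cpp_scan_anchor(seqs[tie], ra, 1L, -1L)
    rt <- cpp_scan_anchor(rc[tie], ra, 1L, -1L)
    strand[tie] <- ifelse(ft[, 2] < rt[, 2], "forward",
                          ifelse(rt[, 2] < ft[, 2], "reverse",
                                 "ambiguous"))
  }
  out <- data.frame(seq = ifelse(strand == "forward", seqs,
                                 ifelse(strand == "reverse", rc,
                                        NA_character_)),
                    strand = strand, stringsAsFactors = FALSE)
  out
}

#' Extract barcodes between conserved flank anchors
#'
#' For each read: orient it by the left anchor, locate the best
#' approximate occurrence of the left anchor (leftmost at minimal
#' mismatches), then the best occurrence of the right anchor (the first
#' `anchor_len` bases of the right flank) downstream of it -- among
#' minimal-mismatch occurrences the one whose implied barcode length is
#' closest to the expected barcode length.  The barcode is the substring
#' strictly between the anchors.  The UMI is recorded when the prefix
#' upstream of the left flank has length `umi_len` plus one of the
#' construct's heterospacer lengths; otherwise it is `NA` (UMI absence
#' never fails a read).
#'
#' Every read receives exactly one status: `ok`, `no_left_anchor`,
#' `no_right_anchor` (also covers anchors in the wrong order),
#' `ambiguous_strand`, `bad_length` (a barcode was found but its length is
#' outside `barcode_len` &plusmn; `len_tol`; the barcode is still
#' reported, for length spectra), or `contains_N`.
#'
#' @param x A `merged_reads` data.frame from [merge_pairs()] (only rows
#'   with status `"merged"` are extracted; other rows keep their merge
#'   rejection as status `NA` barcode), or a character vector of
#'   sequences.
#' @param construct A [barcode_construct()].
#' @param max_flank_mismatches Anchor mismatch budget (default 1).
#' @param min_mean_quality Optional minimum mean phred quality over the
#'   barcode (default 0 = off); requires `x` to carry qualities.
#' @return A data.frame of class `barcode_observations` with columns
#'   `read_id`, `status`, `strand`, `barcode`, `umi`.
#' @export
extract_barcodes <- function(x, construct, max_flank_mismatches = 1L,
                             min_mean_quality = 0) {
  stopifnot(inherits(construct, "barcode_construct"))
  if (is.character(x)) {
    ids <- if (!is.null(names(x))) names(x) else
      sprintf("read%08d", seq_along(x))
    seqs <- unname(x)
    quals <- NULL
  } else {
    stopifnot(all(c("read_id", "seq") %in% names(x)))
    ids <- x$read_id
    seqs <- x$seq
    quals <- x[["qual"]]
  }
  n <- length(seqs)
  status <- rep("no_left_anchor", n)
  strand <- rep(NA_character_, n)
  barcode <- rep(NA_character_, n)
  umi <- rep(NA_character_, n)

  usable <- !is.na(seqs)
  ori <- orient_reads(seqs[usable], construct, max_flank_mismatches)
  strand[usable] <- ori$strand
  status[usable][ori$strand == "ambiguous"] <- "ambiguous_strand"
  status[!usable] <- "no_left_anchor"

  idx <- which(usable)[ori$strand %in% c("forward", "reverse")]
  if (length(idx)) {
    s <- ifelse(strand[idx] == "forward", seqs[idx],
                cpp_revcomp(seqs[idx]))
    max_mm <- as.integer(max_flank_mismatches)
    a <- construct$anchor_len
    la <- left_anchor(construct)
    ra <- right_anchor(construct)
    lsc <- cpp_scan_anchor(s, la, 1L, -1L)
    lpos <- lsc[, 1]
    lend <- lpos + a - 1L
    # right anchor downstream; prefer the occurrence implying the
    # expected barcode length
    rsc <- cpp_scan_anchor(s, ra, lend + 1L,
                           lend + 1L + construct$barcode_len)
    found_r <- rsc[, 1] > 0 & rsc[, 2] <= max_mm
    st <- rep("no_right_anchor", length(idx))
    bc <- rep(NA_character_, length(idx))
    bc[found_r] <- substring(s[found_r], lend[found_r] + 1L,
                             rsc[found_r, 1] - 1L)
    w <- barcode_length_window(construct)
    has_n <- found_r & grepl("N", bc, fixed = TRUE)
    blen <- nchar(bc)
    inwin <- found_r & !has_n & blen >= w[1] & blen <= w[2]
    st[found_r] <- "bad_length"
    st[has_n] <- "contains_N"
    st[inwin] <- "ok"

    if (min_mean_quality > 0 && !is.null(quals)) {
      q <- quals[idx]
      qok <- which(inwin & !is.na(q))
      if (length(qok)) {
        mq <- vapply(qok, function(i) {
          qi <- qual_to_int(q[i])
          if (strand[idx][i] == "reverse") qi <- rev(qi)
          mean(qi[(lend[i] + 1L):(rsc[i, 1] - 1L)])
        }, numeric(1))
        st[qok[mq < min_mean_quality]] <- "low_quality"
      }
    }

    # UMI: intact fixed-length prefix upstream of the heterospacer
    flank_start <- lpos - (nchar(construct$left_flank) - a)
    prefix <- flank_start - 1L
    u_ok <- found_r & construct$umi_len > 0L &
      (prefix - construct$umi_len) %in% construct$heterospacer_lengths
    umi_i <- rep(NA_character_, length(idx))
    umi_i[u_ok] <- substring(s[u_ok], 1L, construct$umi_len)
    status[idx] <- st
    barcode[idx] <- bc
    umi[idx] <- umi_i
  }

  out <- data.frame(read_id = ids, status = status, strand = strand,
                    barcode = barcode, umi = umi,
                    stringsAsFactors = FALSE)
  class(out) <- c("barcode_observations", "data.frame")
  out
}

#' Filter observations by barcode length
#'
#' Keeps status-`ok` observations (whose length is within
#' `barcode_len` &plusmn; `len_tol` by construction) and reports the
#' length histogram over all observations where a barcode was found
#' (`ok` and `bad_length`), with the fraction inside the tolerance
#' window.
#'
#' @param observations A `barcode_observations` data.frame.
#' @param construct A [barcode_construct()].
#' @return A list with `kept` (the filtered observations) and `report`
#'   (list: `histogram` data.frame of `length`/`n`/`frequency`,
#'   `within_tolerance`, `window`).
#' @export
length_filter <- function(observations, construct) {
  stopifnot(inherits(construct, "barcode_construct"))
  kept <- observations[observations$status == "ok", , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- class(observations)
  report <- length_spectrum(observations, construct)
  list(kept = kept, report = report)
}
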