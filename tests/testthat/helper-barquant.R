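# Shared fixtures and independent oracles for the test suite.

# independent reverse complement (string-splitting, no package code)
rc_oracle <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

rand_qual <- function(len, lo = 2L, hi = 40L) {
  intToUtf8(sample(lo:hi, len, replace = TRUE) + 33L)
}

# Brute-force overlap-merge oracle: enumerate every suffix-prefix offset,
# apply the mismatch-fraction filter, pick max matches (ties: longest
# overlap), and build the consensus with the same higher-quality rule.
# Written independently of the package internals.
oracle_merge <- function(s1, q1, s2, q2, min_overlap, max_frac) {
  r2 <- rc_oracle(s2)
  qr2 <- paste(rev(strsplit(q2, "")[[1]]), collapse = "")
  a1 <- strsplit(s1, "")[[1]]; a2 <- strsplit(r2, "")[[1]]
  iq1 <- utf8ToInt(q1) - 33L; iq2 <- rev(utf8ToInt(q2) - 33L)
  l1 <- length(a1); l2 <- length(a2)
  best <- NULL
  for (ov in min(l1, l2):min_overlap) {
    x <- a1[(l1 - ov + 1):l1]; y <- a2[1:ov]
    match <- sum(x == y & x != "N")
    mm <- ov - match
    if (mm > max_frac * ov + 1e-9) next
    if (is.null(best) || match > best$match ||
        (match == best$match && ov > best$ov))
      best <- list(ov = ov, match = match, mm = mm)
  }
  if (is.null(best))
    return(list(status = "no_overlap", seq = NA_character_,
                qual = NA_character_, overlap_len = NA_integer_,
                n_mismatches = NA_integer_))
  ov <- best$ov
  seq <- c(a1[seq_len(l1 - ov)], character(ov), a2[-seq_len(ov)])
  q <- c(iq1[seq_len(l1 - ov)], integer(ov),
         iq2[-seq_len(ov)])
  for (j in seq_len(ov)) {
    b1 <- a1[l1 - ov + j]; b2 <- a2[j]
    e1 <- if (b1 == "N") 0L else iq1[l1 - ov + j]
    e2 <- if (b2 == "N") 0L else iq2[j]
    pos <- l1 - ov + j
    if (b1 == b2) { seq[pos] <- b1; q[pos] <- max(e1, e2) }
    else if (e1 > e2) { seq[pos] <- b1; q[pos] <- e1 }
    else if (e2 > e1) { seq[pos] <- b2; q[pos] <- e2 }
    else { seq[pos] <- b1; q[pos] <- max(0L, e1 - 3L) }
  }
  list(status = "merged", seq = paste(seq, collapse = ""),
       qual = intToUtf8(q + 33L), overlap_len = ov,
       n_mismatches = best$mm)
}

# small construct for fast unit tests: 30 bp flanks, full defaults
# otherwise
test_construct <- function() {
  barcode_construct(
    left_flank = "GATTACCACGGAGACCTGTTACCGGATCTG",
    right_flank = "CCTAAGGCAAGTCCGATTCACTGGCGGTAA")
}

# build a template read for extraction tests
template_for <- function(construct, barcode, umi = NULL, hs = "") {
  umi <- umi %||% paste(rep("A", construct$umi_len), collapse = "")
  paste0(umi, hs, construct$left_flank, barcode, construct$right_flank)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

obs_frame <- function(barcodes, statuses) {
  data.frame(read_id = sprintf("r%04d", seq_along(barcodes)),
             status = statuses, strand = "forward", barcode = barcodes,
             umi = NA_character_, stringsAsFactors = FALSE)
}
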