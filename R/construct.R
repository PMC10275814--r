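#' Describe a barcode cassette
#'
#' A `barcode_construct` records the geometry of the sequenced amplicon:
#' the conserved flanks either side of the random barcode, the expected
#' barcode length and its tolerance, the heterospacer lengths mixed into
#' the first-round primers, and the UMI (randomer) length.  The accepted
#' barcode length window is `[barcode_len - len_tol, barcode_len + len_tol]`,
#' i.e. 23--27 bp at the defaults.
#'
#' @param left_flank,right_flank Conserved DNA sequences (A/C/G/T only)
#'   immediately 5' and 3' of the barcode.
#' @param barcode_len Expected barcode length in bp (default 25).
#' @param len_tol Accepted deviation from `barcode_len` in bp (default 2).
#' @param heterospacer_lengths Integer vector of heterospacer lengths used
#'   in the library (default `0:2`).
#' @param umi_len Length of the unique molecular identifier prefix
#'   (default 8; 0 disables UMIs).
#' @param anchor_len Length of the flank suffix/prefix used as extraction
#'   anchors (default 12).
#' @return An object of class `barcode_construct`.
#' @seealso [example_construct()], [build_reference()]
#' @export
barcode_construct <- function(left_flank, right_flank,
                              barcode_len = 25L, len_tol = 2L,
                              heterospacer_lengths = 0:2,
                              umi_len = 8L, anchor_len = 12L) {
  stopifnot(is.character(left_flank), length(left_flank) == 1L,
            is.character(right_flank), length(right_flank) == 1L)
  if (!grepl("^[ACGT]+$", left_flank) || !grepl("^[ACGT]+$", right_flank))
    stop("flanks must be non-empty and contain only A/C/G/T")
  barcode_len <- as.integer(barcode_len)
  len_tol <- as.integer(len_tol)
  umi_len <- as.integer(umi_len)
  anchor_len <- as.integer(anchor_len)
  heterospacer_lengths <- sort(unique(as.integer(heterospacer_lengths)))
  if (barcode_len < 1L) stop("barcode_len must be >= 1")
  if (len_tol < 0L || len_tol >= barcode_len)
    stop("len_tol must satisfy 0 <= len_tol < barcode_len")
  if (umi_len < 0L) stop("umi_len must be >= 0")
  if (any(heterospacer_lengths < 0L))
    stop("heterospacer lengths must be >= 0")
  if (anchor_len < 1L ||
      anchor_len > min(nchar(left_flank), nchar(right_flank)))
    stop("anchor_len must be >= 1 and <= the length of both flanks")
  structure(
    list(left_flank = left_flank, right_flank = right_flank,
         barcode_len = barcode_len, len_tol = len_tol,
         heterospacer_lengths = heterospacer_lengths,
         umi_len = umi_len, anchor_len = anchor_len),
    class = "barcode_construct")
}

#' @export
print.barcode_construct <- function(x, ...) {
  w <- barcode_length_window(x)
  cat("<barcode_construct>\n")
  cat(sprintf("  left flank : %d bp (anchor ...%s)\n",
              nchar(x$left_flank), left_anchor(x)))
  cat(sprintf("  right flank: %d bp (anchor %s...)\n",
              nchar(x$right_flank), right_anchor(x)))
  cat(sprintf("  barcode    : %d bp (accepted %d-%d)\n",
              x$barcode_len, w[1], w[2]))
  cat(sprintf("  heterospacers: {%s}   UMI: %d bp\n",
              paste(x$heterospacer_lengths, collapse = ","), x$umi_len))
  invisible(x)
}

#' Packaged example cassette
#'
#' A ready-made construct with arbitrary (synthetic) 120-bp conserved
#' flanks, a 25-bp barcode, heterospacers of 0/1/2 nt and an 8-nt UMI --
#' the geometry of a typical chromosomal lineage-barcoding amplicon.  The
#' flank sequences are not any real vector's sequence; they were generated
#' once, screened so that neither anchor occurs approximately (within 2
#' mismatches) anywhere else in the construct or its reverse complement.
#'
#' @return A [barcode_construct()].
#' @export
example_construct <- function() {
  barcode_construct(
    left_flank = .barquant_example_flanks$left,
    right_flank = .barquant_example_flanks$right)
}

#' Reference amplicon for a construct
#'
#' Concatenates the flanks around an `N`-filled barcode placeholder, the
#' reference that reads map to conceptually: `left_flank`, `barcode_len`
#' times `N`, `right_flank`.
#'
#' @param construct A [barcode_construct()].
#' @return A single DNA string.
#' @export
build_reference <- function(construct) {
  stopifnot(inherits(construct, "barcode_construct"))
  paste0(construct$left_flank, strrep("N", construct$barcode_len),
         construct$right_flank)
}

#' Reverse complement DNA strings
#'
#' Vectorised reverse complement; characters other than A/C/G/T (either
#' case) become `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(x) {
  cpp_revcomp(as.character(x))
}

# anchor helpers ------------------------------------------------------------

left_anchor <- function(construct) {
  lf <- construct$left_flank
  substr(lf, nchar(lf) - construct$anchor_len + 1L, nchar(lf))
}

right_anchor <- function(construct) {
  substr(construct$right_flank, 1L, construct$anchor_len)
}

barcode_length_window <- function(construct) {
  c(construct$barcode_len - construct$len_tol,
    construct$barcode_len + construct$len_tol)
}

# internal: random DNA, used by the simulator and tests
random_dna <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# internal: phred+33 string <-> integer qualities
qual_to_int <- function(q) utf8ToInt(q) - 33L
int_to_qual <- function(q) intToUtf8(q + 33L)
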