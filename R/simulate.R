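#' Simulation configuration
#'
#' Parameters of the synthetic barcode-library and amplicon-read
#' generator.  Defaults describe a desk-scale version of a typical
#' lineage-barcoding library prep: 1,000 barcodes with lognormal
#' frequency skew, 150-bp paired-end reads, per-base substitution error
#' 0.1% and indel error 0.01%, about 1% barcode-free ancestral
#' contamination (the undigested-library level; a digested library is
#' < 0.001%), and 0/1/2-nt heterospacers with an 8-nt UMI taken from the
#' construct.
#'
#' @param n_barcodes Number of distinct barcodes in the library.
#' @param freq_model `"lognormal"` (skewed, the realistic default) or
#'   `"uniform"`.
#' @param sigma Lognormal sdlog for `freq_model = "lognormal"`.
#' @param n_read_pairs Number of read pairs to emit.
#' @param read_len Read length in bp (default 150).
#' @param sub_error_rate Per-base substitution error probability.
#' @param indel_error_rate Per-base indel error probability.
#' @param pcr_cycles Number of PCR cycles for the branching-process pool
#'   (used only with a finite `n_molecules`; protocols avoid > 18 total
#'   cycles).
#' @param pcr_efficiency Per-molecule per-cycle duplication probability.
#' @param n_molecules Initial template molecules for [simulate_pcr()].
#'   `NULL` (default) means a deep template pool: each read pair is an
#'   independent draw from the library truth, the realistic limit for
#'   nanogram-scale plasmid input.  A finite value routes reads through
#'   the amplified molecule pool, which adds PCR jackpot skew and makes
#'   UMI collapse informative.
#' @param ancestral_fraction Probability that a template carries no
#'   barcode (residual non-barcoded vector).
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_barcodes = 1000L,
                       freq_model = c("lognormal", "uniform"), sigma = 1,
                       n_read_pairs = 100000L, read_len = 150L,
                       sub_error_rate = 0.001, indel_error_rate = 1e-4,
                       pcr_cycles = 12L, pcr_efficiency = 0.6,
                       n_molecules = NULL, ancestral_fraction = 0.01,
                       seed = NULL) {
  freq_model <- match.arg(freq_model)
  n_barcodes <- as.integer(n_barcodes)
  n_read_pairs <- as.integer(n_read_pairs)
  read_len <- as.integer(read_len)
  pcr_cycles <- as.integer(pcr_cycles)
  if (n_barcodes < 1L) stop("n_barcodes must be >= 1")
  if (n_read_pairs < 0L) stop("n_read_pairs must be >= 0")
  if (read_len < 1L) stop("read_len must be >= 1")
  if (pcr_cycles < 0L) stop("pcr_cycles must be >= 0")
  for (p in c(sub_error_rate, indel_error_rate, pcr_efficiency,
              ancestral_fraction))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(n_molecules)) {
    n_molecules <- as.integer(n_molecules)
    if (n_molecules < 1L) stop("n_molecules must be >= 1")
  }
  structure(
    list(n_barcodes = n_barcodes, freq_model = freq_model, sigma = sigma,
         n_read_pairs = n_read_pairs, read_len = read_len,
         sub_error_rate = sub_error_rate,
         indel_error_rate = indel_error_rate, pcr_cycles = pcr_cycles,
         pcr_efficiency = pcr_efficiency, n_molecules = n_molecules,
         ancestral_fraction = ancestral_fraction,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

#' Generate a ground-truth barcode library
#'
#' Draws `n_barcodes` distinct uniform-random barcodes of the construct's
#' barcode length and assigns true frequencies from the configured model
#' (normalised lognormal draws, or exactly `1/n` for `"uniform"`).
#'
#' @param construct A [barcode_construct()].
#' @param cfg A [sim_config()].
#' @return An object of class `library_truth`: list with `barcodes` and
#'   `true_freq`.
#' @export
generate_library <- function(construct, cfg) {
  stopifnot(inherits(construct, "barcode_construct"),
            inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_barcodes
  len <- construct$barcode_len
  if (4^min(len, 30) < 4 * n)
    stop("barcode space 4^barcode_len too small for n_barcodes")
  bcs <- random_dna(n, len)
  for (i in seq_len(100L)) {
    dup <- duplicated(bcs)
    if (!any(dup)) break
    bcs[dup] <- random_dna(sum(dup), len)
  }
  if (anyDuplicated(bcs))
    stop("could not draw distinct barcodes after bounded redraws")
  f <- switch(cfg$freq_model,
              uniform = rep(1 / n, n),
              lognormal = {
                x <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$sigma)
                x / sum(x)
              })
  structure(list(barcodes = bcs, true_freq = f), class = "library_truth")
}

#' @export
print.library_truth <- function(x, ...) {
  cat(sprintf("<library_truth> %d barcodes, max frequency %.3g\n",
              length(x$barcodes), max(x$true_freq)))
  invisible(x)
}

#' Amplify a library through a branching-process PCR
#'
#' Samples `n_molecules` initial templates multinomially from the true
#' frequencies, attaches a distinct random UMI to each, then lets every
#' copy duplicate independently with probability `pcr_efficiency` in each
#' of `pcr_cycles` cycles (a Galton--Watson process; copies inherit the
#' founder's UMI).  Jackpot skew emerges from early lucky duplications
#' rather than from an ad-hoc parameter.
#'
#' @param truth A `library_truth` from [generate_library()].
#' @param cfg A [sim_config()]; `n_molecules` defaults to 10,000 if unset.
#' @param umi_len UMI length in bases (default 8; 0 disables UMIs).
#' @return A data.frame of class `pcr_pool`: one row per founder molecule
#'   with `barcode`, `umi` and final `copies`.
#' @export
simulate_pcr <- function(truth, cfg, umi_len = 8L) {
  stopifnot(inherits(truth, "library_truth"), inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_mol <- cfg$n_molecules %||% 10000L
  umi_len <- as.integer(umi_len)
  if (umi_len > 0L && n_mol > 4^umi_len)
    stop(sprintf(
      "cannot give %d molecules distinct %d-nt UMIs (only %d exist)",
      n_mol, umi_len, 4^umi_len))
  init <- as.integer(stats::rmultinom(1, n_mol, truth$true_freq))
  barcode <- rep(truth$barcodes, init)
  umi <- if (umi_len > 0L)
    umi_strings(sample.int(4^umi_len, n_mol) - 1L, umi_len)
  else rep(NA_character_, n_mol)
  copies <- rep(1L, n_mol)
  for (cyc in seq_len(cfg$pcr_cycles))
    copies <- copies + stats::rbinom(n_mol, copies, cfg$pcr_efficiency)
  out <- data.frame(barcode = barcode, umi = umi, copies = copies,
                    stringsAsFactors = FALSE)
  class(out) <- c("pcr_pool", "data.frame")
  out
}

# integer 0..4^len-1 -> DNA string of given length (base-4 digits)
umi_strings <- function(ints, len) {
  if (len == 0L) return(rep("", length(ints)))
  m <- matrix("", nrow = length(ints), ncol = len)
  x <- ints
  for (j in len:1) {
    m[, j] <- c("A", "C", "G", "T")[(x %% 4L) + 1L]
    x <- x %/% 4L
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate paired-end amplicon reads
#'
#' Emits `n_read_pairs` read pairs from templates of the form
#' `[UMI][heterospacer][left flank][barcode][right flank]`.  With
#' probability `ancestral_fraction` the barcode segment is absent
#' (residual non-barcoded vector).  Read 1 is the first `read_len` bases
#' of the template; read 2 is the reverse complement of the last
#' `read_len` bases.  Substitution and indel errors are applied per base;
#' qualities follow a two-tier model (Q37 for faithful bases, Q14 for
#' miscalled or inserted ones).
#'
#' @param truth A `library_truth`.
#' @param construct A [barcode_construct()].
#' @param cfg A [sim_config()].
#' @param out1,out2 Optional FASTQ paths; when given, the pair is written
#'   (phred+33).
#' @return A list of class `sim_reads`: `pairs` (data.frame with
#'   `read_id`, `seq1`, `qual1`, `seq2`, `qual2`), `emitted` (per-pair
#'   ground truth: `barcode` (`NA` for ancestral templates), `umi`,
#'   `heterospacer_len`, `ancestral`), `truth`, `config`, and `pool` (the
#'   [simulate_pcr()] molecule pool when `n_molecules` is finite, else
#'   `NULL`).
#' @export
simulate_reads <- function(truth, construct, cfg, out1 = NULL,
                           out2 = NULL) {
  stopifnot(inherits(truth, "library_truth"),
            inherits(construct, "barcode_construct"),
            inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_read_pairs
  umi_len <- construct$umi_len

  pool <- NULL
  if (is.null(cfg$n_molecules)) {
    idx <- sample.int(length(truth$barcodes), n, replace = TRUE,
                      prob = truth$true_freq)
    bc <- truth$barcodes[idx]
    umi <- if (umi_len > 0L)
      umi_strings(sample.int(4^umi_len, n, replace = TRUE) - 1L, umi_len)
    else rep("", n)
  } else {
    pool <- simulate_pcr(truth, cfg, umi_len = umi_len)
    mol <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$copies)
    bc <- pool$barcode[mol]
    umi <- if (umi_len > 0L) pool$umi[mol] else rep("", n)
  }

  ancestral <- stats::runif(n) < cfg$ancestral_fraction
  bc[ancestral] <- ""
  hs_set <- construct$heterospacer_lengths
  hs_len <- hs_set[sample.int(length(hs_set), n, replace = TRUE)]
  max_hs <- max(hs_set)
  hs <- if (max_hs > 0L)
    substring(random_dna(n, max_hs), 1L, hs_len) else rep("", n)

  amplicon <- paste0(umi, hs, construct$left_flank, bc,
                     construct$right_flank)
  alen <- nchar(amplicon)
  if (cfg$read_len > min(alen))
    stop(sprintf("read_len %d exceeds shortest template (%d bp)",
                 cfg$read_len, min(alen)))
  r1 <- substring(amplicon, 1L, cfg$read_len)
  r2 <- cpp_revcomp(substring(amplicon, alen - cfg$read_len + 1L, alen))

  if (cfg$sub_error_rate > 0 || cfg$indel_error_rate > 0) {
    m1 <- cpp_mutate_reads(r1, cfg$sub_error_rate, cfg$indel_error_rate,
                           37L, 14L)
    m2 <- cpp_mutate_reads(r2, cfg$sub_error_rate, cfg$indel_error_rate,
                           37L, 14L)
    q1 <- m1$qual; r1 <- m1$seq
    q2 <- m2$qual; r2 <- m2$seq
  } else {
    q37 <- strrep(rawToChar(as.raw(37L + 33L)), cfg$read_len)
    q1 <- rep(q37, n)
    q2 <- rep(q37, n)
  }

  ids <- sprintf("sim%08d", seq_len(n))
  pairs <- data.frame(read_id = ids, seq1 = r1, qual1 = q1, seq2 = r2,
                      qual2 = q2, stringsAsFactors = FALSE)
  emitted <- data.frame(
    read_id = ids,
    barcode = ifelse(ancestral, NA_character_, bc),
    umi = if (umi_len > 0L) umi else NA_character_,
    heterospacer_len = hs_len, ancestral = ancestral,
    stringsAsFactors = FALSE)
  if (!is.null(out1) && !is.null(out2))
    write_fastq_pairs(pairs, out1, out2)
  structure(list(pairs = pairs, emitted = emitted, truth = truth,
                 config = cfg, pool = pool),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf(
    "<sim_reads> %d read pairs from %d barcodes (%.2g%% ancestral)\n",
    nrow(x$pairs), length(x$truth$barcodes),
    100 * mean(x$emitted$ancestral)))
  invisible(x)
}

#' Write simulator ground truth as TSV
#'
#' @param truth A `library_truth`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_library_truth <- function(truth, path) {
  stopifnot(inherits(truth, "library_truth"))
  df <- data.frame(barcode = truth$barcodes,
                   true_freq = sprintf("%.17g", truth$true_freq),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
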