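#' Pipeline configuration
#'
#' Bundles the construct with the thresholds used by merging and
#' extraction.  All pipeline operations take explicit parameters; the
#' config is a convenience container that round-trips losslessly through
#' JSON.
#'
#' @param construct A [barcode_construct()].
#' @param min_overlap Minimum read-pair overlap accepted by the merger
#'   (bp, default 20).
#' @param max_mismatch_frac Maximum fraction of mismatching bases in the
#'   overlap (default 0.1).
#' @param max_flank_mismatches Mismatch budget for each 12-bp flank anchor
#'   during extraction (default 1).
#' @param min_merge_quality Minimum mean barcode quality for an extraction
#'   to count as ok (default 0 = off; the analogue of a mapping-quality
#'   floor).
#' @param random_seed Integer seed recorded for reproducibility.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(construct = example_construct(),
                            min_overlap = 20L, max_mismatch_frac = 0.1,
                            max_flank_mismatches = 1L,
                            min_merge_quality = 0L, random_seed = 1L) {
  stopifnot(inherits(construct, "barcode_construct"))
  min_overlap <- as.integer(min_overlap)
  max_flank_mismatches <- as.integer(max_flank_mismatches)
  min_merge_quality <- as.integer(min_merge_quality)
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (max_mismatch_frac < 0 || max_mismatch_frac > 1)
    stop("max_mismatch_frac must be in [0, 1]")
  if (max_flank_mismatches < 0L) stop("max_flank_mismatches must be >= 0")
  if (min_merge_quality < 0L) stop("min_merge_quality must be >= 0")
  structure(
    list(construct = construct, min_overlap = min_overlap,
         max_mismatch_frac = max_mismatch_frac,
         max_flank_mismatches = max_flank_mismatches,
         min_merge_quality = min_merge_quality,
         random_seed = as.integer(random_seed)),
    class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  min_overlap=%d  max_mismatch_frac=%.3g  %s=%d  seed=%d\n",
              x$min_overlap, x$max_mismatch_frac,
              "max_flank_mismatches", x$max_flank_mismatches,
              x$random_seed))
  print(x$construct)
  invisible(x)
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the reconstructed [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  flat <- list(
    left_flank = config$construct$left_flank,
    right_flank = config$construct$right_flank,
    barcode_len = config$construct$barcode_len,
    len_tol = config$construct$len_tol,
    heterospacer_lengths = config$construct$heterospacer_lengths,
    umi_len = config$construct$umi_len,
    anchor_len = config$construct$anchor_len,
    min_overlap = config$min_overlap,
    max_mismatch_frac = config$max_mismatch_frac,
    max_flank_mismatches = config$max_flank_mismatches,
    min_merge_quality = config$min_merge_quality,
    random_seed = config$random_seed)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    construct = barcode_construct(
      left_flank = j$left_flank, right_flank = j$right_flank,
      barcode_len = j$barcode_len, len_tol = j$len_tol,
      heterospacer_lengths = j$heterospacer_lengths,
      umi_len = j$umi_len, anchor_len = j$anchor_len),
    min_overlap = j$min_overlap,
    max_mismatch_frac = j$max_mismatch_frac,
    max_flank_mismatches = j$max_flank_mismatches,
    min_merge_quality = j$min_merge_quality,
    random_seed = j$random_seed)
}
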