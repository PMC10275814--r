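test_that("orientation recovers the strand of a read and its reverse complement", {
  ct <- test_construct()
  s <- template_for(ct, rand_dna(1, 25))
  fwd <- orient_reads(s, ct)
  expect_equal(fwd$strand, "forward")
  expect_equal(fwd$seq, s)
  rev <- orient_reads(rc_oracle(s), ct)
  expect_equal(rev$strand, "reverse")
  expect_equal(rev$seq, s)
})

test_that("anchors on both strands at equal score are ambiguous, never guessed", {
  ct <- test_construct()
  la <- barquant:::left_anchor(ct)
  # the anchor next to its own reverse complement: present at equal score
  # on both strands, and the right anchor on neither
  s <- paste0(la, "ACGTACGT", rc_oracle(la))
  o <- orient_reads(s, ct)
  expect_equal(o$strand, "ambiguous")
  obs <- extract_barcodes(s, ct)
  expect_equal(obs$status, "ambiguous_strand")
  expect_true(is.na(obs$barcode))
})

test_that("a clean embedded cassette extracts the exact barcode and UMI", {
  ct <- test_construct()
  bc <- rand_dna(1, 25)
  umi <- rand_dna(1, 8)
  for (hs in c("", "G", "TC")) {
    s <- template_for(ct, bc, umi = umi, hs = hs)
    obs <- extract_barcodes(s, ct)
    expect_equal(obs$status, "ok")
    expect_equal(obs$barcode, bc)
    expect_equal(obs$umi, umi)
  }
  # prefix that is not UMI + heterospacer sized: barcode ok, UMI absent
  s <- paste0(rand_dna(1, 12), ct$left_flank, bc, ct$right_flank)
  obs <- extract_barcodes(s, ct)
  expect_equal(obs$status, "ok")
  expect_true(is.na(obs$umi))
})

test_that("extraction results are identical across heterospacer lengths", {
  ct <- test_construct()
  bcs <- rand_dna(20, 25)
  res <- lapply(c("", "A", "GT"), function(hs) {
    obs <- extract_barcodes(
      vapply(bcs, function(b) template_for(ct, b, hs = hs),
             character(1)), ct)
    obs[, c("status", "barcode", "umi")]
  })
  expect_identical(res[[1]], res[[2]])
  expect_identical(res[[1]], res[[3]])
})

test_that("off-window and degenerate barcodes get the right status", {
  ct <- test_construct()
  s28 <- template_for(ct, rand_dna(1, 28))
  obs <- extract_barcodes(s28, ct)
  expect_equal(obs$status, "bad_length")
  expect_equal(nchar(obs$barcode), 28)  # reported for the length spectrum

  s22 <- template_for(ct, rand_dna(1, 22))
  expect_equal(extract_barcodes(s22, ct)$status, "bad_length")
  s27 <- template_for(ct, rand_dna(1, 27))
  expect_equal(extract_barcodes(s27, ct)$status, "ok")

  bcN <- paste0(rand_dna(1, 12), "N", rand_dna(1, 12))
  expect_equal(extract_barcodes(template_for(ct, bcN), ct)$status,
               "contains_N")

  # anchors in the wrong order: no usable right anchor downstream
  wrong <- paste0(ct$right_flank, ct$left_flank)
  expect_equal(extract_barcodes(wrong, ct)$status, "no_right_anchor")
  # no anchor at all
  expect_equal(extract_barcodes(rand_dna(1, 80), ct)$status,
               "no_left_anchor")
})

test_that("extraction is strand-invariant on simulated reads", {
  ct <- test_construct()
  cfg <- sim_config(n_barcodes = 100, n_read_pairs = 1000, read_len = 60,
                    ancestral_fraction = 0, seed = 401)
  sim <- simulate_reads(generate_library(ct, cfg), ct, cfg)
  merged <- merge_pairs(sim$pairs, min_overlap = 10)
  seqs <- merged$seq[merged$status == "merged"]
  fwd <- extract_barcodes(seqs, ct)
  rev <- extract_barcodes(reverse_complement(seqs), ct)
  expect_identical(fwd$status, rev$status)
  expect_identical(fwd$barcode, rev$barcode)
  expect_identical(fwd$umi, rev$umi)
  flip <- c(forward = "reverse", reverse = "forward")
  same <- fwd$strand %in% c("forward", "reverse")
  expect_identical(unname(flip[fwd$strand[same]]), rev$strand[same])
})

test_that("every read lands in exactly one status class", {
  ct <- test_construct()
  cfg <- sim_config(n_barcodes = 100, n_read_pairs = 2000, read_len = 60,
                    sub_error_rate = 0.01, indel_error_rate = 0.001,
                    seed = 402)
  sim <- simulate_reads(generate_library(ct, cfg), ct, cfg)
  merged <- merge_pairs(sim$pairs, min_overlap = 10)
  obs <- extract_barcodes(merged, ct)
  expect_equal(nrow(obs), nrow(sim$pairs))
  expect_true(all(obs$status %in%
                    c("ok", "no_left_anchor", "no_right_anchor",
                      "ambiguous_strand", "bad_length", "contains_N")))
  expect_equal(sum(table(obs$status)), nrow(sim$pairs))
})

test_that("noiseless extraction recovers the emitted multiset exactly", {
  ct <- test_construct()
  cfg <- sim_config(n_barcodes = 50, n_read_pairs = 2000, read_len = 60,
                    sub_error_rate = 0, indel_error_rate = 0,
                    ancestral_fraction = 0, seed = 403)
  sim <- simulate_reads(generate_library(ct, cfg), ct, cfg)
  merged <- merge_pairs(sim$pairs, min_overlap = 10)
  obs <- extract_barcodes(merged, ct)
  expect_true(all(obs$status == "ok"))
  expect_identical(sort(obs$barcode), sort(sim$emitted$barcode))
  expect_identical(obs$umi, sim$emitted$umi)
})

test_that("length_filter keeps in-window reads and reports the histogram", {
  obs <- obs_frame(
    c(rand_dna(98, 25), rand_dna(1, 24), rand_dna(1, 30)),
    c(rep("ok", 99), "bad_length"))
  lf <- length_filter(obs, example_construct())
  expect_equal(nrow(lf$kept), 99)
  expect_equal(lf$report$within_tolerance, 0.99)
  hist <- lf$report$histogram
  expect_equal(hist$n[hist$length == 25], 98)
  expect_equal(sum(hist$frequency), 1)

  all25 <- obs_frame(rand_dna(10, 25), rep("ok", 10))
  expect_equal(length_filter(all25, example_construct())$
                 report$within_tolerance, 1)
})

test_that("indel errors shift barcode lengths at most at the binomial rate", {
  ct <- test_construct()
  indel <- 0.001
  cfg <- sim_config(n_barcodes = 100, n_read_pairs = 5000, read_len = 60,
                    sub_error_rate = 0, indel_error_rate = indel,
                    ancestral_fraction = 0, seed = 404)
  sim <- simulate_reads(generate_library(ct, cfg), ct, cfg)
  merged <- merge_pairs(sim$pairs, min_overlap = 10)
  obs <- extract_barcodes(merged, ct)
  lf <- length_filter(obs, ct)
  # a barcode goes off-length only if an indel lands inside it on the
  # read that supplies it; with two reads the binomial bound is
  # 2 * barcode_len * rate
  expect_gte(lf$report$within_tolerance, 1 - 3 * 2 * 25 * indel)
  expect_gt(lf$report$within_tolerance, 0.9)
})
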