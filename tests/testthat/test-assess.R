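make_table <- function(barcodes, counts = NULL, id = "S") {
  counts <- counts %||% rep(1L, length(barcodes))
  count_table(barcodes, counts, sample_id = id)
}

test_that("replicate intersections assign every barcode to one subset", {
  a <- make_table(c("AAA", "CCC", "GGG"), id = "A")
  ints <- replicate_intersections(list(A = a, B = a, C = a))
  expect_equal(ints$n_barcodes[ints$subset == "A&B&C"], 3)
  expect_equal(sum(ints$n_barcodes), 3)

  x <- replicate_intersections(list(
    A = make_table(c("x", "y")), B = make_table(c("y", "z")),
    C = make_table("y")))
  expect_equal(x$n_barcodes[x$subset == "A&B&C"], 1)
  expect_equal(x$n_barcodes[x$subset == "A"], 1)
  expect_equal(x$n_barcodes[x$subset == "B"], 1)
  expect_equal(sum(x$n_barcodes), 3)
  expect_true(all(x$n_barcodes[!x$subset %in% c("A&B&C", "A", "B")] == 0))

  expect_error(replicate_intersections(list(a)), "two")
})

test_that("subset counts sum to the union for random replicate triples", {
  set.seed(601)
  for (i in 1:10) {
    pool <- rand_dna(60, 10)
    tabs <- lapply(1:3, function(j)
      make_table(sample(pool, sample(10:50, 1)), id = paste0("R", j)))
    ints <- replicate_intersections(tabs)
    expect_equal(sum(ints$n_barcodes),
                 length(unique(unlist(lapply(tabs, `[[`, "barcode")))))
    expect_equal(nrow(ints), 7)  # every non-empty subset of three sets
  }
})

test_that("the shared-barcode fraction grows with sequencing depth", {
  ct <- test_construct()
  tr <- generate_library(ct, sim_config(n_barcodes = 2000, sigma = 1.5,
                                        seed = 602))
  frac_all3 <- vapply(c(1e3, 1e4, 1e5), function(depth) {
    tabs <- lapply(1:3, function(j) {
      cnt <- stats::rmultinom(1, depth, tr$true_freq)[, 1]
      count_table(tr$barcodes[cnt > 0], cnt[cnt > 0],
                  sample_id = paste0("R", j))
    })
    ints <- replicate_intersections(tabs)
    ints$n_barcodes[ints$degree == 3] / sum(ints$n_barcodes)
  }, numeric(1))
  expect_true(all(diff(frac_all3) > 0))
})

test_that("pairwise Pearson correlation matches closed forms", {
  a <- make_table(c("A", "B", "C"), c(5L, 3L, 2L), id = "a")
  self <- pairwise_frequency_correlation(a, a)
  expect_equal(self$r, 1)
  expect_equal(self$n, 3)

  b <- make_table(c("A", "B", "C"), c(2L, 3L, 5L), id = "b")
  r <- pairwise_frequency_correlation(a, b, scope = "shared")
  expect_equal(r$r, -13 / 14, tolerance = 1e-12)  # hand-computed

  const <- make_table(c("A", "B"), c(3L, 3L))
  z <- pairwise_frequency_correlation(const, make_table(c("A", "B"),
                                                        c(1L, 5L)))
  expect_false(z$defined)
  expect_true(is.na(z$r))
})

test_that("shared and union scopes are both available and disclosed", {
  a <- make_table(c("A", "B", "C"), c(5L, 3L, 2L), id = "a")
  d <- make_table(c("A", "B", "D", "E"), c(5L, 3L, 1L, 1L), id = "d")
  sh <- pairwise_frequency_correlation(a, d, "shared")
  un <- pairwise_frequency_correlation(a, d, "union_with_zeros")
  expect_equal(sh$n, 2)
  expect_equal(un$n, 5)
  expect_equal(sh$scope, "shared")
  expect_equal(un$scope, "union_with_zeros")
})

test_that("diversity metrics match hand-computed values", {
  eq <- make_table(rand_dna(64, 10))
  d <- diversity_metrics(eq)
  expect_equal(d$shannon_entropy, log(64), tolerance = 1e-12)
  expect_equal(d$evenness, 1)
  expect_equal(d$max_frequency, 1 / 64)

  single <- make_table("AAA", 7L)
  ds <- diversity_metrics(single)
  expect_equal(ds$shannon_entropy, 0)
  expect_equal(ds$max_frequency, 1)
  expect_true(is.na(ds$evenness))

  skew <- make_table(c("A", "B", "C"), c(2L, 1L, 1L))
  expect_equal(diversity_metrics(skew)$shannon_entropy, 1.5 * log(2),
               tolerance = 1e-12)

  expect_error(diversity_metrics(make_table(character(), integer())),
               "empty")
})

test_that("evenness is bounded and maximal only when uniform", {
  set.seed(603)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    counts <- sample(1:50, n, replace = TRUE)
    d <- diversity_metrics(make_table(rand_dna(n, 8), counts))
    expect_gte(d$evenness, 0)
    expect_lte(d$evenness, 1 + 1e-12)
    if (length(unique(counts)) > 1) expect_lt(d$evenness, 1)
  }
})

test_that("length spectra normalise and report the tolerance fraction", {
  sp <- length_spectrum(rep(25L, 40), example_construct())
  expect_equal(sp$histogram$frequency, 1)
  expect_equal(sp$within_tolerance, 1)

  sp2 <- length_spectrum(c(rep(25L, 98), 24L, 30L), example_construct())
  expect_equal(sp2$within_tolerance, 0.99)
  expect_equal(sp2$window, c(23, 27))
})

test_that("frequency trajectories cover the union with zeros for absences", {
  t1 <- make_table("AAA", 5L)
  t2 <- make_table("AAA", 9L)
  traj <- frequency_trajectories(list(t1, t2))
  expect_equal(traj$frequency, c(1, 1))

  t3 <- make_table(c("AAA", "CCC"), c(3L, 1L))
  traj2 <- frequency_trajectories(list(t1, t3))
  ccc <- traj2[traj2$barcode == "CCC", ]
  expect_equal(ccc$frequency, c(0, 0.25))
  expect_error(frequency_trajectories(list(t1)), "two")
})

test_that("neutral resampling drift variance scales as f(1-f)/N", {
  set.seed(604)
  n_lineages <- 100
  N <- 1000
  f0 <- as.numeric(stats::rmultinom(1, N, rep(1, n_lineages))) / N
  keep <- f0 > 0
  ratios <- replicate(200, {
    f1 <- as.numeric(stats::rmultinom(1, N, f0)) / N
    tabs <- list(
      count_table(sprintf("L%03d", which(keep)),
                  as.integer(f0[keep] * N)),
      count_table(sprintf("L%03d", which(f1 > 0)),
                  as.integer(f1[f1 > 0] * N)))
    traj <- frequency_trajectories(tabs)
    wide <- stats::reshape(traj, idvar = "barcode", timevar = "time",
                           direction = "wide")
    d <- wide$frequency.2 - wide$frequency.1
    fstart <- wide$frequency.1
    mean(d^2 / (fstart * (1 - fstart) / N))
  })
  pooled <- mean(ratios)
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(pooled - 1), 3 * se + 0.05)
})

test_that("the replicate report aggregates the battery coherently", {
  set.seed(605)
  pool <- rand_dna(80, 12)
  tabs <- lapply(1:3, function(j)
    make_table(sample(pool, 60), sample(1:30, 60, replace = TRUE),
               id = paste0("rep", j)))
  rep <- assess_replicates(tabs)
  expect_s3_class(rep, "replicate_report")
  expect_equal(dim(rep$correlations), c(3, 3))
  expect_equal(diag(rep$correlations), c(rep1 = 1, rep2 = 1, rep3 = 1))
  expect_equal(sum(rep$intersections$n_barcodes),
               length(unique(unlist(lapply(tabs, `[[`, "barcode")))))
  expect_output(print(rep), "replicates")
  grDevices::pdf(NULL)
  expect_invisible(plot(rep))
  grDevices::dev.off()
})
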