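test_that("two hot windows bridged by one cold window merge into one island", {
  cfg <- island_config(window = 600, gap = 600, p0 = 0.2)
  isl <- islands_from_counts(c(9L, 0L, 9L), lambda = 1, cfg)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start, 0L)
  expect_equal(isl$end, 1800L)
  expect_equal(isl$score, 2 * -dpois(9, 1, log = TRUE))
  expect_equal(isl$count, 18L)
  ## matches the brute-force enumerator
  or <- oracle_islands(c(9L, 0L, 9L), 1, 0.2, gap_windows = 1L)
  expect_equal(isl$start, or$start)
  expect_equal(isl$end, or$end)
  expect_equal(isl$score, or$score)
})

test_that("island merging matches exhaustive enumeration on random configurations", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(5:20, 1)
    counts <- rpois(n, sample(c(0.5, 1, 2), 1)) +
      sample(0:8, n, replace = TRUE) * rbinom(n, 1, 0.3)
    lambda <- runif(1, 0.5, 2)
    gap_w <- sample(0:3, 1)
    cfg <- island_config(window = 600, gap = gap_w * 600, p0 = 0.2)
    got <- islands_from_counts(counts, lambda, cfg)
    want <- oracle_islands(counts, lambda, 0.2, gap_windows = cfg$gap %/% 600L)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(as.integer(got$count), as.integer(want$count))
  }
})

test_that("island boundaries align to windows and eligible windows are conserved", {
  set.seed(13)
  counts <- rpois(300, 0.8) + sample(0:6, 300, replace = TRUE) * rbinom(300, 1, 0.2)
  cfg <- island_config(window = 600, gap = 1200, p0 = 0.2)
  isl <- islands_from_counts(counts, 0.8, cfg)
  expect_true(all(isl$start %% 600 == 0))
  ## every eligible window sits inside exactly one island, and island
  ## endpoints are eligible
  elig <- which(ppois(counts - 1, 0.8, lower.tail = FALSE) < 0.2)
  inside <- unlist(lapply(seq_len(nrow(isl)), function(i)
    isl$first_window[i]:isl$last_window[i]))
  expect_true(all(elig %in% inside))
  expect_true(all(isl$first_window %in% elig))
  expect_true(all(isl$last_window %in% elig))
})

test_that("zero chip reads give an empty island set; calls are deterministic", {
  genome <- c(chr1 = 6e5, chr2 = 3e5)
  empty <- read_set(data.frame(chrom = character(0), start = integer(0),
                               end = integer(0)), genome)
  some <- read_set(data.frame(chrom = rep("chr1", 50),
                              start = rep(c(1000, 1100, 1200), length.out = 50),
                              end = rep(c(1036, 1136, 1236), length.out = 50)),
                   genome)
  expect_length(call_islands(empty, some), 0L)
  isl1 <- expect_warning(call_islands(some, NULL), "uniform background")
  isl2 <- expect_warning(call_islands(some, NULL), "uniform background")
  expect_identical(GenomicRanges::start(isl1), GenomicRanges::start(isl2))
  expect_identical(isl1$score, isl2$score)
})

test_that("reads outside chromosome bounds or on unknown chromosomes are rejected", {
  genome <- c(chr1 = 1e4)
  expect_error(read_set(data.frame(chrom = "chr2", start = 0, end = 36), genome),
               "absent from genome")
  expect_error(read_set(data.frame(chrom = "chr1", start = 9990, end = 10036), genome),
               "outside chromosome bounds")
})

test_that("uniform-background eligible-window mass matches the Poisson tail", {
  set.seed(202)
  n <- 1e5
  lambda <- 1
  counts <- rpois(n, lambda)
  cfg <- island_config(window = 600, gap = 600, p0 = 0.2)
  isl <- islands_from_counts(counts, lambda, cfg)
  n_elig <- sum(vapply(seq_len(nrow(isl)), function(i) {
    memb <- isl$first_window[i]:isl$last_window[i]
    sum(ppois(counts[memb] - 1, lambda, lower.tail = FALSE) < 0.2)
  }, numeric(1)))
  ## analytic: eligibility at lambda=1, p0=0.2 means count >= 3
  p_tail <- ppois(2, lambda, lower.tail = FALSE)
  expect_lt(abs(n_elig / n - p_tail), 3 * sqrt(p_tail * (1 - p_tail) / n))
})

test_that("differential occupancy classifies shared and specific islands", {
  g <- c(chr1 = 1e6)
  d0 <- toy_granges(0, 600, genome = g)
  d8 <- toy_granges(c(500, 2000), c(1100, 2600), genome = g)
  occ <- differential_occupancy(d0, d8)
  expect_length(occ$shared_d0, 1L)
  expect_length(occ$shared_d8, 1L)
  expect_length(occ$d0_specific, 0L)
  expect_length(occ$d8_specific, 1L)
  ## classes partition each day's islands
  expect_equal(length(occ$shared_d0) + length(occ$d0_specific), length(d0))
  expect_equal(length(occ$shared_d8) + length(occ$d8_specific), length(d8))
  ## identical sets: everything shared
  occ2 <- differential_occupancy(d8, d8)
  expect_length(occ2$d0_specific, 0L)
  expect_length(occ2$d8_specific, 0L)
  expect_equal(occ2$shared_fraction_union, 1)
  ## genome mismatch errors
  d8b <- toy_granges(0, 600, genome = c(chr1 = 2e6))
  expect_error(differential_occupancy(d0, d8b), "mismatch")
})

test_that("saturation recovery is 1 at full depth and non-decreasing in expectation", {
  fracs <- c(0.3, 0.6, 1.0)
  recov <- matrix(NA_real_, 12, length(fracs))
  for (s in 1:12) {
    cfg <- sim_config(seed = 300 + s, chip = list(
      chroms = c(chr1 = 2e6), n_shared = 0L, n_d0_specific = 25L,
      n_d8_specific = 0L, with_sequence = FALSE))
    chip <- simulate_chip(cfg)
    sat <- saturation_curve(chip$reads$ac_d0, chip$reads$input,
                            fractions = fracs, seed = s)
    expect_equal(sat$recovery[length(fracs)], 1)
    ## identical seed reproduces the curve exactly
    sat2 <- saturation_curve(chip$reads$ac_d0, chip$reads$input,
                             fractions = fracs, seed = s)
    expect_identical(sat, sat2)
    recov[s, ] <- sat$recovery
  }
  m <- colMeans(recov)
  expect_true(all(diff(m) >= 0))
})

test_that("bin density counts features by midpoint with half-open bins", {
  g <- c(chr1 = 6e6)
  ## no features: all-zero bins
  none <- bin_density(toy_granges(integer(0), integer(0), genome = g), g)
  expect_equal(nrow(none), 3L)
  expect_true(all(none$count == 0))
  ## midpoint exactly on a boundary goes to the higher bin:
  ## interval [1999000, 2001000) has midpoint 2000000
  gr <- toy_granges(c(1999000, 100, 3e6, 4100000, 4100600),
                    c(2001000, 700, 3000600, 4100600, 4101200), genome = g)
  bd <- bin_density(gr, g, bin_size = 2e6)
  expect_equal(bd$count, c(1L, 2L, 2L))
})

test_that("mark correlation reports hand-checked Pearson r and Jaccard", {
  g <- c(chr1 = 3600)  # 6 windows of 600 bp
  a <- toy_granges(c(0, 1200), c(600, 2400), genome = g)    # windows 1,3,4
  b <- toy_granges(c(1200, 3000), c(1800, 3600), genome = g) # windows 3,6
  res <- mark_correlation(a, b, g, w = 600)
  va <- c(1, 0, 1, 1, 0, 0); vb <- c(0, 0, 1, 0, 0, 1)
  expect_equal(res$pearson_r, cor(va, vb))
  expect_equal(res$jaccard, 600 / (1800 + 1200 - 600))
  ## identical sets
  same <- mark_correlation(a, a, g, w = 600)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$jaccard, 1)
  ## disjoint coverage
  disj <- mark_correlation(toy_granges(0, 600, genome = g),
                           toy_granges(1200, 1800, genome = g), g, w = 600)
  expect_equal(disj$jaccard, 0)
  ## zero-variance vector: r undefined, Jaccard still reported
  all_cov <- toy_granges(0, 3600, genome = g)
  res2 <- mark_correlation(all_cov, a, g, w = 600)
  expect_true(is.na(res2$pearson_r))
  expect_equal(res2$jaccard, sum(GenomicRanges::width(GenomicRanges::reduce(a))) / 3600)
})

test_that("BED and chrom.sizes round-trip through the readers and writers", {
  genome <- c(chr1 = 1e5, chr2 = 5e4)
  tmp_sizes <- tempfile(fileext = ".chrom.sizes")
  write.table(data.frame(names(genome), genome), tmp_sizes, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_equal(read_genome_sizes(tmp_sizes), genome)
  gr <- toy_granges(c(0, 1200), c(600, 1800), genome = genome)
  gr$chip_count <- c(10L, 20L); gr$input_scaled <- c(1, 2)
  gr$score <- c(5.5, 9.1); gr$p <- c(0.01, 0.001); gr$q <- c(0.02, 0.004)
  tmp_bed <- tempfile(fileext = ".bed")
  write_bed(gr, tmp_bed)
  back <- read_bed(tmp_bed, genome)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
})
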