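# Threshold derivation, run extraction, peak classification, distances
# and the window-value distribution diagnostics.

test_that("genome_stats pools all defined values with population sd", {
  p1 <- make_profile(c(10, 10, 10))
  s <- genome_stats(p1)
  expect_equal(s$mean, 10)
  expect_equal(s$sd, 0)
  expect_equal(s$S, 10)

  p2 <- make_profile(c(8, 12))
  s2 <- genome_stats(p2, sd_mult = 2)
  expect_equal(s2$mean, 10)
  expect_equal(s2$sd, 2)          # population denominator, not n-1
  expect_equal(s2$S, 14)

  s3 <- genome_stats(list(make_profile(c(8, NA)), make_profile(c(12, NA))))
  expect_equal(s3$n, 2L)
  expect_equal(s3$mean, 10)
  expect_error(genome_stats(make_profile(c(NA_real_, NA_real_))), "defined")
})

test_that("call_regions extracts maximal runs with window-union footprints", {
  expect_equal(nrow(call_regions(make_profile(rep(1, 50)), S = 5)), 0L)

  v <- rep(1, 600)
  v[501:530] <- 20          # 30 consecutive windows at window starts 500..529
  r <- call_regions(make_profile(v, L = 100L), S = 10)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 500L)
  expect_equal(r$end, 629L)
  expect_equal(r$n_windows, 30L)
  expect_equal(r$max_value, 20)

  # one sub-threshold window keeps two runs apart (no gap merging)
  v2 <- c(rep(20, 5), 1, rep(20, 4))
  r2 <- call_regions(make_profile(v2, L = 100L), S = 10)
  expect_equal(nrow(r2), 2L)

  # a missing window also breaks a run
  v3 <- c(rep(20, 5), NA, rep(20, 4))
  expect_equal(nrow(call_regions(make_profile(v3, L = 100L), S = 10)), 2L)
})

test_that("run extraction matches a brute-force run finder on random profiles", {
  set.seed(301)
  for (i in 1:30) {
    v <- round(rnorm(500, 10, 2), 2)
    v[sample.int(500, 20)] <- NA
    S <- quantile(v, 0.8, na.rm = TRUE)
    r <- call_regions(make_profile(v, L = 100L), S = S)
    o <- runs_oracle(v, S, L = 100L)
    expect_equal(nrow(r), nrow(o))
    if (nrow(o)) {
      expect_equal(r$start, unname(o[, "start"]))
      expect_equal(r$end, unname(o[, "end"]))
      expect_equal(r$n_windows, unname(o[, "n"]))
    }
  }
})

test_that("classification splits peaks from under-threshold regions at theta", {
  reg <- data.frame(chrom = "chrIV", start = c(0L, 500L), end = c(200L, 700L),
                    max_value = c(13.9, 13.7), mean_value = c(13, 13),
                    n_windows = c(5L, 5L), status = NA, name = NA,
                    stringsAsFactors = FALSE)
  out <- classify_peaks(reg, theta = 13.8)
  expect_equal(out$status, c("peak", "under_threshold"))
  expect_equal(out$name, c("peakIV-1", NA))

  # naming follows ascending coordinates per chromosome and the chrom map
  reg2 <- data.frame(chrom = "scaffold_7", start = c(900L, 100L),
                     end = c(1100L, 300L), max_value = c(15, 15),
                     mean_value = 15, n_windows = 2L, status = NA, name = NA,
                     stringsAsFactors = FALSE)
  out2 <- classify_peaks(reg2, 13.8, chrom_map = c(scaffold_7 = "VII"))
  expect_equal(out2$name[order(out2$start)], c("peakVII-1", "peakVII-2"))
})

test_that("raising theta never increases the peak count", {
  set.seed(17)
  v <- rnorm(2000, 12, 1.5)
  reg <- call_regions(make_profile(v, L = 100L), S = 12.5)
  thetas <- seq(12.5, 18, by = 0.25)
  counts <- vapply(thetas, function(th)
    sum(classify_peaks(reg, th)$status == "peak"), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], nrow(reg))                 # theta <= S: all peaks
  expect_equal(counts[length(counts)], 0L)           # theta > max: none
})

test_that("interpeak distances are edge-to-edge with 5 kb bins", {
  pk <- data.frame(chrom = "c1", start = c(0L, 1200L), end = c(200L, 1400L),
                   status = "peak", name = c("p1", "p2"),
                   stringsAsFactors = FALSE)
  d <- interpeak_distances(pk)
  expect_equal(d$distances$distance, c(1000, 1000))
  expect_equal(d$histogram$count[1], 2L)
  expect_equal(d$histogram$bin_start[1], 0)

  # a chromosome with a single peak contributes nothing
  pk2 <- rbind(pk, data.frame(chrom = "c2", start = 0L, end = 100L,
                              status = "peak", name = "p3"))
  expect_equal(nrow(interpeak_distances(pk2)$distances), 2L)
})

test_that("interpeak histogram matches an all-pairs nearest oracle", {
  set.seed(88)
  start <- sort(sample.int(200000, 20))
  pk <- data.frame(chrom = "c1", start = start, end = start + 150L,
                   status = "peak", name = paste0("p", 1:20),
                   stringsAsFactors = FALSE)
  d <- interpeak_distances(pk)$distances$distance
  oracle <- vapply(1:20, function(i) {
    min(vapply(setdiff(1:20, i), function(j)
      max(0, max(pk$start[i] - pk$end[j], pk$start[j] - pk$end[i])), 0))
  }, 0)
  expect_equal(sort(d), sort(oracle))
})

test_that("value distribution is unit-area and flags planted heavy tails", {
  set.seed(1234)
  v <- rnorm(2e5, 10, 0.5)
  vd <- value_distribution(make_profile(v), tail_min = 12)
  bw <- diff(vd$breaks[1:2])
  expect_equal(sum(vd$density * bw), 1, tolerance = 1e-9)
  # true Gaussian: excess tail mass ~ 0 within 3 Monte-Carlo sds
  p_tail <- pnorm(12, 10, 0.5, lower.tail = FALSE)
  mc_sd <- sqrt(p_tail * (1 - p_tail) / length(v))
  expect_lt(abs(vd$excess_tail_mass), 3 * mc_sd + 1e-6)

  # 1% contamination well above the tail cut is detected at its known mass
  v2 <- c(rnorm(99000, 10, 0.5), rnorm(1000, 14, 0.2))
  vd2 <- value_distribution(make_profile(v2), tail_min = 12)
  expect_gt(vd2$excess_tail_mass, 0.005)
  expect_lt(abs(vd2$excess_tail_mass - 0.01), 0.005)

  expect_warning(vd0 <- value_distribution(make_profile(rep(10, 10))),
                 "sd = 0")
  expect_true(is.na(vd0$excess_tail_mass))
})
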