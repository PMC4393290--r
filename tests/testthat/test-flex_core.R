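# Step-table loading, per-step values and the sliding-window profiler.

test_that("step tables validate symmetry, completeness and positivity", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("step\tvalue", "AA\t7", "AC\t9", "AG\t8", "AT\t12", "CA\t11",
               "CC\t7.5", "CG\t10", "GA\t8.5", "GC\t8.2", "TA\t15"), f)
  tab <- load_step_table(f)
  expect_length(tab, 16L)
  expect_equal(unname(tab["TT"]), 7)     # AA == TT by symmetry expansion
  expect_equal(unname(tab["GT"]), 9)     # AC == GT
  expect_equal(unname(tab["TG"]), 11)    # CA == TG

  writeLines(c("step\tvalue", "AA\t7", "TT\t8"), f)
  expect_error(load_step_table(f), "symmetry")

  writeLines(c("step\tvalue", "AA\t7"), f)
  expect_error(load_step_table(f), "incomplete")

  expect_error(step_table(c(AA = -1)), "positive|incomplete")
  expect_error(step_table(stats::setNames(rep(-1, 16),
                                          twistflexr:::DINUC_STEPS)),
               "positive")
})

test_that("the packaged default table brackets the 7-16 degree window range", {
  tab <- default_step_table()
  expect_length(tab, 16L)
  expect_lte(min(tab), 7)
  expect_gte(max(tab), 16)
  for (s in twistflexr:::DINUC_STEPS)
    expect_equal(unname(tab[s]), unname(tab[twistflexr:::revcomp_step(s)]))
})

test_that("step_values looks up consecutive dinucleotide steps with N -> NA", {
  tab <- default_step_table()
  expect_equal(step_values("AAA", tab), rep(unname(tab["AA"]), 2))
  expect_equal(step_values("ANA", tab), c(NA_real_, NA_real_))
  expect_error(step_values("A", tab), "shorter")
  expect_error(step_values("ACXG", tab), "non-ACGTN")

  set.seed(11)
  s <- rand_seq(200)
  ch <- strsplit(s, "")[[1]]
  oracle <- vapply(seq_len(199), function(i)
    unname(tab[paste0(ch[i], ch[i + 1])]), 0)
  expect_equal(step_values(s, tab), oracle)
})

test_that("window means match direct enumeration on alternating TA sequence", {
  tab <- default_step_table()
  s <- strrep("TA", 100)                       # 200 bp
  prof <- window_profile(s, tab, profile_config(100L, 1L), chrom = "c1")
  x <- step_values(s, tab)
  expected <- vapply(0:100, function(p) mean(x[(p + 1):(p + 99)]), 0)
  expect_equal(prof$values, expected, tolerance = 1e-12)
  # the 99 steps of each window alternate TA/AT: exact hand formula
  expect_equal(prof$values[1],
               (50 * unname(tab["TA"]) + 49 * unname(tab["AT"])) / 99)
})

test_that("constant step table gives a constant profile", {
  tab <- constant_table(9.5)
  set.seed(5)
  prof <- window_profile(rand_seq(400), tab, profile_config(100L, 1L))
  expect_true(all(abs(prof$values - 9.5) < 1e-12))
})

test_that("profile equals the naive per-window oracle within 1e-9", {
  tab <- default_step_table()
  set.seed(21)
  for (i in 1:5) {
    s <- rand_seq(1000)
    prof <- window_profile(s, tab, profile_config(100L, 1L))
    expect_lt(max(abs(prof$values - naive_profile(s, tab, 100L))), 1e-9)
  }
  # non-unit shift
  s <- rand_seq(500)
  prof <- window_profile(s, tab, profile_config(80L, 7L))
  expect_lt(max(abs(prof$values - naive_profile(s, tab, 80L, 7L))), 1e-9)
})

test_that("window count formula holds, including len == L", {
  tab <- constant_table()
  cases <- list(c(100, 100, 1), c(101, 100, 1), c(250, 100, 1),
                c(100, 100, 50), c(157, 40, 7), c(39, 30, 30))
  set.seed(3)
  for (cs in cases) {
    prof <- window_profile(rand_seq(cs[1]), tab,
                           profile_config(cs[2], cs[3]))
    expect_length(prof$values, (cs[1] - cs[2]) %/% cs[3] + 1L)
  }
  expect_warning(p0 <- window_profile(rand_seq(99), tab,
                                      profile_config(100L, 1L)),
                 "shorter")
  expect_length(p0$values, 0L)
})

test_that("defined window values stay within the step-table range", {
  tab <- default_step_table()
  set.seed(77)
  for (i in 1:10) {
    s <- rand_seq(300, gc = runif(1, 0.2, 0.8))
    v <- window_profile(s, tab, profile_config(50L, 1L))$values
    expect_true(all(v >= min(tab) - 1e-12 & v <= max(tab) + 1e-12))
  }
})

test_that("profiles are reverse-complement symmetric", {
  tab <- default_step_table()
  cfg <- profile_config(100L, 1L)
  set.seed(42)
  for (i in 1:10) {
    s <- rand_seq(500)
    f <- window_profile(s, tab, cfg)$values
    r <- window_profile(revcomp(s), tab, cfg)$values
    expect_equal(r, rev(f), tolerance = 1e-9)
  }
})

test_that("windows containing N are missing and anchored at the midpoint step", {
  tab <- constant_table()
  s <- paste0(strrep("A", 150), "N", strrep("A", 149))   # N at 0-based 150
  prof <- window_profile(s, tab, profile_config(100L, 1L))
  # windows covering position 150: starts 51..150 (0-based)
  expect_true(all(is.na(prof$values[52:151])))
  expect_true(all(!is.na(prof$values[c(1:51, 152:201)])))
  # anchor: first window's value sits at genomic position floor((L-1)/2)
  expect_equal(prof$anchor, 49L)
  expect_equal(profile_positions(prof)[1], 49L)
  expect_equal(profile_window_starts(prof)[3], 2L)
})
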