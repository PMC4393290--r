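# InterORF orientation classes, peak placement, UTR overlap, poly(A)
# distances and generic nearest-feature distances.

orfs_df <- function(start, end, strand, chrom = "c1") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             ftype = "ORF", fid = paste0(chrom, "_g", seq_along(start)),
             stringsAsFactors = FALSE)
}

test_that("interORF orientation follows the flanking strands", {
  o <- orfs_df(c(0L, 500L), c(400L, 900L), c("+", "-"))
  r <- classify_interorf(o)
  expect_equal(nrow(r), 1L)                      # terminal gaps excluded
  expect_equal(r$oclass, "convergent")
  expect_equal(c(r$start, r$end), c(400L, 500L))

  expect_equal(classify_interorf(orfs_df(c(0L, 500L), c(400L, 900L),
                                         c("-", "+")))$oclass, "divergent")
  expect_equal(classify_interorf(orfs_df(c(0L, 500L), c(400L, 900L),
                                         c("+", "+")))$oclass,
               "unidirectional")
  # overlapping ORFs produce no region for that gap
  o2 <- orfs_df(c(0L, 300L, 800L), c(400L, 700L, 1000L), c("+", "-", "+"))
  r2 <- classify_interorf(o2)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$oclass, "divergent")
  expect_error(classify_interorf(orfs_df(0L, 10L, ".")), "stranded")
})

test_that("a planted 1:2:1 orientation mix is recovered exactly", {
  strands <- c("-", "+", "+", "-", "-", "+", "+", "-", "-")
  # gaps: div, uni, conv, uni, div, uni, conv, uni
  n <- length(strands)
  o <- orfs_df(seq(0L, by = 1000L, length.out = n),
               seq(600L, by = 1000L, length.out = n), strands)
  r <- classify_interorf(o)
  expect_equal(unname(table(r$oclass)[c("divergent", "unidirectional",
                                        "convergent")]),
               c(2L, 4L, 2L), ignore_attr = TRUE)
})

test_that("peak placement honours the telomere > rRNA > ORF > interORF priority", {
  feats <- rbind(
    orfs_df(c(1000L, 3000L, 5000L), c(2000L, 4000L, 6000L), c("+", "-", "+")),
    data.frame(chrom = "c1", start = 0L, end = 500L, strand = ".",
               ftype = "telomere", fid = "tel1"),
    data.frame(chrom = "c1", start = 7000L, end = 7500L, strand = ".",
               ftype = "rRNA", fid = "rdn1"))
  pk <- data.frame(chrom = "c1",
                   start = c(100L, 1200L, 2400L, 7100L, 1900L),
                   end = c(300L, 1800L, 2700L, 7300L, 2200L),
                   status = "peak",
                   name = paste0("p", 1:5), stringsAsFactors = FALSE)
  ann <- locate_peaks(pk, feats)
  expect_equal(ann$placement,
               c("telomere", "inside_ORF", "interORF", "rRNA", "interORF"))
  expect_equal(ann$oclass[3], "convergent")      # midpoint in + ... - gap
  expect_equal(ann$orf_id[2], "c1_g1")
  # p5 spans the ORF/gap border; its midpoint (2050) is inside the gap
  expect_equal(ann$oclass[5], "convergent")
  # placements always sum to the number of peaks
  expect_equal(sum(table(ann$placement)), nrow(pk))

  # unknown chromosome stays unresolved
  pk2 <- data.frame(chrom = "cX", start = 0L, end = 100L, status = "peak",
                    name = "px", stringsAsFactors = FALSE)
  expect_true(is.na(locate_peaks(pk2, feats)$placement))
})

test_that("UTR overlap uses half-open arithmetic and strand-aware extension", {
  orfs <- orfs_df(c(1000L, 3000L), c(2000L, 4000L), c("+", "-"))
  utrs <- data.frame(orf_id = c("c1_g1", "c1_g2"), utr5_len = 50L,
                     utr3_len = 100L, stringsAsFactors = FALSE)
  # 3'UTRs: g1 (+): [2000,2100); g2 (-): [2900,3000)
  pk_abut <- data.frame(chrom = "c1", start = 2100L, end = 2300L,
                        status = "peak", name = "p1")
  expect_equal(nrow(utr_overlap(pk_abut, orfs, utrs)$hits), 0L)

  pk_span <- data.frame(chrom = "c1", start = 2050L, end = 2950L,
                        status = "peak", name = "p2")
  u <- utr_overlap(pk_span, orfs, utrs)
  expect_equal(sort(u$hits$orf_id), c("c1_g1", "c1_g2"))
  expect_equal(u$summary$n_peaks_3utr, 1L)
  expect_equal(u$summary$n_orfs_3utr, 2L)

  # ORF missing from the table falls back to the table means
  utrs2 <- utrs[1, ]
  u2 <- utr_overlap(pk_span, orfs, utrs2)
  expect_equal(sort(unique(u2$hits$orf_id)), c("c1_g1", "c1_g2"))
})

test_that("poly(A) distances filter by score and distance, order-invariant", {
  reps <- data.frame(chrom = "c1", midpoint = c(1000L, 5000L),
                     family = c("(TA)n", "(TTA)n"), stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "c1",
                      pos = c(1000L, 1501L, 5010L, 980L, 1200L),
                      strand = "+",
                      score = c(2000, 2000, 2000, 100, 950),
                      stringsAsFactors = FALSE)
  r <- polya_distance(sites, reps, score_min = 945, max_dist = 500)
  expect_equal(r$n_intense, 4L)          # score 100 dropped
  expect_equal(r$n_retained, 3L)         # 1501 is 501 nt away: excluded
  expect_equal(sort(r$distances), c(0, 10, 200))
  expect_equal(r$frac_le_25, 2 / 3)
  expect_equal(r$frac_le_100, 2 / 3)

  shuf <- sites[c(4, 2, 5, 1, 3), ]
  r2 <- polya_distance(shuf, reps, score_min = 945, max_dist = 500)
  expect_equal(sort(r2$distances), sort(r$distances))

  rta <- polya_distance(sites, reps, families = "(TA)n")
  expect_equal(sort(rta$distances), c(0, 200))

  expect_warning(r0 <- polya_distance(sites, reps[0, ]), "no repeats")
  expect_equal(r0$n_retained, 0L)
})

test_that("nearest-feature distance is edge-to-edge with overlap = 0", {
  pk <- data.frame(chrom = "c1", start = c(0L, 0L), end = c(100L, 250L),
                   status = "peak", name = c("a", "b"),
                   stringsAsFactors = FALSE)
  ft <- data.frame(chrom = "c1", start = 200L, end = 300L,
                   stringsAsFactors = FALSE)
  d <- nearest_feature_distance(pk, ft)
  expect_equal(d$distance, c(100, 0))

  set.seed(9)
  s1 <- sample.int(10000, 50); s2 <- sample.int(10000, 50)
  pks <- data.frame(chrom = "c1", start = s1, end = s1 + 50L,
                    name = paste0("p", 1:50), stringsAsFactors = FALSE)
  fts <- data.frame(chrom = "c1", start = s2, end = s2 + 50L,
                    stringsAsFactors = FALSE)
  d2 <- nearest_feature_distance(pks, fts)$distance
  oracle <- vapply(1:50, function(i)
    min(pmax(0, pmax(pks$start[i] - fts$end, fts$start - pks$end[i]))), 0)
  expect_equal(d2, oracle)

  expect_warning(nearest_feature_distance(
    data.frame(chrom = "cZ", start = 1L, end = 2L), ft), "shared")
})
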