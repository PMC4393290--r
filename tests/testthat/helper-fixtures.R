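# Shared fixtures and independent oracles, all built in code.

# random ACGT sequence
rand_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# a step table with all steps equal to a constant
constant_table <- function(c = 10) {
  step_table(stats::setNames(rep(c, 16), twistflexr:::DINUC_STEPS))
}

# naive per-window profiler: recomputes every window mean from scratch
naive_profile <- function(s, table, L = 100L, shift = 1L) {
  x <- step_values(s, table)
  n <- nchar(s)
  starts <- seq.int(0L, n - L, by = shift)
  vapply(starts, function(p) mean(x[(p + 1):(p + L - 1)]), 0)
}

# brute-force maximal-run finder over profile values
runs_oracle <- function(values, S, L, shift = 1L) {
  q <- !is.na(values) & values >= S
  out <- list()
  i <- 1L
  while (i <= length(q)) {
    if (q[i]) {
      j <- i
      while (j < length(q) && q[j + 1L]) j <- j + 1L
      out[[length(out) + 1L]] <- c(start = (i - 1L) * shift,
                                   end = (j - 1L) * shift + L,
                                   n = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out)) do.call(rbind, out) else
    matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("start", "end", "n")))
}

# build a flex_profile object directly from values
make_profile <- function(values, chrom = "c1", L = 100L, shift = 1L) {
  twistflexr:::new_flex_profile(chrom, L, shift, (L - 1L) %/% 2L,
                                length(values) * shift + L, values)
}

# minimal GFF3 writer for hand-made fixtures (1-based closed coordinates)
write_gff3 <- function(df, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     df$chrom, df$type, df$start1, df$end1, df$strand, df$id))
  writeLines(lines, path)
  path
}
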