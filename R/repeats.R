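#' Detect AT tandem repeats ((TA)n, (TTA)n and degenerate AT-rich tracts)
#'
#' A lightweight built-in detector for the AT-rich tandem repeats that form
#' the core of flexibility peaks. For every phasing of the period-2 unit TA
#' (rotations TA, AT) and of the period-3 unit TTA (rotations TTA, TAT, ATT
#' plus the reverse-complement family TAA, AAT, ATA, treated as one family),
#' positions matching the phased unit score \code{1 - min_purity} and
#' mismatching positions score \code{-min_purity}; all maximal
#' positive-scoring segments of this profile (a Ruzzo-Tompa style scan) are
#' therefore intervals that start and end on matching positions and whose
#' match fraction is at least \code{min_purity}. Segments shorter than
#' \code{min_len} are dropped and overlapping candidates across phasings are
#' resolved greedily by match count. When a RepeatMasker annotation is
#' available it should take precedence ([read_repeatmasker_out()]); this
#' detector removes the external-tool dependency.
#'
#' @param seq One sequence (string/\code{DNAString}) or a named set
#'   (\code{DNAStringSet} / named character vector) to scan per chromosome.
#' @param min_len Minimum tract length in bp (default 20; must be >= 4).
#' @param min_purity Minimum fraction of phase-matching positions
#'   (default 0.8).
#' @param chrom Chromosome name used when \code{seq} is a single unnamed
#'   sequence.
#' @return data.frame with \code{chrom, start, end} (0-based half-open),
#'   \code{family} (\code{"(TA)n"}, \code{"(TTA)n"} or \code{"AT-rich"} for
#'   degenerate tracts with purity < 0.9), \code{purity}, \code{matches},
#'   \code{midpoint = floor((start + end) / 2)}.
#' @export
find_at_repeats <- function(seq, min_len = 20L, min_purity = 0.8,
                            chrom = "chr") {
  if (min_len < 4L) .stopf("min_len must be >= 4")
  if (is(seq, "DNAStringSet") ||
      (is.character(seq) && length(seq) > 1L) ||
      (is.character(seq) && !is.null(names(seq)))) {
    nm <- names(seq)
    if (is.null(nm)) nm <- paste0("chr", seq_along(seq))
    out <- lapply(seq_along(seq), function(i)
      find_at_repeats(as.character(seq[[i]]), min_len, min_purity, nm[i]))
    return(do.call(rbind, out))
  }
  s <- toupper(as.character(seq))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  units <- list("(TA)n" = c("TA", "AT"),
                "(TTA)n" = c("TTA", "TAT", "ATT", "TAA", "AAT", "ATA"))
  cand <- list()
  for (fam in names(units)) {
    for (u in units[[fam]]) {
      uc <- strsplit(u, "", fixed = TRUE)[[1]]
      period <- length(uc)
      expected <- uc[((seq_len(n) - 1L) %% period) + 1L]
      m <- ch == expected
      segs <- .max_segments_cpp(m, min_purity)
      if (nrow(segs)) {
        segs <- segs[segs$end - segs$start >= min_len, , drop = FALSE]
        if (nrow(segs)) {
          segs$family <- fam
          cand[[length(cand) + 1L]] <- segs
        }
      }
    }
  }
  if (!length(cand))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      purity = numeric(0), matches = integer(0),
                      midpoint = integer(0), stringsAsFactors = FALSE))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$matches, cand$start), ]
  # greedy non-overlapping selection by match count
  keep <- logical(nrow(cand))
  taken_start <- integer(0); taken_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < taken_end & taken_start < cand$end[i])) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, cand$start[i])
      taken_end <- c(taken_end, cand$end[i])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  fam <- ifelse(cand$purity >= 0.9, cand$family, "AT-rich")
  data.frame(chrom = chrom, start = cand$start, end = cand$end,
             family = fam, purity = cand$purity, matches = cand$matches,
             midpoint = (cand$start + cand$end) %/% 2L,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Plain-R reference implementation of the all-maximal-scoring-subsequence
# decomposition (the compiled .max_segments_cpp is the production path;
# this one is kept as a cross-check). t = match - purity; returned segments
# start/end on matches and have mean(match) >= purity. 0-based half-open.
.max_segments <- function(m, purity) {
  wmis <- -round(purity * 1e6)                   # exact integer weights
  t <- ifelse(m, 1e6 + wmis, wmis)
  cum <- c(0, cumsum(t))
  segs <- list()                  # each: c(start, end, L, R)
  for (i in seq_along(t)) {
    if (t[i] <= 0) next
    k <- c(i - 1L, i, cum[i], cum[i + 1L])
    repeat {
      j <- length(segs)
      while (j >= 1L && segs[[j]][3] >= k[3]) j <- j - 1L
      if (j < 1L) { segs[[length(segs) + 1L]] <- k; break }
      if (segs[[j]][4] >= k[4]) { segs[[length(segs) + 1L]] <- k; break }
      k[1] <- segs[[j]][1]; k[3] <- segs[[j]][3]
      segs <- segs[seq_len(j - 1L)]
    }
  }
  if (!length(segs))
    return(data.frame(start = integer(0), end = integer(0),
                      matches = integer(0), purity = numeric(0)))
  starts <- vapply(segs, `[`, 0, 1); ends <- vapply(segs, `[`, 0, 2)
  matches <- vapply(seq_along(segs), function(i)
    sum(m[(starts[i] + 1L):ends[i]]), 0)
  data.frame(start = as.integer(starts), end = as.integer(ends),
             matches = as.integer(matches),
             purity = matches / (ends - starts))
}
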