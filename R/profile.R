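#' Sliding-window twist-flexibility profiles
#'
#' The profiler evaluates, for every dinucleotide step of a sequence, the
#' twist-angle fluctuation assigned by a [step_table()], then averages the
#' steps of overlapping windows of length \code{window_len} advanced by
#' \code{shift}. Each window's mean is anchored to the window's midpoint
#' dinucleotide step, position \code{window_start + floor((L - 1) / 2)}
#' (for the default L = 100 that is \code{window_start + 49}). Windows that
#' contain an ambiguous base (N) yield \code{NA} and are excluded from all
#' downstream statistics and peak calling.
#'
#' @param window_len Window length L in bp (default 100).
#' @param shift Window shift s in bp (default 1).
#' @return \code{profile_config()} returns a validated configuration list.
#' @export
profile_config <- function(window_len = 100L, shift = 1L) {
  window_len <- as.integer(window_len); shift <- as.integer(shift)
  if (is.na(window_len) || window_len < 2L) .stopf("window_len must be >= 2")
  if (is.na(shift) || shift < 1L || shift > window_len)
    .stopf("shift must satisfy 1 <= shift <= window_len")
  structure(list(window_len = window_len, shift = shift),
            class = "profile_config")
}

#' Per-step twist-fluctuation values of a sequence
#'
#' @param seq A nucleotide string over A/C/G/T/N (or a
#'   \code{Biostrings::DNAString}).
#' @param table A [step_table()].
#' @return Numeric vector of length \code{nchar(seq) - 1}; element i is the
#'   table value of the step \code{(seq[i], seq[i+1])}, \code{NA} where either
#'   base is N.
#' @rdname profile_config
#' @export
step_values <- function(seq, table) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < 2L) .stopf("sequence shorter than 2 bp has no dinucleotide step")
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  b <- code[utf8ToInt(s)]
  bad <- b == 0L & !(strsplit(s, "", fixed = TRUE)[[1]] == "N")
  if (any(bad))
    .stopf("non-ACGTN residue in sequence at position(s) %s",
           paste(utils::head(which(bad), 5L), collapse = ", "))
  b[b == 0L] <- NA_integer_
  idx <- 4L * (b[-n] - 1L) + b[-1L]            # NA propagates
  as.numeric(table)[idx]
}

#' Compute the window profile of one chromosome
#'
#' @param chromseq Sequence (string or \code{DNAString}); for a named element
#'   of a \code{DNAStringSet} pass \code{chrom} explicitly.
#' @param chrom Chromosome name recorded in the profile.
#' @param cfg A [profile_config()].
#' @return An object of class \code{"flex_profile"}: a list with fields
#'   \code{chrom}, \code{window_len}, \code{shift}, \code{anchor} (genomic
#'   0-based position of the first window's midpoint step), \code{seqlen} and
#'   \code{values}. The number of values is
#'   \code{floor((seqlen - L) / s) + 1}; a sequence shorter than L yields an
#'   empty profile with a warning.
#' @rdname profile_config
#' @export
window_profile <- function(chromseq, table, cfg = profile_config(),
                           chrom = "chr") {
  s <- toupper(as.character(chromseq))
  n <- nchar(s)
  L <- cfg$window_len; sh <- cfg$shift
  anchor <- (L - 1L) %/% 2L
  if (n < L) {
    .warnf("sequence %s (%d bp) shorter than window length %d: empty profile",
           chrom, n, L)
    return(new_flex_profile(chrom, L, sh, anchor, n, numeric(0)))
  }
  x <- step_values(s, table)
  w <- L - 1L                                   # steps per window
  # fresh per-window sums (convolution filter): no running-sum cancellation
  sums <- as.numeric(stats::filter(x, rep(1, w), method = "convolution",
                                   sides = 1L))
  starts0 <- seq.int(0L, n - L, by = sh)        # 0-based window starts
  vals <- sums[starts0 + w] / w
  new_flex_profile(chrom, L, sh, anchor, n, vals)
}

new_flex_profile <- function(chrom, window_len, shift, anchor, seqlen, values) {
  structure(list(chrom = chrom, window_len = window_len, shift = shift,
                 anchor = anchor, seqlen = seqlen, values = values),
            class = "flex_profile")
}

#' @param profile A \code{"flex_profile"}.
#' @return \code{profile_positions()} returns the 0-based genomic positions
#'   (midpoint-step anchors) of the profile's values;
#'   \code{profile_window_starts()} the 0-based window start positions.
#' @rdname profile_config
#' @export
profile_positions <- function(profile) {
  profile$anchor + profile$shift * (seq_along(profile$values) - 1L)
}

#' @rdname profile_config
#' @export
profile_window_starts <- function(profile) {
  profile$shift * (seq_along(profile$values) - 1L)
}

#' @export
print.flex_profile <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("flex_profile %s: %d windows (L=%d, s=%d), %d defined, range [%s]\n",
              x$chrom, length(x$values), x$window_len, x$shift, length(v),
              if (length(v)) paste(sprintf("%.3f", range(v)), collapse = ", ")
              else "-"))
  invisible(x)
}
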