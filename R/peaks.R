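#' Two-threshold flexibility peak calling
#'
#' Peak calling proceeds in two stages. First, window values deviating
#' significantly from the genome-wide average are preselected: all windows
#' with value at or above \eqn{S = mean + k \cdot sd} (default k = 2; mean
#' and population sd pooled over every defined window of every chromosome).
#' Maximal runs of consecutive window placements simultaneously at/above S
#' form flexible regions whose genomic footprint is the union of the member
#' windows. Second, regions whose maximal window value reaches the fixed
#' peak threshold \eqn{\theta} (default 13.8 deg) are classified as
#' flexibility peaks; the rest are under-threshold flexible regions.
#'
#' @param preselect_sd_mult Multiplier k in \eqn{S = mean + k \cdot sd}.
#' @param peak_theta Peak threshold \eqn{\theta} in degrees.
#' @param preselect_S Optional explicit preselection threshold overriding the
#'   mean + k sd rule.
#' @return \code{peak_config()}: a validated configuration list.
#' @export
peak_config <- function(preselect_sd_mult = 2, peak_theta = 13.8,
                        preselect_S = NULL) {
  if (preselect_sd_mult <= 0) .stopf("preselect_sd_mult must be > 0")
  if (!is.null(preselect_S) && peak_theta <= preselect_S)
    .stopf("peak_theta must exceed the preselection threshold S")
  structure(list(preselect_sd_mult = preselect_sd_mult,
                 peak_theta = peak_theta, preselect_S = preselect_S),
            class = "peak_config")
}

#' Genome-wide profile statistics and preselection threshold
#'
#' @param profiles A \code{flex_profile} or list of them (all chromosomes).
#' @param sd_mult Multiplier k.
#' @return list with \code{mean}, \code{sd} (population, n denominator),
#'   \code{S = mean + k * sd}, and \code{n} (defined windows pooled).
#' @rdname peak_config
#' @export
genome_stats <- function(profiles, sd_mult = 2) {
  if (inherits(profiles, "flex_profile")) profiles <- list(profiles)
  v <- unlist(lapply(profiles, `[[`, "values"), use.names = FALSE)
  v <- v[!is.na(v)]
  if (length(v) == 0L) .stopf("no defined window values to pool")
  m <- mean(v)
  sd_pop <- sqrt(mean((v - m)^2))
  list(mean = m, sd = sd_pop, S = m + sd_mult * sd_pop, n = length(v))
}

#' Extract maximal above-threshold runs of one chromosome's profile
#'
#' A run is a maximal stretch of consecutive \emph{evaluated} window
#' placements with value >= S; a missing (N-containing) window breaks a run.
#' The region footprint is \code{[first window start, last window start + L)}.
#' No gap merging is performed.
#'
#' @param profile A \code{flex_profile}.
#' @param S Preselection threshold in degrees.
#' @return data.frame with \code{chrom, start, end, max_value, mean_value,
#'   n_windows, status, name} (status/name filled by [classify_peaks()]).
#' @rdname peak_config
#' @export
call_regions <- function(profile, S) {
  v <- profile$values
  q <- !is.na(v) & v >= S
  out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    max_value = numeric(0), mean_value = numeric(0),
                    n_windows = integer(0), status = character(0),
                    name = character(0), stringsAsFactors = FALSE)
  if (!any(q)) return(out)
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  i1 <- starts[keep]; i2 <- ends[keep]
  ws <- profile_window_starts(profile)
  data.frame(chrom = profile$chrom,
             start = ws[i1],
             end = ws[i2] + profile$window_len,
             max_value = vapply(seq_along(i1),
                                function(j) max(v[i1[j]:i2[j]]), 0),
             mean_value = vapply(seq_along(i1),
                                 function(j) mean(v[i1[j]:i2[j]]), 0),
             n_windows = i2 - i1 + 1L,
             status = NA_character_, name = NA_character_,
             stringsAsFactors = FALSE)
}

#' Classify regions into peaks and under-threshold regions
#'
#' Regions with \code{max_value >= theta} get \code{status = "peak"} and are
#' named \code{peak<ROMAN>-<k>}, k counting peaks in ascending coordinate
#' order within each chromosome; the roman numeral comes from
#' \code{chrom_map}, from a \code{chr<ROMAN>} chromosome name, or from the
#' order of first appearance.
#'
#' @param regions Output of [call_regions()] (possibly row-bound across
#'   chromosomes).
#' @param theta Peak threshold in degrees.
#' @param chrom_map Optional named character vector chrom -> roman numeral.
#' @rdname peak_config
#' @export
classify_peaks <- function(regions, theta = 13.8, chrom_map = NULL) {
  if (nrow(regions) == 0L) return(regions)
  regions$status <- ifelse(regions$max_value >= theta, "peak",
                           "under_threshold")
  regions$name <- NA_character_
  rom <- .roman_names(regions$chrom, chrom_map)
  for (cn in unique(regions$chrom)) {
    idx <- which(regions$chrom == cn & regions$status == "peak")
    idx <- idx[order(regions$start[idx])]
    if (length(idx))
      regions$name[idx] <- sprintf("peak%s-%d", rom[idx], seq_along(idx))
  }
  regions
}

#' Distances between adjacent peaks
#'
#' For every peak, the edge-to-edge distance (bp, 0 when footprints touch or
#' overlap) to the nearest other peak on the same chromosome; chromosomes
#' with fewer than two peaks contribute nothing.
#'
#' @param peaks data.frame of peaks (\code{status == "peak"} rows are used).
#' @param bin_width Histogram bin width in bp (default 5000).
#' @return list with \code{distances} (data.frame name, chrom, distance) and
#'   \code{histogram} (data.frame bin_start, bin_end, count).
#' @rdname peak_config
#' @export
interpeak_distances <- function(peaks, bin_width = 5000) {
  if (!is.null(peaks$status)) peaks <- peaks[peaks$status %in% "peak", ]
  rows <- list()
  for (cn in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == cn, ]
    if (nrow(p) < 2L) next
    p <- p[order(p$start), ]
    d <- numeric(nrow(p))
    for (i in seq_len(nrow(p))) {
      gaps <- pmax(0, pmax(p$start[i] - p$end[-i], p$start[-i] - p$end[i]))
      d[i] <- min(gaps)
    }
    rows[[cn]] <- data.frame(name = p$name, chrom = cn, distance = d,
                             stringsAsFactors = FALSE)
  }
  distances <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), chrom = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(distances)) {
    bins <- floor(distances$distance / bin_width)
    tab <- table(factor(bins, levels = 0:max(bins)))
    hist <- data.frame(bin_start = as.integer(names(tab)) * bin_width,
                       bin_end = (as.integer(names(tab)) + 1L) * bin_width,
                       count = as.integer(tab))
  } else {
    hist <- data.frame(bin_start = numeric(0), bin_end = numeric(0),
                       count = integer(0))
  }
  list(distances = distances, histogram = hist)
}

#' Window-value distribution and Gaussian tail comparison
#'
#' Builds the unit-area histogram of all defined window values pooled over
#' chromosomes and compares its upper tail with the density of a Gaussian
#' with the same mean and (population) standard deviation. The excess tail
#' mass, \code{sum((observed - gaussian) * binwidth)} over bins with centre
#' at or above \code{tail_min}, quantifies the non-Gaussian tail of genomic
#' flexibility values out of which peaks emerge.
#'
#' @param tail_min Lower edge (deg) of the tail to compare (default 12).
#' @param binwidth Histogram bin width in degrees.
#' @return list with \code{mids}, \code{breaks}, \code{density},
#'   \code{gaussian}, \code{excess_tail_mass}, \code{mean}, \code{sd}.
#' @rdname peak_config
#' @export
value_distribution <- function(profiles, tail_min = 12, binwidth = 0.05) {
  if (inherits(profiles, "flex_profile")) profiles <- list(profiles)
  v <- unlist(lapply(profiles, `[[`, "values"), use.names = FALSE)
  v <- v[!is.na(v)]
  if (length(v) < 2L) .stopf("need at least two defined window values")
  m <- mean(v); sd_pop <- sqrt(mean((v - m)^2))
  breaks <- seq(floor(min(v) / binwidth) * binwidth,
                ceiling(max(v) / binwidth) * binwidth + binwidth,
                by = binwidth)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  if (sd_pop == 0) {
    .warnf("degenerate sd = 0: Gaussian comparison skipped")
    gauss <- rep(NA_real_, length(h$mids)); excess <- NA_real_
  } else {
    gauss <- stats::dnorm(h$mids, mean = m, sd = sd_pop)
    tail <- h$mids >= tail_min
    excess <- sum((h$density[tail] - gauss[tail]) * binwidth)
  }
  list(mids = h$mids, breaks = h$breaks, density = h$density,
       gaussian = gauss, excess_tail_mass = excess, mean = m, sd = sd_pop)
}
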