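#' Classify intergenic regions by flanking gene orientation
#'
#' Gaps between consecutive non-overlapping ORFs on the same chromosome are
#' classed by the strands of their flanking genes: \code{+ ... -} means the
#' 3' ends face each other (convergent, terminator-only territory),
#' \code{- ... +} means both promoters face the gap (divergent), and equal
#' strands give a unidirectional (tandem) gap containing one gene's
#' terminator and the next gene's promoter. Terminal gaps (before the first
#' or after the last ORF) are excluded; overlapping or abutting ORF pairs
#' produce no region (logged).
#'
#' @param orfs data.frame of features; rows with \code{ftype == "ORF"} (or
#'   all rows when no \code{ftype} column) are used. Strands must be + or -.
#' @return data.frame with \code{chrom, start, end, left_strand,
#'   right_strand, left_id, right_id, oclass}.
#' @export
classify_interorf <- function(orfs) {
  if (!is.null(orfs$ftype)) orfs <- orfs[orfs$ftype == "ORF", ]
  if (nrow(orfs) && any(!(orfs$strand %in% c("+", "-"))))
    .stopf("ORFs must be stranded (+/-) for interORF classification")
  rows <- list()
  for (cn in unique(orfs$chrom)) {
    o <- orfs[orfs$chrom == cn, ]
    o <- o[order(o$start, o$end), ]
    if (nrow(o) < 2L) next
    for (i in seq_len(nrow(o) - 1L)) {
      if (o$start[i + 1L] < o$end[i]) {
        .log(sprintf("overlapping ORFs %s/%s on %s: no interORF region",
                     o$fid[i], o$fid[i + 1L], cn))
        next
      }
      if (o$start[i + 1L] == o$end[i]) next        # abutting: zero-width gap
      ls <- o$strand[i]; rs <- o$strand[i + 1L]
      oclass <- if (ls == "+" && rs == "-") "convergent"
                else if (ls == "-" && rs == "+") "divergent"
                else "unidirectional"
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = cn, start = o$end[i], end = o$start[i + 1L],
                   left_strand = ls, right_strand = rs,
                   left_id = o$fid[i], right_id = o$fid[i + 1L],
                   oclass = oclass, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               left_strand = character(0), right_strand = character(0),
               left_id = character(0), right_id = character(0),
               oclass = character(0), stringsAsFactors = FALSE)
}

#' Assign each peak a genomic placement
#'
#' Placement priority is telomere > rRNA > inside_ORF > interORF: any overlap
#' with an annotated telomere (then rRNA locus) wins; otherwise a peak lies
#' inside an ORF when at least \code{inside_frac} of its length overlaps a
#' single ORF; all remaining peaks are interORF and inherit the orientation
#' class of the intergenic region containing the peak midpoint
#' (\code{floor((start + end) / 2)}). Peaks on chromosomes absent from the
#' annotation stay unresolved (NA placement, logged).
#'
#' @param peaks data.frame of peaks (uses rows with \code{status == "peak"}
#'   when a status column is present).
#' @param features Annotation data.frame from [read_annotation()].
#' @param interorf Optional precomputed [classify_interorf()] table.
#' @param inside_frac Minimum fraction of peak length overlapping one ORF to
#'   call the peak inside that ORF (default 0.5).
#' @return data.frame with \code{name, chrom, start, end, placement, oclass,
#'   orf_id}.
#' @export
locate_peaks <- function(peaks, features, interorf = NULL,
                         inside_frac = 0.5) {
  if (!is.null(peaks$status)) peaks <- peaks[peaks$status %in% "peak", ]
  if (nrow(peaks) == 0L)
    return(data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      placement = character(0), oclass = character(0),
                      orf_id = character(0), stringsAsFactors = FALSE))
  if (is.null(interorf)) interorf <- classify_interorf(features)
  pg <- .df_to_gr(peaks)
  placement <- rep(NA_character_, nrow(peaks))
  oclass <- rep(NA_character_, nrow(peaks))
  orf_id <- rep(NA_character_, nrow(peaks))
  known <- peaks$chrom %in% unique(features$chrom)
  if (any(!known))
    .log(sprintf("%d peak(s) on chromosomes absent from annotation: placement unresolved",
                 sum(!known)))
  .any_overlap <- function(ft) {
    sub <- features[features$ftype == ft, , drop = FALSE]
    if (nrow(sub) == 0L) return(rep(FALSE, nrow(peaks)))
    suppressWarnings(GenomicRanges::countOverlaps(pg, .df_to_gr(sub),
                                                  ignore.strand = TRUE)) > 0
  }
  tel <- .any_overlap("telomere")
  rrn <- .any_overlap("rRNA")
  placement[known & tel] <- "telomere"
  placement[known & !tel & rrn] <- "rRNA"
  orfs <- features[features$ftype == "ORF", , drop = FALSE]
  open <- known & is.na(placement)
  if (nrow(orfs) && any(open)) {
    og <- .df_to_gr(orfs)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(pg, og,
                                                         ignore.strand = TRUE))
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ov <- BiocGenerics::width(IRanges::pintersect(
        GenomicRanges::ranges(pg)[qh], GenomicRanges::ranges(og)[sh]))
      plen <- peaks$end - peaks$start
      for (i in which(open)) {
        j <- which(qh == i)
        if (!length(j)) next
        best <- j[which.max(ov[j])]
        if (ov[best] >= inside_frac * plen[i]) {
          placement[i] <- "inside_ORF"
          orf_id[i] <- orfs$fid[sh[best]]
        }
      }
    }
  }
  open <- known & is.na(placement)
  placement[open] <- "interORF"
  mid <- (peaks$start + peaks$end) %/% 2L
  for (i in which(open)) {
    reg <- interorf[interorf$chrom == peaks$chrom[i] &
                    interorf$start <= mid[i] & mid[i] < interorf$end, ]
    if (nrow(reg)) oclass[i] <- reg$oclass[1]
  }
  data.frame(name = peaks$name, chrom = peaks$chrom, start = peaks$start,
             end = peaks$end, placement = placement, oclass = oclass,
             orf_id = orf_id, stringsAsFactors = FALSE)
}

#' Peak / UTR co-localization
#'
#' UTR intervals are derived per ORF from a measured-length table: the 3'UTR
#' extends \code{utr3_len} nt downstream of the ORF's 3' end on its strand,
#' the 5'UTR \code{utr5_len} nt upstream of its 5' end. ORFs missing from
#' the table fall back to the table's mean lengths (rounded), mirroring how
#' unmeasured genes are usually handled; explicit defaults can override this.
#' A hit is at least 1 bp of overlap between a peak footprint and a UTR
#' interval, so one peak spanning two convergent 3'UTRs scores both ORFs.
#'
#' @param peaks Peak data.frame (rows with \code{status == "peak"} used when
#'   present).
#' @param orfs Feature data.frame; \code{ftype == "ORF"} rows are used.
#' @param utrs data.frame from [read_utr_table()].
#' @param default_utr5,default_utr3 Fallback lengths (nt) for ORFs missing
#'   from \code{utrs}; default: rounded mean of the supplied table.
#' @return list with \code{hits} (peak, orf_id, which_utr) and
#'   \code{summary} (n_peaks_3utr, n_orfs_3utr, n_peaks_5utr, n_orfs_5utr).
#' @export
utr_overlap <- function(peaks, orfs, utrs,
                        default_utr5 = NULL, default_utr3 = NULL) {
  if (!is.null(peaks$status)) peaks <- peaks[peaks$status %in% "peak", ]
  if (!is.null(orfs$ftype)) orfs <- orfs[orfs$ftype == "ORF", ]
  if (is.null(default_utr5)) default_utr5 <- round(mean(utrs$utr5_len))
  if (is.null(default_utr3)) default_utr3 <- round(mean(utrs$utr3_len))
  m <- match(orfs$fid, utrs$orf_id)
  u5 <- ifelse(is.na(m), default_utr5, utrs$utr5_len[m])
  u3 <- ifelse(is.na(m), default_utr3, utrs$utr3_len[m])
  plus <- orfs$strand == "+"
  utr3 <- data.frame(chrom = orfs$chrom,
                     start = ifelse(plus, orfs$end, orfs$start - u3),
                     end = ifelse(plus, orfs$end + u3, orfs$start),
                     orf_id = orfs$fid, which_utr = "3UTR",
                     stringsAsFactors = FALSE)
  utr5 <- data.frame(chrom = orfs$chrom,
                     start = ifelse(plus, orfs$start - u5, orfs$end),
                     end = ifelse(plus, orfs$start, orfs$end + u5),
                     orf_id = orfs$fid, which_utr = "5UTR",
                     stringsAsFactors = FALSE)
  utr <- rbind(utr3, utr5)
  utr$start <- pmax(0L, utr$start)
  utr <- utr[utr$end > utr$start, , drop = FALSE]
  hits <- data.frame(peak = character(0), orf_id = character(0),
                     which_utr = character(0), stringsAsFactors = FALSE)
  if (nrow(peaks) && nrow(utr)) {
    ov <- suppressWarnings(GenomicRanges::findOverlaps(
      .df_to_gr(peaks), .df_to_gr(utr), ignore.strand = TRUE))
    if (length(ov))
      hits <- data.frame(peak = peaks$name[S4Vectors::queryHits(ov)],
                         orf_id = utr$orf_id[S4Vectors::subjectHits(ov)],
                         which_utr = utr$which_utr[S4Vectors::subjectHits(ov)],
                         stringsAsFactors = FALSE)
  }
  h3 <- hits[hits$which_utr == "3UTR", ]
  h5 <- hits[hits$which_utr == "5UTR", ]
  list(hits = hits,
       summary = list(n_peaks_3utr = length(unique(h3$peak)),
                      n_orfs_3utr = length(unique(h3$orf_id)),
                      n_peaks_5utr = length(unique(h5$peak)),
                      n_orfs_5utr = length(unique(h5$orf_id))))
}

#' Distance from scored poly(A) cleavage sites to in-peak repeat midpoints
#'
#' Retains sites with \code{score >= score_min}, computes for each the
#' unsigned distance to the nearest repeat midpoint on the same chromosome
#' (repeats should be restricted to those within peaks, see
#' [repeats_in_peaks()]), and keeps distances \code{<= max_dist}. Reports the
#' retained count, a binned histogram and the fractions within 25 and 100 nt.
#'
#' @param sites data.frame from [read_polya_sites()].
#' @param repeats Repeat data.frame with \code{chrom} and \code{midpoint}
#'   columns (e.g. [repeats_in_peaks()] output).
#' @param score_min Minimum site score (default 945).
#' @param max_dist Maximum distance retained, nt (default 500).
#' @param families Optional character vector restricting repeat families
#'   (matched against \code{repeats$family}).
#' @param bin_width Histogram bin width, nt (default 25).
#' @return list with \code{n_sites, n_intense, n_retained, distances,
#'   histogram, frac_le_25, frac_le_100}.
#' @export
polya_distance <- function(sites, repeats, score_min = 945, max_dist = 500,
                           families = NULL, bin_width = 25) {
  if (!is.null(families) && !is.null(repeats$family))
    repeats <- repeats[repeats$family %in% families, , drop = FALSE]
  n_sites <- nrow(sites)
  sites <- sites[sites$score >= score_min, , drop = FALSE]
  n_intense <- nrow(sites)
  if (nrow(repeats) == 0L) {
    .warnf("no repeats within peaks: empty poly(A) distance result")
    return(list(n_sites = n_sites, n_intense = n_intense, n_retained = 0L,
                distances = numeric(0),
                histogram = data.frame(bin_start = numeric(0),
                                       bin_end = numeric(0),
                                       count = integer(0)),
                frac_le_25 = NA_real_, frac_le_100 = NA_real_))
  }
  d <- rep(NA_real_, nrow(sites))
  for (cn in unique(sites$chrom)) {
    mids <- sort(repeats$midpoint[repeats$chrom == cn])
    i <- which(sites$chrom == cn)
    if (!length(mids) || !length(i)) next
    d[i] <- vapply(sites$pos[i], function(p) min(abs(p - mids)), 0)
  }
  keep <- !is.na(d) & d <= max_dist
  d <- d[keep]
  if (length(d)) {
    bins <- floor(d / bin_width)
    tab <- table(factor(bins, levels = 0:floor(max_dist / bin_width)))
    hist <- data.frame(bin_start = as.integer(names(tab)) * bin_width,
                       bin_end = (as.integer(names(tab)) + 1L) * bin_width,
                       count = as.integer(tab))
  } else {
    hist <- data.frame(bin_start = numeric(0), bin_end = numeric(0),
                       count = integer(0))
  }
  list(n_sites = n_sites, n_intense = n_intense, n_retained = length(d),
       distances = d, histogram = hist,
       frac_le_25 = if (length(d)) mean(d <= 25) else NA_real_,
       frac_le_100 = if (length(d)) mean(d <= 100) else NA_real_)
}

#' Restrict repeats to those overlapping peak footprints
#'
#' @param repeats Repeat data.frame (from [find_at_repeats()] or
#'   [read_repeatmasker_out()]); a missing \code{midpoint} column is filled
#'   with \code{floor((start + end) / 2)}.
#' @param peaks Peak data.frame.
#' @return The overlapping subset of \code{repeats}.
#' @export
repeats_in_peaks <- function(repeats, peaks) {
  if (!is.null(peaks$status)) peaks <- peaks[peaks$status %in% "peak", ]
  if (is.null(repeats$midpoint))
    repeats$midpoint <- (repeats$start + repeats$end) %/% 2L
  if (nrow(repeats) == 0L || nrow(peaks) == 0L)
    return(repeats[integer(0), , drop = FALSE])
  ov <- suppressWarnings(GenomicRanges::countOverlaps(
    .df_to_gr(repeats), .df_to_gr(peaks), ignore.strand = TRUE))
  repeats[ov > 0, , drop = FALSE]
}

#' Edge-to-edge distance from each peak to the nearest feature
#'
#' Generic nearest-feature analysis (used e.g. to compare peaks with
#' nucleosome-depleted segments): 0 for overlapping intervals, otherwise the
#' gap in bp; peaks on chromosomes with no features get NA.
#'
#' @param peaks,features Interval data.frames (\code{chrom, start, end}).
#' @return data.frame with \code{name, chrom, distance}.
#' @export
nearest_feature_distance <- function(peaks, features) {
  if (!is.null(peaks$status)) peaks <- peaks[peaks$status %in% "peak", ]
  shared <- intersect(unique(peaks$chrom), unique(features$chrom))
  if (!length(shared)) {
    .warnf("no shared chromosomes between peaks and features")
    return(data.frame(name = character(0), chrom = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  }
  pg <- .df_to_gr(peaks); fg <- .df_to_gr(features)
  hit <- suppressWarnings(GenomicRanges::distanceToNearest(pg, fg,
                                                           ignore.strand = TRUE))
  d <- rep(NA_real_, nrow(peaks))
  d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  nm <- if (!is.null(peaks$name)) peaks$name else
    sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  data.frame(name = nm, chrom = peaks$chrom, distance = d,
             stringsAsFactors = FALSE)
}
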