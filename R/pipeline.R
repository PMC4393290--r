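#' Run the full flexibility-profiling pipeline in memory
#'
#' Profiles every chromosome, derives the genome-wide preselection threshold
#' S = mean + k*sd, extracts flexible regions, classifies peaks at theta,
#' and (where the corresponding inputs are given) runs the downstream
#' co-localization analytics: interORF orientation classes, peak placement,
#' UTR overlap, AT-repeat localization, poly(A)-site distances, enrichment
#' tables and the half-life group comparison.
#'
#' @param genome Named \code{DNAStringSet} (e.g. from [read_fasta()]).
#' @param features Annotation data.frame ([read_annotation()]); optional.
#' @param table A [step_table()]; default [default_step_table()].
#' @param profile_cfg A [profile_config()].
#' @param peak_cfg A [peak_config()].
#' @param utrs,polya,halflife Optional side tables ([read_utr_table()],
#'   [read_polya_sites()], [read_halflife_table()]).
#' @param repeats Optional repeat annotation ([read_repeatmasker_out()]);
#'   when absent the built-in [find_at_repeats()] detector is used.
#' @param min_len,min_purity Built-in repeat-detector parameters.
#' @param score_min,max_dist Poly(A) distance-analysis parameters.
#' @param chrom_map Optional chrom -> roman map for peak names.
#' @return list with components \code{profiles}, \code{stats},
#'   \code{regions}, \code{peaks}, \code{interorf}, \code{annotations},
#'   \code{utr}, \code{repeats}, \code{repeats_in_peaks}, \code{polya},
#'   \code{enrichment}, \code{halflife_tests}, \code{interpeak},
#'   \code{value_dist}, \code{config}.
#' @export
flex_pipeline <- function(genome, features = NULL,
                          table = default_step_table(),
                          profile_cfg = profile_config(),
                          peak_cfg = peak_config(),
                          utrs = NULL, polya = NULL, halflife = NULL,
                          repeats = NULL,
                          min_len = 20L, min_purity = 0.8,
                          score_min = 945, max_dist = 500,
                          chrom_map = NULL) {
  chroms <- names(genome)
  profiles <- lapply(chroms, function(cn)
    window_profile(genome[[cn]], table, profile_cfg, chrom = cn))
  names(profiles) <- chroms
  gstats <- genome_stats(profiles, peak_cfg$preselect_sd_mult)
  S <- if (!is.null(peak_cfg$preselect_S)) peak_cfg$preselect_S else gstats$S
  regions <- do.call(rbind, lapply(profiles, call_regions, S = S))
  rownames(regions) <- NULL
  regions <- classify_peaks(regions, peak_cfg$peak_theta, chrom_map)
  peaks <- regions[regions$status %in% "peak", , drop = FALSE]
  out <- list(profiles = profiles,
              stats = c(gstats, list(S_used = S,
                                     theta = peak_cfg$peak_theta)),
              regions = regions, peaks = peaks,
              interpeak = interpeak_distances(peaks),
              value_dist = value_distribution(profiles),
              config = list(profile = profile_cfg, peak = peak_cfg,
                            min_len = min_len, min_purity = min_purity,
                            score_min = score_min, max_dist = max_dist))
  if (is.null(repeats)) {
    repeats <- find_at_repeats(genome, min_len = min_len,
                               min_purity = min_purity)
  } else if (is.null(repeats$family)) {
    repeats$family <- repeats$fid
  }
  out$repeats <- repeats
  out$repeats_in_peaks <- repeats_in_peaks(repeats, peaks)
  if (!is.null(features)) {
    out$interorf <- classify_interorf(features)
    out$annotations <- locate_peaks(peaks, features, out$interorf)
    iop <- out$annotations[out$annotations$placement %in% "interORF", ]
    enr <- list()
    n_orfs <- sum(features$ftype == "ORF")
    enr$placement <- enrichment_tables(
      c(interORF = sum(out$annotations$placement %in% "interORF"),
        other = sum(!(out$annotations$placement %in% "interORF"))),
      c(interORF = nrow(out$interorf), other = n_orfs))
    oc_obs <- table(factor(iop$oclass,
                           c("divergent", "unidirectional", "convergent")))
    oc_bg <- table(factor(out$interorf$oclass,
                          c("divergent", "unidirectional", "convergent")))
    enr$orientation <- enrichment_tables(
      stats::setNames(as.integer(oc_obs), names(oc_obs)),
      stats::setNames(as.integer(oc_bg), names(oc_bg)))
    out$enrichment <- enr
    if (!is.null(utrs)) {
      out$utr <- utr_overlap(peaks, features, utrs)
      if (!is.null(halflife)) {
        hit3 <- unique(out$utr$hits$orf_id[out$utr$hits$which_utr == "3UTR"])
        flagged <- halflife$orf_id %in% hit3
        if (sum(flagged) >= 2L && sum(!flagged) >= 2L) {
          out$halflife_tests <- list(
            overall = welch_t_test(halflife$overall_halflife[flagged],
                                   halflife$overall_halflife[!flagged],
                                   c("3UTR-peak ORFs", "other ORFs")),
            polya = welch_t_test(halflife$polya_halflife[flagged],
                                 halflife$polya_halflife[!flagged],
                                 c("3UTR-peak ORFs", "other ORFs")))
        } else {
          .log("too few ORFs per group: half-life comparison skipped")
        }
      }
    }
  }
  if (!is.null(polya)) {
    out$polya <- polya_distance(polya, out$repeats_in_peaks,
                                score_min = score_min, max_dist = max_dist)
    out$polya_ta_only <- polya_distance(polya, out$repeats_in_peaks,
                                        score_min = score_min,
                                        max_dist = max_dist,
                                        families = "(TA)n")
  }
  out
}
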