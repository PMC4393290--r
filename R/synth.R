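#' Specification for the synthetic test genome
#'
#' The generator emulates the statistical structure the pipeline is built
#' for: a compact genome of stranded ORFs separated by short intergenic gaps
#' in a 1:2:1 divergent:unidirectional:convergent mix, AT tandem-repeat
#' tracts planted in the 3'UTR side of convergent and unidirectional gaps
#' (divergent gaps host none), poly(A) cleavage sites concentrated a few nt
#' from the repeat midpoints, and lognormal mRNA half-lives that are lower
#' for ORFs carrying a repeat in their 3'UTR. Background sequence is i.i.d.
#' with a fixed GC fraction. Everything is deterministic given \code{seed}
#' and the returned manifest is exact ground truth, not a statistical
#' summary.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length, bp.
#' @param gc Background GC fraction.
#' @param n_div,n_uni,n_conv Intergenic gaps per chromosome of each
#'   orientation class (divergent / unidirectional / convergent); the
#'   orientation chain requires \code{abs(n_div - n_conv) <= 1}.
#' @param gene_len,gap_len,margin ORF length, gap length, chromosome-end
#'   margin (bp).
#' @param utr5_len,utr3_len UTR lengths recorded in the UTR table (nt).
#' @param repeat_unit,repeat_copies,repeat_sub_rate Planted tandem repeat:
#'   unit (\code{"TA"} or \code{"TTA"}), copy number, per-position
#'   substitution rate. The default (TA)x60 (120 bp) makes at least one
#'   100-bp window lie entirely inside the tract, so under the shipped step
#'   table its window mean equals the pure-tract mean (well above the peak
#'   threshold) and every planted tract is guaranteed to produce a peak.
#' @param repeat_offset Tract offset (bp) inside the hosting 3'UTR.
#' @param plant_stride Plant a repeat in every \code{plant_stride}-th
#'   eligible (convergent or unidirectional) gap, in coordinate order
#'   (default 2). Keeps repeat-carrying ORFs a minority of all ORFs, the
#'   situation the downstream group statistics are meant for. \code{0}
#'   plants nothing.
#' @param sites_per_repeat Poly(A) sites generated per planted repeat.
#' @param polya_near_frac,polya_near_range,polya_far_range Site offsets from
#'   the repeat midpoint are drawn from \code{near_range} with probability
#'   \code{near_frac}, else from \code{far_range} (nt, unsigned; sign
#'   random).
#' @param intense_frac,intense_score_range,weak_score_range Site score
#'   model: intense sites (score >= 945) vs weak ones.
#' @param noise_sites_per_chrom Unrelated background sites per chromosome.
#' @param halflife_flagged_meanlog,halflife_bg_meanlog,halflife_sdlog,
#'   polya_halflife_factor Lognormal half-life model (minutes) for
#'   repeat-carrying vs background ORFs.
#' @param seed RNG seed; all generator randomness flows through it.
#' @return A validated spec (class \code{"synth_spec"}).
#' @export
synth_spec <- function(n_chrom = 3L, chrom_len = 100000L, gc = 0.38,
                       n_div = 4L, n_uni = 8L, n_conv = 4L,
                       gene_len = 1500L, gap_len = 400L, margin = 2000L,
                       utr5_len = 70L, utr3_len = 120L,
                       repeat_unit = "TA", repeat_copies = 60L,
                       repeat_sub_rate = 0, repeat_offset = 10L,
                       plant_stride = 2L,
                       sites_per_repeat = 4L,
                       polya_near_frac = 0.75,
                       polya_near_range = c(5L, 25L),
                       polya_far_range = c(26L, 500L),
                       intense_frac = 0.8,
                       intense_score_range = c(945L, 8000L),
                       weak_score_range = c(1L, 944L),
                       noise_sites_per_chrom = 20L,
                       halflife_flagged_meanlog = log(14),
                       halflife_bg_meanlog = log(24),
                       halflife_sdlog = 0.4,
                       polya_halflife_factor = 0.6,
                       seed = 1L) {
  spec <- as.list(environment())
  n_gaps <- n_div + n_uni + n_conv
  n_genes <- n_gaps + 1L
  needed <- 2L * margin + n_genes * gene_len + n_gaps * gap_len
  if (needed > chrom_len)
    .stopf("infeasible packing: %d bp of genes/gaps/margins in a %d bp chromosome",
           needed, chrom_len)
  if (abs(n_div - n_conv) > 1L)
    .stopf("infeasible orientation chain: |n_div - n_conv| must be <= 1")
  rep_len <- repeat_copies * nchar(repeat_unit)
  if (repeat_offset + rep_len > gap_len)
    .stopf("planted repeat (%d bp + offset %d) does not fit in a %d bp gap",
           rep_len, repeat_offset, gap_len)
  if (utr3_len > gap_len || utr5_len > gap_len)
    .stopf("UTR lengths must fit inside a gap")
  structure(spec, class = "synth_spec")
}

# gap class order honouring the strand chain (conv needs left +, div left -)
.gap_class_sequence <- function(n_div, n_uni, n_conv) {
  classes <- character(0)
  cur <- if (n_conv >= n_div) "+" else "-"
  first <- cur
  nd <- n_div; nu <- n_uni; nc <- n_conv
  while (nd + nu + nc > 0L) {
    if (nu > nd + nc) { classes <- c(classes, "unidirectional"); nu <- nu - 1L }
    else if (cur == "+" && nc > 0L) { classes <- c(classes, "convergent"); nc <- nc - 1L; cur <- "-" }
    else if (cur == "-" && nd > 0L) { classes <- c(classes, "divergent"); nd <- nd - 1L; cur <- "+" }
    else if (nu > 0L) { classes <- c(classes, "unidirectional"); nu <- nu - 1L }
    else .stopf("infeasible orientation counts")
  }
  list(classes = classes, first_strand = first)
}

#' Simulate the genome and its ground-truth manifest
#'
#' @param spec A [synth_spec()].
#' @return list with \code{genome} (named \code{DNAStringSet}) and
#'   \code{manifest}: data.frames \code{genes}, \code{interorf} (with true
#'   orientation class), \code{repeats}, \code{utrs}, \code{polya} (with
#'   true offsets), \code{halflife} (with the flagged-group indicator).
#' @rdname synth_spec
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
         G = spec$gc / 2, T = (1 - spec$gc) / 2)
  chroms <- paste0("chr", as.character(utils::as.roman(seq_len(spec$n_chrom))))
  n_gaps <- spec$n_div + spec$n_uni + spec$n_conv
  n_genes <- n_gaps + 1L
  unit <- toupper(spec$repeat_unit)
  rep_len <- spec$repeat_copies * nchar(unit)
  seqs <- character(spec$n_chrom)
  genes <- list(); gaps <- list(); reps <- list(); sites <- list()
  for (ci in seq_len(spec$n_chrom)) {
    cn <- chroms[ci]
    ch <- sample(names(p), spec$chrom_len, replace = TRUE, prob = p)
    ord <- .gap_class_sequence(spec$n_div, spec$n_uni, spec$n_conv)
    strands <- character(n_genes)
    strands[1] <- ord$first_strand
    for (j in seq_len(n_gaps)) {
      strands[j + 1L] <- switch(ord$classes[j],
                                convergent = "-",
                                divergent = "+",
                                unidirectional = strands[j])
    }
    pos <- spec$margin
    gstart <- integer(n_genes); gend <- integer(n_genes)
    gapdf <- data.frame(start = integer(n_gaps), end = integer(n_gaps),
                        oclass = ord$classes, stringsAsFactors = FALSE)
    for (g in seq_len(n_genes)) {
      gstart[g] <- pos; gend[g] <- pos + spec$gene_len
      pos <- pos + spec$gene_len
      if (g <= n_gaps) {
        gapdf$start[g] <- pos; gapdf$end[g] <- pos + spec$gap_len
        pos <- pos + spec$gap_len
      }
    }
    fid <- sprintf("%s_g%02d", cn, seq_len(n_genes))
    genes[[ci]] <- data.frame(chrom = cn, start = gstart, end = gend,
                              strand = strands, ftype = "ORF", fid = fid,
                              stringsAsFactors = FALSE)
    gapdf$chrom <- cn
    gapdf$left_id <- fid[seq_len(n_gaps)]
    gapdf$right_id <- fid[seq_len(n_gaps) + 1L]
    gaps[[ci]] <- gapdf
    # plant repeats in the 3'UTR side of convergent/unidirectional gaps,
    # every plant_stride-th eligible gap
    eligible <- which(gapdf$oclass != "divergent")
    planted <- if (spec$plant_stride >= 1L && length(eligible))
      eligible[seq(1L, length(eligible), by = spec$plant_stride)]
    else integer(0)
    for (j in planted) {
      cls <- gapdf$oclass[j]
      left_plus <- strands[j] == "+"
      host <- if (cls == "convergent") gapdf$left_id[j]
              else if (left_plus) gapdf$left_id[j] else gapdf$right_id[j]
      host_left <- cls == "convergent" || left_plus
      tstart <- if (host_left) gapdf$start[j] + spec$repeat_offset
                else gapdf$end[j] - spec$repeat_offset - rep_len
      tract <- strsplit(strrep(unit, spec$repeat_copies), "")[[1]]
      if (spec$repeat_sub_rate > 0) {
        nsub <- stats::rbinom(1L, rep_len, spec$repeat_sub_rate)
        if (nsub > 0) {
          at <- sample.int(rep_len, nsub)
          tract[at] <- sample(c("A", "C", "G", "T"), nsub, replace = TRUE)
        }
      }
      ch[(tstart + 1L):(tstart + rep_len)] <- tract
      reps[[length(reps) + 1L]] <-
        data.frame(chrom = cn, start = tstart, end = tstart + rep_len,
                   unit = unit, copies = spec$repeat_copies,
                   sub_rate = spec$repeat_sub_rate, host_orf = host,
                   gap_class = cls,
                   midpoint = (2L * tstart + rep_len) %/% 2L,
                   stringsAsFactors = FALSE)
      # poly(A) sites around the repeat midpoint
      mid <- (2L * tstart + rep_len) %/% 2L
      for (k in seq_len(spec$sites_per_repeat)) {
        near <- stats::runif(1) < spec$polya_near_frac
        rng <- if (near) spec$polya_near_range else spec$polya_far_range
        off <- sample(rng[1]:rng[2], 1L) * sample(c(-1L, 1L), 1L)
        intense <- stats::runif(1) < spec$intense_frac
        srng <- if (intense) spec$intense_score_range else spec$weak_score_range
        sites[[length(sites) + 1L]] <-
          data.frame(chrom = cn,
                     pos = min(max(mid + off, 0L), spec$chrom_len - 1L),
                     strand = if (host_left) strands[j] else strands[j + 1L],
                     score = sample(srng[1]:srng[2], 1L),
                     offset = abs(off), from_repeat = TRUE,
                     stringsAsFactors = FALSE)
      }
    }
    # unrelated background sites
    if (spec$noise_sites_per_chrom > 0L) {
      sites[[length(sites) + 1L]] <-
        data.frame(chrom = cn,
                   pos = sample.int(spec$chrom_len, spec$noise_sites_per_chrom) - 1L,
                   strand = sample(c("+", "-"), spec$noise_sites_per_chrom,
                                   replace = TRUE),
                   score = sample(spec$weak_score_range[1]:spec$intense_score_range[2],
                                  spec$noise_sites_per_chrom, replace = TRUE),
                   offset = NA_real_, from_repeat = FALSE,
                   stringsAsFactors = FALSE)
    }
    seqs[ci] <- paste(ch, collapse = "")
  }
  genes <- do.call(rbind, genes)
  gaps <- do.call(rbind, gaps)
  reps <- if (length(reps)) do.call(rbind, reps) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               unit = character(0), copies = integer(0), sub_rate = numeric(0),
               host_orf = character(0), gap_class = character(0),
               midpoint = integer(0), stringsAsFactors = FALSE)
  polya <- if (length(sites)) do.call(rbind, sites) else
    data.frame(chrom = character(0), pos = integer(0), strand = character(0),
               score = integer(0), offset = numeric(0),
               from_repeat = logical(0), stringsAsFactors = FALSE)
  utrs <- data.frame(orf_id = genes$fid, utr5_len = spec$utr5_len,
                     utr3_len = spec$utr3_len, stringsAsFactors = FALSE)
  flagged <- genes$fid %in% reps$host_orf
  overall <- stats::rlnorm(nrow(genes),
                           ifelse(flagged, spec$halflife_flagged_meanlog,
                                  spec$halflife_bg_meanlog),
                           spec$halflife_sdlog)
  halflife <- data.frame(orf_id = genes$fid,
                         overall_halflife = overall,
                         polya_halflife = overall * spec$polya_halflife_factor *
                           exp(stats::rnorm(nrow(genes), 0, 0.1)),
                         flagged = flagged, stringsAsFactors = FALSE)
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
  list(genome = genome,
       manifest = list(genes = genes, interorf = gaps, repeats = reps,
                       utrs = utrs, polya = polya, halflife = halflife))
}

#' Write a full on-disk fixture exercising the whole pipeline
#'
#' Materializes [simulate_genome()] output as the standard input formats:
#' genome FASTA, gene annotation GFF3, UTR / poly(A)-site / half-life
#' tab-separated tables, a RepeatMasker-style .out of the planted repeats,
#' plus the ground-truth manifest tables.
#'
#' @param dir Output directory (created if missing).
#' @return list with \code{paths} (named file paths) and the simulation's
#'   \code{manifest}.
#' @rdname synth_spec
#' @export
end_to_end_fixture <- function(spec, dir) {
  sim <- simulate_genome(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    utrs = file.path(dir, "utrs.tsv"),
    polya = file.path(dir, "polya_sites.tsv"),
    halflife = file.path(dir, "halflives.tsv"),
    repeats = file.path(dir, "repeats.out")
  )
  write_fasta(sim$genome, paths$fasta)
  g <- sim$manifest$genes
  gr <- GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(g$start + 1L, g$end),
                               strand = g$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- g$fid
  rtracklayer::export(gr, paths$gff3, format = "gff3")
  write_tsv_table(sim$manifest$utrs, paths$utrs)
  write_tsv_table(sim$manifest$polya[, c("chrom", "pos", "strand", "score")],
                  paths$polya)
  write_tsv_table(sim$manifest$halflife[, c("orf_id", "overall_halflife",
                                            "polya_halflife")],
                  paths$halflife)
  r <- sim$manifest$repeats
  if (nrow(r)) {
    r$strand <- "+"
    r$fid <- paste0("(", r$unit, ")n")
    write_repeatmasker_out(r, paths$repeats)
  }
  for (nm in names(sim$manifest))
    write_tsv_table(sim$manifest[[nm]],
                    file.path(dir, sprintf("manifest_%s.tsv", nm)))
  list(paths = paths, manifest = sim$manifest)
}
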