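#' Read a genome FASTA
#'
#' Sequences are normalized to uppercase A/C/G/T/N: lowercase is folded to
#' uppercase and every IUPAC ambiguity code (R, Y, S, W, K, M, B, D, H, V) is
#' mapped to N. Any residue outside the nucleotide alphabet after
#' normalization is a hard error naming the record.
#'
#' @param path FASTA file (possibly multi-record).
#' @return A \code{Biostrings::DNAStringSet}, one element per record, in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) .stopf("cannot parse FASTA %s: %s",
                                             path, conditionMessage(e)))
  if (length(set) == 0L) .stopf("FASTA file %s contains no records", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    .stopf("duplicate chromosome name(s) in %s: %s", path,
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(gsub("[ \t]", "", as.character(set)))
  seqs <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seqs)
  ok <- grepl("^[ACGTN]+$", seqs)
  if (!all(ok))
    .stopf("record '%s' contains non-nucleotide residues after normalization",
           nm[which(!ok)[1]])
  if (any(nchar(seqs) == 0L))
    .stopf("record '%s' has an empty sequence", nm[which(nchar(seqs) == 0L)[1]])
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' @param seqs Named \code{DNAStringSet} or named character vector.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# configurable GFF3 type -> internal feature class mapping
default_type_map <- function() {
  c(gene = "ORF", ORF = "ORF", CDS = "ORF", mRNA = "ORF",
    five_prime_UTR = "5UTR", three_prime_UTR = "3UTR",
    telomere = "telomere", rRNA = "rRNA", rRNA_gene = "rRNA",
    repeat_region = "repeat")
}

#' Read feature annotations (GFF3 or BED6)
#'
#' All coordinates are normalized to the package-wide 0-based half-open
#' convention: GFF3's 1-based closed intervals are shifted, BED passes
#' through unchanged.
#'
#' @param path Annotation file.
#' @param dialect \code{"gff3"} or \code{"bed6"}.
#' @param type_map Named character vector mapping GFF3 \code{type} values to
#'   internal feature classes (ORF, telomere, rRNA, 5UTR, 3UTR, repeat,
#'   other); unmapped types become \code{"other"}.
#' @param ftype Feature class assigned to BED records (BED carries none).
#' @return data.frame with columns \code{chrom, start, end, strand, ftype,
#'   fid}.
#' @export
read_annotation <- function(path, dialect = c("gff3", "bed6"),
                            type_map = default_type_map(), ftype = "other") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  gr <- rtracklayer::import(path,
                            format = if (dialect == "gff3") "gff3" else "bed")
  if (length(gr) == 0L) return(.empty_features())
  mc <- S4Vectors::mcols(gr)
  if (dialect == "gff3") {
    ft <- unname(type_map[as.character(mc$type)])
    ft[is.na(ft)] <- "other"
    fid <- as.character(mc$ID)
    if (all(is.na(fid)) && "Name" %in% names(mc)) fid <- as.character(mc$Name)
    fid[is.na(fid)] <- paste0("feature", seq_len(length(gr)))[is.na(fid)]
  } else {
    ft <- rep(ftype, length(gr))
    fid <- if ("name" %in% names(mc)) as.character(mc$name)
           else paste0("feature", seq_len(length(gr)))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   strand = strand, ftype = ft, fid = fid,
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end))
    .stopf("interval with start >= end after conversion in %s (e.g. %s)",
           path, df$fid[which(df$start >= df$end)[1]])
  if (any(df$ftype == "ORF" & !(df$strand %in% c("+", "-"))))
    .stopf("ORF feature without strand in %s", path)
  df
}

#' Write intervals as BED6
#'
#' @param regions data.frame with \code{chrom, start, end} (0-based
#'   half-open) and optionally \code{name} (or \code{fid}), \code{score},
#'   \code{strand}.
#' @rdname read_annotation
#' @export
write_bed <- function(regions, path) {
  if (is.null(regions) || nrow(regions) == 0L)
    .stopf("refusing to write empty region list to %s", path)
  name <- if (!is.null(regions$name)) regions$name
          else if (!is.null(regions$fid)) regions$fid else "."
  name[is.na(name)] <- "."
  score <- if (!is.null(regions$score)) regions$score else 0
  strand <- if (!is.null(regions$strand)) regions$strand else "."
  strand[is.na(strand)] <- "."
  out <- data.frame(regions$chrom, regions$start, regions$end,
                    name, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a RepeatMasker .out file
#'
#' Expects the standard column layout (three header lines, whitespace
#' separated); 1-based inclusive query coordinates are converted to 0-based
#' half-open. The repeat family string (e.g. \code{"(TA)n"}) is kept verbatim
#' as \code{fid}. Malformed data lines are skipped with a warning; a file
#' whose data lines are all malformed (or absent) is an error.
#'
#' @param path RepeatMasker .out file.
#' @return data.frame as [read_annotation()], \code{ftype = "repeat"}.
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) .stopf("RepeatMasker file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) > 0L) lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) .stopf("no data lines in RepeatMasker file %s", path)
  rows <- vector("list", length(lines))
  nbad <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    beg <- suppressWarnings(as.integer(f[6])); end <- suppressWarnings(as.integer(f[7]))
    if (length(f) < 11L || is.na(beg) || is.na(end) || beg > end) {
      nbad <- nbad + 1L
      .warnf("skipping malformed RepeatMasker line %d in %s", i, path)
      next
    }
    rows[[i]] <- data.frame(chrom = f[5], start = beg - 1L, end = end,
                            strand = if (f[9] == "C") "-" else "+",
                            ftype = "repeat", fid = f[10],
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    .stopf("all %d data lines malformed in RepeatMasker file %s", nbad, path)
  do.call(rbind, rows)
}

#' @param repeats data.frame with \code{chrom, start, end, strand, fid}
#'   (internal coordinates); written in the standard .out column layout.
#' @rdname read_repeatmasker_out
#' @export
write_repeatmasker_out <- function(repeats, path) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  strand <- ifelse(repeats$strand == "-", "C", "+")
  body <- sprintf(" 1000   0.0  0.0  0.0  %s %8d %8d (0) %s %-14s %-18s 1 %d (0) %d",
                  repeats$chrom, repeats$start + 1L, repeats$end, strand,
                  repeats$fid, "Simple_repeat",
                  repeats$end - repeats$start, seq_len(nrow(repeats)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a flexibility profile as bedGraph or fixedStep wiggle
#'
#' bedGraph intervals are 0-based half-open and runs of consecutive equal
#' values are merged into one line; wiggle \code{fixedStep} blocks are
#' 1-based. Values are printed with 4 decimal places; windows with missing
#' (N-containing) values are omitted (bedGraph) or break the block (wiggle).
#'
#' @param profile A \code{flex_profile}.
#' @param path Output file.
#' @export
write_bedgraph <- function(profile, path) {
  v <- profile$values
  if (length(v) == 0L) .stopf("profile is empty; nothing to write")
  pos <- profile_positions(profile)
  keep <- !is.na(v)
  v <- v[keep]; pos <- pos[keep]
  if (length(v) == 0L) .stopf("profile has no defined values")
  s <- profile$shift
  # merge runs of equal value at contiguous positions
  newrun <- c(TRUE, !(v[-1] == v[-length(v)] & pos[-1] == pos[-length(pos)] + s))
  run <- cumsum(newrun)
  first <- !duplicated(run); last <- !duplicated(run, fromLast = TRUE)
  lines <- sprintf("%s\t%d\t%d\t%.4f", profile$chrom, pos[first],
                   pos[last] + s, v[first])
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
write_wiggle <- function(profile, path) {
  v <- profile$values
  if (length(v) == 0L) .stopf("profile is empty; nothing to write")
  pos <- profile_positions(profile)
  con <- file(path, "w"); on.exit(close(con))
  def <- !is.na(v)
  block <- cumsum(c(TRUE, diff(def) != 0))
  for (b in unique(block[def])) {
    idx <- which(block == b)
    writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                       profile$chrom, pos[idx[1]] + 1L, profile$shift,
                       profile$shift), con)
    writeLines(sprintf("%.4f", v[idx]), con)
  }
  invisible(path)
}

# ---- tab-separated tables (documented column order, header required) ------

.read_tsv <- function(path, required) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    .stopf("%s lacks required column(s): %s", path, paste(miss, collapse = ", "))
  df
}

#' Read the tabular side inputs
#'
#' All three tables are tab-separated with a header line.
#' \itemize{
#'   \item UTR table: \code{orf_id}, \code{utr5_len}, \code{utr3_len}
#'     (non-negative nt).
#'   \item half-life table: \code{orf_id}, \code{overall_halflife},
#'     \code{polya_halflife} (minutes; NA allowed).
#'   \item poly(A) site table: \code{chrom}, \code{pos} (0-based),
#'     \code{strand} (+/-), \code{score} (non-negative read count).
#' }
#' @param path Input file.
#' @return data.frame with the validated columns.
#' @export
read_utr_table <- function(path) {
  df <- .read_tsv(path, c("orf_id", "utr5_len", "utr3_len"))
  if (any(df$utr5_len < 0 | df$utr3_len < 0, na.rm = TRUE))
    .stopf("negative UTR length in %s", path)
  df
}

#' @rdname read_utr_table
#' @export
read_halflife_table <- function(path) {
  df <- .read_tsv(path, c("orf_id", "overall_halflife", "polya_halflife"))
  if (any(df$overall_halflife <= 0 | df$polya_halflife <= 0, na.rm = TRUE))
    .stopf("non-positive half-life in %s", path)
  df
}

#' @rdname read_utr_table
#' @export
read_polya_sites <- function(path) {
  df <- .read_tsv(path, c("chrom", "pos", "strand", "score"))
  if (any(!(df$strand %in% c("+", "-")))) .stopf("bad strand in %s", path)
  if (any(df$score < 0)) .stopf("negative score in %s", path)
  df
}

#' @param df data.frame to write.
#' @rdname read_utr_table
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
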