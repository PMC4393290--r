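# Shared internal helpers: coordinate conversion, dinucleotide alphabet,
# roman chromosome naming. All internal coordinates are 0-based half-open;
# conversion to/from 1-based closed happens only at I/O boundaries.

#' @importFrom methods as is
NULL

# The 16 dinucleotide steps in fixed alphabetical order.
DINUC_STEPS <- c("AA","AC","AG","AT","CA","CC","CG","CT",
                 "GA","GC","GG","GT","TA","TC","TG","TT")

.revcomp_chars <- c(A = "T", C = "G", G = "C", T = "A")

# reverse complement of a dinucleotide step, e.g. "AC" -> "GT"
revcomp_step <- function(step) {
  ch <- strsplit(step, "", fixed = TRUE)
  vapply(ch, function(x) paste0(.revcomp_chars[x[2]], .revcomp_chars[x[1]]), "")
}

# log to stderr; data never goes through message()
.log <- function(...) message("[twistflexr] ", ...)

# internal 0-based half-open data.frame -> GRanges (1-based closed)
.df_to_gr <- function(df, keep = character(0)) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[is.na(strand) | strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  for (k in keep) S4Vectors::mcols(gr)[[k]] <- df[[k]]
  gr
}

# map chromosome names to roman numerals for peak naming.
# chrom_map: named character vector (chrom -> roman); unmapped chromosomes
# fall back to an embedded roman in the name ("chrIV" -> "IV") or, failing
# that, to the order of first appearance.
.roman_names <- function(chroms, chrom_map = NULL) {
  uc <- unique(chroms)
  out <- character(length(uc))
  names(out) <- uc
  for (i in seq_along(uc)) {
    cn <- uc[i]
    if (!is.null(chrom_map) && cn %in% names(chrom_map)) {
      out[cn] <- chrom_map[[cn]]
    } else if (grepl("^chr([IVXLCDM]+)$", cn)) {
      out[cn] <- sub("^chr", "", cn)
    } else {
      out[cn] <- as.character(utils::as.roman(i))
    }
  }
  out[chroms]
}

# empty feature data.frame with the internal column layout
.empty_features <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), ftype = character(0), fid = character(0),
             stringsAsFactors = FALSE)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
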