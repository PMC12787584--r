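#' Describe a genome as an ordered set of chromosome lengths
#'
#' All coordinates in this package are 0-based, half-open (BED convention):
#' an interval `[start, end)` covers bases `start` to `end - 1`.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bases (> 0).
#' @return An object of class `genome_description`: a data.frame with columns
#'   `chrom` and `length`, preserving the given order.
#' @examples
#' genome_description(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_description <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != base::length(length)) stop("chrom and length differ in length")
  if (any(!is.finite(length)) || any(length <= 0)) stop("chromosome lengths must be > 0")
  structure(data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
            class = c("genome_description", "data.frame"))
}

#' @export
print.genome_description <- function(x, ...) {
  cat("genome_description:", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bases\n")
  print.data.frame(x, ...)
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop("chromosome(s) not in genome: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$length[i]
}

#' Construct a table of genomic intervals
#'
#' @param chrom,start,end Vectors defining 0-based half-open spans.
#' @param name,score,strand Optional per-interval annotations; strand must be
#'   one of `"+"`, `"-"`, `"."`.
#' @param genome Optional [genome_description()]; when given, intervals are
#'   validated against chromosome bounds.
#' @return A data.frame with columns chrom, start, end, name, score, strand.
#' @export
genome_intervals <- function(chrom, start, end, name = NA_character_,
                             score = NA_real_, strand = ".", genome = NULL) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df, genome)
  df
}

validate_intervals <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) stop("invalid interval(s) at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "),
                        ": need 0 <= start < end")
  if (!is.null(genome)) {
    len <- chrom_length(genome, x$chrom)
    bad <- which(x$end > len)
    if (length(bad)) stop("interval(s) exceed chromosome length at row(s) ",
                          paste(utils::head(bad, 5), collapse = ", "))
  }
  if ("strand" %in% names(x)) {
    ok <- x$strand %in% c("+", "-", ".")
    if (!all(ok)) stop("strand must be one of '+', '-', '.'")
  }
  invisible(x)
}

## 0-based half-open data.frame -> 1-based closed GRanges
as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

## logical: does each interval of a overlap >= minoverlap bases of any in b
overlaps_any <- function(a, b, minoverlap = 1L) {
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  if (nrow(a) == 0L) return(logical(0))
  IRanges::overlapsAny(as_granges(a), as_granges(b), minoverlap = minoverlap)
}

#' Merge intervals, joining overlapping and bookended spans
#'
#' @param x Interval data.frame.
#' @return Interval data.frame of merged spans, sorted by chrom then start.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(genome_intervals(character(), numeric(), numeric() + 1))
  r <- GenomicRanges::reduce(as_granges(x))
  data.frame(chrom = as.character(GenomicRanges::seqnames(r)),
             start = GenomicRanges::start(r) - 1,
             end = as.numeric(GenomicRanges::end(r)),
             name = NA_character_, score = NA_real_, strand = ".",
             stringsAsFactors = FALSE)
}

#' Construct a peak table
#'
#' Peaks are intervals with an optional summit offset (bases from `start`),
#' an enrichment score, and a replicate label.
#'
#' @inheritParams genome_intervals
#' @param summit_offset Offset of the summit from `start`, or `NA`.
#' @param enrichment Peak enrichment (e.g. MACS2 signalValue).
#' @param replicate_id Replicate label.
#' @return A data.frame of peaks.
#' @export
peaks_table <- function(chrom, start, end, name = NA_character_,
                        summit_offset = NA_real_, enrichment = NA_real_,
                        replicate_id = NA_character_, genome = NULL) {
  df <- genome_intervals(chrom, start, end, name = name, genome = genome)
  df$summit_offset <- as.numeric(summit_offset)
  df$enrichment <- as.numeric(enrichment)
  df$replicate_id <- as.character(replicate_id)
  bad <- which(!is.na(df$summit_offset) &
                 (df$summit_offset < 0 | df$summit_offset >= df$end - df$start))
  if (length(bad)) stop("summit_offset out of range at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  df
}
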