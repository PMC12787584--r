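## Readers/writers for the plain-text formats the pipeline consumes.
## All writers emit tab-separated, newline-terminated records.

read_tab_lines <- function(path) {
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

num_or_stop <- function(x, line_no, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) stop("malformed ", what, " at line ", line_no[bad[1]],
                        " of ", path)
  v
}

#' Read a BED3–BED6 or ENCODE narrowPeak file
#'
#' narrowPeak input (10 columns) populates peak fields: column 7 (signalValue)
#' becomes `enrichment` and column 10 becomes `summit_offset` (bases from
#' start; `-1` maps to `NA`). Input order is preserved.
#'
#' @param path File path.
#' @param genome Optional [genome_description()] used to validate coordinates.
#' @return An interval data.frame; for narrowPeak input, a peak data.frame
#'   (see [peaks_table()]).
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- read_tab_lines(path)
  if (!length(lines))
    return(genome_intervals(character(), numeric(), numeric() + 1))
  fl <- split_fields(lines)
  nf <- lengths(fl)
  if (any(nf < 3)) stop("malformed BED line ", which(nf < 3)[1], " in ", path,
                        ": fewer than 3 fields")
  ln <- seq_along(lines)
  chrom <- vapply(fl, `[`, "", 1L)
  start <- num_or_stop(vapply(fl, `[`, "", 2L), ln, path, "start")
  end <- num_or_stop(vapply(fl, `[`, "", 3L), ln, path, "end")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) stop("empty or inverted interval at line ", bad[1], " of ", path)
  get_col <- function(k, default) {
    ifelse(nf >= k, vapply(fl, function(f) if (length(f) >= k) f[k] else NA_character_, ""),
           default)
  }
  name <- get_col(4L, NA_character_)
  score <- suppressWarnings(as.numeric(get_col(5L, NA_character_)))
  strand <- get_col(6L, ".")
  strand[is.na(strand) | !strand %in% c("+", "-", ".")] <- "."
  if (all(nf >= 10L)) {
    enrich <- num_or_stop(vapply(fl, `[`, "", 7L), ln, path, "signalValue")
    summit <- num_or_stop(vapply(fl, `[`, "", 10L), ln, path, "summit")
    summit[summit < 0] <- NA_real_
    out <- peaks_table(chrom, start, end, name = name, summit_offset = summit,
                       enrichment = enrich, genome = genome)
    out$score <- score
    out$strand <- strand
    return(out)
  }
  genome_intervals(chrom, start, end, name = name, score = score,
                   strand = strand, genome = genome)
}

fmt_num <- function(x) {
  ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE, digits = 12))
}

#' Write intervals as BED6
#'
#' @param x Interval data.frame.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  score <- if ("score" %in% names(x)) fmt_num(x$score) else "."
  strand <- if ("strand" %in% names(x)) x$strand else "."
  writeLines(paste(x$chrom, fmt_num(x$start), fmt_num(x$end),
                   name, score, strand, sep = "\t"), path)
  invisible(path)
}

#' Write peaks as ENCODE narrowPeak
#'
#' @param x Peak data.frame (see [peaks_table()]).
#' @param path Output path.
#' @export
write_narrowpeak <- function(x, path) {
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  summit <- ifelse(is.na(x$summit_offset), -1, x$summit_offset)
  writeLines(paste(x$chrom, fmt_num(x$start), fmt_num(x$end), name, "0", ".",
                   fmt_num(x$enrichment), "-1", "-1", fmt_num(summit),
                   sep = "\t"), path)
  invisible(path)
}

#' Read a 4-column bedGraph into a binned signal track
#'
#' Records are rasterized per base, then averaged per bin: a bin's value is
#' the base sum over the bin divided by the bin width, with bases not covered
#' by any record contributing 0; the bin is flagged covered when at least one
#' of its bases is. Overlapping records are an error.
#'
#' @param path File path.
#' @param genome A [genome_description()].
#' @param bin_size Bin width in bases.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, genome, bin_size) {
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size <= 0L) stop("bin_size must be positive")
  lines <- read_tab_lines(path)
  track <- signal_track(genome, bin_size)
  if (!length(lines)) return(track)
  fl <- split_fields(lines)
  if (any(lengths(fl) < 4)) stop("malformed bedGraph line ",
                                 which(lengths(fl) < 4)[1], " in ", path)
  ln <- seq_along(lines)
  chrom <- vapply(fl, `[`, "", 1L)
  start <- num_or_stop(vapply(fl, `[`, "", 2L), ln, path, "start")
  end <- num_or_stop(vapply(fl, `[`, "", 3L), ln, path, "end")
  value <- num_or_stop(vapply(fl, `[`, "", 4L), ln, path, "value")
  df <- genome_intervals(chrom, start, end, genome = genome)
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    o <- i[order(start[i])]
    if (any(start[o][-1] < end[o][-length(o)]))
      stop("overlapping bedGraph records on ", ch, " in ", path)
    len <- chrom_length(genome, ch)
    nb <- as.integer(ceiling(len / bin_size))
    sums <- numeric(nb); covb <- numeric(nb)
    for (j in o) {
      s <- start[j]; e <- end[j]; v <- value[j]
      b0 <- s %/% bin_size; b1 <- (e - 1) %/% bin_size
      if (b0 == b1) {
        sums[b0 + 1] <- sums[b0 + 1] + (e - s) * v
        covb[b0 + 1] <- covb[b0 + 1] + (e - s)
      } else {
        first_len <- (b0 + 1) * bin_size - s
        last_len <- e - b1 * bin_size
        sums[b0 + 1] <- sums[b0 + 1] + first_len * v
        covb[b0 + 1] <- covb[b0 + 1] + first_len
        if (b1 > b0 + 1) {
          mid <- (b0 + 2):b1
          sums[mid] <- sums[mid] + bin_size * v
          covb[mid] <- covb[mid] + bin_size
        }
        sums[b1 + 1] <- sums[b1 + 1] + last_len * v
        covb[b1 + 1] <- covb[b1 + 1] + last_len
      }
    }
    width <- pmin(bin_size, len - (seq_len(nb) - 1) * bin_size)
    track$values[[ch]] <- sums / width
    track$covered[[ch]] <- covb > 0
  }
  track
}

#' Write a signal track as bedGraph
#'
#' Runs of equal-valued covered bins are merged into single records;
#' uncovered bins are omitted.
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @param digits Significant digits for values.
#' @export
write_bedgraph <- function(track, path, digits = 10) {
  con <- file(path, "w"); on.exit(close(con))
  bs <- track$bin_size
  for (ch in track$genome$chrom) {
    v <- track$values[[ch]]; cov <- track$covered[[ch]]
    if (!any(cov)) next
    len <- chrom_length(track$genome, ch)
    key <- ifelse(cov, format(v, digits = digits, trim = TRUE, scientific = FALSE), NA)
    r <- rle(key)
    endsb <- cumsum(r$lengths)
    startsb <- endsb - r$lengths
    keep <- !is.na(r$values)
    s <- startsb[keep] * bs
    e <- pmin(endsb[keep] * bs, len)
    writeLines(paste(ch, fmt_num(s), fmt_num(e), r$values[keep], sep = "\t"), con)
  }
  invisible(path)
}

#' Read a JASPAR-style PWM text file
#'
#' Expected layout: a header line starting with `>` giving the motif name,
#' then four rows (A, C, G, T) of counts or probabilities, optionally
#' prefixed with the base letter and bracketed, e.g. `A [ 10 2 0 ]`.
#'
#' @param path File path.
#' @param ... Passed to [pwm()] (background, pseudocount, score_threshold).
#' @return A [pwm()] object (the first motif in the file).
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr)) stop("no '>' header in ", path)
  name <- sub("^>\\s*", "", lines[hdr[1]])
  rows <- lines[(hdr[1] + 1):min(hdr[1] + 4, length(lines))]
  if (length(rows) < 4) stop("expected 4 matrix rows after header in ", path)
  parse_row <- function(r) {
    r <- gsub("^[ACGTacgt]\\s*", "", r)
    r <- gsub("\\[|\\]", " ", r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }
  m <- do.call(rbind, lapply(rows, parse_row))
  rownames(m) <- c("A", "C", "G", "T")
  pwm(m, name = name, ...)
}

#' Read a chromatin-state segmentation BED
#'
#' A 4-column BED whose name field carries the state label (`"3"` or `"E3"`).
#'
#' @param path File path.
#' @param genome Optional [genome_description()] for validation.
#' @return An interval data.frame with an integer `state` column.
#' @export
read_segmentation <- function(path, genome = NULL) {
  x <- read_bed(path, genome)
  if (all(is.na(x$name))) stop("segmentation BED needs a name column with state labels")
  x$state <- as.integer(sub("^[A-Za-z]+", "", x$name))
  if (anyNA(x$state)) stop("could not parse state labels in ", path)
  x
}

#' Write a chromatin-state segmentation BED
#'
#' @param x Interval data.frame with a `state` column.
#' @param path Output path.
#' @param prefix Label prefix, e.g. `"E"` for labels `E1..EK`.
#' @export
write_segmentation <- function(x, path, prefix = "E") {
  writeLines(paste(x$chrom, fmt_num(x$start), fmt_num(x$end),
                   paste0(prefix, x$state), sep = "\t"), path)
  invisible(path)
}
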