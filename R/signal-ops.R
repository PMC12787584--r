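#' Mean signal over intervals, with covered fraction
#'
#' The mean is the covered-weighted base sum over the interval divided by the
#' interval length in bases: bases in uncovered bins contribute 0 to the sum
#' but still count in the denominator. The covered fraction is the share of
#' interval bases falling in covered bins.
#'
#' @param track A [signal_track()].
#' @param intervals An interval data.frame (within the track's genome).
#' @return A data.frame with one row per interval: `mean`, `covered_fraction`.
#' @export
average_over_interval <- function(track, intervals) {
  validate_intervals(intervals, track$genome)
  if (nrow(intervals) == 0L)
    return(data.frame(mean = numeric(), covered_fraction = numeric()))
  rs <- track_range_sums(track, intervals$chrom, intervals$start, intervals$end)
  len <- intervals$end - intervals$start
  data.frame(mean = rs$sum / len, covered_fraction = rs$covered_bases / len)
}

## window [center - floor(w/2), center - floor(w/2) + w), clipped to the
## chromosome; returns data.frame(chrom, start, end) (clipped, possibly empty)
central_windows <- function(intervals, width, genome) {
  center <- floor((intervals$start + intervals$end) / 2)
  s <- center - floor(width / 2)
  e <- s + width
  len <- chrom_length(genome, intervals$chrom)
  data.frame(chrom = intervals$chrom, start = pmax(0, s), end = pmin(len, e),
             stringsAsFactors = FALSE)
}

#' Mean signal over the central window of each interval
#'
#' Samples a `width`-base window centered on `floor((start + end) / 2)`,
#' clipped at chromosome bounds (the denominator is the clipped window
#' length). This mirrors central-window averaging of peak/motif signal
#' (e.g. the central 100 bases).
#'
#' @inheritParams average_over_interval
#' @param width Window width in bases (default 100).
#' @return A data.frame with one row per interval: `mean`, `covered_fraction`.
#' @export
central_window_mean <- function(track, intervals, width = 100) {
  if (width < 1) stop("width must be >= 1")
  validate_intervals(intervals, track$genome)
  if (nrow(intervals) == 0L)
    return(data.frame(mean = numeric(), covered_fraction = numeric()))
  w <- central_windows(intervals, width, track$genome)
  len <- w$end - w$start
  out <- data.frame(mean = rep(0, nrow(w)), covered_fraction = rep(0, nrow(w)))
  ok <- len > 0
  if (any(ok)) {
    rs <- track_range_sums(track, w$chrom[ok], w$start[ok], w$end[ok])
    out$mean[ok] <- rs$sum / len[ok]
    out$covered_fraction[ok] <- rs$covered_bases / len[ok]
  }
  out
}

#' Reference-point signal matrix
#'
#' One row per interval; columns are fixed-width bins spanning
#' `[reference - window, reference + window)` where the reference is the
#' interval center or the peak summit. Cells are per-base means over the
#' column's span; spans beyond the chromosome or over uncovered bins
#' contribute 0 when `missing_as_zero` (otherwise cells with no covered base
#' are `NA`).
#'
#' @inheritParams average_over_interval
#' @param window Half-width of the spanned region in bases.
#' @param bin Column width in bases; `window` must be a multiple of `bin`.
#' @param reference `"center"` or `"summit"` (requires a `summit_offset`
#'   column; rows without one fall back to the center).
#' @param skip_zero_rows Drop rows whose cells are all zero.
#' @param missing_as_zero Treat missing data as signal 0.
#' @return An object of class `signal_matrix`: a numeric matrix with
#'   attributes `window`, `bin`, and `offsets` (column start offsets).
#' @export
signal_matrix <- function(track, intervals, window = 2000, bin = 50,
                          reference = c("center", "summit"),
                          skip_zero_rows = FALSE, missing_as_zero = TRUE) {
  reference <- match.arg(reference)
  if (window %% bin != 0) stop("window must be a multiple of bin")
  validate_intervals(intervals, track$genome)
  ref <- floor((intervals$start + intervals$end) / 2)
  if (reference == "summit" && "summit_offset" %in% names(intervals)) {
    s <- intervals$start + intervals$summit_offset
    ref[!is.na(s)] <- s[!is.na(s)]
  }
  ncols <- as.integer(2 * window / bin)
  offsets <- -window + (seq_len(ncols) - 1) * bin
  n <- nrow(intervals)
  m <- matrix(0, n, ncols)
  if (n > 0) {
    len <- chrom_length(track$genome, intervals$chrom)
    for (j in seq_len(ncols)) {
      s <- ref + offsets[j]
      e <- s + bin
      cs <- pmax(0, pmin(s, len))
      ce <- pmax(0, pmin(e, len))
      ok <- ce > cs
      val <- numeric(n); covb <- numeric(n)
      if (any(ok)) {
        rs <- track_range_sums(track, intervals$chrom[ok], cs[ok], ce[ok])
        val[ok] <- rs$sum; covb[ok] <- rs$covered_bases
      }
      cell <- val / bin
      if (!missing_as_zero) cell[covb == 0] <- NA_real_
      m[, j] <- cell
    }
  }
  rownames(m) <- if ("name" %in% names(intervals) && !all(is.na(intervals$name)))
    make.unique(ifelse(is.na(intervals$name), "", intervals$name)) else NULL
  if (skip_zero_rows && nrow(m) > 0) {
    keep <- rowSums(abs(m), na.rm = TRUE) > 0
    m <- m[keep, , drop = FALSE]
  }
  structure(m, window = window, bin = bin, offsets = offsets,
            class = c("signal_matrix", "matrix", "array"))
}

#' Column-mean metaprofile of a signal matrix
#'
#' @param matrix A [signal_matrix()] (or any numeric matrix).
#' @return Numeric vector of column means, named by bin start offset where
#'   available.
#' @export
metaprofile <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L) stop("empty signal matrix")
  p <- colMeans(matrix, na.rm = TRUE)
  off <- attr(matrix, "offsets")
  if (!is.null(off)) names(p) <- off
  p
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", nrow(x), "region(s) x", ncol(x), "bins ",
      "(window ", attr(x, "window"), ", bin ", attr(x, "bin"), ")\n", sep = " ")
  invisible(x)
}

#' @method plot signal_matrix
#' @export
plot.signal_matrix <- function(x, ...) {
  p <- metaprofile(x)
  off <- attr(x, "offsets")
  graphics::plot(off + attr(x, "bin") / 2, p, type = "l",
                 xlab = "distance from reference (bp)", ylab = "mean signal", ...)
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Standardize peak widths and recenter
#'
#' Rewrites every interval to the rounded mean width of the set, centered on
#' each interval's center (round-half-up to whole bases), clipped at
#' chromosome bounds when a genome is given. Used before binned motif
#' enrichment so foreground/background sequences are length-matched.
#'
#' @param intervals Interval data.frame.
#' @param genome Optional [genome_description()] for clipping.
#' @param width Target width; default the rounded mean width of the set.
#' @return The interval data.frame with adjusted `start`/`end`.
#' @export
standardize_widths <- function(intervals, genome = NULL, width = NULL) {
  if (nrow(intervals) == 0L) return(intervals)
  if (is.null(width)) width <- round_half_up(mean(intervals$end - intervals$start))
  center <- floor((intervals$start + intervals$end) / 2)
  s <- center - floor(width / 2)
  e <- s + width
  if (!is.null(genome)) {
    len <- chrom_length(genome, intervals$chrom)
    shift_r <- pmax(0, -s)
    s <- s + shift_r; e <- e + shift_r
    shift_l <- pmax(0, e - len)
    s <- s - shift_l; e <- e - shift_l
    s <- pmax(0, s)
  }
  intervals$start <- s
  intervals$end <- e
  intervals
}
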