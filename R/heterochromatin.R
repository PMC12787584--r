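#' Intersect peaks with heterochromatin domains
#'
#' Domains of each mark are merged (overlapping and bookended intervals
#' joined) before intersection; a peak is assigned to a mark when it overlaps
#' at least one base of a merged domain. A peak may carry both marks.
#'
#' @param peaks Peak data.frame.
#' @param domains Interval data.frame with a `mark` column (e.g. `"H3K9me3"`,
#'   `"H3K27me3"`).
#' @return Named list, one peak subset per mark.
#' @export
intersect_domains <- function(peaks, domains) {
  stopifnot("mark" %in% names(domains))
  out <- list()
  for (mk in unique(domains$mark)) {
    merged <- merge_intervals(domains[domains$mark == mk, , drop = FALSE])
    out[[mk]] <- peaks[overlaps_any(peaks, merged), , drop = FALSE]
  }
  out
}

## median nonzero covered value of a track, for ratio stabilization
track_median_nonzero <- function(track) {
  v <- unlist(Map(function(x, cov) x[cov & x != 0], track$values, track$covered),
              use.names = FALSE)
  if (!length(v)) return(0)
  stats::median(v)
}

#' Classify local heterochromatin density at binding sites
#'
#' Operationalizes the three qualitative targeting subtypes seen at
#' repressive domains: sites where the mark is focally enriched over the
#' flanking domain (`high`), sites as enriched as their flanks (`moderate`),
#' and sites of local depletion exploiting small gaps in broad domains
#' (`low`). The site signal is the mean over a central window; the flank
#' signal pools two windows placed at +/- `flank_offset` from the site
#' center. The subtype is a pure function of the center/flank ratio and the
#' two thresholds; the ratio is stabilized with an epsilon of 1% of the
#' track's median nonzero value, so classification is invariant under
#' rescaling of the track.
#'
#' @param peaks Peak data.frame (already assigned to the mark, see
#'   [intersect_domains()]).
#' @param mark_track H3K9me3 or H3K27me3 [signal_track()].
#' @param mark Label stored in the output.
#' @param center_width Central window width in bases (default 1000).
#' @param flank_offset Distance from site center to each flank window center
#'   (default 5000).
#' @param flank_width Width of each flank window (default 2000).
#' @param r_hi,r_lo Ratio thresholds: `high` when ratio >= `r_hi` (1.5),
#'   `low` when ratio <= `r_lo` (0.67), else `moderate`.
#' @return An object of class `local_density_calls`: the peak data.frame with
#'   `center_signal`, `flank_signal`, `ratio`, `subtype`, and `mark`.
#' @export
local_density <- function(peaks, mark_track, mark = "mark",
                          center_width = 1000, flank_offset = 5000,
                          flank_width = 2000, r_hi = 1.5, r_lo = 0.67) {
  validate_intervals(peaks, mark_track$genome)
  genome <- mark_track$genome
  center <- floor((peaks$start + peaks$end) / 2)
  len <- chrom_length(genome, peaks$chrom)
  clip_win <- function(mid) {
    s <- pmax(0, mid - floor(flank_width / 2))
    e <- pmin(len, mid - floor(flank_width / 2) + flank_width)
    list(s = s, e = pmax(s, e))
  }
  cw <- central_window_mean(mark_track, peaks, width = center_width)
  l <- clip_win(center - flank_offset)
  r <- clip_win(center + flank_offset)
  fsum <- numeric(nrow(peaks)); flen <- numeric(nrow(peaks))
  for (w in list(l, r)) {
    ok <- w$e > w$s
    if (any(ok)) {
      rs <- track_range_sums(mark_track, peaks$chrom[ok], w$s[ok], w$e[ok])
      fsum[ok] <- fsum[ok] + rs$sum
      flen[ok] <- flen[ok] + (w$e - w$s)[ok]
    }
  }
  flank <- ifelse(flen > 0, fsum / flen, 0)
  eps <- 0.01 * track_median_nonzero(mark_track)
  ratio <- cw$mean / (flank + eps)
  subtype <- ifelse(ratio >= r_hi, "high", ifelse(ratio <= r_lo, "low", "moderate"))
  peaks$mark <- mark
  peaks$center_signal <- cw$mean
  peaks$flank_signal <- flank
  peaks$ratio <- ratio
  peaks$subtype <- subtype
  class(peaks) <- c("local_density_calls", "data.frame")
  peaks
}

#' Summarize a factor's heterochromatin targeting subtypes
#'
#' @param calls A [local_density()] result, or an rbind of them over marks.
#' @return An object of class `subtype_summary`: list with `fractions` (one
#'   row per mark, columns high/moderate/low summing to 1) and `majority`
#'   (per-mark majority subtype; ties broken high > moderate > low).
#' @export
factor_subtype_summary <- function(calls) {
  if (nrow(calls) == 0L) stop("no local-density calls")
  lev <- c("high", "moderate", "low")
  marks <- unique(calls$mark)
  frac <- t(vapply(marks, function(mk) {
    tab <- table(factor(calls$subtype[calls$mark == mk], levels = lev))
    as.numeric(tab) / sum(tab)
  }, numeric(3)))
  colnames(frac) <- lev
  rownames(frac) <- marks
  majority <- apply(frac, 1, function(f) lev[which.max(f)])  # which.max: first tie wins
  structure(list(fractions = frac, majority = majority), class = "subtype_summary")
}

#' @export
print.subtype_summary <- function(x, ...) {
  cat("heterochromatin local-density subtype fractions:\n")
  print(round(x$fractions, 3))
  cat("majority subtype:", paste(rownames(x$fractions), x$majority,
                                 sep = "=", collapse = ", "), "\n")
  invisible(x)
}
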