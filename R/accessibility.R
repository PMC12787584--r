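#' Classify peaks by preexisting DNase accessibility
#'
#' Each peak's DNase level is the full-peak mean ([average_over_interval()]);
#' a peak is `accessible` when that mean strictly exceeds the cutoff and
#' `resistant` otherwise. Exact ties go to `resistant`: the split predicates
#' (`> cutoff` / `< cutoff`) assign a tie to neither class, and resistant is
#' the conservative call for claiming closed-chromatin targeting.
#'
#' @param peaks Peak data.frame.
#' @param dnase DNase-seq [signal_track()] (RPM).
#' @param cutoff RPM cutoff; default 0.05.
#' @return The peak data.frame with columns `dnase_mean` and `label`
#'   (`"accessible"`/`"resistant"`), plus attribute `closed_fraction`.
#' @export
classify_accessibility <- function(peaks, dnase, cutoff = 0.05) {
  if (nrow(peaks) == 0L) stop("empty peak list")
  if (cutoff < 0) stop("cutoff must be >= 0")
  av <- average_over_interval(dnase, peaks)
  peaks$dnase_mean <- av$mean
  peaks$label <- ifelse(av$mean > cutoff, "accessible", "resistant")
  attr(peaks, "closed_fraction") <- mean(peaks$label == "resistant")
  peaks
}

#' Classify peaks by nucleosome (H2B) turnover
#'
#' Turnover is sampled over the central 100 bases of each peak; peaks are
#' `high` when the mean strictly exceeds the cutoff. No absolute cutoff is
#' established for pulse-labeled H2B signal, so the default is the peak-set
#' median of the turnover means (configurable).
#'
#' @param calls Peak data.frame (typically from [classify_accessibility()]).
#' @param h2b 6h H2B turnover [signal_track()] (RPM).
#' @param cutoff RPM cutoff; default `NULL` = median turnover mean of the set.
#' @param width Central window width in bases.
#' @return The input with columns `turnover_mean` and `turnover_label`
#'   (`"high"`/`"low"`).
#' @export
classify_turnover <- function(calls, h2b, cutoff = NULL, width = 100) {
  cw <- central_window_mean(h2b, calls, width = width)
  calls$turnover_mean <- cw$mean
  if (is.null(cutoff)) cutoff <- stats::median(cw$mean)
  if (cutoff < 0) stop("cutoff must be >= 0")
  calls$turnover_label <- ifelse(cw$mean > cutoff, "high", "low")
  attr(calls, "turnover_cutoff") <- cutoff
  calls
}

#' Split motif instances by central-window DNase accessibility
#'
#' Applies the accessibility cutoff to the mean DNase over the central 100
#' bases of each motif; same tie rule as [classify_accessibility()].
#'
#' @param motifs Interval data.frame of motif instances.
#' @param dnase DNase-seq [signal_track()].
#' @param cutoff RPM cutoff; default 0.05.
#' @param width Central window width in bases.
#' @return The motif data.frame with columns `dnase_mean` and `label`
#'   (`"accessible"`/`"inaccessible"`).
#' @export
motif_accessibility_split <- function(motifs, dnase, cutoff = 0.05, width = 100) {
  cw <- central_window_mean(dnase, motifs, width = width)
  motifs$dnase_mean <- cw$mean
  motifs$label <- ifelse(cw$mean > cutoff, "accessible", "inaccessible")
  motifs
}

## equal-size bin membership: peaks ranked by value ascending, floor(n/k) per
## bin, remainder appended to the last (most accessible) bin
accessibility_bins <- function(values, n_bins) {
  n <- length(values)
  m <- n %/% n_bins
  sizes <- rep(m, n_bins)
  sizes[n_bins] <- sizes[n_bins] + n - m * n_bins
  ord <- order(values)  # ties: stable, original order
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), sizes)
  bin
}

#' Binned motif enrichment across accessibility deciles
#'
#' Peaks are width-standardized and recentered, sorted by DNase level, and
#' cut into `n_bins` equal-size bins (remainder appended to the most
#' accessible bin). For each motif and bin, the bin is the foreground and all
#' other bins the background; the motif frequency is the fraction of peak
#' sequences with at least one PWM hit at the PWM's score threshold.
#' Enrichment is `log2((fg + eps) / (bg + eps))` with `eps = 1/(2 * bin
#' size)`; the p-value is a one-sided exact binomial test of the foreground
#' hit count at the background frequency, adjusted across all (motif, bin)
#' pairs by Benjamini-Hochberg. A motif is reported enriched in a bin when
#' `-log10(adjusted p) > 2` and its foreground frequency exceeds 5%.
#'
#' @param peaks Peak data.frame.
#' @param dnase_values Numeric vector of per-peak DNase levels (parallel to
#'   `peaks`).
#' @param pwms A [pwm()] or list of them.
#' @param genome_sequence Named character vector of chromosome sequences.
#' @param n_bins Number of accessibility bins (default 10).
#' @param genome Optional [genome_description()] for clipping standardized
#'   peaks; defaults to the sequence lengths.
#' @return An object of class `binned_enrichment`: a long data.frame with one
#'   row per (motif, bin) carrying frequencies, `log2_enrichment`, `p_value`,
#'   `p_adj`, and the `enriched` flag, plus a `bins` attribute with per-bin
#'   DNase ranges.
#' @export
binned_motif_enrichment <- function(peaks, dnase_values, pwms, genome_sequence,
                                    n_bins = 10, genome = NULL) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (nrow(peaks) < n_bins) stop("need at least n_bins peaks")
  if (length(dnase_values) != nrow(peaks))
    stop("dnase_values must parallel peaks")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(genome))
    genome <- genome_description(names(genome_sequence), nchar(genome_sequence))
  peaks <- standardize_widths(peaks, genome)
  seqs <- substr(genome_sequence[peaks$chrom], peaks$start + 1, peaks$end)
  if (any(!nzchar(seqs))) stop("empty sequence for some standardized peak")
  bin <- accessibility_bins(dnase_values, n_bins)
  hits <- vapply(pwms, function(p) has_pwm_hit(seqs, p), logical(length(seqs)))
  hits <- matrix(hits, nrow = length(seqs))
  motif_names <- vapply(pwms, function(p) p$name, "")
  rows <- list()
  for (mi in seq_along(pwms)) {
    h <- hits[, mi]
    for (b in seq_len(n_bins)) {
      fg <- bin == b
      n_fg <- sum(fg); n_bg <- sum(!fg)
      fg_hits <- sum(h[fg]); bg_hits <- sum(h[!fg])
      fg_freq <- fg_hits / n_fg; bg_freq <- bg_hits / n_bg
      eps <- 1 / (2 * n_fg)
      l2 <- log2((fg_freq + eps) / (bg_freq + eps))
      p <- if (bg_freq <= 0) as.numeric(fg_hits == 0)
      else if (bg_freq >= 1) 1
      else stats::binom.test(fg_hits, n_fg, p = bg_freq,
                             alternative = "greater")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif_names[mi], bin = b, n_fg = n_fg, fg_hits = fg_hits,
        fg_freq = fg_freq, bg_freq = bg_freq, log2_enrichment = l2,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- -log10(out$p_adj) > 2 & out$fg_freq > 0.05
  ranges <- vapply(seq_len(n_bins), function(b)
    range(dnase_values[bin == b]), numeric(2))
  attr(out, "bins") <- data.frame(bin = seq_len(n_bins),
                                  dnase_min = ranges[1, ], dnase_max = ranges[2, ],
                                  n = tabulate(bin, n_bins))
  class(out) <- c("binned_enrichment", "data.frame")
  out
}

#' @export
print.binned_enrichment <- function(x, ...) {
  cat("binned_enrichment:", length(unique(x$motif)), "motif(s) x",
      max(x$bin), "accessibility bins\n")
  hit <- x[x$enriched, c("motif", "bin", "fg_freq", "log2_enrichment", "p_adj")]
  if (nrow(hit)) {
    cat("enriched (motif, bin) pairs:\n")
    print.data.frame(hit, row.names = FALSE, digits = 3)
  } else cat("no (motif, bin) pair passes -log10(adj p) > 2 and fg freq > 5%\n")
  invisible(x)
}
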