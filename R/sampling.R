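#' Shift motif intervals to build a background set
#'
#' Translates every interval by `+shift` bases (the shifted-motif null:
#' sequence-matched loci far enough from the real motifs to carry only
#' background signal). Intervals pushed past their chromosome end are
#' dropped.
#'
#' @param motifs Interval data.frame.
#' @param shift Shift in bases (> 0); default 10000.
#' @param genome A [genome_description()].
#' @return The shifted interval data.frame, with attribute `n_dropped`.
#' @export
shift_background <- function(motifs, shift = 10000, genome) {
  if (shift <= 0) stop("shift must be > 0")
  out <- motifs
  out$start <- out$start + shift
  out$end <- out$end + shift
  keep <- out$end <= chrom_length(genome, out$chrom)
  res <- out[keep, , drop = FALSE]
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Classify genomic motif instances as bound, sampled, or unsampled
#'
#' Implements the motif-sampling cistrome analysis. Every motif instance gets
#' its ChIP enrichment over the central 100 bases of the (input-subtracted)
#' IP track, together with the covered fraction of that window. Instances
#' with covered fraction at or below `coverage_min` are `filtered` (excludes
#' low-coverage/unmappable regions). Of the rest: instances overlapping at
#' least one consensus peak are `bound` (peak overlap takes precedence over
#' any signal threshold); the remaining instances are `sampled` when their
#' central signal strictly exceeds the background threshold, else
#' `unsampled`. The background threshold is the `background_quantile`
#' quantile of central signal over the coverage-filtered shifted-motif
#' background — an operationalization of "specific low-level sampling"
#' versus no sampling at shifted sites.
#'
#' @param motifs Interval data.frame of motif instances (genome-wide scan).
#' @param ip_track Input-subtracted IP [signal_track()].
#' @param peaks Consensus peak data.frame for the condition.
#' @param background_quantile Quantile of the background central-signal
#'   distribution used as the sampling threshold (default 0.95).
#' @param coverage_min Minimum covered fraction (exclusive) to retain a
#'   motif (default 0.75).
#' @param shift Background shift in bases (default 10000).
#' @param width Central window width in bases (default 100).
#' @return An object of class `sampling_result`: list with `instances` (one
#'   row per motif — `motif_id`, coordinates, `central_signal`,
#'   `covered_fraction`, `klass` — sorted by central signal descending, ties
#'   by coordinate), `background_threshold`, `fractions` over unfiltered
#'   motifs, `n_total`, `n_unfiltered`, `n_background`,
#'   `n_background_dropped`.
#' @export
classify_motifs <- function(motifs, ip_track, peaks,
                            background_quantile = 0.95, coverage_min = 0.75,
                            shift = 10000, width = 100) {
  validate_intervals(motifs, ip_track$genome)
  motifs$motif_id <- seq_len(nrow(motifs))
  cw <- central_window_mean(ip_track, motifs, width = width)
  motifs$central_signal <- cw$mean
  motifs$covered_fraction <- cw$covered_fraction
  unfiltered <- motifs$covered_fraction > coverage_min
  bound <- overlaps_any(motifs, peaks)

  bg <- shift_background(motifs[, c("chrom", "start", "end")],
                         shift = shift, genome = ip_track$genome)
  n_bg_dropped <- attr(bg, "n_dropped")
  bg_cw <- central_window_mean(ip_track, bg, width = width)
  bg_keep <- bg_cw$covered_fraction > coverage_min
  if (!any(bg_keep))
    stop("no background motifs survive the coverage filter; ",
         "use a larger genome or a lower coverage_min")
  threshold <- stats::quantile(bg_cw$mean[bg_keep], background_quantile,
                               names = FALSE)

  klass <- rep("filtered", nrow(motifs))
  klass[unfiltered] <- ifelse(bound[unfiltered], "bound",
                              ifelse(motifs$central_signal[unfiltered] > threshold,
                                     "sampled", "unsampled"))
  motifs$klass <- klass
  ord <- order(-motifs$central_signal, motifs$chrom, motifs$start)
  lev <- c("bound", "sampled", "unsampled")
  fractions <- as.numeric(table(factor(klass[unfiltered], levels = lev))) /
    max(1L, sum(unfiltered))
  names(fractions) <- lev
  structure(list(instances = motifs[ord, , drop = FALSE],
                 background_threshold = threshold,
                 fractions = fractions,
                 n_total = nrow(motifs),
                 n_unfiltered = sum(unfiltered),
                 n_background = sum(bg_keep),
                 n_background_dropped = n_bg_dropped),
            class = "sampling_result")
}

#' @export
print.sampling_result <- function(x, ...) {
  cat("sampling_result:", x$n_total, "motifs (",
      x$n_unfiltered, "unfiltered )\n")
  cat(sprintf("  background threshold (RPM): %.4g over %d background motifs\n",
              x$background_threshold, x$n_background))
  f <- x$fractions
  cat(sprintf("  bound %.1f%% | sampled %.1f%% | unsampled %.1f%%\n",
              100 * f["bound"], 100 * f["sampled"], 100 * f["unsampled"]))
  invisible(x)
}

#' @method summary sampling_result
#' @export
summary.sampling_result <- function(object, ...) {
  data.frame(klass = names(object$fractions),
             fraction = as.numeric(object$fractions),
             n = round(as.numeric(object$fractions) * object$n_unfiltered))
}

#' Write a sampling result as TSV
#'
#' One row per motif instance, followed by a `#`-prefixed footer block with
#' the class fractions and the background threshold.
#'
#' @param x A [classify_motifs()] result.
#' @param path Output path.
#' @export
write_sampling_result <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  inst <- x$instances
  cols <- c("motif_id", "chrom", "start", "end", "central_signal",
            "covered_fraction", "klass")
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(inst[cols], function(v)
    if (is.numeric(v)) fmt_num(v) else as.character(v)), sep = "\t")), con)
  writeLines(sprintf("# background_threshold\t%.10g", x$background_threshold), con)
  for (k in names(x$fractions))
    writeLines(sprintf("# fraction_%s\t%.10g", k, x$fractions[[k]]), con)
  invisible(path)
}

#' Transition table of motif classes between two conditions
#'
#' Counts unfiltered-in-both motifs moving between bound/sampled/unsampled
#' from condition A to condition B (the alluvial-diagram statistic).
#'
#' @param a,b [classify_motifs()] results over the identical motif list.
#' @return A 3 x 3 integer matrix (rows = class in A, columns = class in B)
#'   of class `transition_table`.
#' @export
transition_table <- function(a, b) {
  ia <- a$instances[order(a$instances$motif_id), ]
  ib <- b$instances[order(b$instances$motif_id), ]
  if (nrow(ia) != nrow(ib) ||
      !identical(ia$chrom, ib$chrom) ||
      !isTRUE(all.equal(ia$start, ib$start)) ||
      !isTRUE(all.equal(ia$end, ib$end)))
    stop("conditions were classified over different motif lists")
  keep <- ia$klass != "filtered" & ib$klass != "filtered"
  lev <- c("bound", "sampled", "unsampled")
  tab <- table(factor(ia$klass[keep], levels = lev),
               factor(ib$klass[keep], levels = lev))
  m <- matrix(as.integer(tab), 3, 3, dimnames = list(from = lev, to = lev))
  class(m) <- c("transition_table", class(m))
  m
}

#' @export
print.transition_table <- function(x, ...) {
  cat("motif class transitions (rows: condition A, cols: condition B):\n")
  print(unclass(x))
  invisible(x)
}
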