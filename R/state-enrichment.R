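## Check that a segmentation's intervals tile the genome without gaps or
## overlaps; returns invisibly or errors listing uncovered spans.
check_segmentation_coverage <- function(segmentation, genome) {
  gaps <- character()
  for (ch in genome$chrom) {
    s <- segmentation[segmentation$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    len <- chrom_length(genome, ch)
    pos <- 0
    for (i in seq_len(nrow(s))) {
      if (s$start[i] > pos)
        gaps <- c(gaps, sprintf("%s:%d-%d", ch, pos, s$start[i]))
      if (s$start[i] < pos)
        stop("overlapping segmentation intervals on ", ch)
      pos <- s$end[i]
    }
    if (pos < len) gaps <- c(gaps, sprintf("%s:%d-%.0f", ch, pos, len))
  }
  if (length(gaps))
    stop("segmentation does not cover the genome; uncovered span(s): ",
         paste(utils::head(gaps, 10), collapse = ", "))
  invisible(TRUE)
}

#' Fold enrichment of motif classes over a chromatin-state segmentation
#'
#' For state `s` and class `c`, the fold enrichment is the share of the
#' class's bases lying in the state divided by the state's share of the
#' genome: `(bases of c in s / total bases of c) / (bases of s / genome
#' size)`. Overlaps are counted in bases (half-open), so the statistic is
#' insensitive to motif length heterogeneity.
#'
#' @param segmentation Interval data.frame with integer `state` labels,
#'   tiling the genome (see [read_segmentation()]).
#' @param classed_motifs Named list of interval data.frames, one per motif
#'   class (e.g. bound / sampled / unsampled).
#' @param genome A [genome_description()].
#' @return An object of class `overlap_enrichment`: list with `fold` (states
#'   x classes matrix), `state_fractions`, `class_state_bases`,
#'   `class_total_bases`, `genome_size`.
#' @export
overlap_enrichment <- function(segmentation, classed_motifs, genome) {
  stopifnot("state" %in% names(segmentation))
  check_segmentation_coverage(segmentation, genome)
  states <- sort(unique(segmentation$state))
  G <- sum(genome$length)
  state_bases <- vapply(states, function(st) {
    s <- segmentation[segmentation$state == st, , drop = FALSE]
    sum(s$end - s$start)
  }, 0)
  names(state_bases) <- states
  seg_gr <- as_granges(segmentation)
  base_by_state <- function(x) {
    validate_intervals(x, genome)
    out <- numeric(length(states)); names(out) <- states
    if (nrow(x) == 0L) return(out)
    hits <- GenomicRanges::findOverlaps(as_granges(x), seg_gr)
    if (!length(hits)) return(out)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(x$end[qi], segmentation$end[si]) -
      pmax(x$start[qi], segmentation$start[si])
    agg <- tapply(ov, segmentation$state[si], sum)
    out[names(agg)] <- agg
    out
  }
  cls_bases <- vapply(classed_motifs, base_by_state, numeric(length(states)))
  cls_bases <- matrix(cls_bases, nrow = length(states),
                      dimnames = list(state = states, class = names(classed_motifs)))
  totals <- colSums(cls_bases)
  fold <- sweep(sweep(cls_bases, 2, totals, "/"), 1, state_bases / G, "/")
  structure(list(fold = fold,
                 state_fractions = state_bases / G,
                 class_state_bases = cls_bases,
                 class_total_bases = totals,
                 genome_size = G),
            class = "overlap_enrichment")
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  cat("overlap_enrichment:", nrow(x$fold), "states x", ncol(x$fold), "classes\n")
  print(round(x$fold, 3))
  invisible(x)
}

#' Long-format chromatin-state enrichment report
#'
#' @param e An [overlap_enrichment()] result.
#' @param state_labels Named character vector mapping every state to a human
#'   label (names = state ids as in the segmentation).
#' @return A data.frame with one row per (state, class): `state`, `label`,
#'   `class`, `fold`, `state_fraction`, `class_fraction` (share of the
#'   class's bases in the state).
#' @export
enrichment_report <- function(e, state_labels) {
  states <- rownames(e$fold)
  missing <- setdiff(states, names(state_labels))
  if (length(missing)) stop("missing label for state(s): ",
                            paste(missing, collapse = ", "))
  classes <- colnames(e$fold)
  out <- expand.grid(state = states, class = classes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$label <- state_labels[out$state]
  idx <- cbind(match(out$state, states), match(out$class, classes))
  out$fold <- e$fold[idx]
  out$state_fraction <- e$state_fractions[out$state]
  out$class_fraction <- e$class_state_bases[idx] / e$class_total_bases[out$class]
  out[, c("state", "label", "class", "fold", "state_fraction", "class_fraction")]
}

#' Write/read an enrichment report TSV
#'
#' @param report A data.frame from [enrichment_report()].
#' @param path File path.
#' @export
write_enrichment_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_report
#' @export
read_enrichment_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(state = "character"), stringsAsFactors = FALSE)
}
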