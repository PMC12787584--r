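#' Consensus peaks across biological replicates
#'
#' A peak of the first replicate is retained when it overlaps at least
#' `min_overlap` bases with at least one peak in every other replicate;
#' retained peaks keep the first replicate's coordinates.
#'
#' @param replicates List of peak data.frames (>= 1).
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return Peak data.frame (subset of replicate 1).
#' @export
consensus_peaks <- function(replicates, min_overlap = 1L) {
  if (!length(replicates)) stop("empty replicate list")
  ref <- replicates[[1L]]
  keep <- rep(TRUE, nrow(ref))
  for (other in replicates[-1L])
    keep <- keep & overlaps_any(ref, other, minoverlap = min_overlap)
  ref[keep, , drop = FALSE]
}

detected_in_any <- function(x, reps) {
  hit <- rep(FALSE, nrow(x))
  for (r in reps) hit <- hit | overlaps_any(x, r)
  hit
}

#' Compare peak sets between two conditions
#'
#' Builds the consensus set of each condition, then classifies loci: a locus
#' is `shared` when detected in at least one replicate of each condition,
#' and `unique` to a condition when present in all of its replicates but in
#' no replicate of the other. The union of the two consensus sets is
#' deduplicated by overlap keeping condition A's coordinates. Percentages
#' use condition A's consensus count as denominator (so gained can exceed
#' 100%): `retained_pct` = share of A-consensus peaks detected in at least
#' one B replicate; `gained_pct` = 100 * |unique to B| / |A consensus|.
#'
#' @param a_reps,b_reps Lists of replicate peak data.frames.
#' @return An object of class `peak_comparison`: list with `shared`,
#'   `unique_a`, `unique_b` (peak data.frames), `retained_pct`,
#'   `gained_pct`, `n_a`, `n_b`.
#' @export
compare_conditions <- function(a_reps, b_reps) {
  if (!length(a_reps) || !length(b_reps)) stop("each condition needs >= 1 replicate")
  A <- consensus_peaks(a_reps)
  B <- consensus_peaks(b_reps)
  if (nrow(A) == 0L) stop("condition A has no consensus peaks")
  a_in_b <- detected_in_any(A, b_reps)          # A peaks seen in >=1 B replicate
  b_in_a <- detected_in_any(B, a_reps)
  b_novel <- !overlaps_any(B, A)                # dedup union: keep A coords
  shared <- rbind(A[a_in_b, , drop = FALSE],
                  B[b_novel & b_in_a, , drop = FALSE])
  unique_a <- A[!a_in_b, , drop = FALSE]
  unique_b <- B[!b_in_a, , drop = FALSE]
  structure(list(shared = shared,
                 unique_a = unique_a,
                 unique_b = unique_b,
                 retained_pct = 100 * sum(a_in_b) / nrow(A),
                 gained_pct = 100 * nrow(unique_b) / nrow(A),
                 n_a = nrow(A), n_b = nrow(B)),
            class = "peak_comparison")
}

#' @export
print.peak_comparison <- function(x, ...) {
  cat("peak_comparison: A =", x$n_a, "consensus peaks, B =", x$n_b, "\n")
  cat(sprintf("  shared %d | unique to A %d | unique to B %d\n",
              nrow(x$shared), nrow(x$unique_a), nrow(x$unique_b)))
  cat(sprintf("  retained %.1f%% | gained %.1f%% (denominator: condition A)\n",
              x$retained_pct, x$gained_pct))
  invisible(x)
}

#' Gained/shared/lost peaks relative to an external reference set
#'
#' Restricts both conditions to peaks overlapping the reference (e.g. the
#' factor's binding sites in another cell type), then counts loci by the
#' condition-comparison rules: `shared` = reference-overlapping A peaks also
#' present in B; `lost` = reference-overlapping A peaks absent from B;
#' `gained` = reference-overlapping B peaks absent from A.
#'
#' @param a,b Peak data.frames (consensus sets of the two conditions).
#' @param reference Reference peak/interval data.frame.
#' @return Named list of counts: `gained`, `shared`, `lost`.
#' @export
reference_overlap <- function(a, b, reference) {
  a_ref <- a[overlaps_any(a, reference), , drop = FALSE]
  b_ref <- b[overlaps_any(b, reference), , drop = FALSE]
  in_b <- overlaps_any(a_ref, b)
  in_a <- overlaps_any(b_ref, a)
  list(gained = sum(!in_a), shared = sum(in_b), lost = sum(!in_b))
}
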