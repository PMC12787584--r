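#' Construct a position weight matrix
#'
#' Columns are positions, rows are bases A, C, G, T. Count matrices are
#' converted to probabilities with the pseudocount: `(n + pc) / (N + 4 pc)`
#' per column; probability matrices are re-normalized the same way so that
#' zero entries stay scoreable.
#'
#' @param matrix A 4 x L numeric matrix of counts or probabilities
#'   (rows A, C, G, T).
#' @param background Base composition of the scan background (sums to 1).
#' @param pseudocount Pseudocount added per cell before normalization.
#' @param score_threshold Log-odds score (bits) above which a scanned window
#'   counts as a motif hit.
#' @param name Motif name.
#' @return An object of class `pwm` with elements `matrix` (probabilities),
#'   `background`, `pseudocount`, `score_threshold`, `name`.
#' @export
pwm <- function(matrix, background = rep(0.25, 4), pseudocount = 0.01,
                score_threshold = 0, name = "motif") {
  m <- as.matrix(matrix)
  if (nrow(m) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(m) < 4L) stop("PWM must have length >= 4")
  if (any(m < 0) || any(!is.finite(m))) stop("PWM entries must be finite and >= 0")
  cs <- colSums(m)
  if (any(cs + 4 * pseudocount <= 0)) stop("PWM column sums to zero even after pseudocount")
  probs <- sweep(m + pseudocount, 2, cs + 4 * pseudocount, "/")
  rownames(probs) <- c("A", "C", "G", "T")
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6 || any(background <= 0))
    stop("background must be 4 positive probabilities summing to 1")
  structure(list(matrix = probs, background = background,
                 pseudocount = pseudocount, score_threshold = score_threshold,
                 name = name),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm '", x$name, "': length ", ncol(x$matrix),
      ", score_threshold ", x$score_threshold, " bits\n", sep = "")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param x A [pwm()].
#' @return A character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$matrix)[apply(x$matrix, 2, which.max)], collapse = "")
}

## log2 odds matrix, row 5 = N (never matches)
pwm_logodds <- function(x) {
  lom <- log2(x$matrix / x$background)
  rbind(lom, N = rep(-Inf, ncol(lom)))
}

encode_seq <- function(s) {
  code <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T", "N"))
  if (anyNA(code)) stop("sequence alphabet must be within {A,C,G,T,N}")
  code
}

COMPLEMENT <- c(4L, 3L, 2L, 1L, 5L)  # A<->T, C<->G, N->N

## scores of every window of `code` against log-odds matrix `lom` (5 x L)
window_scores <- function(code, lom) {
  L <- ncol(lom)
  n <- length(code)
  if (n < L) return(numeric(0))
  s <- numeric(n - L + 1)
  for (j in seq_len(L)) s <- s + lom[cbind(code[j:(n - L + j)], j)]
  s
}

#' Scan sequences genome-wide with a PWM
#'
#' Scores every window on both strands as the log-odds sum (bits) of window
#' bases against the PWM probabilities over the background composition.
#' Windows containing `N` never match. Opposite-strand hits over the same
#' window are deduplicated keeping the higher score (ties to `+`).
#'
#' @param sequences Named character vector, one string per chromosome.
#' @param pwm A [pwm()].
#' @param threshold Minimum score for a hit; defaults to the PWM's
#'   `score_threshold`. Use `-Inf` to return every window.
#' @return An interval data.frame with columns `chrom`, `start`, `end`,
#'   `name`, `score` (bits), `strand`, ordered by chromosome then start.
#' @export
scan_pwm <- function(sequences, pwm, threshold = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be a named character vector")
  if (any(!nzchar(sequences))) stop("empty sequence for chromosome ",
                                    names(sequences)[!nzchar(sequences)][1])
  if (is.null(threshold)) threshold <- pwm$score_threshold
  lom <- pwm_logodds(pwm)
  L <- ncol(pwm$matrix)
  lom_rc <- lom[COMPLEMENT, rev(seq_len(L)), drop = FALSE]
  out <- vector("list", length(sequences))
  for (k in seq_along(sequences)) {
    code <- encode_seq(sequences[[k]])
    fwd <- window_scores(code, lom)
    rev_ <- window_scores(code, lom_rc)
    if (!length(fwd)) { out[[k]] <- NULL; next }
    best <- pmax(fwd, rev_)
    hit <- which(best >= threshold & is.finite(best))
    if (!length(hit)) { out[[k]] <- NULL; next }
    strand <- ifelse(fwd[hit] >= rev_[hit], "+", "-")
    out[[k]] <- data.frame(chrom = names(sequences)[k],
                           start = hit - 1, end = hit - 1 + L,
                           name = pwm$name, score = best[hit], strand = strand,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## TRUE per sequence: has >= 1 PWM hit at the threshold on either strand
has_pwm_hit <- function(sequences, pwm, threshold = NULL) {
  if (is.null(threshold)) threshold <- pwm$score_threshold
  lom <- pwm_logodds(pwm)
  L <- ncol(pwm$matrix)
  lom_rc <- lom[COMPLEMENT, rev(seq_len(L)), drop = FALSE]
  vapply(sequences, function(s) {
    code <- encode_seq(s)
    if (length(code) < L) return(FALSE)
    any(window_scores(code, lom) >= threshold) ||
      any(window_scores(code, lom_rc) >= threshold)
  }, TRUE, USE.NAMES = FALSE)
}
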