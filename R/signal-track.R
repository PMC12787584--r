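#' Construct a binned signal track
#'
#' A signal track stores one dense float vector per chromosome at a fixed bin
#' resolution, together with a parallel logical coverage mask (`TRUE` where at
#' least one read/observation informed the bin). Uncovered bins hold a fill
#' value of 0 that is never treated as data.
#'
#' @param genome A [genome_description()].
#' @param bin_size Bin width in bases (> 0).
#' @param values Optional named list of per-chromosome numeric vectors; default
#'   all-zero. Each vector must have `ceiling(length / bin_size)` elements.
#' @param covered Optional named list of logical vectors (same shape);
#'   default all `FALSE` when `values` is absent, all `TRUE` otherwise.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(genome, bin_size, values = NULL, covered = NULL) {
  stopifnot(inherits(genome, "genome_description"))
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size <= 0L) stop("bin_size must be a positive integer")
  nb <- n_bins(genome$length, bin_size)
  if (is.null(values)) {
    values <- lapply(nb, numeric)
    names(values) <- genome$chrom
    if (is.null(covered)) {
      covered <- lapply(nb, logical)
      names(covered) <- genome$chrom
    }
  } else {
    if (!setequal(names(values), genome$chrom))
      stop("values must be named by the genome's chromosomes")
    values <- values[genome$chrom]
    got <- vapply(values, length, 0L)
    if (any(got != nb)) stop("value vector length must be ceiling(chrom length / bin_size)")
    if (is.null(covered)) {
      covered <- lapply(nb, function(n) rep(TRUE, n))
      names(covered) <- genome$chrom
    }
  }
  covered <- covered[genome$chrom]
  stopifnot(identical(unname(vapply(covered, length, 0L)), unname(nb)))
  structure(list(genome = genome, bin_size = bin_size,
                 values = values, covered = covered),
            class = "signal_track")
}

n_bins <- function(len, bin_size) {
  x <- as.integer(ceiling(len / bin_size))
  names(x) <- names(len)
  x
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", nrow(x$genome), "chromosome(s), bin_size", x$bin_size, "\n")
  cov <- sum(vapply(x$covered, sum, 0)) / max(1, sum(vapply(x$covered, length, 0L)))
  cat(sprintf("  covered bins: %.1f%%\n", 100 * cov))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!identical(a$genome$chrom, b$genome$chrom) ||
      !isTRUE(all.equal(a$genome$length, b$genome$length)) ||
      a$bin_size != b$bin_size)
    stop("signal tracks differ in genome or bin_size")
  invisible(TRUE)
}

#' Subtract an input track from an IP track
#'
#' The per-bin signed difference is retained (negatives are not clipped);
#' downstream thresholds operate on the signed value. A bin counts as covered
#' when either operand covers it.
#'
#' @param ip,input `signal_track`s on the same genome and bin grid, typically
#'   RPM-normalized IP and input coverage.
#' @return A `signal_track` of per-bin `ip - input`.
#' @export
subtract_input <- function(ip, input) {
  check_same_grid(ip, input)
  vals <- Map(function(a, b, ca, cb) ifelse(ca | cb, a - b, 0),
              ip$values, input$values, ip$covered, input$covered)
  cov <- Map(`|`, ip$covered, input$covered)
  signal_track(ip$genome, ip$bin_size, values = vals, covered = cov)
}

#' Reads-per-million normalization
#'
#' @param counts A `signal_track` of raw per-bin read counts/coverage.
#' @param total_reads Total mapped reads (> 0).
#' @return A `signal_track` with `value * 1e6 / total_reads` per bin.
#' @export
rpm_normalize <- function(counts, total_reads) {
  if (!is.numeric(total_reads) || length(total_reads) != 1L || total_reads <= 0)
    stop("total_reads must be a single positive number")
  vals <- lapply(counts$values, function(v) v * 1e6 / total_reads)
  signal_track(counts$genome, counts$bin_size, values = vals, covered = counts$covered)
}

## Vectorized covered-weighted base sums over half-open base ranges [s, e)
## on one chromosome. Returns list(sum = covered value-sum, cov = covered
## base count). Within a bin every base carries the bin value; uncovered
## bins contribute 0 to the sum.
range_base_sums <- function(values, covered, bin_size, s, e) {
  v1 <- values * covered
  C <- c(0, cumsum(v1))          # C[k+1] = sum of v1[1..k]
  K <- c(0, cumsum(as.numeric(covered)))
  b0 <- s %/% bin_size           # 0-based first bin
  b1 <- (e - 1) %/% bin_size     # 0-based last bin
  one <- b0 == b1
  ssum <- numeric(length(s)); scov <- numeric(length(s))
  if (any(one)) {
    i <- which(one)
    ssum[i] <- (e[i] - s[i]) * v1[b0[i] + 1]
    scov[i] <- (e[i] - s[i]) * covered[b0[i] + 1]
  }
  if (any(!one)) {
    i <- which(!one)
    first_len <- (b0[i] + 1) * bin_size - s[i]
    last_len <- e[i] - b1[i] * bin_size
    mid_sum <- (C[b1[i] + 1] - C[b0[i] + 2]) * bin_size
    mid_cov <- (K[b1[i] + 1] - K[b0[i] + 2]) * bin_size
    ssum[i] <- first_len * v1[b0[i] + 1] + mid_sum + last_len * v1[b1[i] + 1]
    scov[i] <- first_len * covered[b0[i] + 1] + mid_cov + last_len * covered[b1[i] + 1]
  }
  list(sum = ssum, cov = scov)
}

## Vectorized over a data.frame of intervals (possibly many chromosomes).
## Returns data.frame(sum, covered_bases). Ranges must be pre-clipped.
track_range_sums <- function(track, chrom, start, end) {
  ssum <- numeric(length(start)); scov <- numeric(length(start))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (!ch %in% names(track$values)) stop("chromosome not in track genome: ", ch)
    rs <- range_base_sums(track$values[[ch]], track$covered[[ch]], track$bin_size,
                          start[i], end[i])
    ssum[i] <- rs$sum; scov[i] <- rs$cov
  }
  data.frame(sum = ssum, covered_bases = scov)
}
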