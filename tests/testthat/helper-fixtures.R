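# shared fixture builders: everything generated in code, nothing on disk

toy_genome <- function(n = 1, len = 1000) {
  genome_description(paste0("chr", seq_len(n)), rep(len, n))
}

const_track <- function(genome, bin_size, value, covered = TRUE) {
  nb <- as.integer(ceiling(genome$length / bin_size))
  vals <- lapply(nb, function(k) rep(value, k))
  cov <- lapply(nb, function(k) rep(covered, k))
  names(vals) <- names(cov) <- genome$chrom
  signal_track(genome, bin_size, values = vals, covered = cov)
}

random_track <- function(genome, bin_size, cover_p = 0.8) {
  nb <- as.integer(ceiling(genome$length / bin_size))
  vals <- lapply(nb, function(k) stats::rnorm(k))
  cov <- lapply(nb, function(k) stats::runif(k) < cover_p)
  names(vals) <- names(cov) <- genome$chrom
  signal_track(genome, bin_size, values = vals, covered = cov)
}

# expand a track to per-base vectors on one chromosome
per_base <- function(track, chrom) {
  len <- track$genome$length[match(chrom, track$genome$chrom)]
  v <- rep(track$values[[chrom]], each = track$bin_size)[seq_len(len)]
  cov <- rep(track$covered[[chrom]], each = track$bin_size)[seq_len(len)]
  list(v = v, cov = cov)
}

# brute-force per-base mean/covered fraction over [s, e) (0-based half-open)
oracle_mean <- function(track, chrom, s, e) {
  pb <- per_base(track, chrom)
  idx <- (s + 1):e
  c(mean = sum((pb$v * pb$cov)[idx]) / (e - s),
    covered_fraction = mean(pb$cov[idx]))
}

# random non-degenerate intervals on a genome
random_intervals <- function(genome, n, max_width = 200) {
  ch <- sample(genome$chrom, n, replace = TRUE)
  len <- genome$length[match(ch, genome$chrom)]
  w <- sample(max_width, n, replace = TRUE)
  s <- floor(stats::runif(n) * (len - w))
  genome_intervals(ch, s, s + w)
}

# a sharp PWM over an alphabet excluding C, on an all-C background: the only
# windows scoring >= 0 are exact consensus matches on the plus strand
strict_pwm <- function(consensus = "ATTGTA", name = consensus) {
  cons <- strsplit(consensus, "")[[1]]
  m <- matrix(1, 4, length(cons), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(cons, rownames(m)), seq_along(cons))] <- 9997
  pwm(m, pseudocount = 0, score_threshold = 0, name = name)
}

plant_in_C <- function(consensus, positions, len = 200) {
  v <- rep("C", len)
  for (p in positions)
    v[(p + 1):(p + nchar(consensus))] <- strsplit(consensus, "")[[1]]
  paste(v, collapse = "")
}

small_synth <- function(seed = 11, ...) {
  args <- utils::modifyList(list(n_chroms = 2, chrom_length = 5e5,
                                 n_motifs = 200, n_hetero_sites = 0,
                                 seed = seed),
                            list(...))
  do.call(synthetic_spec, args)
}
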