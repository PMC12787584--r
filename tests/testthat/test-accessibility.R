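test_that("peaks split at the DNase cutoff with ties going to resistant", {
  gn <- toy_genome(len = 1000)
  mk <- function(v) const_track(gn, 10, v)
  pk <- peaks_table("chr1", 100, 110, genome = gn)   # single-bin peak
  expect_equal(classify_accessibility(pk, mk(0.07))$label, "accessible")
  expect_equal(classify_accessibility(pk, mk(0))$label, "resistant")
  expect_equal(classify_accessibility(pk, mk(0.05))$label, "resistant")
  expect_error(classify_accessibility(pk[0, ], mk(1)), "empty")
  expect_error(classify_accessibility(pk, mk(1), cutoff = -1), ">= 0")
})

test_that("accessible and resistant fractions are complementary and monotone in cutoff", {
  gn <- toy_genome(len = 100000)
  set.seed(21)
  tr <- random_track(gn, 10, cover_p = 1)
  tr$values$chr1 <- abs(tr$values$chr1)
  pk <- random_intervals(gn, 200, max_width = 300)
  prev <- rep("accessible", 200)
  for (cutoff in c(0, 0.2, 0.5, 1, 2)) {
    calls <- classify_accessibility(pk, tr, cutoff = cutoff)
    frac_acc <- mean(calls$label == "accessible")
    expect_equal(frac_acc + attr(calls, "closed_fraction"), 1)
    # raising the cutoff never moves a peak resistant -> accessible
    expect_false(any(prev == "resistant" & calls$label == "accessible"))
    prev <- calls$label
  }
})

test_that("planted open fractions are recovered from synthetic peaks", {
  for (p_open in c(0.2, 0.8)) {
    spec <- synthetic_spec(
      n_chroms = 2, chrom_length = 1e6, n_motifs = 400, n_hetero_sites = 0,
      state_fractions = c(open_naive = p_open, closed_naive = 1 - p_open,
                          K9_domain = 0, K27_domain = 0),
      class_fractions = c(bound = 0.5, sampled = 0.2, unsampled = 0.3),
      seed = 40 + round(10 * p_open))
    g <- generate_synthetic_genome(spec)
    peaks <- consensus_peaks(g$peaks)
    calls <- classify_accessibility(peaks, g$tracks$dnase)
    truth <- g$truth$motifs$accessible[g$truth$motifs$klass == "bound"]
    expect_equal(mean(calls$label == "accessible"), mean(truth))
    n <- nrow(peaks)
    ci <- stats::qbinom(c(0.005, 0.995), n, p_open) / n
    rec <- mean(calls$label == "accessible")
    expect_gte(rec, ci[1]); expect_lte(rec, ci[2])
  }
})

test_that("turnover labels follow the central-window mean and cutoff", {
  gn <- toy_genome(len = 10000)
  pk <- random_intervals(gn, 20, max_width = 200)
  expect_true(all(classify_turnover(pk, const_track(gn, 10, 0), cutoff = 0)$turnover_label == "low"))
  expect_true(all(classify_turnover(pk, const_track(gn, 10, 5), cutoff = Inf)$turnover_label == "low"))
  # planted high-turnover (open) sites recovered at the default median cutoff
  # (median separates the dichotomy when the planted split is balanced)
  spec <- small_synth(seed = 13,
                      state_fractions = c(open_naive = 0.5, closed_naive = 0.3,
                                          K9_domain = 0.1, K27_domain = 0.1),
                      class_fractions = c(bound = 0.5, sampled = 0.2,
                                          unsampled = 0.3))
  g <- generate_synthetic_genome(spec)
  m <- g$truth$motifs
  iv <- genome_intervals(m$chrom, m$start, m$end)
  calls <- classify_turnover(iv, g$tracks$turnover)
  expect_gte(mean(calls$turnover_label[m$accessible] == "high"), 0.95)
  expect_gte(mean(calls$turnover_label[!m$accessible] == "low"), 0.95)
})

test_that("motif accessibility split recovers the planted open fraction", {
  gn <- toy_genome(len = 1000)
  iv <- random_intervals(gn, 10, max_width = 8)
  out <- motif_accessibility_split(iv, const_track(gn, 10, 0))
  expect_true(all(out$label == "inaccessible"))
  spec <- small_synth(seed = 14,
                      state_fractions = c(open_naive = 0.5, closed_naive = 0.5,
                                          K9_domain = 0, K27_domain = 0))
  g <- generate_synthetic_genome(spec)
  split <- motif_accessibility_split(g$motifs, g$tracks$dnase)
  expect_equal(mean(split$label == "accessible"),
               mean(g$truth$motifs$accessible), tolerance = 0.03)
})

test_that("equal-size accessibility bins put the remainder in the top bin", {
  gn <- toy_genome(len = 100000)
  set.seed(77)
  pk <- random_intervals(gn, 25, max_width = 60)
  pk$start <- pk$start + 1000  # keep away from edges after standardization
  pk$end <- pk$end + 1000
  dnase <- runif(25)
  seqs <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 1e5, TRUE), collapse = ""))
  res <- binned_motif_enrichment(pk, dnase, strict_pwm(), seqs, n_bins = 10,
                                 genome = gn)
  sizes <- attr(res, "bins")$n
  expect_equal(sizes, c(rep(2, 9), 7))
  # brute-force partition: lowest 2 dnase values in bin 1, etc.
  ord <- order(dnase)
  expect_equal(sort(dnase[ord[1:2]]),
               sort(dnase[dnase <= attr(res, "bins")$dnase_max[1] &
                          dnase >= attr(res, "bins")$dnase_min[1]]))
  expect_error(binned_motif_enrichment(pk, dnase, strict_pwm(), seqs, n_bins = 1),
               "n_bins")
})

test_that("bin-specific motifs are reported and uniform motifs are not", {
  gn <- toy_genome(len = 200000)
  set.seed(78)
  n <- 200
  start <- seq(1000, by = 900, length.out = n)
  pk <- peaks_table("chr1", start, start + 200, genome = gn)
  dnase <- seq_len(n) / n                   # rank = accessibility
  seq_v <- sample(c("A", "C", "G", "T"), 2e5, TRUE)
  plant <- function(v, s, cons) { v[(s + 1):(s + nchar(cons))] <- strsplit(cons, "")[[1]]; v }
  # uniform motif in every peak, top-bin motif only in the 20 most accessible
  for (i in seq_len(n)) seq_v <- plant(seq_v, start[i] + 50, "ATTGTA")
  top <- which(dnase > 0.9)
  for (i in top) seq_v <- plant(seq_v, start[i] + 120, "TTAGGC")
  seqs <- c(chr1 = paste(seq_v, collapse = ""))
  res <- binned_motif_enrichment(pk, dnase,
                                 list(strict_pwm("ATTGTA"), strict_pwm("TTAGGC")),
                                 seqs, n_bins = 10, genome = gn)
  planted <- res[res$motif == "TTAGGC", ]
  expect_true(planted$enriched[planted$bin == 10])
  expect_gt(planted$fg_freq[planted$bin == 10], 0.95)
  uniform_rows <- res[res$motif == "ATTGTA", ]
  expect_false(any(uniform_rows$enriched))
  expect_true(all(abs(uniform_rows$log2_enrichment) < 0.2))
})
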