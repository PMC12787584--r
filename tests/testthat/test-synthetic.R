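test_that("class apportionment is exact and deterministic", {
  spec <- synthetic_spec(seed = 1)
  g <- generate_synthetic_genome(spec)
  counts <- table(factor(g$truth$motifs$klass, c("bound", "sampled", "unsampled")))
  expect_equal(as.integer(counts), c(30L, 310L, 660L))
  # state apportionment is exact too
  st <- table(factor(g$truth$motifs$state,
                     c("open_naive", "closed_naive", "K9_domain", "K27_domain")))
  expect_equal(as.integer(st), c(250L, 450L, 150L, 150L))
})

test_that("a fixed seed reproduces the bundle exactly", {
  spec <- small_synth(seed = 5, n_motifs = 80)
  g1 <- generate_synthetic_genome(spec)
  g2 <- generate_synthetic_genome(spec)
  expect_identical(g1, g2)
  g3 <- generate_synthetic_genome(small_synth(seed = 6, n_motifs = 80))
  expect_false(identical(g1$tracks$ip$values, g3$tracks$ip$values))
})

test_that("degenerate all-bound spec places every motif under a peak with signal", {
  spec <- small_synth(seed = 8, n_motifs = 50,
                      class_fractions = c(bound = 1, sampled = 0, unsampled = 0),
                      noise_sd = 1e-12)
  g <- generate_synthetic_genome(spec)
  expect_true(all(g$truth$motifs$klass == "bound"))
  expect_true(all(overlaps_any <- sapply(seq_len(nrow(g$motifs)), function(i)
    any(g$peaks$rep1$chrom == g$motifs$chrom[i] &
        g$peaks$rep1$start < g$motifs$end[i] &
        g$peaks$rep1$end > g$motifs$start[i]))))
  sig <- central_window_mean(g$tracks$ip, g$motifs)$mean
  expect_true(all(sig > 0))
})

test_that("IP signal orders bound > sampled > unsampled for several seeds", {
  for (seed in c(2, 9, 31)) {
    g <- generate_synthetic_genome(small_synth(seed = seed, n_motifs = 120))
    sig <- central_window_mean(g$tracks$ip, g$motifs)$mean
    k <- g$truth$motifs$klass
    expect_gt(mean(sig[k == "bound"]), mean(sig[k == "sampled"]))
    expect_gt(mean(sig[k == "sampled"]), mean(sig[k == "unsampled"]))
  }
})

test_that("every planted gap is depleted relative to its flanking domain", {
  spec <- synthetic_spec(seed = 12, n_chroms = 2, chrom_length = 1e6,
                         n_motifs = 50, n_hetero_sites = 10,
                         domains_per_chrom = 1, gap_rate = 3,
                         state_fractions = c(open_naive = 0.15, closed_naive = 0.15,
                                             K9_domain = 0.35, K27_domain = 0.35))
  g <- generate_synthetic_genome(spec)
  gaps <- g$truth$gaps
  expect_gt(nrow(gaps), 0)
  for (i in seq_len(nrow(gaps))) {
    tr <- if (gaps$mark[i] == "H3K9me3") g$tracks$h3k9me3 else g$tracks$h3k27me3
    gap_mean <- average_over_interval(tr, gaps[i, ])$mean
    flank <- genome_intervals(rep(gaps$chrom[i], 2),
                              c(gaps$start[i] - 1000, gaps$end[i]),
                              c(gaps$start[i], gaps$end[i] + 1000))
    flank_mean <- mean(average_over_interval(tr, flank)$mean)
    expect_lt(gap_mean, flank_mean)
    # gaps lie strictly inside a domain of their mark
    d <- g$truth$domains
    inside <- any(d$mark == gaps$mark[i] & d$chrom == gaps$chrom[i] &
                    d$start < gaps$start[i] & d$end > gaps$end[i])
    expect_true(inside)
  }
})

test_that("generation fails cleanly when sites cannot be placed", {
  expect_error(generate_synthetic_genome(
    synthetic_spec(n_chroms = 1, chrom_length = 1e5, n_motifs = 10,
                   n_hetero_sites = 50)),
    "generation error")
  expect_error(generate_synthetic_genome(
    small_synth(seed = 1, n_motifs = 100000)),
    "generation error")
})

test_that("fixtures round-trip through the plain-text writers", {
  spec <- small_synth(seed = 3, n_motifs = 40, chrom_length = 1e5,
                      replicate_dropout = 0.2)
  g <- generate_synthetic_genome(spec)
  out <- withr::local_tempdir()
  files <- write_fixture(g, out)
  expect_gte(length(files), 7L)
  expect_true(all(file.exists(files)))
  expect_true(all(file.size(files) > 0))
  # track round trip
  tr <- read_bedgraph(file.path(out, "ip.bedGraph"), g$genome, spec$bin_size)
  expect_lt(max(abs(tr$values$chr1 - g$tracks$ip$values$chr1)), 1e-9)
  # peaks, motifs, segmentation, truth
  p1 <- read_bed(file.path(out, "peaks_rep1.narrowPeak"), g$genome)
  expect_equal(nrow(p1), nrow(g$peaks$rep1))
  expect_lt(nrow(read_bed(file.path(out, "peaks_rep2.narrowPeak"), g$genome)),
            nrow(p1) + 1)
  m <- read_bed(file.path(out, "motifs.bed"), g$genome)
  expect_equal(m[c("chrom", "start", "end")], g$motifs[c("chrom", "start", "end")],
               ignore_attr = TRUE)
  seg <- read_segmentation(file.path(out, "segmentation.bed"), g$genome)
  expect_equal(seg$state, g$truth$segmentation$state)
  truth <- read.delim(file.path(out, "truth.tsv"))
  expect_equal(nrow(truth), 40L)
  expect_equal(truth$klass, g$truth$motifs$klass)
})

test_that("specifications validate their fractions and geometry", {
  expect_error(synthetic_spec(state_fractions = c(open_naive = 0.5, closed_naive = 0.4,
                                                  K9_domain = 0.2, K27_domain = 0.2)),
               "sum to 1")
  expect_error(synthetic_spec(class_fractions = c(bound = 1, sampled = 0.5,
                                                  unsampled = -0.5)),
               "sum to 1|fractions")
  expect_error(synthetic_spec(bound_signal_mean = 0.1, sampled_signal_mean = 0.5),
               "bound_signal_mean")
  expect_error(synthetic_spec(chrom_length = 1e6 + 5), "multiple")
})
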