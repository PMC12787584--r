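test_that("interval means match the per-base brute-force oracle", {
  set.seed(31)
  for (bin in c(1, 3, 10)) {
    gn <- toy_genome(n = 2, len = 5000)
    tr <- random_track(gn, bin)
    iv <- random_intervals(gn, 300)
    got <- average_over_interval(tr, iv)
    exp <- t(vapply(seq_len(nrow(iv)), function(i)
      oracle_mean(tr, iv$chrom[i], iv$start[i], iv$end[i]), numeric(2)))
    expect_equal(got$mean, exp[, 1], tolerance = 1e-12)
    expect_equal(got$covered_fraction, exp[, 2], tolerance = 1e-12)
  }
  expect_error(average_over_interval(random_track(toy_genome(), 5),
                                     genome_intervals("chr1", 900, 1100)),
               "exceed")
})

test_that("uncovered spans contribute zero signal but full denominator", {
  gn <- toy_genome(len = 100)
  tr <- const_track(gn, 10, 4)
  tr$covered$chr1[6:10] <- FALSE    # second half uncovered
  out <- average_over_interval(tr, genome_intervals("chr1", 0, 100))
  expect_equal(out$mean, 2)
  expect_equal(out$covered_fraction, 0.5)
  tr$covered$chr1[] <- FALSE
  out <- average_over_interval(tr, genome_intervals("chr1", 10, 60))
  expect_equal(out$mean, 0)
  expect_equal(out$covered_fraction, 0)
})

test_that("central windows center on floor((start+end)/2) and clip at edges", {
  gn <- toy_genome(len = 1000)
  tr <- const_track(gn, 10, 1.5)
  expect_equal(central_window_mean(tr, genome_intervals("chr1", 0, 1000), 100),
               data.frame(mean = 1.5, covered_fraction = 1))
  # window wider than the interval: brute-force over the explicit window
  set.seed(5)
  tr2 <- random_track(gn, 10)
  iv <- genome_intervals("chr1", 480, 500)   # center 490, window [440, 540)
  got <- central_window_mean(tr2, iv, 100)
  exp <- oracle_mean(tr2, "chr1", 440, 540)
  expect_equal(got$mean, unname(exp["mean"]))
  # clipped at chromosome start: denominator is the clipped length
  iv2 <- genome_intervals("chr1", 0, 20)     # center 10, clipped window [0, 60)
  got2 <- central_window_mean(tr2, iv2, 100)
  exp2 <- oracle_mean(tr2, "chr1", 0, 60)
  expect_equal(got2$mean, unname(exp2["mean"]))
  expect_equal(got2$covered_fraction, unname(exp2["covered_fraction"]))
})

test_that("central window of full even width equals the interval mean", {
  gn <- toy_genome(len = 2000)
  set.seed(6)
  tr <- random_track(gn, 10)
  iv <- genome_intervals("chr1", c(100, 500), c(300, 900))  # bin-aligned, even
  w <- iv$end - iv$start
  for (i in 1:2)
    expect_equal(central_window_mean(tr, iv[i, ], w[i])$mean,
                 average_over_interval(tr, iv[i, ])$mean)
})

test_that("signal matrices bin signal around the reference point", {
  gn <- toy_genome(len = 10000)
  tr <- const_track(gn, 10, 3)
  m <- signal_matrix(tr, genome_intervals("chr1", c(4000, 6000), c(4400, 6400)),
                     window = 1000, bin = 50)
  expect_equal(dim(m), c(2L, 40L))
  expect_true(all(m == 3))
  # delta signal at the reference point: center bins maximal, symmetric
  tr2 <- signal_track(gn, 10)
  tr2$values$chr1[501] <- 10    # bases 5000-5009
  tr2$covered$chr1[] <- TRUE
  iv <- genome_intervals("chr1", 4900, 5110)  # center 5005
  m2 <- signal_matrix(tr2, iv, window = 200, bin = 20)
  exp <- vapply(seq_len(20), function(j) {
    s <- 5005 - 200 + (j - 1) * 20
    unname(oracle_mean(tr2, "chr1", s, s + 20)["mean"])
  }, 0)
  expect_equal(as.numeric(m2[1, ]), exp)
  expect_equal(which.max(m2[1, ]), which.max(exp))
  # summit reference
  pk <- peaks_table("chr1", 4000, 6000, summit_offset = 1005, genome = gn)
  m3 <- signal_matrix(tr2, pk, window = 200, bin = 20, reference = "summit")
  expect_equal(as.numeric(m3[1, ]), exp)
  expect_error(signal_matrix(tr, iv, window = 130, bin = 50), "multiple")
})

test_that("zero-row skipping and permutation equivariance", {
  gn <- toy_genome(len = 10000)
  z <- const_track(gn, 10, 0)
  iv <- random_intervals(gn, 5, max_width = 100)
  expect_equal(nrow(signal_matrix(z, iv, 1000, 50, skip_zero_rows = TRUE)), 0L)
  set.seed(8)
  tr <- random_track(gn, 10)
  iv <- random_intervals(gn, 20, max_width = 100)
  iv$start <- pmax(iv$start, 1000); iv$end <- iv$start + 50
  perm <- sample(nrow(iv))
  m1 <- signal_matrix(tr, iv, 500, 50)
  m2 <- signal_matrix(tr, iv[perm, ], 500, 50)
  expect_equal(unname(m2), unname(m1[perm, ]), ignore_attr = TRUE)
})

test_that("metaprofiles are column means", {
  gn <- toy_genome(len = 10000)
  set.seed(10)
  tr <- random_track(gn, 10)
  iv <- genome_intervals("chr1", c(3000, 3000), c(3400, 3400))
  m <- signal_matrix(tr, iv, 400, 40)
  expect_equal(unname(metaprofile(m)), as.numeric(m[1, ]))
  m2 <- matrix(rnorm(200), 10, 20)
  expect_equal(unname(metaprofile(m2)), colMeans(m2))
  expect_equal(unname(metaprofile(m2[1, , drop = FALSE])), m2[1, ])
  expect_error(metaprofile(m2[0, , drop = FALSE]), "empty")
})

test_that("width standardization recenters at the rounded mean width", {
  gn <- toy_genome(len = 10000)
  iv <- genome_intervals("chr1", c(1000, 2000, 3000), c(1100, 2251, 3150))
  # widths 100, 251, 150 -> mean 167, round-half-up 167
  out <- standardize_widths(iv, gn)
  expect_equal(out$end - out$start, rep(167, 3))
  expect_equal(floor((out$start + out$end) / 2),
               floor((iv$start + iv$end) / 2))
  # round-half-up at .5
  iv2 <- genome_intervals("chr1", c(0, 0), c(100, 101))
  expect_equal(unique(with(standardize_widths(iv2), end - start)), 101)
  # clipped at chromosome edges but width preserved
  iv3 <- genome_intervals("chr1", 2, 30)
  out3 <- standardize_widths(iv3, gn, width = 100)
  expect_equal(out3$start, 0)
  expect_equal(out3$end, 100)
})
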