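#' Built-in SOX-like position weight matrix
#'
#' A sharp 7-position matrix (consensus `CATTGTT`, the HMG-box binding site
#' family) used as the generator default and in examples.
#'
#' @param score_threshold Hit threshold in bits.
#' @return A [pwm()].
#' @export
default_pwm <- function(score_threshold = 6) {
  cons <- c("C", "A", "T", "T", "G", "T", "T")
  m <- matrix(2, 4, length(cons), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(cons, rownames(m)), seq_along(cons))] <- 94
  pwm(m, score_threshold = score_threshold, name = "SOX")
}

## largest-remainder apportionment of n among named fractions
apportion <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(q - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  out <- as.integer(base)
  names(out) <- names(fractions)
  out
}

#' Specify a synthetic genome with planted chromatin ground truth
#'
#' The generated genome emulates the fibroblast-style epigenome the pipeline
#' is designed for: chromosomes partitioned into open naive, closed naive,
#' H3K9me3-domain and H3K27me3-domain states; broad repressive domains with
#' small internal gaps; motif instances planted with true classes bound /
#' sampled / unsampled; IP signal with strong bumps at bound and weak bumps
#' at sampled motifs; and DNase/turnover tracks consistent with the planted
#' states. Every stochastic choice derives from `seed`, so a fixed seed
#' reproduces the bundle byte for byte.
#'
#' @param n_chroms,chrom_length,bin_size Genome geometry; `chrom_length`
#'   must be a multiple of `bin_size`.
#' @param state_fractions Named fractions over `open_naive`, `closed_naive`,
#'   `K9_domain`, `K27_domain` (sum to 1).
#' @param gap_rate Expected random gaps per repressive domain (Poisson).
#' @param gap_width Width of planted gaps in bases.
#' @param motif A [pwm()]; its consensus is planted at motif instances.
#' @param n_motifs Number of motif instances.
#' @param class_fractions Named fractions over `bound`, `sampled`,
#'   `unsampled` (sum to 1); assigned by largest-remainder apportionment then
#'   a seeded shuffle, so truth counts are exact.
#' @param bound_signal_mean,sampled_signal_mean IP bump amplitudes (RPM) at
#'   bound and sampled motifs; must satisfy `bound > sampled > 0`.
#' @param noise_sd IP background noise standard deviation (RPM).
#' @param dnase_open_mean,dnase_closed_mean DNase level (RPM) in open/other
#'   states.
#' @param turnover_high_mean,turnover_low_mean 6h H2B turnover level (RPM)
#'   in open/other states.
#' @param n_hetero_sites Planted heterochromatin test sites per local-density
#'   subtype (high / flat / gap), split across the two marks.
#' @param domains_per_chrom Repressive domains per mark per chromosome.
#' @param replicate_dropout Probability that a peak is missing from the
#'   second pseudo-replicate.
#' @param peak_halfwidth Half-width of emitted peaks in bases.
#' @param seed Random seed.
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_chroms = 4, chrom_length = 2e6, bin_size = 10,
                           state_fractions = c(open_naive = 0.25,
                                               closed_naive = 0.45,
                                               K9_domain = 0.15,
                                               K27_domain = 0.15),
                           gap_rate = 2, gap_width = 2000,
                           motif = default_pwm(), n_motifs = 1000,
                           class_fractions = c(bound = 0.03, sampled = 0.31,
                                               unsampled = 0.66),
                           bound_signal_mean = 5, sampled_signal_mean = 0.5,
                           noise_sd = 0.05,
                           dnase_open_mean = 2, dnase_closed_mean = 0.01,
                           turnover_high_mean = 1.5, turnover_low_mean = 0.05,
                           n_hetero_sites = 30, domains_per_chrom = 2,
                           replicate_dropout = 0, peak_halfwidth = 150,
                           seed = 1) {
  spec <- as.list(environment())
  states <- c("open_naive", "closed_naive", "K9_domain", "K27_domain")
  if (!setequal(names(spec$state_fractions), states))
    stop("state_fractions must be named ", paste(states, collapse = ", "))
  spec$state_fractions <- spec$state_fractions[states]
  klasses <- c("bound", "sampled", "unsampled")
  if (!setequal(names(spec$class_fractions), klasses))
    stop("class_fractions must be named ", paste(klasses, collapse = ", "))
  spec$class_fractions <- spec$class_fractions[klasses]
  if (abs(sum(spec$state_fractions) - 1) > 1e-9) stop("state_fractions must sum to 1")
  if (abs(sum(spec$class_fractions) - 1) > 1e-9) stop("class_fractions must sum to 1")
  if (any(spec$state_fractions < 0) || any(spec$class_fractions < 0))
    stop("fractions must be >= 0")
  if (!(bound_signal_mean > sampled_signal_mean && sampled_signal_mean > 0))
    stop("need bound_signal_mean > sampled_signal_mean > 0")
  if (chrom_length %% bin_size != 0) stop("chrom_length must be a multiple of bin_size")
  if (!inherits(motif, "pwm")) stop("motif must be a pwm object")
  structure(spec, class = "synthetic_spec")
}

## Gaussian bumps added in place on a binned vector
add_bumps <- function(v, bin_size, centers, amp, sd) {
  if (!length(centers)) return(v)
  nb <- length(v)
  halfspan <- ceiling(4 * sd)
  for (i in seq_along(centers)) {
    b0 <- max(0, (centers[i] - halfspan) %/% bin_size)
    b1 <- min(nb - 1, (centers[i] + halfspan) %/% bin_size)
    idx <- seq.int(b0, b1)
    x <- idx * bin_size + bin_size / 2
    v[idx + 1] <- v[idx + 1] + amp * exp(-((x - centers[i])^2) / (2 * sd^2))
  }
  v
}

## set [start, end) spans of a binned vector to value * factor
scale_spans <- function(v, bin_size, start, end, factor) {
  nb <- length(v)
  for (i in seq_along(start)) {
    b0 <- max(0, start[i] %/% bin_size)
    b1 <- min(nb - 1, (end[i] - 1) %/% bin_size)
    v[(b0 + 1):(b1 + 1)] <- v[(b0 + 1):(b1 + 1)] * factor
  }
  v
}

STATE_IDS <- c(open_naive = 1L, closed_naive = 2L, K9_domain = 3L, K27_domain = 4L)

#' Generate a synthetic genome bundle from a specification
#'
#' See [synthetic_spec()] for the data model. Chromosomes are laid out as a
#' seeded shuffle of state segments (open and closed naive chromatin split
#' into several segments each; each repressive mark as `domains_per_chrom`
#' broad domains), giving exact per-state base counts. Motifs are planted
#' inside their target state with >= 1 kb spacing and the PWM consensus
#' written into the background sequence. IP bumps are Gaussian with a 200-b
#' standard deviation, approximating a 300-500 bp ChIP fragment footprint.
#' Peaks are emitted at bound motifs only, in two pseudo-replicates.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_genome`:
#'   `genome` ([genome_description()]),
#'   `tracks` (named list: `dnase`, `turnover`, `h3k9me3`, `h3k27me3`, `ip`),
#'   `peaks` (list of two replicate peak data.frames),
#'   `motifs` (interval data.frame),
#'   `sequences` (named character vector),
#'   `truth` (list: `motifs` with true class/state/accessibility, `domains`,
#'   `gaps`, `hetero_sites`, `segmentation`),
#'   `spec`.
#' @export
generate_synthetic_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  bs <- spec$bin_size
  L <- spec$chrom_length
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  genome <- genome_description(chroms, rep(L, spec$n_chroms))
  pwm_len <- ncol(spec$motif$matrix)
  consensus <- strsplit(pwm_consensus(spec$motif), "")[[1]]

  ## --- chromosome layout: shuffled state segments on the bin grid ---
  n_pieces <- c(open_naive = 4L, closed_naive = 5L,
                K9_domain = spec$domains_per_chrom,
                K27_domain = spec$domains_per_chrom)
  seg_rows <- list()
  for (ch in chroms) {
    bases <- apportion(L %/% bs, spec$state_fractions) * bs
    pieces <- list()
    for (st in names(bases)) {
      if (bases[[st]] == 0) next
      k <- min(n_pieces[[st]], bases[[st]] %/% bs)
      widths <- apportion(bases[[st]] %/% bs, rep(1 / k, k)) * bs
      for (w in widths[widths > 0]) pieces[[length(pieces) + 1L]] <- c(STATE_IDS[[st]], w)
    }
    pieces <- pieces[sample.int(length(pieces))]
    pos <- 0
    for (p in pieces) {
      seg_rows[[length(seg_rows) + 1L]] <-
        data.frame(chrom = ch, start = pos, end = pos + p[2], state = p[1])
      pos <- pos + p[2]
    }
  }
  segmentation <- do.call(rbind, seg_rows)
  segmentation$name <- paste0("E", segmentation$state)
  segmentation$score <- NA_real_; segmentation$strand <- "."

  dlist <- lapply(c(H3K9me3 = 3L, H3K27me3 = 4L), function(id) {
    d <- merge_intervals(segmentation[segmentation$state == id, , drop = FALSE])
    if (nrow(d) == 0L) return(NULL)
    d$mark <- names(which(c(H3K9me3 = 3L, H3K27me3 = 4L) == id))
    d
  })
  dlist <- Filter(Negate(is.null), dlist)
  domains <- if (length(dlist)) do.call(rbind, dlist) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character(), score = numeric(), strand = character(),
               mark = character())
  rownames(domains) <- NULL

  ## --- heterochromatin test sites and random gaps inside domains ---
  site_margin <- 6500; site_spacing <- 8000
  slot_list <- list()
  if (!is.null(domains) && nrow(domains)) {
    for (i in seq_len(nrow(domains))) {
      lo <- domains$start[i] + site_margin
      hi <- domains$end[i] - site_margin
      if (hi - lo < site_spacing) next
      centers <- seq(lo, hi, by = site_spacing)
      slot_list[[i]] <- data.frame(chrom = domains$chrom[i], center = centers,
                                   mark = domains$mark[i], domain = i)
    }
  }
  slots <- if (length(slot_list)) do.call(rbind, slot_list) else
    data.frame(chrom = character(), center = numeric(), mark = character(),
               domain = integer())
  n_sites <- 3L * spec$n_hetero_sites
  if (n_sites > nrow(slots))
    stop("generation error: cannot place ", n_sites,
         " heterochromatin sites in the available domains")
  hetero_sites <- NULL
  if (n_sites > 0) {
    pick <- sample.int(nrow(slots), n_sites)
    hetero_sites <- slots[pick, , drop = FALSE]
    hetero_sites$subtype <- sample(rep(c("high", "flat", "gap"),
                                       each = spec$n_hetero_sites))
    slots <- slots[-pick, , drop = FALSE]
  } else {
    hetero_sites <- data.frame(chrom = character(), center = numeric(),
                               mark = character(), domain = integer(),
                               subtype = character())
  }
  gap_rows <- list()
  if (!is.null(domains) && nrow(domains)) {
    for (i in seq_len(nrow(domains))) {
      avail <- slots[slots$domain == i, , drop = FALSE]
      ng <- min(stats::rpois(1, spec$gap_rate), nrow(avail))
      if (ng > 0) {
        g <- avail[sample.int(nrow(avail), ng), , drop = FALSE]
        gap_rows[[length(gap_rows) + 1L]] <-
          data.frame(chrom = g$chrom, start = g$center - spec$gap_width / 2,
                     end = g$center + spec$gap_width / 2, mark = g$mark)
      }
    }
  }
  site_gaps <- hetero_sites[hetero_sites$subtype == "gap", , drop = FALSE]
  if (nrow(site_gaps))
    gap_rows[[length(gap_rows) + 1L]] <-
      data.frame(chrom = site_gaps$chrom,
                 start = site_gaps$center - spec$gap_width / 2,
                 end = site_gaps$center + spec$gap_width / 2,
                 mark = site_gaps$mark)
  gaps <- if (length(gap_rows)) do.call(rbind, gap_rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               mark = character())

  ## --- motif placement, stratified by state, >= 1 kb apart ---
  motif_margin <- 1000; motif_spacing <- 1000
  state_counts <- apportion(spec$n_motifs, spec$state_fractions)
  names(state_counts) <- names(spec$state_fractions)
  motif_rows <- list()
  for (st in names(state_counts)) {
    cnt <- state_counts[[st]]
    if (cnt == 0) next
    segs <- segmentation[segmentation$state == STATE_IDS[[st]], , drop = FALSE]
    pool <- list()
    for (i in seq_len(nrow(segs))) {
      lo <- segs$start[i] + motif_margin
      hi <- segs$end[i] - motif_margin - pwm_len
      if (hi <= lo) next
      pool[[i]] <- data.frame(chrom = segs$chrom[i],
                              start = seq(lo, hi, by = motif_spacing))
    }
    pool <- do.call(rbind, pool)
    if (is.null(pool) || nrow(pool) < cnt)
      stop("generation error: cannot place ", cnt, " motifs in state ", st)
    sel <- pool[sample.int(nrow(pool), cnt), , drop = FALSE]
    sel$state <- st
    motif_rows[[st]] <- sel
  }
  motifs <- do.call(rbind, motif_rows)
  motifs <- motifs[order(motifs$chrom, motifs$start), , drop = FALSE]
  rownames(motifs) <- NULL
  motifs$end <- motifs$start + pwm_len
  class_counts <- apportion(spec$n_motifs, spec$class_fractions)
  motifs$klass <- sample(rep(names(spec$class_fractions), class_counts))
  motifs$accessible <- motifs$state == "open_naive"
  motifs$name <- paste0("motif_", seq_len(nrow(motifs)))

  ## --- background sequence with planted consensus ---
  sequences <- vapply(chroms, function(ch) {
    v <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    m <- motifs[motifs$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(m)))
      v[(m$start[i] + 1):(m$start[i] + pwm_len)] <- consensus
    paste(v, collapse = "")
  }, "", USE.NAMES = TRUE)

  ## --- signal tracks ---
  nb <- L %/% bs
  rel_sd <- 0.25
  mk_track <- function(values) signal_track(genome, bs, values = values)
  bin_state <- lapply(chroms, function(ch) {
    s <- segmentation[segmentation$chrom == ch, , drop = FALSE]
    rep(s$state, (s$end - s$start) %/% bs)
  })
  names(bin_state) <- chroms
  two_level <- function(hi_mean, lo_mean) {
    vals <- lapply(chroms, function(ch) {
      open <- bin_state[[ch]] == 1L
      v <- stats::rnorm(nb, lo_mean, rel_sd * lo_mean)
      v[open] <- stats::rnorm(sum(open), hi_mean, rel_sd * hi_mean)
      pmax(v, 0)
    })
    names(vals) <- chroms
    vals
  }
  dnase <- mk_track(two_level(spec$dnase_open_mean, spec$dnase_closed_mean))
  turnover <- mk_track(two_level(spec$turnover_high_mean, spec$turnover_low_mean))

  domain_level <- 1
  mark_vals <- function(state_id, mark_name) {
    vals <- lapply(chroms, function(ch) {
      v <- stats::rnorm(nb, 0.02, 0.01)
      inside <- bin_state[[ch]] == state_id
      v[inside] <- stats::rnorm(sum(inside), domain_level, 0.1 * domain_level)
      g <- gaps[gaps$chrom == ch & gaps$mark == mark_name, , drop = FALSE]
      v <- scale_spans(v, bs, g$start, g$end, 0.1)
      hs <- hetero_sites[hetero_sites$chrom == ch &
                           hetero_sites$mark == mark_name &
                           hetero_sites$subtype == "high", , drop = FALSE]
      v <- add_bumps(v, bs, hs$center, 2 * domain_level, 300)
      pmax(v, 0)
    })
    names(vals) <- chroms
    vals
  }
  h3k9me3 <- mk_track(mark_vals(3L, "H3K9me3"))
  h3k27me3 <- mk_track(mark_vals(4L, "H3K27me3"))

  ip_vals <- lapply(chroms, function(ch) {
    v <- stats::rnorm(nb, 0, spec$noise_sd)
    m <- motifs[motifs$chrom == ch, , drop = FALSE]
    ctr <- floor((m$start + m$end) / 2)
    v <- add_bumps(v, bs, ctr[m$klass == "bound"], spec$bound_signal_mean, 200)
    v <- add_bumps(v, bs, ctr[m$klass == "sampled"], spec$sampled_signal_mean, 200)
    pmax(v, 0)
  })
  names(ip_vals) <- chroms
  ip <- mk_track(ip_vals)

  ## --- peaks at bound motifs, two pseudo-replicates ---
  bm <- motifs[motifs$klass == "bound", , drop = FALSE]
  ctr <- floor((bm$start + bm$end) / 2)
  mk_peaks <- function(rep_id, keep) {
    peaks_table(bm$chrom[keep],
                pmax(0, ctr[keep] - spec$peak_halfwidth),
                pmin(L, ctr[keep] + spec$peak_halfwidth),
                name = paste0(rep_id, "_peak_", seq_len(sum(keep))),
                summit_offset = spec$peak_halfwidth,
                enrichment = spec$bound_signal_mean,
                replicate_id = rep_id, genome = genome)
  }
  keep2 <- stats::runif(nrow(bm)) >= spec$replicate_dropout
  peaks <- list(rep1 = mk_peaks("rep1", rep(TRUE, nrow(bm))),
                rep2 = mk_peaks("rep2", keep2))

  truth_motifs <- motifs[, c("name", "chrom", "start", "end", "klass",
                             "state", "accessible")]
  motifs_out <- genome_intervals(motifs$chrom, motifs$start, motifs$end,
                                 name = motifs$name, genome = genome)
  structure(list(genome = genome,
                 tracks = list(dnase = dnase, turnover = turnover,
                               h3k9me3 = h3k9me3, h3k27me3 = h3k27me3, ip = ip),
                 peaks = peaks,
                 motifs = motifs_out,
                 sequences = sequences,
                 truth = list(motifs = truth_motifs, domains = domains,
                              gaps = gaps, hetero_sites = hetero_sites,
                              segmentation = segmentation),
                 spec = spec),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome:", nrow(x$genome), "chromosome(s) x",
      format(x$genome$length[1], big.mark = ","), "bases, ",
      nrow(x$truth$motifs), "motifs\n")
  print(table(x$truth$motifs$klass))
  invisible(x)
}

#' Write a generated bundle to plain-text fixture files
#'
#' Emits one bedGraph per track, narrowPeak files for the peak replicates,
#' BED for motifs, the state segmentation BED, a chromosome-size table, and
#' a truth TSV with one row per motif.
#'
#' @param gen A [generate_synthetic_genome()] bundle.
#' @param outdir Output directory (created if absent).
#' @param write_sequence Also write the genome sequence as FASTA.
#' @return Invisibly, the vector of files written.
#' @export
write_fixture <- function(gen, outdir, write_sequence = FALSE) {
  stopifnot(inherits(gen, "synthetic_genome"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  p <- function(f) file.path(outdir, f)
  for (nm in names(gen$tracks)) {
    write_bedgraph(gen$tracks[[nm]], p(paste0(nm, ".bedGraph")))
    files <- c(files, p(paste0(nm, ".bedGraph")))
  }
  write_narrowpeak(gen$peaks$rep1, p("peaks_rep1.narrowPeak"))
  write_narrowpeak(gen$peaks$rep2, p("peaks_rep2.narrowPeak"))
  write_bed(gen$motifs, p("motifs.bed"))
  write_segmentation(gen$truth$segmentation, p("segmentation.bed"))
  utils::write.table(gen$genome, p("genome.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gen$truth$motifs, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, p(c("peaks_rep1.narrowPeak", "peaks_rep2.narrowPeak",
                        "motifs.bed", "segmentation.bed", "genome.tsv",
                        "truth.tsv")))
  if (write_sequence) {
    con <- file(p("genome.fa"), "w")
    for (ch in names(gen$sequences)) {
      writeLines(paste0(">", ch), con)
      writeLines(gen$sequences[[ch]], con)
    }
    close(con)
    files <- c(files, p("genome.fa"))
  }
  invisible(files)
}
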