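# Mappability, binning, counting, masking, GC correction, CBS,
# spurious-segment removal and event calling.

test_that("unique mappability flags repeats and leaves random sequence unique", {
  g <- generate_genome(1, 5e4, gc = 0.5, seed = 9)
  mp <- compute_mappability(g, 40)
  expect_gt(mean(mp$chr1[1:(5e4 - 39)]), 0.999)
  expect_true(all(!mp$chr1[(5e4 - 38):5e4]))  # no full probe fits

  # two identical chromosomes: no unique positions at all
  g2 <- tiny_genome(chr1 = g$seq[[1]], chr2 = g$seq[[1]])
  mp2 <- compute_mappability(g2, 40)
  expect_equal(sum(mp2$chr1) + sum(mp2$chr2), 0)

  # a planted exact duplication kills uniqueness inside both copies
  s <- g$seq[[1]]
  dup <- substring(s, 10001, 11000)
  g3 <- tiny_genome(chr1 = paste0(s, dup))
  mp3 <- compute_mappability(g3, 40)
  expect_true(all(!mp3$chr1[10001:(11000 - 39)]))
  expect_true(all(!mp3$chr1[(5e4 + 1):(5e4 + 1000 - 39)]))

  expect_error(compute_mappability(g, 10), ">= 20")
  expect_error(compute_mappability(g, 1e5), "shortest chromosome")
})

test_that("bins hold equal mappable counts; physical width varies", {
  # idealized fully-mappable genome: uniform 600 bp bins
  g <- generate_genome(1, 6e5, gc = 0.5, seed = 10)
  mp <- list(chr1 = rep(TRUE, 6e5))
  bins <- make_bins(g, mp, 1000)
  expect_equal(nrow(bins), 1000L)
  expect_true(all(bins$end - bins$start == 600))
  expect_true(all(bins$n_mappable == 600))
  expect_true(all(!bins$masked))

  # an unmappable block widens its bin but keeps the mappable target
  mp2 <- list(chr1 = rep(TRUE, 6e5))
  mp2$chr1[100001:110000] <- FALSE
  bins2 <- make_bins(g, mp2, 100)
  target <- ceiling((6e5 - 1e4) / 100)
  wide <- which(bins2$start <= 100000 & bins2$end >= 110000)
  expect_equal(length(wide), 1L)
  expect_equal(bins2$n_mappable[wide], target)
  expect_gt(bins2$end[wide] - bins2$start[wide], 10000)

  # bins tile the genome
  expect_equal(bins2$start, c(0, utils::head(bins2$end, -1)))
  expect_equal(bins2$end[nrow(bins2)], 6e5)

  expect_error(make_bins(g, mp, 2e6), "fewer mappable")
})

test_that("fragment counting is unique-only and midpoint-based", {
  g <- generate_genome(1, 6e5, gc = 0.5, seed = 10)
  bins <- make_bins(g, list(chr1 = rep(TRUE, 6e5)), 100)

  # no fragments: all zero
  b0 <- count_fragments(bins, data.frame(chrom = character(),
                                         ref_start = numeric(),
                                         ref_end = numeric(),
                                         is_unique = logical()))
  expect_true(all(b0$raw_count == 0))

  # midpoint exactly on a boundary goes to the bin that contains it
  # (bin 2 is [6000, 12000); midpoint 6000 belongs to it)
  f <- data.frame(chrom = "chr1", ref_start = 5900, ref_end = 6100,
                  is_unique = TRUE)
  b1 <- count_fragments(bins, f)
  expect_equal(b1$raw_count[2], 1)
  expect_equal(sum(b1$raw_count), 1)

  # non-unique fragments are not counted
  f2 <- data.frame(chrom = "chr1", ref_start = c(0, 0), ref_end = c(100, 100),
                   is_unique = c(FALSE, TRUE))
  expect_equal(sum(count_fragments(bins, f2)$raw_count), 1)

  # uniform fragments give Poisson counts around the mean
  set.seed(2)
  n <- 1e5
  mid <- sort(sample.int(6e5, n, replace = TRUE)) - 1
  fu <- data.frame(chrom = "chr1", ref_start = pmax(0, mid - 50),
                   ref_end = pmin(6e5, mid + 50), is_unique = TRUE)
  bu <- count_fragments(bins, fu)
  expect_lt(abs(mean(bu$raw_count) - 1000), 10)
  expect_gte(mean(abs(bu$raw_count - 1000) <= 3 * sqrt(1000)), 0.99)

  expect_error(count_fragments(bins, data.frame(chrom = "chr1",
                                                ref_start = 7e5,
                                                ref_end = 7e5 + 100,
                                                is_unique = TRUE)), "bounds")
})

test_that("bad-bin masking removes spikes and converges to a fixed point", {
  bins <- synthetic_bins(n = 200, counts = rep(1000, 200))

  # uniform counts: nothing masked
  expect_true(all(!mask_bad_bins(bins)$masked))

  # a single 100x spike is masked
  b2 <- bins; b2$raw_count[57] <- 1e5
  m2 <- mask_bad_bins(b2)
  expect_true(m2$masked[57])
  expect_equal(sum(m2$masked), 1L)

  # two-tier outliers: the big spike hides the small one until the first
  # pass removes it; both are masked at the fixed point
  b3 <- synthetic_bins(n = 200, counts = rpois(200, 1000), seed = 8)
  b3$raw_count[10] <- 2e5
  b3$raw_count[20] <- 3e4
  m3 <- mask_bad_bins(b3)
  expect_true(all(m3$masked[c(10, 20)]))
  expect_equal(sum(m3$masked), 2L)

  # genuine 2x amplification levels are not maskable (min_fold guard)
  b4 <- synthetic_bins(n = 200, counts = c(rpois(180, 1000), rpois(20, 2000)),
                       seed = 9)
  expect_true(all(!mask_bad_bins(b4)$masked))

  expect_error(mask_bad_bins(synthetic_bins(n = 10)), "at least 30")
})

test_that("LOWESS GC correction flattens linear bias and spares unbiased data", {
  # exactly linear bias: corrected counts constant at the grand mean
  bins <- synthetic_bins(n = 200)
  bins$raw_count <- 100 + 200 * (bins$gc - 0.5)
  bc <- gc_correct(bins)
  expect_lt(max(abs(bc$corrected_count - mean(bins$raw_count))), 2)

  # residual correlation with GC is gone (add tiny noise so cor is defined)
  set.seed(1)
  bins2 <- synthetic_bins(n = 300)
  bins2$raw_count <- rpois(300, 400 + 600 * (bins2$gc - 0.5))
  bc2 <- gc_correct(bins2)
  expect_gt(abs(cor(bins2$raw_count, bins2$gc)), 0.5)
  expect_lt(abs(cor(bc2$corrected_count, bc2$gc)), 0.05)

  # counts independent of GC are nearly unchanged
  bins3 <- synthetic_bins(n = 500, counts = rpois(500, 2000), seed = 4)
  bc3 <- gc_correct(bins3)
  expect_lt(max(abs(bc3$corrected_count - bins3$raw_count)) /
              mean(bins3$raw_count), 0.02)

  # idempotence: correcting already-flat data changes nothing
  flat <- bc; flat$raw_count <- bc$corrected_count
  bc4 <- gc_correct(flat)
  expect_lt(max(abs(bc4$corrected_count - flat$raw_count)) /
              mean(flat$raw_count), 0.001)

  # constant GC: identity with a warning
  bins5 <- synthetic_bins(n = 100, gc = rep(0.5, 100))
  expect_warning(bc5 <- gc_correct(bins5), "constant")
  expect_equal(bc5$corrected_count, bins5$raw_count)
})

test_that("bin ratios average exactly 1 over unmasked bins", {
  bins <- synthetic_bins(n = 100, counts = rpois(100, 500), seed = 5)
  bins$masked[c(3, 50)] <- TRUE
  bins$corrected_count <- bins$raw_count
  br <- bin_ratios(bins)
  expect_equal(mean(br$ratio[!br$masked]), 1, tolerance = 1e-12)
  expect_true(all(is.na(br$ratio[br$masked])))
})

test_that("CBS splits real steps, not i.i.d. noise", {
  # null sequence: a single segment
  set.seed(31)
  s0 <- segment_cbs(rnorm(100, 1, 0.05), alpha = 0.01, seed = 7)
  expect_equal(nrow(s0), 1L)

  # obvious long step: one changepoint, within +/-1 bin
  set.seed(32)
  x <- c(rnorm(50, 1, 0.05), rnorm(50, 2, 0.05))
  s1 <- segment_cbs(x, alpha = 0.01, seed = 7)
  expect_equal(nrow(s1), 2L)
  expect_lte(abs(s1$last[1] - 50), 1)
  expect_equal(s1$mean_ratio, c(1, 2), tolerance = 0.05)

  # the canonical tiny step splits once the permutation granularity allows
  # it (best p for a 4+4 circular step is ~8/70, out of reach of alpha 0.01)
  set.seed(33)
  x8 <- c(1, 1, 1, 1, 2, 2, 2, 2) + rnorm(8, 0, 0.01)
  s8 <- segment_cbs(x8, alpha = 0.2, seed = 1)
  expect_equal(nrow(s8), 2L)
  expect_equal(s8$last[1], 4L)

  # short inputs: single trivial segment
  expect_equal(nrow(segment_cbs(c(1))), 1L)
  expect_equal(nrow(segment_cbs(numeric(0))), 0L)

  # determinism
  expect_identical(segment_cbs(x, seed = 12), segment_cbs(x, seed = 12))
})

test_that("the best arc agrees with the exhaustive SSE-minimizing oracle", {
  sse_oracle <- function(x) {
    n <- length(x); best <- Inf; bi <- 0; bj <- 0
    for (i in 0:(n - 1)) for (j in (i + 1):n) {
      k <- j - i
      if (k == n) next
      arc <- x[(i + 1):j]; rest <- x[-((i + 1):j)]
      sse <- sum((arc - mean(arc))^2) + sum((rest - mean(rest))^2)
      if (sse < best - 1e-12) { best <- sse; bi <- i; bj <- j }
    }
    c(bi, bj)
  }
  # an arc and its complement induce the same partition: compare the
  # changepoint sets, not the (i, j) representatives
  cps <- function(i, j, n) setdiff(c(i, j), c(0, n))
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    cp <- sample(3:(n - 3), 1)
    x <- c(rnorm(cp, 1, 0.1), rnorm(n - cp, 1 + sample(c(0.5, 1), 1), 0.1))
    got <- smurfseq:::cpp_best_arc(x)
    want <- sse_oracle(x)
    expect_equal(cps(got$i, got$j, n), cps(want[1], want[2], n))
  }
})

test_that("type-I split rate stays at or below alpha", {
  set.seed(55)
  n_runs <- 300
  splits <- 0
  for (r in seq_len(n_runs)) {
    x <- rnorm(100, 1, 0.05)
    if (nrow(segment_cbs(x, alpha = 0.05, n_perm = 500, seed = r)) > 1)
      splits <- splits + 1
  }
  # binomial upper bound for p = 0.05 at n = 300
  expect_lte(splits / n_runs, 0.05 + 2 * sqrt(0.05 * 0.95 / n_runs))
})

test_that("spurious segments merge into the closer neighbor until stable", {
  x <- c(rep(1, 20), rep(1.8, 2), rep(1, 20))
  seg <- data.frame(first = c(1L, 21L, 23L), last = c(20L, 22L, 42L),
                    n_bins = c(20L, 2L, 20L),
                    mean_ratio = c(1, 1.8, 1))
  out <- remove_spurious_segments(seg, x)
  expect_equal(nrow(out), 1L)
  expect_equal(out$first, 1L)
  expect_equal(out$last, 42L)

  # nothing to merge: unchanged
  x2 <- c(rep(1, 20), rep(2, 20))
  seg2 <- data.frame(first = c(1L, 21L), last = c(20L, 40L),
                     n_bins = c(20L, 20L), mean_ratio = c(1, 2))
  expect_identical(remove_spurious_segments(seg2, x2), seg2)

  # chains of merges terminate (stairway of shallow steps collapses)
  x3 <- rep(c(1, 1.05, 1.1, 1.15), each = 10)
  seg3 <- data.frame(first = seq(1L, 31L, 10L), last = seq(10L, 40L, 10L),
                     n_bins = rep(10L, 4),
                     mean_ratio = c(1, 1.05, 1.1, 1.15))
  out3 <- remove_spurious_segments(seg3, x3)
  expect_equal(nrow(out3), 1L)
})

test_that("event calls follow the segment means with inclusive cutoffs", {
  bins <- synthetic_bins(n = 30, counts = rep(100, 30))
  segs <- data.frame(chrom = "chr1", first_bin = c(1L, 11L, 21L),
                     last_bin = c(10L, 20L, 30L),
                     mean_ratio = c(1.0, 1.3, 0.7))
  out <- call_events(bins, segs)
  expect_equal(unique(out$state[1:10]), "neutral")
  expect_equal(unique(out$state[11:20]), "amplified")
  expect_equal(unique(out$state[21:30]), "deleted")

  # boundary values are inclusive
  segs$mean_ratio <- c(1.25, 0.8, 1.0)
  out2 <- call_events(bins, segs)
  expect_equal(out2$state[1], "amplified")
  expect_equal(out2$state[11], "deleted")

  # all-neutral: no events
  segs$mean_ratio <- c(1, 1.1, 0.9)
  expect_true(all(call_events(bins, segs)$state == "neutral"))

  expect_error(call_events(bins, segs, amp_cutoff = 0.5, del_cutoff = 0.8),
               "amp_cutoff")
})

test_that("the full profile recovers a planted copy-number landscape", {
  g <- generate_genome(1, 2e6, gc = 0.5, seed = 61)
  # CN4 and CN1 segments sized so the genome-wide mean stays at CN 2
  tr <- plant_cnv(g, data.frame(chrom = "chr1", start = c(4e5, 1e6),
                                end = c(6e5, 14e5), copy_number = c(4, 1)))
  dig <- digest_genome(g, "SaqAI")
  fr <- sample_fragments(dig, tr, 2e5, seed = 13)
  p <- cnv_profile(g, truth_as_alignments(fr), n_bins = 100, seed = 3)
  expect_equal(nrow(p$segments), 5L)
  expect_equal(p$segments$mean_ratio, c(1, 2, 1, 0.5, 1), tolerance = 0.05)
  st <- p$bins$state
  expect_true(all(st[p$bins$start >= 4e5 & p$bins$end <= 6e5] == "amplified"))
  expect_true(all(st[p$bins$start >= 1e6 & p$bins$end <= 14e5] == "deleted"))

  # determinism of the whole pipeline
  p2 <- cnv_profile(g, truth_as_alignments(fr), n_bins = 100, seed = 3)
  expect_identical(p$bins, p2$bins)
  expect_identical(p$segments, p2$segments)
})
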