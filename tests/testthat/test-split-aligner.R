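# Seed index, chaining, banded extension and the full split mapper.

test_that("the seed index finds every occurrence of a k-mer", {
  g <- tiny_genome("ACGTACGTACGT")
  idx <- build_index(g, k = 8)
  hits <- index_lookup(idx, "ACGTACGT")
  expect_setequal(hits$pos, c(0, 4))

  # absent k-mer: empty hit list
  expect_equal(nrow(index_lookup(idx, "TTTTTTTT")), 0L)

  # every k-mer of a genome is found at its own position
  g2 <- generate_genome(1, 1e4, gc = 0.5, seed = 8)
  idx2 <- build_index(g2, k = 12)
  at <- c(1, 500, 9988)
  for (p in at) {
    km <- substring(g2$seq[[1]], p, p + 11)
    hits <- index_lookup(idx2, km)
    expect_true((p - 1) %in% hits$pos[hits$strand == "+"])
  }
  expect_error(build_index(tiny_genome("ACGT"), 12), "shorter")
})

test_that("seed chains are one per co-linear fragment", {
  g <- generate_genome(2, 1e5, gc = 0.5, seed = 41)
  idx <- build_index(g, 12)

  # exact copy of a unique locus: one chain covering the read
  f1 <- substring(g$seq[[1]], 10001, 10200)
  ch <- seed_chains(f1, idx)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$read_start, 0)
  expect_equal(ch$read_end, 200)

  # two fragments from different chromosomes: two chains, one per chrom
  f2 <- substring(g$seq[[2]], 50001, 50200)
  ch2 <- seed_chains(paste0(f1, f2), idx)
  expect_equal(nrow(ch2), 2L)
  expect_setequal(ch2$chrom, c("chr1", "chr2"))

  # random read vs an unrelated genome: a couple of spurious single-seed
  # chains are expected (189 positions x 2 strands x 2e5/4^12 hits each
  # ~ 4), but none of them survives extension to the score floor
  other <- generate_genome(1, 1e5, gc = 0.5, seed = 99)
  rnd <- substring(other$seq[[1]], 1, 200)
  expect_lt(nrow(seed_chains(rnd, idx)), 10L)
  expect_equal(nrow(map_read(rnd, idx)), 0L)
})

test_that("extension scores obey the threshold arithmetic exactly", {
  g <- generate_genome(1, 2e5, gc = 0.5, seed = 11)
  idx <- build_index(g, 12)

  # perfect 30 bp match scores 30*4 = 120: exactly reportable
  f30 <- substring(g$seq[[1]], 70001, 70030)
  m30 <- map_read(f30, idx)
  expect_equal(nrow(m30), 1L)
  expect_equal(m30$score, 120)

  # 31 bp with one central mismatch: 30*4 - 10 = 110 < 120, suppressed
  f31 <- substring(g$seq[[1]], 80001, 80031)
  s <- strsplit(f31, "")[[1]]
  s[16] <- setdiff(c("A", "C", "G", "T"), s[16])[1]
  expect_equal(nrow(map_read(paste(s, collapse = ""), idx)), 0L)

  # 40 matched bases with one 2 bp deletion: 160 - (6 + 2*3) = 148
  f42 <- substring(g$seq[[1]], 90001, 90042)
  rd <- paste0(substr(f42, 1, 20), substr(f42, 23, 42))
  m42 <- map_read(rd, idx)
  expect_equal(m42$score, 148)
  expect_equal(m42$ref_end - m42$ref_start, 42)

  # reads too short to reach the score floor report nothing
  expect_equal(nrow(map_read(substring(g$seq[[1]], 100, 125), idx)), 0L)
})

test_that("error-free multi-fragment reads are recovered fragment for fragment", {
  fx <- map_fixture()
  truth <- fx$reads$truth
  m <- fx$mapped
  # nearly every truth fragment is recovered at its mapping location;
  # boundaries are score-determined (local extension) and may slip by a few
  # bases into the adjacent ligated fragment when bases match by chance
  # (with restriction fragments the slip is partly systematic: the
  # reference continues with the recognition-site bases that the next
  # ligated fragment also begins with, so 3-4 bp overshoots are expected)
  mt <- match_fragments(truth, m, min_overlap = 0.5)
  expect_gt(nrow(mt) / nrow(truth), 0.99)
  d_start <- abs(m$ref_start[mt$pred_row] - truth$start[mt$truth_row])
  d_end <- abs(m$ref_end[mt$pred_row] - truth$end[mt$truth_row])
  expect_lte(median(d_start), 4)
  expect_lte(median(d_end), 4)
  expect_gt(mean(d_start <= 10 & d_end <= 10), 0.90)

  # fragments are sorted by read_start and never overlap by > 20%
  for (id in unique(m$read_id)[1:25]) {
    f <- m[m$read_id == id, ]
    expect_true(!is.unsorted(f$read_start))
    if (nrow(f) > 1) {
      ov <- utils::head(f$read_end, -1) - f$read_start[-1]
      shorter <- pmin(utils::head(f$read_end - f$read_start, -1),
                      (f$read_end - f$read_start)[-1])
      expect_true(all(ov <= 0.2 * shorter + 1e-9))
    }
  }
})

test_that("a fragment duplicated at two loci is reported as non-unique", {
  g <- generate_genome(2, 1e5, gc = 0.5, seed = 41)
  dup <- substring(g$seq[[1]], 20001, 20200)
  s2 <- g$seq
  s2[["chr2"]] <- paste0(substr(s2[["chr2"]], 1, 7e4), dup,
                         substr(s2[["chr2"]], 70201, 1e5))
  gd <- tiny_genome(chr1 = s2[["chr1"]], chr2 = s2[["chr2"]])
  idx <- build_index(gd, 12)
  md <- map_read(dup, idx)
  expect_equal(nrow(md), 1L)
  expect_false(md$is_unique)
  # deterministic tie-break: lowest chromosome wins
  expect_equal(md$chrom, "chr1")
})

test_that("reported scores equal the full Smith-Waterman oracle", {
  fx <- map_fixture()
  m <- fx$mapped_err
  m <- m[m$read_end - m$read_start <= 500, ]
  m <- m[seq_len(min(nrow(m), 120)), ]
  seqs <- setNames(fx$reads_err$reads$sequence, fx$reads_err$reads$read_id)
  for (i in seq_len(nrow(m))) {
    f <- m[i, ]
    q <- substring(seqs[[f$read_id]], f$read_start + 1, f$read_end)
    if (f$strand == "-") q <- revcomp1(q)
    t <- substring(fx$genome$seq[[f$chrom]], f$ref_start + 1, f$ref_end)
    expect_equal(sw_oracle_score(q, t), f$score)
  }
})

test_that("re-scoring the reported CIGAR path reproduces the score exactly", {
  fx <- map_fixture()
  m <- fx$mapped_err[seq_len(100), ]
  sc <- vapply(seq_len(nrow(m)), function(i)
    rescore_alignment(m[i, ], fx$reads_err, fx$genome), numeric(1))
  expect_equal(sc, m$score)
})

test_that("raising the score floor never increases reported fragments", {
  fx <- map_fixture()
  sub <- structure(list(reads = fx$reads_err$reads[1:10, ],
                        truth = fx$reads_err$truth), class = "smurf_reads")
  n_prev <- Inf
  for (T in c(120, 200, 400, 800)) {
    n <- nrow(map_reads(sub, fx$index, scoring_scheme(min_report_score = T)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("mapping is deterministic", {
  fx <- map_fixture()
  sub <- structure(list(reads = fx$reads_err$reads[1:5, ],
                        truth = fx$reads_err$truth), class = "smurf_reads")
  expect_identical(map_reads(sub, fx$index), map_reads(sub, fx$index))
})
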