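# Fragment sampling, read concatenation and the error model.

test_that("fragments are sampled proportional to midpoint copy number", {
  g <- generate_genome(1, 3e5, gc = 0.5, seed = 1)
  dig <- digest_genome(g, "SaqAI")

  # half CN2, half CN4: 4/(2+4) = 2/3 of draws from the CN4 half
  tr <- plant_cnv(g, data.frame(chrom = "chr1", start = 15e4, end = 3e5,
                                copy_number = 4))
  fr <- sample_fragments(dig, tr, 1e5, seed = 2)
  frac4 <- mean((fr$start + fr$end) %/% 2 >= 15e4)
  expect_lt(abs(frac4 - 2 / 3), 0.01)

  # thirds at CN {2,1,3}: normalized weights {1/3, 1/6, 1/2}
  tr3 <- plant_cnv(g, data.frame(chrom = "chr1", start = c(0, 1e5, 2e5),
                                 end = c(1e5, 2e5, 3e5),
                                 copy_number = c(2, 1, 3)))
  fr3 <- sample_fragments(dig, tr3, 9e4, seed = 3)
  mid <- (fr3$start + fr3$end) %/% 2
  fracs <- c(mean(mid < 1e5), mean(mid >= 1e5 & mid < 2e5), mean(mid >= 2e5))
  expect_lt(max(abs(fracs - c(1 / 3, 1 / 6, 1 / 2))), 0.015)

  # zero copy number everywhere: nothing to sample
  tr0 <- plant_cnv(g, data.frame(chrom = "chr1", start = 0, end = 3e5,
                                 copy_number = 0))
  expect_error(sample_fragments(dig, tr0, 10), "zero")

  # determinism
  expect_identical(sample_fragments(dig, tr, 100, seed = 11),
                   sample_fragments(dig, tr, 100, seed = 11))
})

test_that("concatenation packs fragments without splitting them", {
  g <- generate_genome(1, 1e4, gc = 0.5, seed = 4)
  fr <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                   end = c(100, 200, 300), strand = "+")
  rds <- concatenate_fragments(fr, g, 250)
  expect_equal(nrow(rds$reads), 2L)
  expect_equal(nchar(rds$reads$sequence), c(200L, 100L))
  expect_equal(rds$truth$frag_index, c(1L, 2L, 1L))

  # a single fragment with a huge target: one read, interval [0, len)
  one <- concatenate_fragments(fr[1, ], g, 1e4)
  expect_equal(nrow(one$reads), 1L)
  expect_equal(one$truth$read_start, 0L)
  expect_equal(one$truth$read_end, 100L)

  expect_error(concatenate_fragments(fr, g, 50), "longest fragment")
})

test_that("truth tiles every read and error-free fragments match the reference", {
  fx <- map_fixture()
  truth <- fx$reads$truth
  for (id in unique(truth$read_id)[1:20]) {
    t1 <- truth[truth$read_id == id, ]
    expect_equal(t1$read_start, c(0L, utils::head(t1$read_end, -1)))
  }
  expect_equal(sum(nchar(fx$reads$reads$sequence)),
               sum(truth$read_end - truth$read_start))

  # strand-adjusted reference substring equals the read substring
  idx <- sample.int(nrow(truth), 50)
  seqs <- setNames(fx$reads$reads$sequence, fx$reads$reads$read_id)
  for (i in idx) {
    t1 <- truth[i, ]
    got <- substring(seqs[[t1$read_id]], t1$read_start + 1, t1$read_end)
    ref <- substring(fx$genome$seq[[t1$chrom]], t1$start + 1, t1$end)
    if (t1$strand == "-") ref <- revcomp1(ref)
    expect_identical(got, ref)
  }
})

test_that("fragments per read track target length / mean fragment length", {
  fx <- map_fixture()
  fpr <- nrow(fx$reads$truth) / nrow(fx$reads$reads)
  mean_frag <- mean(fx$reads$truth$end - fx$reads$truth$start)
  expect_lt(abs(fpr - 6750 / mean_frag) / (6750 / mean_frag), 0.10)
})

test_that("the error model is a per-base process with correct edit load", {
  fx <- map_fixture()
  rds <- fx$reads

  # all-zero rates: identity
  clean <- apply_errors(rds, error_model(0, 0, 0, seed = 1))
  expect_identical(clean$reads$sequence, rds$reads$sequence)
  expect_identical(clean$truth, rds$truth)

  # rates out of range are rejected
  expect_error(error_model(sub_rate = 1.0), "0.5")
  expect_error(error_model(del_rate = 0.5), "0.5")

  # edit distance per base ~ sum of effective rates (0.117) on a long read
  long <- which.max(nchar(rds$reads$sequence))[1]
  sub <- structure(list(reads = rds$reads[long, ],
                        truth = rds$truth[rds$truth$read_id ==
                                            rds$reads$read_id[long], ]),
                   class = "smurf_reads")
  mut <- apply_errors(sub, error_model(seed = 21))
  ed <- utils::adist(sub$reads$sequence, mut$reads$sequence)[1, 1]
  expect_lt(abs(ed / nchar(sub$reads$sequence) - 0.12), 0.02)

  # truth still tiles after errors
  err <- fx$reads_err
  for (id in unique(err$truth$read_id)[1:20]) {
    t1 <- err$truth[err$truth$read_id == id, ]
    expect_equal(t1$read_start, c(0L, utils::head(t1$read_end, -1)))
    expect_equal(t1$read_end[nrow(t1)],
                 nchar(err$reads$sequence[err$reads$read_id == id]))
  }

  # determinism
  again <- apply_errors(rds, error_model(seed = 9))
  expect_identical(again$reads$sequence, err$reads$sequence)
})

test_that("splicing cuts fragments out of origin-bearing long reads", {
  g <- generate_genome(1, 5e4, gc = 0.5, seed = 6)
  src <- data.frame(read_id = "src1",
                    sequence = substring(g$seq[[1]], 1001, 3000),
                    chrom = "chr1", start = 1000, end = 3000, strand = "+",
                    stringsAsFactors = FALSE)

  # one fragment = the whole source read reproduces it exactly
  out <- splice_from_reads(src, 2000, 2000, 1, seed = 1)
  expect_identical(out$reads$sequence, src$sequence)
  expect_equal(out$truth$start, 1000)
  expect_equal(out$truth$end, 3000)

  # fixed 200 bp fragments at target 1000: 5 fragments per read
  out2 <- splice_from_reads(src, 200, 1000, 50, seed = 2)
  per_read <- table(out2$truth$read_id)
  expect_true(all(per_read == 5))

  # spliced substrings really originate where the truth says
  for (i in seq_len(20)) {
    t1 <- out2$truth[i, ]
    rd <- out2$reads$sequence[out2$reads$read_id == t1$read_id]
    expect_identical(substring(rd, t1$read_start + 1, t1$read_end),
                     substring(g$seq[[1]], t1$start + 1, t1$end))
  }

  # empirical fragment-length mean follows the requested distribution
  lens <- sample(100:300, 50, replace = TRUE)
  out3 <- splice_from_reads(src, lens, 1500, 2000, seed = 3)
  got <- mean(out3$truth$read_end - out3$truth$read_start)
  expect_lt(abs(got - mean(lens)) / mean(lens), 0.05)

  expect_error(splice_from_reads(src, 5000, 5000, 1), "exceeds")
})
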