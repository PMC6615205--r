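# Shared fixtures, built in code.  Small genomes are constructed directly;
# the larger simulation fixtures used by several tests are computed once per
# session and memoized here.

# A genome object from explicit sequences (bypasses the >= 10 kb floor of
# generate_genome, for hand-traced cases).
tiny_genome <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("chr", seq_along(seqs))
  structure(list(seq = seqs, seed = NA_integer_), class = "smurf_genome")
}

# Full Smith-Waterman local alignment score under the package's default
# scoring, via an independent implementation (Biostrings).
sw_oracle_score <- function(q, t, match = 4, mismatch = 10, gap_open = 6,
                            gap_extend = 3) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = -mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(q, t, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = gap_open,
                                gapExtension = gap_extend, scoreOnly = TRUE)
}

revcomp1 <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Memoized medium-size mapping fixture: 2 Mb genome, >= 100 bp restriction
# fragments, error-free and error-model read sets plus their mappings.
.fixtures <- new.env(parent = emptyenv())

map_fixture <- function() {
  if (!is.null(.fixtures$map)) return(.fixtures$map)
  g <- generate_genome(1, 2e6, gc = 0.5, seed = 2)
  dig <- digest_genome(g, "SaqAI")
  dig <- dig[dig$end - dig$start >= 100, ]
  truth <- plant_cnv(g)
  frags <- sample_fragments(dig, truth, 3000, seed = 4)
  reads <- concatenate_fragments(frags, g, 6750)
  reads_err <- apply_errors(reads, error_model(seed = 9))
  idx <- build_index(g, 12)
  .fixtures$map <- list(genome = g, digest = dig, reads = reads,
                        reads_err = reads_err, index = idx,
                        mapped = map_reads(reads, idx),
                        mapped_err = map_reads(reads_err, idx))
  .fixtures$map
}

# Memoized study-scale fixture shared by the whole-pipeline tests:
# 10 Mb genome with a planted CN {2,4,1} landscape whose genome-wide mean
# copy number stays 2 (1 Mb at CN 4 balanced by 2 Mb at CN 1), its SaqAI
# digest, mappability and a 1e6-fragment draw.
study_fixture <- function() {
  if (!is.null(.fixtures$study)) return(.fixtures$study)
  g <- generate_genome(1, 1e7, gc = 0.5, seed = 101)
  tr_cnv <- plant_cnv(g, data.frame(chrom = "chr1", start = c(2e6, 5e6),
                                    end = c(3e6, 7e6), copy_number = c(4, 1)))
  dig <- digest_genome(g, "SaqAI")
  mp <- compute_mappability(g, 40)
  frags <- sample_fragments(dig, tr_cnv, 1e6, seed = 102)
  # group sampled fragments into pseudo-reads of ~25 for read-granularity
  # downsampling (the packing that concatenation would apply, without
  # materializing read sequences)
  fa <- truth_as_alignments(frags)
  pk <- smurfseq:::cpp_pack(as.integer(frags$end - frags$start), 6750L)
  fa$read_id <- sprintf("read%06d", pk$read)
  .fixtures$study <- list(genome = g, truth_cnv = tr_cnv, digest = dig,
                          mappability = mp, fragments = fa)
  .fixtures$study
}

# An idealized fully-mappable bin table for pipeline-stage unit tests.
synthetic_bins <- function(n = 200, counts = NULL, gc = NULL, seed = 3) {
  set.seed(seed)
  if (is.null(gc)) gc <- runif(n, 0.3, 0.7)
  if (is.null(counts)) counts <- stats::rpois(n, 2000)
  data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1000,
             end = seq_len(n) * 1000, n_mappable = 1000, gc = gc,
             raw_count = counts, corrected_count = NA_real_,
             ratio = NA_real_, masked = FALSE, stringsAsFactors = FALSE)
}
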