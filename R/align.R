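# Split-read mapping of concatenated-fragment reads: exact-match k-mer
# seeding, co-linear chaining within a diagonal band, and banded affine
# Smith-Waterman extension outward from the longest exact anchor of each
# chain.  One fragment alignment is reported per surviving chain.

#' Alignment scoring scheme
#'
#' The default constants are the regime selected for mapping
#' concatenated-fragment nanopore reads: match +4, mismatch -10, gap of
#' length k costs `gap_open + k * gap_extend` = 6 + 3k, seeds of at least 12
#' exact bases, chains of at least 12 seed-covered bases, and a minimum
#' reportable local alignment score of 120 (a perfect 30 bp match).
#'
#' @param match Match reward (positive).
#' @param mismatch Mismatch penalty (positive; subtracted).
#' @param gap_open,gap_extend Affine gap penalties (positive; a gap of
#'   length k costs `gap_open + k * gap_extend`).
#' @param min_seed_len Minimum exact seed length.
#' @param min_chain_weight Minimum read bases covered by a chain's seeds.
#' @param min_report_score Minimum alignment score to report a fragment.
#' @param chain_band Diagonal band (bp) within which seeds are chained.
#' @param max_seed_gap Maximum read-coordinate gap (bp) between consecutive
#'   seeds of one chain.
#' @param max_occ Seeds whose k-mer occurs more than this many times in the
#'   genome are skipped.
#' @param xdrop Extension stops once the score drops this far below the best.
#' @param ext_band Half-width of the extension band (max indel imbalance).
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 4, mismatch = 10, gap_open = 6,
                           gap_extend = 3, min_seed_len = 12,
                           min_chain_weight = 12, min_report_score = 120,
                           chain_band = 100, max_seed_gap = 150,
                           max_occ = 64, xdrop = 100, ext_band = 25) {
  vals <- c(mismatch = mismatch, gap_open = gap_open, gap_extend = gap_extend)
  if (any(vals < 0)) stopf("penalties must be >= 0")
  if (min_report_score <= 0) stopf("`min_report_score` must be > 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_seed_len = min_seed_len,
                 min_chain_weight = min_chain_weight,
                 min_report_score = min_report_score, chain_band = chain_band,
                 max_seed_gap = max_seed_gap, max_occ = max_occ,
                 xdrop = xdrop, ext_band = ext_band),
            class = "scoring_scheme")
}

#' Build an exact-match seed index over a genome
#'
#' Every k-mer of the forward strand is indexed (k-mers containing N are
#' excluded); reverse-strand hits are found at query time by looking up the
#' reverse complement of each read k-mer.
#'
#' @param genome A `smurf_genome`.
#' @param k Seed length (8-13).
#' @return A `smurf_index` object.
#' @export
build_index <- function(genome, k = 12) {
  k <- assert_count(k, "k", min = 8)
  if (sum(nchar(genome$seq)) < k) stopf("genome shorter than seed length k")
  ptr <- cpp_build_index(unname(genome$seq), k)
  structure(list(ptr = ptr, k = k, chrom_names = names(genome$seq),
                 chrom_lengths = unname(nchar(genome$seq))),
            class = "smurf_index")
}

#' @export
print.smurf_index <- function(x, ...) {
  cat(sprintf("smurf_index: k = %d over %d chromosome(s), %s bp\n",
              x$k, length(x$chrom_names),
              format(sum(x$chrom_lengths), big.mark = ",")))
  invisible(x)
}

#' Look up the reference positions of one k-mer
#'
#' @param index A `smurf_index`.
#' @param kmer A string of length `index$k` over A/C/G/T.
#' @return data.frame `chrom`, `pos` (0-based), `strand`.
#' @export
index_lookup <- function(index, kmer) {
  hits <- cpp_index_lookup(index$ptr, toupper(kmer))
  data.frame(chrom = index$chrom_names[hits$chrom], pos = hits$pos,
             strand = ifelse(hits$strand > 0, "+", "-"),
             stringsAsFactors = FALSE)
}

reads_as_character <- function(reads) {
  if (inherits(reads, "smurf_reads"))
    setNames(reads$reads$sequence, reads$reads$read_id)
  else if (is.character(reads)) {
    if (is.null(names(reads)))
      names(reads) <- sprintf("read%06d", seq_along(reads))
    reads
  } else stopf("`reads` must be a smurf_reads object or a character vector")
}

#' Map reads by splitting them into constituent fragments
#'
#' Full pipeline per read: seed, chain, extend, then resolve overlapping
#' fragment reports greedily by score (read-interval overlaps above 20% of
#' the shorter fragment are removed; ties are broken by lowest chromosome
#' and reference start).  `is_unique` is `TRUE` when the fragment's score
#' strictly exceeds every competing placement covering at least half of the
#' same read interval.
#'
#' @param reads A `smurf_reads` object or a (optionally named) character
#'   vector of read sequences.
#' @param index A `smurf_index` built with [build_index()].
#' @param scoring A [scoring_scheme()].
#' @return data.frame of fragment alignments: `read_id`, `read_start`,
#'   `read_end`, `chrom`, `ref_start`, `ref_end`, `strand`, `score`,
#'   `is_unique`, `cigar` (0-based half-open; CIGAR follows the SAM
#'   convention of reverse-complemented read coordinates on '-').
#' @export
map_reads <- function(reads, index, scoring = scoring_scheme()) {
  seqs <- reads_as_character(reads)
  raw <- cpp_map_reads(index$ptr, unname(seqs),
                       scoring$match, scoring$mismatch, scoring$gap_open,
                       scoring$gap_extend, scoring$min_seed_len,
                       scoring$min_chain_weight, scoring$min_report_score,
                       scoring$chain_band, scoring$max_seed_gap,
                       scoring$max_occ, scoring$xdrop, scoring$ext_band,
                       FALSE)
  data.frame(read_id = names(seqs)[raw$read],
             read_start = raw$read_start, read_end = raw$read_end,
             chrom = index$chrom_names[raw$chrom],
             ref_start = raw$ref_start, ref_end = raw$ref_end,
             strand = raw$strand, score = raw$score,
             is_unique = raw$score > raw$second_best,
             cigar = raw$cigar, stringsAsFactors = FALSE)
}

#' @rdname map_reads
#' @param read A single read sequence.
#' @export
map_read <- function(read, index, scoring = scoring_scheme()) {
  map_reads(setNames(as.character(read), "read"), index, scoring)
}

#' Seed chains for a read, before extension
#'
#' Exposes the seed-and-chain stage of [map_reads()]: maximal exact seed
#' hits are clustered by diagonal (within `chain_band`), ordered along the
#' read, and chains lighter than `min_chain_weight` or dominated by a
#' heavier chain covering more than half of the same read interval are
#' dropped.  The `weight` column is the number of read bases covered by the
#' chain's seeds.
#'
#' @inheritParams map_reads
#' @return data.frame `read_id`, `read_start`, `read_end`, `chrom`,
#'   `ref_start`, `ref_end`, `strand`, `weight`.
#' @export
seed_chains <- function(reads, index, scoring = scoring_scheme()) {
  seqs <- reads_as_character(reads)
  raw <- cpp_map_reads(index$ptr, unname(seqs),
                       scoring$match, scoring$mismatch, scoring$gap_open,
                       scoring$gap_extend, scoring$min_seed_len,
                       scoring$min_chain_weight, scoring$min_report_score,
                       scoring$chain_band, scoring$max_seed_gap,
                       scoring$max_occ, scoring$xdrop, scoring$ext_band,
                       TRUE)
  data.frame(read_id = names(seqs)[raw$read],
             read_start = raw$read_start, read_end = raw$read_end,
             chrom = index$chrom_names[raw$chrom],
             ref_start = raw$ref_start, ref_end = raw$ref_end,
             strand = raw$strand, weight = raw$score,
             stringsAsFactors = FALSE)
}

#' Re-score a reported alignment from its CIGAR
#'
#' Walks the alignment path (M/I/D operations) against the read and the
#' reference and recomputes the score under the scoring scheme; used to
#' verify that reported scores are exactly the score of the reported path.
#'
#' @param frag One row of the [map_reads()] output.
#' @param reads The reads the fragment came from.
#' @param genome The reference `smurf_genome`.
#' @param scoring A [scoring_scheme()].
#' @return The recomputed alignment score (integer).
#' @export
rescore_alignment <- function(frag, reads, genome, scoring = scoring_scheme()) {
  seqs <- reads_as_character(reads)
  rd <- seqs[[frag$read_id]]
  rseq <- seq_extract(rd, frag$read_start, frag$read_end)
  if (frag$strand == "-") rseq <- dna_revcomp(rseq)
  tseq <- seq_extract(genome$seq[[frag$chrom]], frag$ref_start, frag$ref_end)
  ops <- regmatches(frag$cigar, gregexpr("[0-9]+[MID]", frag$cigar))[[1]]
  n <- as.integer(sub("[MID]", "", ops))
  op <- sub("[0-9]+", "", ops)
  qi <- 0L; ti <- 0L; score <- 0L
  q <- strsplit(rseq, "")[[1]]
  t <- strsplit(tseq, "")[[1]]
  for (j in seq_along(op)) {
    if (op[j] == "M") {
      eq <- q[qi + seq_len(n[j])] == t[ti + seq_len(n[j])]
      score <- score + sum(eq) * scoring$match - sum(!eq) * scoring$mismatch
      qi <- qi + n[j]; ti <- ti + n[j]
    } else if (op[j] == "I") {
      score <- score - scoring$gap_open - n[j] * scoring$gap_extend
      qi <- qi + n[j]
    } else {
      score <- score - scoring$gap_open - n[j] * scoring$gap_extend
      ti <- ti + n[j]
    }
  }
  if (qi != length(q) || ti != length(t))
    stopf("CIGAR does not span the reported intervals")
  score
}
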