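# Simulation of concatenated-fragment (SMURF-seq) reads: fragment sampling
# proportional to local copy number, packing into long reads, and a
# nanopore-like substitution/indel error process.  Per-fragment truth is
# carried through every step in final-read coordinates.

#' Nanopore-like error model
#'
#' Independent per-base error process: each base is deleted with `del_rate`;
#' otherwise it is emitted (substituted with `sub_rate` to a uniformly chosen
#' different base) and followed by a random inserted base with `ins_rate`.
#' The defaults (0.05 / 0.03 / 0.04) give ~88% identity, in the range of
#' R9-era nanopore reads.
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities, each in [0, 0.5).
#' @param seed Integer RNG seed used when the model is applied.
#' @return An `error_model` object.
#' @export
error_model <- function(sub_rate = 0.05, ins_rate = 0.03, del_rate = 0.04,
                        seed = 1) {
  for (r in c(sub = sub_rate, ins = ins_rate, del = del_rate)) {
    if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r >= 0.5)
      stopf("error rates must each be in [0, 0.5)")
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, seed = seed),
            class = "error_model")
}

#' Sample restriction fragments proportional to local copy number
#'
#' Each draw picks a digest fragment with probability proportional to the
#' planted copy number at the fragment midpoint, with replacement; strand is
#' Bernoulli(1/2) per fragment, reflecting random ligation orientation.
#'
#' @param digest Fragment table from [digest_genome()].
#' @param truth A `cnv_truth` from [plant_cnv()].
#' @param n Number of fragments to draw.
#' @param seed Integer RNG seed.
#' @return data.frame `chrom`, `start`, `end`, `strand` in draw order.
#' @export
sample_fragments <- function(digest, truth, n, seed = 1) {
  n <- assert_count(n, "n", min = 1)
  if (is.null(digest) || nrow(digest) == 0) stopf("empty digest")
  mid <- (digest$start + digest$end) %/% 2
  w <- copy_number_at(truth, digest$chrom, mid)
  w[is.na(w)] <- 0
  if (all(w == 0)) stopf("all copy numbers are zero: no mass to sample from")
  set.seed(seed)
  idx <- sample.int(nrow(digest), n, replace = TRUE, prob = w)
  data.frame(chrom = digest$chrom[idx],
             start = digest$start[idx],
             end = digest$end[idx],
             strand = ifelse(runif(n) < 0.5, "+", "-"),
             stringsAsFactors = FALSE)
}

new_smurf_reads <- function(reads, truth) {
  structure(list(reads = reads, truth = truth), class = "smurf_reads")
}

#' @export
print.smurf_reads <- function(x, ...) {
  cat(sprintf("smurf_reads: %d read(s), %d fragment(s), mean length %.1f bp\n",
              nrow(x$reads), nrow(x$truth), mean(nchar(x$reads$sequence))))
  invisible(x)
}

#' Concatenate sampled fragments into long reads
#'
#' Fragments are packed in sampled order; a read is closed when adding the
#' next fragment would exceed `target_read_len` (fragments are never split,
#' so read lengths spread by about one fragment).  Reverse-strand fragments
#' are reverse-complemented before insertion.  Per-fragment truth records the
#' source interval, strand and the fragment's interval within the read.
#'
#' @param fragments Sampled fragments from [sample_fragments()].
#' @param genome The `smurf_genome` the fragments come from.
#' @param target_read_len Target read length in bp; must be at least the
#'   longest fragment.
#' @param read_prefix Prefix for generated read identifiers.
#' @return A `smurf_reads` object: `reads` (read_id, sequence) and `truth`
#'   (read_id, frag_index, chrom, start, end, strand, read_start, read_end).
#' @export
concatenate_fragments <- function(fragments, genome, target_read_len,
                                  read_prefix = "read") {
  target_read_len <- assert_count(target_read_len, "target_read_len", min = 1)
  len <- fragments$end - fragments$start
  if (any(len > target_read_len))
    stopf("`target_read_len` must be >= the longest fragment (%d bp)", max(len))
  pk <- cpp_pack(as.integer(len), as.integer(target_read_len))
  frag_seq <- seq_extract(genome$seq[fragments$chrom], fragments$start, fragments$end)
  rev <- fragments$strand == "-"
  if (any(rev)) frag_seq[rev] <- dna_revcomp(frag_seq[rev])
  read_id <- sprintf("%s%06d", read_prefix, pk$read)
  seqs <- vapply(split(frag_seq, pk$read), paste, character(1), collapse = "")
  reads <- data.frame(read_id = sprintf("%s%06d", read_prefix,
                                        as.integer(names(seqs))),
                      sequence = unname(seqs), stringsAsFactors = FALSE)
  truth <- data.frame(
    read_id = read_id,
    frag_index = NA_integer_,
    chrom = fragments$chrom,
    start = fragments$start,
    end = fragments$end,
    strand = fragments$strand,
    read_start = pk$offset,
    read_end = pk$offset + len,
    stringsAsFactors = FALSE
  )
  # frag_index: position of the fragment within its read, in packing order
  truth$frag_index <- stats::ave(seq_len(nrow(truth)), pk$read,
                                 FUN = seq_along)
  new_smurf_reads(reads, truth)
}

#' Apply a nanopore-like error process to simulated reads
#'
#' Per base: deletion with `del_rate`; otherwise the base is emitted,
#' substituted with `sub_rate`, and followed by one inserted random base with
#' `ins_rate`.  Truth intervals are remapped to post-error coordinates, so
#' the fragments still tile each read exactly.  Deterministic given the
#' model's seed.
#'
#' @param reads A `smurf_reads` object.
#' @param model An [error_model()].
#' @return A `smurf_reads` object with mutated sequences and updated truth.
#' @export
apply_errors <- function(reads, model) {
  stopifnot(inherits(reads, "smurf_reads"), inherits(model, "error_model"))
  set.seed(model$seed)
  bases <- c("A", "C", "G", "T")
  seqs <- reads$reads$sequence
  truth <- reads$truth
  truth_by_read <- split(seq_len(nrow(truth)), truth$read_id)
  out_seq <- character(length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    L <- length(chars)
    del <- runif(L) < model$del_rate
    sub <- runif(L) < model$sub_rate & !del
    ins <- runif(L) < model$ins_rate & !del
    if (any(sub)) {
      # substitute to a uniformly chosen different base
      cur <- match(chars[sub], bases)
      shift <- sample.int(3L, sum(sub), replace = TRUE)
      chars[sub] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
    contrib <- as.integer(!del) + as.integer(ins)
    n_ins <- sum(ins)
    out <- character(sum(contrib))
    pos_end <- cumsum(contrib)
    keep <- !del
    out[pos_end[keep] - as.integer(ins[keep])] <- chars[keep]
    if (n_ins > 0)
      out[pos_end[ins]] <- bases[sample.int(4L, n_ins, replace = TRUE)]
    out_seq[i] <- paste(out, collapse = "")
    # remap truth boundaries: new position of old boundary b is the number
    # of output bases emitted for input bases [0, b)
    prefix <- c(0L, pos_end)
    rid <- reads$reads$read_id[i]
    rows <- truth_by_read[[rid]]
    if (!is.null(rows)) {
      truth$read_start[rows] <- prefix[truth$read_start[rows] + 1L]
      truth$read_end[rows] <- prefix[truth$read_end[rows] + 1L]
    }
  }
  new_smurf_reads(data.frame(read_id = reads$reads$read_id, sequence = out_seq,
                             stringsAsFactors = FALSE), truth)
}

#' Splice concatenated reads out of existing long reads
#'
#' Emulates building idealized concatenated-fragment reads from real long
#' reads: random substrings (lengths drawn with replacement from
#' `fragment_lengths`) are cut out of source reads that carry a known
#' reference origin, then packed into reads of about `target_read_len`.
#' Truth is derived from each source read's origin interval, assuming the
#' source read matches its origin base for base (as is the case for
#' error-free simulated sources).
#'
#' @param source_reads data.frame with columns `read_id`, `sequence`,
#'   `chrom`, `start`, `end`, `strand`: long reads with reference origins.
#' @param fragment_lengths Numeric vector of fragment lengths to draw from.
#' @param target_read_len Target output read length (bp).
#' @param n_fragments Number of fragments to cut.
#' @param seed Integer RNG seed.
#' @return A `smurf_reads` object.
#' @export
splice_from_reads <- function(source_reads, fragment_lengths, target_read_len,
                              n_fragments, seed = 1) {
  n_fragments <- assert_count(n_fragments, "n_fragments", min = 1)
  src_len <- nchar(source_reads$sequence)
  fragment_lengths <- as.integer(fragment_lengths)
  if (any(fragment_lengths < 1)) stopf("fragment lengths must be >= 1")
  if (min(fragment_lengths) > max(src_len))
    stopf("every requested fragment length exceeds every source read")
  set.seed(seed)
  lens <- fragment_lengths[sample.int(length(fragment_lengths), n_fragments,
                                      replace = TRUE)]
  ok_any <- lens <= max(src_len)
  if (!all(ok_any)) lens <- lens[ok_any]
  # choose a source read uniformly among those long enough
  src <- integer(length(lens))
  for (i in seq_along(lens)) {
    cand <- which(src_len >= lens[i])
    src[i] <- cand[sample.int(length(cand), 1L)]
  }
  off <- floor(runif(length(lens)) * (src_len[src] - lens + 1L))
  frag_seq <- substring(source_reads$sequence[src], off + 1L, off + lens)
  # origin-derived reference interval of each cut
  s_strand <- source_reads$strand[src]
  ref_start <- ifelse(s_strand == "+",
                      source_reads$start[src] + off,
                      source_reads$end[src] - off - lens)
  frags <- data.frame(chrom = source_reads$chrom[src],
                      start = ref_start, end = ref_start + lens,
                      strand = s_strand, stringsAsFactors = FALSE)
  pk <- cpp_pack(as.integer(lens), as.integer(target_read_len))
  read_id <- sprintf("splice%06d", pk$read)
  seqs <- vapply(split(frag_seq, pk$read), paste, character(1), collapse = "")
  reads <- data.frame(read_id = sprintf("splice%06d", as.integer(names(seqs))),
                      sequence = unname(seqs), stringsAsFactors = FALSE)
  truth <- data.frame(read_id = read_id,
                      frag_index = stats::ave(seq_along(read_id), pk$read,
                                              FUN = seq_along),
                      chrom = frags$chrom, start = frags$start, end = frags$end,
                      strand = frags$strand,
                      read_start = pk$offset, read_end = pk$offset + lens,
                      stringsAsFactors = FALSE)
  new_smurf_reads(reads, truth)
}

#' Simulate a full set of SMURF-seq reads
#'
#' Convenience wrapper: digest the genome, sample `n_fragments` proportional
#' to the planted copy number, concatenate into reads of about
#' `target_read_len`, and (optionally) apply the error model.
#'
#' @param genome A `smurf_genome`.
#' @param truth A `cnv_truth`; defaults to all-neutral.
#' @param enzyme Restriction enzyme (name or object).
#' @param n_fragments Number of fragments to sample.
#' @param target_read_len Target read length (bp).
#' @param model Optional [error_model()]; `NULL` for error-free reads.
#' @param seed Integer RNG seed.
#' @return A `smurf_reads` object.
#' @export
simulate_reads <- function(genome, truth = NULL, enzyme = "SaqAI",
                           n_fragments = 1e5, target_read_len = 6750,
                           model = NULL, seed = 1) {
  if (is.null(truth)) truth <- plant_cnv(genome)
  dig <- digest_genome(genome, enzyme)
  frags <- sample_fragments(dig, truth, n_fragments, seed = seed)
  reads <- concatenate_fragments(frags, genome, target_read_len)
  if (!is.null(model)) reads <- apply_errors(reads, model)
  reads
}
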