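# File formats.  FASTA/FASTQ go through Biostrings; tables are plain TSV
# with 0-based half-open coordinates, except BED (0-based, by its own
# convention) and SAM (1-based, per the SAM specification).

#' Read and write genomes as FASTA
#'
#' Sequences are written wrapped at 70 columns and read back uppercased.
#'
#' @param genome A `smurf_genome`.
#' @param path File path.
#' @return `read_genome_fasta()` returns a `smurf_genome`.
#' @export
write_genome_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(dna, path, width = 70L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  new_smurf_genome(setNames(toupper(as.character(dna)), names(dna)))
}

#' Read and write copy-number truth as BED4
#'
#' Columns: chrom, start, end, copy_number (BED uses 0-based half-open
#' coordinates, matching the package's internal convention).
#'
#' @param truth A `cnv_truth` data.frame.
#' @param path File path.
#' @export
write_truth_bed <- function(truth, path) {
  write.table(truth[, c("chrom", "start", "end", "copy_number")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("chrom", "start", "end", "copy_number"))
  class(df) <- c("cnv_truth", "data.frame")
  df
}

#' Write digest fragments as BED3
#'
#' @param fragments data.frame with `chrom`, `start`, `end`.
#' @param path File path.
#' @export
write_bed3 <- function(fragments, path) {
  write.table(fragments[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write simulated reads
#'
#' FASTA or FASTQ by file extension; FASTQ qualities are a constant
#' placeholder ("I"), since the simulator does not model per-base quality.
#' The per-fragment truth travels separately as TSV
#' ([write_fragment_truth()]).
#'
#' @param reads A `smurf_reads` object.
#' @param path Output path ending in .fa/.fasta or .fq/.fastq.
#' @export
write_reads <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(setNames(reads$reads$sequence,
                                           reads$reads$read_id))
  if (grepl("\\.(fq|fastq)$", path)) {
    qual <- Biostrings::BStringSet(vapply(nchar(reads$reads$sequence),
                                          function(n) strrep("I", n), ""))
    Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  } else {
    Biostrings::writeXStringSet(dna, path, width = 70L)
  }
  invisible(path)
}

#' @rdname write_reads
#' @param truth Optional truth table to attach (from
#'   [read_fragment_truth()]).
#' @export
read_reads <- function(path, truth = NULL) {
  fmt <- if (grepl("\\.(fq|fastq)$", path)) "fastq" else "fasta"
  dna <- Biostrings::readDNAStringSet(path, format = fmt)
  names(dna) <- sub("\\s.*$", "", names(dna))
  reads <- data.frame(read_id = names(dna),
                      sequence = toupper(as.character(dna)),
                      stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  new_smurf_reads(reads, truth)
}

#' Read and write per-fragment truth as TSV
#'
#' Columns: read_id, frag_index, chrom, start, end, strand, read_start,
#' read_end (0-based half-open, read coordinates post-error).
#'
#' @param reads A `smurf_reads` object (or its `truth` component).
#' @param path File path.
#' @export
write_fragment_truth <- function(reads, path) {
  truth <- if (inherits(reads, "smurf_reads")) reads$truth else reads
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_truth
#' @export
read_fragment_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read and write fragment alignments as TSV
#'
#' Columns as in the [map_reads()] output.
#'
#' @param fragments Fragment alignment table.
#' @param path File path.
#' @export
write_fragments_tsv <- function(fragments, path) {
  write.table(fragments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_tsv
#' @export
read_fragments_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write fragment alignments as minimal SAM
#'
#' One alignment line per fragment: the highest-scoring fragment of each
#' read is primary, the rest are supplementary (flag 2048); reverse-strand
#' fragments carry flag 16 and reverse-complemented sequence, per the SAM
#' convention.  Unaligned read parts appear as soft clips.  Mapping quality
#' is 60 for unique fragments and 0 otherwise.
#'
#' @param fragments [map_reads()] output (needs the `cigar` column).
#' @param reads The reads that were mapped.
#' @param genome The reference genome (for header `@SQ` lines).
#' @param path File path.
#' @export
write_sam <- function(fragments, reads, genome, path) {
  seqs <- reads_as_character(reads)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(genome$seq))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome$seq)[i],
                       nchar(genome$seq[[i]])), con)
  if (nrow(fragments) == 0) return(invisible(path))
  # exactly one primary per read: the first fragment attaining the max score
  is_primary <- rep(FALSE, nrow(fragments))
  for (id in unique(fragments$read_id)) {
    rows <- which(fragments$read_id == id)
    is_primary[rows[which.max(fragments$score[rows])]] <- TRUE
  }
  for (i in seq_len(nrow(fragments))) {
    f <- fragments[i, ]
    flag <- 0L
    if (f$strand == "-") flag <- flag + 16L
    if (!is_primary[i]) flag <- flag + 2048L
    rd <- seqs[[f$read_id]]
    n <- nchar(rd)
    sub <- seq_extract(rd, f$read_start, f$read_end)
    lead <- f$read_start; trail <- n - f$read_end
    if (f$strand == "-") {
      sub <- dna_revcomp(sub)
      tmp <- lead; lead <- trail; trail <- tmp
    }
    cig <- paste0(if (lead > 0) paste0(lead, "S") else "", f$cigar,
                  if (trail > 0) paste0(trail, "S") else "")
    writeLines(paste(f$read_id, flag, f$chrom, f$ref_start + 1L,
                     if (isTRUE(f$is_unique)) 60L else 0L, cig, "*", 0L, 0L,
                     sub, "*", paste0("AS:i:", f$score), sep = "\t"), con)
  }
  invisible(path)
}

#' Read fragment alignments from a SAM file
#'
#' Minimal SAM text parser for ingesting externally produced split
#' alignments: header lines are skipped, unmapped records dropped, and each
#' alignment line becomes one fragment.  Read coordinates are recovered
#' from soft/hard clips and the CIGAR; `is_unique` is `MAPQ > 0`, following
#' the common uniquely-mapped convention.
#'
#' @param path SAM file path.
#' @return data.frame in [map_reads()] output format (without scores when
#'   the AS tag is absent).
#' @export
read_sam_fragments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0) next # unmapped
    cigar <- f[6]
    if (cigar == "*") next
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    len <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("[0-9]+", "", ops)
    ref_span <- sum(len[op %in% c("M", "D", "N", "=", "X")])
    q_span <- sum(len[op %in% c("M", "I", "=", "X")])
    lead <- if (op[1] %in% c("S", "H")) len[1] else 0L
    trail <- if (op[length(op)] %in% c("S", "H")) len[length(op)] else 0L
    total <- lead + q_span + trail
    rev <- bitwAnd(flag, 16L) > 0
    read_start <- if (rev) trail else lead
    score <- NA_integer_
    as_tag <- grep("^AS:i:", f[-(1:11)], value = TRUE)
    if (length(as_tag)) score <- as.integer(sub("AS:i:", "", as_tag[1]))
    out[[length(out) + 1]] <- data.frame(
      read_id = f[1], read_start = read_start,
      read_end = read_start + q_span, chrom = f[3],
      ref_start = as.numeric(f[4]) - 1, ref_end = as.numeric(f[4]) - 1 + ref_span,
      strand = if (rev) "-" else "+", score = score,
      is_unique = as.integer(f[5]) > 0,
      cigar = paste0(ops[op %in% c("M", "I", "D", "=", "X")], collapse = ""),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(read_id = character(), read_start = integer(),
                      read_end = integer(), chrom = character(),
                      ref_start = numeric(), ref_end = numeric(),
                      strand = character(), score = integer(),
                      is_unique = logical(), cigar = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write profile tables
#'
#' Bins as a BED-like TSV with all per-bin columns; segments as a SEG-like
#' TSV; events as BED4 (state in the fourth column, unmasked non-neutral
#' bins only).
#'
#' @param profile A `smurf_profile`.
#' @param prefix Output path prefix; writes `<prefix>.bins.tsv`,
#'   `<prefix>.segments.tsv` and `<prefix>.events.bed`.
#' @export
write_profile <- function(profile, prefix) {
  write.table(profile$bins, paste0(prefix, ".bins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(profile$segments[, c("chrom", "start", "end", "n_bins", "mean_ratio")],
              paste0(prefix, ".segments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ev <- profile$bins[!profile$bins$masked & profile$bins$state != "neutral", ]
  write.table(ev[, c("chrom", "start", "end", "state")],
              paste0(prefix, ".events.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
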