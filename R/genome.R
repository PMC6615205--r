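# Synthetic reference genomes, planted copy-number truth and in-silico
# restriction digestion.

#' Generate a synthetic multi-chromosome reference genome
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc`, split evenly between G and
#' C (and between A and T).  With `gc_gradient = c(lo, hi)` the GC fraction
#' instead varies linearly from `lo` at the start to `hi` at the end of every
#' chromosome, which is useful for exercising GC-bias correction.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (>= 10 kb).
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param seed Integer RNG seed; the same seed reproduces the same genome.
#' @param gc_gradient Optional numeric of length 2 overriding `gc` with a
#'   linear GC gradient along each chromosome.
#' @return A `smurf_genome`: list with `seq` (named uppercase character
#'   vector of chromosome sequences) and `seed`.
#' @examples
#' g <- generate_genome(1, 2e4, gc = 0.5, seed = 7)
#' nchar(g$seq)
#' @export
generate_genome <- function(n_chroms, chrom_length, gc = 0.5, seed = 1,
                            gc_gradient = NULL) {
  n_chroms <- assert_count(n_chroms, "n_chroms", min = 1)
  chrom_length <- assert_count(chrom_length, "chrom_length")
  if (chrom_length < 1e4) stopf("`chrom_length` must be >= 10 kb")
  assert_fraction(gc, "gc")
  if (!is.null(gc_gradient)) {
    if (length(gc_gradient) != 2 || any(gc_gradient <= 0) || any(gc_gradient >= 1))
      stopf("`gc_gradient` must be two fractions in (0,1)")
  }
  set.seed(seed)
  seqs <- character(n_chroms)
  for (c in seq_len(n_chroms)) {
    if (is.null(gc_gradient)) {
      p_gc <- rep.int(gc, chrom_length)
    } else {
      p_gc <- seq(gc_gradient[1], gc_gradient[2], length.out = chrom_length)
    }
    is_gc <- runif(chrom_length) < p_gc
    pick <- runif(chrom_length) < 0.5
    base <- ifelse(is_gc, ifelse(pick, "G", "C"), ifelse(pick, "A", "T"))
    seqs[c] <- paste(base, collapse = "")
  }
  names(seqs) <- paste0("chr", seq_len(n_chroms))
  new_smurf_genome(seqs, seed = seed)
}

new_smurf_genome <- function(seqs, seed = NA_integer_) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stopf("chromosome names must be present and unique")
  if (any(nchar(seqs) == 0)) stopf("chromosome lengths must be > 0")
  structure(list(seq = seqs, seed = seed), class = "smurf_genome")
}

#' @export
print.smurf_genome <- function(x, ...) {
  cat(sprintf("smurf_genome: %d chromosome(s), %s bp total\n",
              length(x$seq), format(sum(nchar(x$seq)), big.mark = ",")))
  invisible(x)
}

genome_lengths <- function(genome) setNames(nchar(genome$seq), names(genome$seq))

#' Restriction enzymes
#'
#' `restriction_enzyme()` defines an enzyme by its recognition site and the
#' cut position within the site on the forward strand (0 <= offset <=
#' nchar(site)).  `enzymes()` lists the built-ins: SaqAI (T^TAA) and Hin1II
#' (CATG^).  Both built-in sites are palindromic, so forward-strand scanning
#' finds every cut; enzymes with non-palindromic sites would need
#' double-strand scanning, which is not supported.
#'
#' @param name Enzyme name.
#' @param site Recognition site, characters A/C/G/T only.
#' @param cut_offset Cut position within the site on the forward strand.
#' @return A `restriction_enzyme` object.
#' @examples
#' enzymes()$SaqAI
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (!nzchar(site) || grepl("[^ACGT]", site))
    stopf("recognition site must be a non-empty string over A/C/G/T")
  cut_offset <- assert_count(cut_offset, "cut_offset")
  if (cut_offset > nchar(site))
    stopf("`cut_offset` must be between 0 and nchar(site)")
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @rdname restriction_enzyme
#' @export
enzymes <- function() {
  list(
    SaqAI  = restriction_enzyme("SaqAI", "TTAA", 1L),
    Hin1II = restriction_enzyme("Hin1II", "CATG", 4L)
  )
}

resolve_enzyme <- function(enzyme) {
  if (inherits(enzyme, "restriction_enzyme")) return(enzyme)
  if (is.character(enzyme) && length(enzyme) == 1L) {
    hit <- enzymes()[[enzyme]]
    if (!is.null(hit)) return(hit)
    stopf("unknown enzyme '%s'; use restriction_enzyme() to define it", enzyme)
  }
  stopf("`enzyme` must be an enzyme name or a restriction_enzyme object")
}

#' In-silico restriction digestion
#'
#' Scans the forward strand of every chromosome for exact occurrences of the
#' recognition site (overlapping occurrences included; sites containing N in
#' the genome never match) and cuts at `site_start + cut_offset`.  Fragments
#' are the half-open intervals between consecutive cuts, including the two
#' chromosome-end pieces; a site-free chromosome yields one fragment spanning
#' the whole chromosome.
#'
#' @param genome A `smurf_genome`.
#' @param enzyme A `restriction_enzyme` or a built-in enzyme name.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @examples
#' g <- generate_genome(1, 1e4 * 5, gc = 0.5, seed = 1)
#' frags <- digest_genome(g, "SaqAI")
#' head(frags)
#' @export
digest_genome <- function(genome, enzyme) {
  enzyme <- resolve_enzyme(enzyme)
  out <- vector("list", length(genome$seq))
  for (i in seq_along(genome$seq)) {
    chrom <- names(genome$seq)[i]
    len <- nchar(genome$seq[[i]])
    m <- Biostrings::matchPattern(enzyme$site,
                                  Biostrings::DNAString(genome$seq[[i]]))
    cuts <- sort(unique(Biostrings::start(m) - 1L + enzyme$cut_offset))
    cuts <- cuts[cuts > 0L & cuts < len]
    bounds <- c(0L, cuts, len)
    out[[i]] <- data.frame(chrom = chrom,
                           start = bounds[-length(bounds)],
                           end = bounds[-1L],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fragment length statistics
#'
#' Arithmetic mean, median and a 1-bp-resolution histogram of digest fragment
#' lengths, pooled across chromosomes.  Chromosome-end fragments are
#' included: genome-wide they are a negligible fraction of all inter-site
#' distances.
#'
#' @param fragments data.frame with `start` and `end` columns (0-based
#'   half-open), as returned by [digest_genome()].
#' @return list with `mean`, `median`, `n` and `histogram` (data.frame of
#'   `length` and `count`).
#' @export
fragment_length_stats <- function(fragments) {
  if (is.null(fragments) || nrow(fragments) == 0)
    stopf("no fragments: empty input")
  len <- fragments$end - fragments$start
  tab <- table(len)
  list(mean = mean(len), median = median(len), n = length(len),
       histogram = data.frame(length = as.integer(names(tab)),
                              count = as.integer(tab)))
}

#' Plant a copy-number truth profile on a genome
#'
#' Validates user segments (within bounds, non-overlapping, start < end,
#' integer copy number >= 0), fills unspecified regions with copy number 2
#' (diploid neutral) and merges abutting segments of equal copy number, so
#' the returned truth covers every chromosome exactly.
#'
#' @param genome A `smurf_genome`.
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `copy_number`; may be `NULL` or empty for an all-neutral genome.
#' @return A `cnv_truth` data.frame covering the genome.
#' @examples
#' g <- generate_genome(1, 1e4, gc = 0.5, seed = 1)
#' plant_cnv(g, data.frame(chrom = "chr1", start = 2000, end = 4000,
#'                         copy_number = 4))
#' @export
plant_cnv <- function(genome, segments = NULL) {
  lens <- genome_lengths(genome)
  if (is.null(segments) || nrow(segments) == 0) {
    segments <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), copy_number = numeric())
  }
  need <- c("chrom", "start", "end", "copy_number")
  if (!all(need %in% names(segments)))
    stopf("segments need columns: %s", paste(need, collapse = ", "))
  bad <- character()
  seg_str <- function(s) sprintf("%s:%g-%g", s$chrom, s$start, s$end)
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    if (!s$chrom %in% names(lens)) bad <- c(bad, paste(seg_str(s), "unknown chromosome"))
    else if (s$start < 0 || s$end > lens[[s$chrom]]) bad <- c(bad, paste(seg_str(s), "out of bounds"))
    if (s$start >= s$end) bad <- c(bad, paste(seg_str(s), "start >= end"))
    if (s$copy_number < 0 || s$copy_number != round(s$copy_number))
      bad <- c(bad, paste(seg_str(s), "copy_number must be a non-negative integer"))
  }
  # overlap check per chromosome
  for (ch in unique(segments$chrom)) {
    sub <- segments[segments$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) {
      ov <- which(sub$start[-1] < sub$end[-nrow(sub)])
      for (i in ov) bad <- c(bad, sprintf("%s overlaps %s", seg_str(sub[i + 1, ]),
                                          seg_str(sub[i, ])))
    }
  }
  if (length(bad)) stopf("invalid truth segments:\n  %s", paste(bad, collapse = "\n  "))

  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    ch <- names(lens)[i]
    sub <- segments[segments$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    # fill gaps with CN 2
    pieces <- list()
    at <- 0
    for (j in seq_len(nrow(sub))) {
      if (sub$start[j] > at)
        pieces[[length(pieces) + 1]] <- data.frame(chrom = ch, start = at,
                                                   end = sub$start[j], copy_number = 2)
      pieces[[length(pieces) + 1]] <- sub[j, need]
      at <- sub$end[j]
    }
    if (at < lens[i])
      pieces[[length(pieces) + 1]] <- data.frame(chrom = ch, start = at,
                                                 end = lens[[i]], copy_number = 2)
    chrom_df <- do.call(rbind, pieces)
    # merge abutting equal copy numbers
    keep <- c(TRUE, chrom_df$copy_number[-1] != chrom_df$copy_number[-nrow(chrom_df)])
    grp <- cumsum(keep)
    merged <- data.frame(
      chrom = ch,
      start = tapply(chrom_df$start, grp, min),
      end = tapply(chrom_df$end, grp, max),
      copy_number = tapply(chrom_df$copy_number, grp, `[`, 1)
    )
    rownames(merged) <- NULL
    out[[i]] <- merged
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$start <- as.numeric(res$start)
  res$end <- as.numeric(res$end)
  res$copy_number <- as.numeric(res$copy_number)
  class(res) <- c("cnv_truth", "data.frame")
  res
}

# Copy number of the truth profile at given (chrom, pos) pairs.
copy_number_at <- function(truth, chrom, pos) {
  cn <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    sub <- truth[truth$chrom == ch, ]
    sel <- chrom == ch
    idx <- findInterval(pos[sel], sub$start)
    idx[idx < 1 | pos[sel] >= max(sub$end)] <- NA
    cn[sel] <- sub$copy_number[idx]
  }
  cn
}
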