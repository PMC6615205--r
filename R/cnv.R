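# Read-count CNV profiling: variable-width bins holding equal numbers of
# uniquely mappable positions, bad-bin masking, LOWESS GC correction,
# circular binary segmentation with permutation p-values, spurious-segment
# removal and amplification/deletion event calling.

#' Per-position unique mappability
#'
#' A position is uniquely mappable iff the `probe_len`-mer starting there
#' occurs exactly once in the genome, counting both strands, and contains no
#' N.  Positions within `probe_len - 1` of a chromosome end are not
#' mappable (no full probe starts there).
#'
#' @param genome A `smurf_genome`.
#' @param probe_len Probe length in bp (20-64).
#' @return Named list of logical vectors, one per chromosome, each of the
#'   chromosome's length.
#' @export
compute_mappability <- function(genome, probe_len = 40) {
  probe_len <- assert_count(probe_len, "probe_len", min = 20)
  if (probe_len > min(nchar(genome$seq)))
    stopf("`probe_len` exceeds the shortest chromosome")
  res <- cpp_unique_positions(unname(genome$seq), probe_len)
  names(res) <- names(genome$seq)
  res
}

#' Split a genome into bins of equal unique mappability
#'
#' Greedy sweep in genome order: a bin closes when it has accumulated
#' `ceiling(total_mappable / n_bins)` mappable positions.  Bins never cross
#' chromosome boundaries; the last bin of each chromosome absorbs the
#' remainder and is masked from the start when its mappable count deviates
#' more than 10% from the target.  GC content is computed over each bin's
#' full physical span.
#'
#' @param genome A `smurf_genome`.
#' @param mappability Output of [compute_mappability()] (or any list of
#'   per-position logical vectors, e.g. all-`TRUE` for an idealized genome).
#' @param n_bins Requested number of bins (>= number of chromosomes).
#' @return data.frame of bins: `chrom`, `start`, `end`, `n_mappable`, `gc`,
#'   `raw_count`, `corrected_count`, `ratio`, `masked`.
#' @export
make_bins <- function(genome, mappability, n_bins) {
  n_bins <- assert_count(n_bins, "n_bins", min = 1)
  if (n_bins < length(genome$seq))
    stopf("`n_bins` must be at least the number of chromosomes")
  total <- sum(vapply(mappability, sum, numeric(1)))
  if (total < n_bins)
    stopf("fewer mappable positions (%d) than requested bins", total)
  target <- ceiling(total / n_bins)
  out <- vector("list", length(genome$seq))
  for (i in seq_along(genome$seq)) {
    ch <- names(genome$seq)[i]
    m <- mappability[[ch]]
    len <- length(m)
    cum <- cumsum(m)
    chrom_total <- cum[len]
    n_full <- chrom_total %/% target
    if (n_full == 0) {
      starts <- 0L; ends <- len
      n_map <- chrom_total
    } else {
      # end of bin j = first position where cum reaches j * target
      cuts <- findInterval(seq_len(n_full) * target - 0.5, cum) + 1L
      starts <- c(0L, cuts[-n_full])
      ends <- cuts
      n_map <- rep.int(target, n_full)
      # last bin absorbs the remainder
      n_map[n_full] <- chrom_total - (n_full - 1L) * target
      ends[n_full] <- len
    }
    out[[i]] <- data.frame(chrom = ch, start = starts, end = ends,
                           n_mappable = n_map, stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, out)
  spans <- seq_extract(genome$seq[bins$chrom], bins$start, bins$end)
  bins$gc <- gc_fraction(spans)
  bins$raw_count <- NA_real_
  bins$corrected_count <- NA_real_
  bins$ratio <- NA_real_
  bins$masked <- abs(bins$n_mappable - target) > 0.1 * target
  rownames(bins) <- NULL
  bins
}

#' Count uniquely mapped fragments per bin
#'
#' Only fragments with `is_unique = TRUE` are counted (multi-mapped
#' fragments carry no reliable location).  A fragment is assigned to the
#' bin whose half-open interval contains its reference midpoint, so long
#' fragments straddling a boundary are counted exactly once.  Masked bins
#' are still counted; masking is applied downstream.
#'
#' @param bins Bin table from [make_bins()].
#' @param fragments Fragment alignments with `chrom`, `ref_start`,
#'   `ref_end` and optionally `is_unique` (assumed `TRUE` when absent).
#' @return `bins` with `raw_count` filled in.
#' @export
count_fragments <- function(bins, fragments) {
  if (!is.null(fragments$is_unique))
    fragments <- fragments[fragments$is_unique, , drop = FALSE]
  bins$raw_count <- 0
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    f <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0) next
    mid <- (f$ref_start + f$ref_end) %/% 2
    if (any(mid < 0 | mid >= max(b$end)))
      stopf("fragment midpoint outside genome bounds on %s", ch)
    idx <- findInterval(mid, b$start)
    tab <- tabulate(idx, nbins = nrow(b))
    bins$raw_count[bins$chrom == ch] <- tab
  }
  bad <- !fragments$chrom %in% bins$chrom
  if (any(bad)) stopf("fragments on chromosomes absent from the bin table")
  bins
}

#' Mask bins with spuriously high counts
#'
#' Iterative upper-outlier masking: bins whose raw count exceeds
#' `median + z_cutoff * MAD` of the currently unmasked bins *and* exceeds
#' `min_fold` times their median are masked, and the rule is re-applied
#' until no further bin is masked.  This targets the count spikes that, on
#' real genomes, concentrate near centromeres and telomeres.  The
#' multiplicative guard matters at high depth, where the MAD of the counts
#' is small relative to genuine copy-number signal: without it, ordinary
#' 2x amplifications would be masked as artifacts.  Lowered counts are
#' left alone (they carry deletion signal).
#'
#' @param bins Bin table with `raw_count` filled in.
#' @param z_cutoff Robust z-score cutoff (default 5).
#' @param min_fold Only bins above `min_fold * median` are maskable
#'   (default 3).
#' @return `bins` with updated `masked` flags.
#' @export
mask_bad_bins <- function(bins, z_cutoff = 5, min_fold = 3) {
  if (nrow(bins) < 30) stopf("need at least 30 bins to estimate outliers")
  repeat {
    ok <- !bins$masked
    if (!any(ok)) stopf("all bins masked")
    med <- median(bins$raw_count[ok])
    dev <- mad(bins$raw_count[ok])
    hit <- ok & bins$raw_count > med + z_cutoff * dev &
      bins$raw_count > min_fold * med
    if (!any(hit)) break
    bins$masked[hit] <- TRUE
  }
  if (all(bins$masked)) stopf("all bins masked")
  bins
}

#' LOWESS GC-bias correction of bin counts
#'
#' Fits a LOWESS curve (locally weighted linear regression, tricube
#' weights, `iters` robustness iterations) of raw count on GC fraction over
#' the unmasked bins, and subtracts the fitted value from each count,
#' re-centering at the grand mean and flooring at zero.  Masked bins keep
#' their raw count.  If GC is constant across bins the correction is the
#' identity (with a warning).
#'
#' @param bins Bin table with `raw_count` filled in.
#' @param span LOWESS span (fraction of points in each local fit).
#' @param iters Robustness iterations.
#' @return `bins` with `corrected_count` filled in.
#' @export
gc_correct <- function(bins, span = 0.3, iters = 3) {
  ok <- !bins$masked
  if (sum(ok) < 50) stopf("need at least 50 unmasked bins for GC correction")
  if (any(bins$raw_count[ok] < 0)) stopf("negative counts")
  gc <- bins$gc[ok]; raw <- bins$raw_count[ok]
  bins$corrected_count <- bins$raw_count
  if (length(unique(gc)) < 2) {
    warning("GC content constant across bins; correction is the identity")
    return(bins)
  }
  lw <- lowess(gc, raw, f = span, iter = iters)
  fitted <- numeric(length(gc))
  fitted[order(gc)] <- lw$y
  bins$corrected_count[ok] <- pmax(0, raw - fitted + mean(raw))
  bins
}

#' Bin ratios to the unmasked mean
#'
#' `ratio = corrected_count / mean(corrected_count over unmasked bins)`, so
#' the unmasked ratios average exactly 1; masked bins get `NA`.
#'
#' @param bins Bin table with `corrected_count` filled in.
#' @return `bins` with `ratio` filled in.
#' @export
bin_ratios <- function(bins) {
  ok <- !bins$masked
  denom <- mean(bins$corrected_count[ok])
  if (!is.finite(denom) || denom <= 0) stopf("non-positive mean corrected count")
  bins$ratio <- ifelse(ok, bins$corrected_count / denom, NA_real_)
  bins
}

#' Circular binary segmentation of an ordered ratio sequence
#'
#' Recursive changepoint search: for the current segment, the arc (i, j]
#' of the circularized sequence maximizing the two-sample statistic
#' `|mean(arc) - mean(rest)| / (s * sqrt(1/k + 1/(n-k)))` is tested by
#' permutation (p-value `(1 + #exceed) / (n_perm + 1)`); if p < `alpha` the
#' segment splits into up to three children, which are searched
#' recursively.  Deterministic given `seed`.
#'
#' @param x Numeric vector of ordered (unmasked) bin ratios for one
#'   chromosome.
#' @param alpha Split significance level in (0, 1).
#' @param n_perm Number of permutations.
#' @param seed Integer RNG seed for the permutations.
#' @return data.frame of segments: `first`, `last` (1-based inclusive
#'   indices into `x`), `n_bins`, `mean_ratio`.
#' @export
segment_cbs <- function(x, alpha = 0.01, n_perm = 1000, seed = 1) {
  assert_fraction(alpha, "alpha")
  n <- length(x)
  if (n < 2)
    return(data.frame(first = if (n) 1L else integer(), last = if (n) 1L else integer(),
                      n_bins = if (n) 1L else integer(),
                      mean_ratio = if (n) mean(x) else numeric()))
  bounds <- cpp_cbs(as.numeric(x), alpha, as.integer(n_perm), as.integer(seed))
  first <- c(1L, bounds + 1L)
  last <- c(bounds, n)
  data.frame(first = first, last = last, n_bins = last - first + 1L,
             mean_ratio = vapply(seq_along(first),
                                 function(i) mean(x[first[i]:last[i]]),
                                 numeric(1)))
}

#' Remove spurious segments
#'
#' Iteratively merges any segment shorter than `min_bins`, or whose mean
#' differs from an adjacent segment's mean by less than `min_delta`, into
#' the neighbor with the closer mean; means are recomputed and the rule is
#' re-applied to a fixed point.  A single remaining segment is never
#' merged further, so termination is guaranteed.
#'
#' @param segments Segment table from [segment_cbs()].
#' @param x The ratio vector the segments were fit on.
#' @param min_bins Minimum segment length in bins.
#' @param min_delta Minimum mean difference from neighbors.
#' @return Filtered segment table in the same format.
#' @export
remove_spurious_segments <- function(segments, x, min_bins = 5, min_delta = 0.1) {
  seg <- segments
  repeat {
    if (nrow(seg) <= 1) break
    viol <- NA_integer_
    for (i in seq_len(nrow(seg))) {
      short <- seg$n_bins[i] < min_bins
      d_prev <- if (i > 1) abs(seg$mean_ratio[i] - seg$mean_ratio[i - 1]) else Inf
      d_next <- if (i < nrow(seg)) abs(seg$mean_ratio[i] - seg$mean_ratio[i + 1]) else Inf
      if (short || min(d_prev, d_next) < min_delta) { viol <- i; break }
    }
    if (is.na(viol)) break
    i <- viol
    d_prev <- if (i > 1) abs(seg$mean_ratio[i] - seg$mean_ratio[i - 1]) else Inf
    d_next <- if (i < nrow(seg)) abs(seg$mean_ratio[i] - seg$mean_ratio[i + 1]) else Inf
    into <- if (d_prev <= d_next) i - 1L else i + 1L
    a <- min(i, into); b <- max(i, into)
    seg$last[a] <- seg$last[b]
    seg <- seg[-b, , drop = FALSE]
    seg$n_bins <- seg$last - seg$first + 1L
    seg$mean_ratio <- vapply(seq_len(nrow(seg)),
                             function(j) mean(x[seg$first[j]:seg$last[j]]),
                             numeric(1))
    rownames(seg) <- NULL
  }
  seg
}

#' Call amplification / deletion events per bin
#'
#' A bin's state is determined solely by its segment's mean ratio:
#' `amplified` when the mean is at or above `amp_cutoff`, `deleted` at or
#' below `del_cutoff`, otherwise `neutral` (boundaries inclusive).  Masked
#' bins get `NA`.
#'
#' @param bins Bin table.
#' @param segments Genome-level segment table with `chrom`, `first_bin`,
#'   `last_bin` (row indices into `bins`) and `mean_ratio`.
#' @param amp_cutoff,del_cutoff Segment-mean cutoffs; `amp_cutoff` must
#'   exceed `del_cutoff`, both positive.
#' @return `bins` with a `state` column.
#' @export
call_events <- function(bins, segments, amp_cutoff = 1.25, del_cutoff = 0.8) {
  if (!(amp_cutoff > del_cutoff && del_cutoff > 0))
    stopf("need amp_cutoff > del_cutoff > 0")
  state <- rep(NA_character_, nrow(bins))
  for (i in seq_len(nrow(segments))) {
    rows <- segments$first_bin[i]:segments$last_bin[i]
    s <- if (segments$mean_ratio[i] >= amp_cutoff) "amplified"
         else if (segments$mean_ratio[i] <= del_cutoff) "deleted"
         else "neutral"
    state[rows] <- s
  }
  state[bins$masked] <- NA_character_
  if (any(is.na(state) & !bins$masked))
    stopf("some unmasked bins are not covered by any segment")
  bins$state <- state
  bins
}

#' Full copy-number profile from mapped fragments
#'
#' Composition of the pipeline stages: mappability bins, fragment counting
#' (unique fragments, midpoint assignment), bad-bin masking, LOWESS GC
#' correction, normalization to the unmasked mean, per-chromosome circular
#' binary segmentation, spurious-segment removal and event calling.
#'
#' @param genome A `smurf_genome`.
#' @param fragments Fragment alignments ([map_reads()] output, simulator
#'   truth converted with [truth_as_alignments()], or [read_fragments_tsv()]).
#' @param n_bins Number of bins across the genome.
#' @param mappability Optional precomputed [compute_mappability()] result.
#' @param probe_len Probe length for mappability when not precomputed.
#' @param z_cutoff Bad-bin robust z cutoff.
#' @param min_fold Bad-bin multiplicative floor (see [mask_bad_bins()]).
#' @param span,iters LOWESS span and robustness iterations.
#' @param alpha,n_perm CBS significance level and permutation count.
#' @param min_seg_bins,min_seg_delta Spurious-segment thresholds.
#' @param amp_cutoff,del_cutoff Event-calling cutoffs on segment means.
#' @param seed Integer RNG seed (CBS permutations).
#' @return A `smurf_profile`: list with `bins` (including per-bin `state`),
#'   `segments` (`chrom`, `start`, `end`, `first_bin`, `last_bin`,
#'   `n_bins`, `mean_ratio`) and `params`.
#' @export
cnv_profile <- function(genome, fragments, n_bins,
                        mappability = NULL, probe_len = 40,
                        z_cutoff = 5, min_fold = 3, span = 0.3, iters = 3,
                        alpha = 0.01, n_perm = 1000,
                        min_seg_bins = 5, min_seg_delta = 0.1,
                        amp_cutoff = 1.25, del_cutoff = 0.8, seed = 1) {
  if (is.null(mappability)) mappability <- compute_mappability(genome, probe_len)
  bins <- make_bins(genome, mappability, n_bins)
  bins <- count_fragments(bins, fragments)
  bins <- mask_bad_bins(bins, z_cutoff, min_fold)
  bins <- gc_correct(bins, span, iters)
  bins <- bin_ratios(bins)

  seg_all <- list()
  for (ch in unique(bins$chrom)) {
    un <- which(bins$chrom == ch & !bins$masked)
    if (length(un) == 0) next
    x <- bins$ratio[un]
    seg <- segment_cbs(x, alpha = alpha, n_perm = n_perm, seed = seed)
    seg <- remove_spurious_segments(seg, x, min_bins = min_seg_bins,
                                    min_delta = min_seg_delta)
    seg_all[[ch]] <- data.frame(
      chrom = ch,
      start = bins$start[un[seg$first]],
      end = bins$end[un[seg$last]],
      first_bin = un[seg$first], last_bin = un[seg$last],
      n_bins = seg$n_bins, mean_ratio = seg$mean_ratio,
      stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_all)
  rownames(segments) <- NULL
  bins <- call_events(bins, segments, amp_cutoff, del_cutoff)
  structure(list(bins = bins, segments = segments,
                 params = list(n_bins = n_bins, probe_len = probe_len,
                               z_cutoff = z_cutoff, span = span, iters = iters,
                               alpha = alpha, n_perm = n_perm,
                               min_seg_bins = min_seg_bins,
                               min_seg_delta = min_seg_delta,
                               amp_cutoff = amp_cutoff,
                               del_cutoff = del_cutoff, seed = seed)),
            class = "smurf_profile")
}

#' Treat simulator truth fragments as perfect alignments
#'
#' Converts a sampled-fragment table or a `smurf_reads` truth table into
#' the fragment-alignment format consumed by [count_fragments()] and
#' [cnv_profile()], with every fragment flagged unique.  Useful for
#' profiling directly from simulation truth, bypassing the mapper.
#'
#' @param truth A `smurf_reads` object, its `truth` component, or a
#'   sampled-fragment table with `chrom`, `start`, `end`, `strand`.
#' @return data.frame in [map_reads()] output format.
#' @export
truth_as_alignments <- function(truth) {
  if (inherits(truth, "smurf_reads")) truth <- truth$truth
  data.frame(read_id = truth$read_id %||% sprintf("frag%07d", seq_len(nrow(truth))),
             read_start = truth$read_start %||% 0L,
             read_end = truth$read_end %||% (truth$end - truth$start),
             chrom = truth$chrom, ref_start = truth$start, ref_end = truth$end,
             strand = truth$strand, score = NA_integer_, is_unique = TRUE,
             cigar = NA_character_, stringsAsFactors = FALSE)
}

#' @export
print.smurf_profile <- function(x, ...) {
  st <- table(factor(x$bins$state, levels = c("deleted", "neutral", "amplified")))
  cat(sprintf(paste0(
    "smurf_profile: %d bins (%d masked), %d segments\n",
    "  deleted %d  neutral %d  amplified %d\n"),
    nrow(x$bins), sum(x$bins$masked), nrow(x$segments),
    st[["deleted"]], st[["neutral"]], st[["amplified"]]))
  invisible(x)
}

#' Plot a copy-number profile
#'
#' Bin ratios as points in genome order with the segmented means overlaid
#' as horizontal line segments; chromosome boundaries are marked.
#'
#' @param x A `smurf_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.smurf_profile <- function(x, ...) {
  bins <- x$bins
  idx <- seq_len(nrow(bins))
  graphics::plot(idx, bins$ratio, pch = 16, cex = 0.4, col = "steelblue",
                 xlab = "bin (genome order)", ylab = "bin ratio to mean", ...)
  bnd <- cumsum(table(factor(bins$chrom, levels = unique(bins$chrom))))
  graphics::abline(v = utils::head(bnd, -1) + 0.5, col = "grey70", lty = 2)
  for (i in seq_len(nrow(x$segments)))
    graphics::segments(x$segments$first_bin[i], x$segments$mean_ratio[i],
                       x$segments$last_bin[i], x$segments$mean_ratio[i],
                       col = "red", lwd = 2)
  invisible(x)
}
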