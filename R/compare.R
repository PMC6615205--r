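# Comparison of two CNV profiles over the same bin universe: bin-ratio
# correlation, event-level precision/recall with a full confusion table,
# and read-granularity downsampling.

same_bins <- function(a, b) {
  identical(a$bins$chrom, b$bins$chrom) &&
    identical(a$bins$start, b$bins$start) &&
    identical(a$bins$end, b$bins$end)
}

#' Pearson correlation of paired bin ratios
#'
#' Bins masked in either profile are excluded pairwise; the correlation is
#' computed over the remaining paired ratios.
#'
#' @param profile_a,profile_b Two `smurf_profile`s over identical bins.
#' @return list with `pearson_r`, `n_bins` and `pairs` (the paired ratio
#'   table, for plotting).
#' @export
correlate_profiles <- function(profile_a, profile_b) {
  if (!same_bins(profile_a, profile_b))
    stopf("profiles use different bin definitions")
  ok <- !profile_a$bins$masked & !profile_b$bins$masked
  if (sum(ok) < 10) stopf("fewer than 10 shared unmasked bins")
  pairs <- data.frame(ratio_a = profile_a$bins$ratio[ok],
                      ratio_b = profile_b$bins$ratio[ok])
  list(pearson_r = cor(pairs$ratio_a, pairs$ratio_b),
       n_bins = nrow(pairs), pairs = pairs)
}

#' Event-level agreement of two profiles
#'
#' An event is a non-neutral bin state.  By default a test event counts as
#' a true positive only when the reference bin has the same non-neutral
#' state (an amplification called where the reference is deleted is both a
#' false positive and a missed reference event); `ignore_direction = TRUE`
#' relaxes this to any non-neutral agreement.  Bins masked in either
#' profile are excluded.
#'
#' @param ref,test `smurf_profile`s (or their `bins` tables with `state`)
#'   over identical bins; `ref` supplies the ground-truth calls.
#' @param ignore_direction Count any non-neutral overlap as agreement.
#' @return A `comparison_report` list: `event_precision`, `event_recall`,
#'   `n_events_ref`, `n_events_test`, `n_matched` and `confusion` (3x3
#'   table, reference states in rows).
#' @export
compare_events <- function(ref, test, ignore_direction = FALSE) {
  bref <- if (inherits(ref, "smurf_profile")) ref$bins else ref
  btst <- if (inherits(test, "smurf_profile")) test$bins else test
  if (!identical(bref$chrom, btst$chrom) || !identical(bref$start, btst$start))
    stopf("profiles use different bin definitions")
  ok <- !bref$masked & !btst$masked
  lev <- c("amplified", "neutral", "deleted")
  rs <- factor(bref$state[ok], levels = lev)
  ts <- factor(btst$state[ok], levels = lev)
  confusion <- table(reference = rs, test = ts)
  ref_ev <- rs != "neutral"
  tst_ev <- ts != "neutral"
  if (ignore_direction) {
    tp <- sum(ref_ev & tst_ev)
  } else {
    tp <- sum(ref_ev & tst_ev & rs == ts)
  }
  n_ref <- sum(ref_ev); n_tst <- sum(tst_ev)
  structure(list(
    event_precision = if (n_tst == 0) 1 else tp / n_tst,
    event_recall = if (n_ref == 0) 1 else tp / n_ref,
    n_events_ref = n_ref, n_events_test = n_tst, n_matched = tp,
    confusion = confusion
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("event precision %.4f  recall %.4f  (ref %d, test %d, matched %d)\n",
              x$event_precision, x$event_recall,
              x$n_events_ref, x$n_events_test, x$n_matched))
  print(x$confusion)
  invisible(x)
}

#' Downsample fragments at read granularity
#'
#' Uniform sampling without replacement.  The default unit is the read: all
#' fragments of a sampled read are kept together, preserving the read-level
#' structure of concatenated-fragment data; `unit = "fragment"` samples
#' individual fragments instead.
#'
#' @param fragments Fragment alignment table with a `read_id` column.
#' @param n Number of reads (or fragments) to keep; alternatively use
#'   `fraction`.
#' @param fraction Fraction of reads (or fragments) to keep.
#' @param seed Integer RNG seed.
#' @param unit `"read"` (default) or `"fragment"`.
#' @return Subset of `fragments`, original order preserved.
#' @export
downsample_fragments <- function(fragments, n = NULL, fraction = NULL,
                                 seed = 1, unit = c("read", "fragment")) {
  unit <- match.arg(unit)
  if (is.null(n) == is.null(fraction))
    stopf("supply exactly one of `n` or `fraction`")
  set.seed(seed)
  if (unit == "read") {
    ids <- unique(fragments$read_id)
    if (is.null(n)) n <- round(assert_fraction(fraction, "fraction", open = FALSE) * length(ids))
    if (n > length(ids)) stopf("`n` exceeds the number of reads (%d)", length(ids))
    keep <- sample(ids, n)
    fragments[fragments$read_id %in% keep, , drop = FALSE]
  } else {
    if (is.null(n)) n <- round(assert_fraction(fraction, "fraction", open = FALSE) * nrow(fragments))
    if (n > nrow(fragments)) stopf("`n` exceeds the number of fragments (%d)", nrow(fragments))
    fragments[sort(sample.int(nrow(fragments), n)), , drop = FALSE]
  }
}
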