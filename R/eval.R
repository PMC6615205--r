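# Fragment- and base-level evaluation of a fragment mapping against
# simulation truth.

#' Match predicted fragments to truth fragments
#'
#' A predicted fragment can match a truth fragment only on the same read,
#' chromosome and strand, and only when the reciprocal reference-interval
#' overlap (overlap divided by the longer of the two interval lengths taken
#' pairwise, i.e. `min(ov/len_truth, ov/len_pred)`) reaches `min_overlap`.
#' Matching is one-to-one and greedy by decreasing overlap, ties broken by
#' smaller reference start.
#'
#' @param truth Truth table (`smurf_reads$truth` or [read_fragment_truth()]).
#' @param predicted Fragment alignments ([map_reads()] output or
#'   [read_fragments_tsv()]).
#' @param min_overlap Reciprocal overlap threshold in (0, 1].
#' @return data.frame with `truth_row`, `pred_row`, `overlap` for each
#'   matched pair (row indices into the two inputs).
#' @export
match_fragments <- function(truth, predicted, min_overlap = 0.5) {
  if (!is.numeric(min_overlap) || min_overlap <= 0 || min_overlap > 1)
    stopf("`min_overlap` must be in (0, 1]")
  if (nrow(truth) == 0 || nrow(predicted) == 0)
    return(data.frame(truth_row = integer(), pred_row = integer(),
                      overlap = numeric()))
  t <- data.frame(key = paste(truth$read_id, truth$chrom, truth$strand),
                  start = truth$start, end = truth$end,
                  row = seq_len(nrow(truth)))
  p <- data.frame(key = paste(predicted$read_id, predicted$chrom,
                              predicted$strand),
                  start = predicted$ref_start, end = predicted$ref_end,
                  row = seq_len(nrow(predicted)))
  cand <- merge(t, p, by = "key", suffixes = c("_t", "_p"))
  if (nrow(cand) == 0)
    return(data.frame(truth_row = integer(), pred_row = integer(),
                      overlap = numeric()))
  ov <- pmax(0, pmin(cand$end_t, cand$end_p) - pmax(cand$start_t, cand$start_p))
  rec <- pmin(ov / (cand$end_t - cand$start_t), ov / (cand$end_p - cand$start_p))
  cand <- cand[rec >= min_overlap, , drop = FALSE]
  rec <- rec[rec >= min_overlap]
  if (nrow(cand) == 0)
    return(data.frame(truth_row = integer(), pred_row = integer(),
                      overlap = numeric()))
  ord <- order(-rec, cand$start_p, cand$start_t)
  cand <- cand[ord, ]; rec <- rec[ord]
  used_t <- logical(nrow(truth)); used_p <- logical(nrow(predicted))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    tr <- cand$row_t[i]; pr <- cand$row_p[i]
    if (!used_t[tr] && !used_p[pr]) {
      keep[i] <- TRUE
      used_t[tr] <- TRUE; used_p[pr] <- TRUE
    }
  }
  data.frame(truth_row = cand$row_t[keep], pred_row = cand$row_p[keep],
             overlap = rec[keep])
}

# Sum over positions of min(coverage_a, coverage_b) for two interval sets
# (multiset intersection of covered reference bases).
cov_min_sum <- function(s1, e1, s2, e2) {
  b <- sort(unique(c(s1, e1, s2, e2)))
  if (length(b) < 2) return(0)
  d1 <- numeric(length(b)); d2 <- numeric(length(b))
  add <- function(d, s, e) {
    i <- match(s, b); j <- match(e, b)
    for (k in seq_along(i)) { d[i[k]] <- d[i[k]] + 1; d[j[k]] <- d[j[k]] - 1 }
    d
  }
  d1 <- add(d1, s1, e1); d2 <- add(d2, s2, e2)
  c1 <- cumsum(d1)[-length(b)]; c2 <- cumsum(d2)[-length(b)]
  sum(pmin(c1, c2) * diff(b))
}

#' Evaluate a fragment mapping against simulation truth
#'
#' Fragment level: precision = matched / predicted, recall = matched /
#' truth, with matching as in [match_fragments()].  Base level: precision
#' and recall of the multiset of reference bases covered by predicted
#' fragments versus truth fragments, computed per read and pooled.  Using
#' reference positions (not read positions) penalizes both boundary and
#' placement errors.  With zero predictions, precision is reported as 1
#' with `zero_predictions = TRUE` and recall 0.
#'
#' @inheritParams match_fragments
#' @param unique_only If `TRUE`, drop non-unique predictions first
#'   (the CNV pipeline's view of the data).
#' @return An `eval_report` list: `fragment_precision`, `fragment_recall`,
#'   `base_precision`, `base_recall`, `n_truth`, `n_predicted`, `n_matched`,
#'   `zero_predictions`.
#' @export
evaluate_mapping <- function(truth, predicted, min_overlap = 0.5,
                             unique_only = FALSE) {
  if (unique_only && nrow(predicted) > 0)
    predicted <- predicted[predicted$is_unique, , drop = FALSE]
  n_t <- nrow(truth); n_p <- nrow(predicted)
  m <- match_fragments(truth, predicted, min_overlap)
  n_m <- nrow(m)
  zero <- n_p == 0
  if (zero) warning("no predicted fragments; precision reported as 1")
  frag_prec <- if (zero) 1 else n_m / n_p
  frag_rec <- if (n_t == 0) 1 else n_m / n_t

  # base level, per read then pooled
  inter <- 0; tot_t <- 0; tot_p <- 0
  if (n_t > 0) tot_t <- sum(truth$end - truth$start)
  if (n_p > 0) tot_p <- sum(predicted$ref_end - predicted$ref_start)
  if (n_t > 0 && n_p > 0) {
    tkey <- paste(truth$read_id, truth$chrom)
    pkey <- paste(predicted$read_id, predicted$chrom)
    ts_list <- split(data.frame(s = truth$start, e = truth$end), tkey)
    ps_list <- split(data.frame(s = predicted$ref_start, e = predicted$ref_end),
                     pkey)
    for (key in intersect(names(ts_list), names(ps_list))) {
      ts <- ts_list[[key]]; ps <- ps_list[[key]]
      inter <- inter + cov_min_sum(ts$s, ts$e, ps$s, ps$e)
    }
  }
  structure(list(
    fragment_precision = frag_prec, fragment_recall = frag_rec,
    base_precision = if (tot_p == 0) 1 else inter / tot_p,
    base_recall = if (tot_t == 0) 1 else inter / tot_t,
    n_truth = n_t, n_predicted = n_p, n_matched = n_m,
    zero_predictions = zero
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0(
    "fragment precision %.4f  recall %.4f\n",
    "base     precision %.4f  recall %.4f\n",
    "truth %d  predicted %d  matched %d\n"),
    x$fragment_precision, x$fragment_recall,
    x$base_precision, x$base_recall,
    x$n_truth, x$n_predicted, x$n_matched))
  invisible(x)
}
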