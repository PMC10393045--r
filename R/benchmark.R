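#' Match predicted TIP calls against an annotated truth set
#'
#' A predicted insertion is a true positive when a truth insertion of the
#' same TE family lies within `tolerance_bp` on the same chromosome
#' (positional proximity + family identity abstract the orthologous-region
#' assembly comparison used to validate rice TIP calls). Matching is
#' greedy nearest-first and each truth record matches at most one
#' prediction. Unmatched predictions are false positives; unmatched truth
#' insertions are false negatives.
#'
#' @param predicted data.frame of predicted presences: `chrom`, `pos`,
#'   `te_family`.
#' @param truth data.frame of annotated insertions: `chrom`, `pos`,
#'   `te_family` (rows with a `present` column equal to `FALSE` are
#'   ignored).
#' @param tolerance_bp maximum matching distance, default 100.
#' @return list of class `tip_matches`: `pairs` (matched prediction/truth
#'   indices and distances), `tp`, `fp` (unmatched prediction rows), `fn`
#'   (unmatched truth rows), `tolerance_bp`.
#' @export
match_predictions <- function(predicted, truth, tolerance_bp = 100) {
  predicted <- as.data.frame(predicted)
  truth <- as.data.frame(truth)
  if (!is.null(truth$present)) truth <- truth[as.logical(truth$present), ,
                                              drop = FALSE]
  np <- nrow(predicted)
  nt <- nrow(truth)
  cand <- NULL
  if (np > 0 && nt > 0) {
    cand <- do.call(rbind, lapply(seq_len(np), function(i) {
      j <- which(truth$chrom == predicted$chrom[i] &
                   truth$te_family == predicted$te_family[i] &
                   abs(truth$pos - predicted$pos[i]) <= tolerance_bp)
      if (length(j) == 0) return(NULL)
      data.frame(pred = i, truth = j,
                 distance = abs(truth$pos[j] - predicted$pos[i]))
    }))
  }
  matched_p <- logical(np)
  matched_t <- logical(nt)
  pairs <- data.frame(pred = integer(0), truth = integer(0),
                      distance = integer(0))
  if (!is.null(cand) && nrow(cand) > 0) {
    cand <- cand[order(cand$distance, cand$pred, cand$truth), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand$pred[r]; j <- cand$truth[r]
      if (!matched_p[i] && !matched_t[j]) {
        matched_p[i] <- TRUE
        matched_t[j] <- TRUE
        pairs <- rbind(pairs, cand[r, ])
      }
    }
  }
  structure(list(
    pairs = pairs,
    tp = sum(matched_p),
    fp = predicted[!matched_p, , drop = FALSE],
    fn = truth[!matched_t, , drop = FALSE],
    n_predicted = np, n_truth = nt,
    tolerance_bp = tolerance_bp,
    predicted = predicted, truth = truth
  ), class = "tip_matches")
}

#' Sensitivity and precision of TIP calls
#'
#' `sensitivity = TP / (TP + FN)` and `precision = TP / (TP + FP)`,
#' globally and per TE family; undefined ratios (zero denominator) are
#' reported as `NA`.
#'
#' @param matches `tip_matches` from [match_predictions()].
#' @return list of class `benchmark_result`: `tp`, `fp`, `fn` counts,
#'   `sensitivity`, `precision`, `per_family` data.frame.
#' @export
score_benchmark <- function(matches) {
  stopifnot(inherits(matches, "tip_matches"))
  tp <- matches$tp
  fp <- nrow(matches$fp)
  fn <- nrow(matches$fn)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  fams <- sort(unique(c(matches$predicted$te_family,
                        matches$truth$te_family)))
  per_family <- do.call(rbind, lapply(fams, function(f) {
    tp_f <- sum(matches$predicted$te_family[matches$pairs$pred] == f)
    fp_f <- sum(matches$fp$te_family == f)
    fn_f <- sum(matches$fn$te_family == f)
    data.frame(te_family = f, tp = tp_f, fp = fp_f, fn = fn_f,
               sensitivity = ratio(tp_f, tp_f + fn_f),
               precision = ratio(tp_f, tp_f + fp_f),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    tp = tp, fp = fp, fn = fn,
    sensitivity = ratio(tp, tp + fn),
    precision = ratio(tp, tp + fp),
    per_family = per_family %||% data.frame()
  ), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "<benchmark_result> TP=%d FP=%d FN=%d | sensitivity=%.4f precision=%.4f\n",
    x$tp, x$fp, x$fn, x$sensitivity, x$precision))
  invisible(x)
}
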