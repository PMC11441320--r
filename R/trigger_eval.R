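#' Span matching in one of four modes
#'
#' Compares two 0-based half-open character spans: `exact` requires both
#' boundaries equal, `left` equal starts, `right` equal ends, `overlap` a
#' non-empty intersection.
#'
#' @param pred,gold numeric vectors `c(start, end)`.
#' @param mode one of `"left"`, `"right"`, `"overlap"`, `"exact"`.
#' @return logical.
#' @export
match_span <- function(pred, gold, mode = c("left", "right", "overlap", "exact")) {
  mode <- match.arg(mode)
  switch(mode,
         exact = pred[1] == gold[1] && pred[2] == gold[2],
         left = pred[1] == gold[1],
         right = pred[2] == gold[2],
         overlap = max(pred[1], gold[1]) < min(pred[2], gold[2]))
}

trigger_modes <- function() c("left", "right", "overlap", "exact")

#' Evaluate trigger predictions against gold spans
#'
#' Gold annotations may carry several equally valid alternative spans per
#' pair. Two accounting modes are provided:
#' \describe{
#'   \item{penalizing}{every gold span is a recall target — a pair with
#'     `k` alternatives contributes `k` opportunities, and a prediction
#'     counts one TP per gold span it matches; a pair whose prediction
#'     matches no alternative counts one FP plus `k` FN; a pair without a
#'     prediction (the classifier said negative) counts `k` FN.}
#'   \item{non-penalizing}{a pair counts one TP if its prediction matches
#'     any alternative, otherwise one FP and one FN; a pair without a
#'     prediction counts one FN.}
#' }
#' Scores are computed per matching mode (left/right/overlap/exact) and
#' averaged over the four modes.
#'
#' @param preds data.frame with columns `doc_id`, `e1`, `e2`, `start`,
#'   `end` — at most one prediction per pair. A prediction for a pair
#'   absent from `golds` is an error.
#' @param golds data.frame with columns `doc_id`, `e1`, `e2`, `start`,
#'   `end` — one row per alternative gold span; all positive pairs under
#'   evaluation must appear.
#' @param penalize_alternatives use the penalizing accounting (default
#'   TRUE, the protocol used for method development).
#' @return object of class `trigger_eval_report`: `per_mode` (data.frame
#'   with mode/tp/fp/fn/precision/recall/f1), `avg_precision`,
#'   `avg_recall`, `avg_f1`, `penalize`.
#' @export
evaluate_triggers <- function(preds, golds, penalize_alternatives = TRUE) {
  pk <- function(df) paste(df$doc_id, pair_key(df$e1, df$e2))
  gold_keys <- pk(golds)
  if (nrow(preds)) {
    pred_keys <- pk(preds)
    if (anyDuplicated(pred_keys))
      stop("at most one trigger prediction per pair is allowed")
    unknown <- setdiff(pred_keys, gold_keys)
    if (length(unknown))
      stop(sprintf("prediction for pair absent from gold standard: %s", unknown[1]))
  } else pred_keys <- character()

  pairs <- unique(gold_keys)
  per_mode <- lapply(trigger_modes(), function(mode) {
    tp <- fp <- fn <- 0L
    for (key in pairs) {
      g <- golds[gold_keys == key, , drop = FALSE]
      pi <- which(pred_keys == key)
      if (!length(pi)) {
        fn <- fn + if (penalize_alternatives) nrow(g) else 1L
        next
      }
      p <- preds[pi, , drop = FALSE]
      matches <- vapply(seq_len(nrow(g)), function(j)
        match_span(c(p$start, p$end), c(g$start[j], g$end[j]), mode), TRUE)
      if (penalize_alternatives) {
        tp <- tp + sum(matches)
        fn <- fn + sum(!matches)
        if (!any(matches)) fp <- fp + 1L
      } else {
        if (any(matches)) tp <- tp + 1L else { fp <- fp + 1L; fn <- fn + 1L }
      }
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(mode = mode, tp = tp, fp = fp, fn = fn,
               precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  })
  per_mode <- do.call(rbind, per_mode)
  structure(list(per_mode = per_mode,
                 avg_precision = mean(per_mode$precision),
                 avg_recall = mean(per_mode$recall),
                 avg_f1 = mean(per_mode$f1),
                 penalize = penalize_alternatives),
            class = "trigger_eval_report")
}

#' @export
print.trigger_eval_report <- function(x, ...) {
  cat(sprintf("trigger evaluation (%s alternative spans)\n",
              if (x$penalize) "penalizing" else "not penalizing"))
  print(x$per_mode, row.names = FALSE, digits = 3)
  cat(sprintf("average: P=%.3f R=%.3f F1=%.3f\n",
              x$avg_precision, x$avg_recall, x$avg_f1))
  invisible(x)
}

#' Trigger report as a TSV-ready table
#' @param report a `trigger_eval_report`.
#' @return data.frame with the four per-mode rows plus an `average` row.
#' @export
trigger_report_table <- function(report) {
  avg <- data.frame(mode = "average", tp = NA_integer_, fp = NA_integer_,
                    fn = NA_integer_, precision = report$avg_precision,
                    recall = report$avg_recall, f1 = report$avg_f1,
                    stringsAsFactors = FALSE)
  rbind(report$per_mode, avg)
}
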