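# Scoring of detection output against a simulated truth table: precision,
# recall, F1 at the gene-pair level, plus breakpoint accuracy.

#' F1 score
#'
#' Harmonic mean of precision and recall,
#' `F1 = 2 * precision * recall / (precision + recall)`, defined as 0 when
#' both inputs are 0.
#'
#' @param precision,recall fractions in `[0, 1]` (vectors recycle)
#' @return numeric vector
#' @export
f1_score <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1, na.rm = TRUE),
            all(recall >= 0 & recall <= 1, na.rm = TRUE))
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Match fusion predictions against simulated truth
#'
#' A prediction is a true positive iff its unordered gene pair appears in
#' the truth set; breakpoint distances are recorded but not required for a
#' match (the headline metric is gene-pair accuracy), unless
#' `strict = TRUE`, in which case both breakpoints must additionally lie
#' within `breakpoint_tol` bp of the truth. Each truth fusion matches at
#' most one prediction; duplicated predicted pairs are counted once with a
#' warning.
#'
#' @param predicted data.table/data.frame of candidates with columns
#'   `gene_a`, `gene_b`, `breakpoint_a`, `breakpoint_b`, and optionally
#'   `support_count`
#' @param truth data.table/data.frame with columns `gene_a`, `gene_b`,
#'   `breakpoint_a`, `breakpoint_b`
#' @param breakpoint_tol tolerance in bp for strict matching and for the
#'   per-fusion `within_tol` flag (default 25 = half the default window)
#' @param strict require both breakpoints within tolerance for a TP
#' @return list of class `fusion_eval`: n_truth, n_predicted,
#'   n_true_positive, precision, recall, f1, `matches` (per-TP gene pair,
#'   breakpoint errors in bp, within_tol), `support_tp`/`support_fp`
#'   (support-count vectors, when `support_count` present)
#' @export
match_predictions <- function(predicted, truth, breakpoint_tol = 25,
                              strict = FALSE) {
  pred <- data.table::as.data.table(predicted)
  tru <- data.table::as.data.table(truth)
  n_truth <- nrow(tru)
  if (nrow(pred)) {
    pred[, pair := pair_key(gene_a, gene_b)]
    if (anyDuplicated(pred$pair)) {
      warning("duplicate predicted gene pair(s) counted once", call. = FALSE)
      pred <- pred[!duplicated(pair)]
    }
  } else {
    pred <- data.table::data.table(gene_a = character(), gene_b = character(),
                                   breakpoint_a = numeric(),
                                   breakpoint_b = numeric(), pair = character())
  }
  n_predicted <- nrow(pred)
  if (n_truth) tru[, pair := pair_key(gene_a, gene_b)]

  matches <- data.table::data.table(
    pair = character(), err_a = numeric(), err_b = numeric(),
    within_tol = logical())
  if (n_predicted && n_truth) {
    m <- merge(pred, tru, by = "pair", suffixes = c("", ".t"))
    if (nrow(m)) {
      # per-gene breakpoint error irrespective of reported orientation
      same_orient <- m$gene_a == m$gene_a.t
      ea <- ifelse(same_orient, abs(m$breakpoint_a - m$breakpoint_a.t),
                   abs(m$breakpoint_a - m$breakpoint_b.t))
      eb <- ifelse(same_orient, abs(m$breakpoint_b - m$breakpoint_b.t),
                   abs(m$breakpoint_b - m$breakpoint_a.t))
      matches <- data.table::data.table(
        pair = m$pair, err_a = ea, err_b = eb,
        within_tol = ea <= breakpoint_tol & eb <= breakpoint_tol)
    }
  }
  if (strict) matches <- matches[within_tol == TRUE]
  tp <- nrow(matches)
  precision <- if (n_predicted) tp / n_predicted else 0
  recall <- if (n_truth) tp / n_truth else 0

  sup_tp <- sup_fp <- numeric(0)
  if (n_predicted && "support_count" %in% names(pred)) {
    is_tp <- pred$pair %in% matches$pair
    sup_tp <- pred$support_count[is_tp]
    sup_fp <- pred$support_count[!is_tp]
  }
  structure(list(n_truth = n_truth, n_predicted = n_predicted,
                 n_true_positive = tp, precision = precision,
                 recall = recall, f1 = f1_score(precision, recall),
                 matches = matches, support_tp = sup_tp, support_fp = sup_fp,
                 breakpoint_tol = breakpoint_tol, strict = strict),
            class = "fusion_eval")
}

#' @export
print.fusion_eval <- function(x, ...) {
  cat(sprintf(paste0("fusion_eval: %d truth, %d predicted, %d TP | ",
                     "precision %.3f recall %.3f F1 %.3f\n"),
              x$n_truth, x$n_predicted, x$n_true_positive,
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate a prediction TSV against a truth TSV
#'
#' File-level wrapper around [match_predictions()]; optionally writes the
#' metrics as TSV and/or JSON.
#'
#' @param pred_path candidate report (as written by [write_fusion_report()])
#' @param truth_path truth table (as written by [simulate_fusion_dataset()])
#' @param out_tsv,out_json optional output paths
#' @inheritParams match_predictions
#' @return a `fusion_eval`, invisibly returns it after writing any outputs
#' @export
evaluate_files <- function(pred_path, truth_path, breakpoint_tol = 25,
                           strict = FALSE, out_tsv = NULL, out_json = NULL) {
  pred <- data.table::fread(pred_path)
  tru <- data.table::fread(truth_path)
  ev <- match_predictions(pred, tru, breakpoint_tol = breakpoint_tol,
                          strict = strict)
  metrics <- data.table::data.table(
    n_truth = ev$n_truth, n_predicted = ev$n_predicted,
    n_true_positive = ev$n_true_positive, precision = ev$precision,
    recall = ev$recall, f1 = ev$f1)
  if (!is.null(out_tsv)) data.table::fwrite(metrics, out_tsv, sep = "\t")
  if (!is.null(out_json))
    jsonlite::write_json(as.list(metrics), out_json, auto_unbox = TRUE,
                         digits = NA)
  invisible(ev)
}
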