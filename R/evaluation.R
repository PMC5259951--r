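#' Confusion-matrix metrics against a truth set
#'
#' Scores calls against genes of known copy-number status. The positive
#' class is either CNE (truth status `expanded`) or CNR (truth status
#' `reduced`); every other truth gene is a negative. Truth genes absent
#' from the call table are counted as predicted-negative, with a warning.
#' Sensitivity is the percentage of true positives correctly identified,
#' specificity the percentage of true negatives correctly identified, and
#' precision the percentage of true positives among all predicted
#' positives (`NA` when nothing was predicted positive).
#'
#' @param calls A `cnd_calls` tibble.
#' @param truth Tibble (`gene_id`, `status`) from [read_truth_set()].
#' @param positive_class `"CNE"` or `"CNR"`.
#' @param id_col Column of `calls` matching `truth$gene_id` (default
#'   `"gene_id"` if present, else `"probeset_id"`).
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `precision` (percentages).
#' @export
confusion_metrics <- function(calls, truth, positive_class = c("CNE", "CNR"),
                              id_col = NULL) {
  positive_class <- match.arg(positive_class)
  if (nrow(truth) == 0) abort("empty truth set")
  id_col <- id_col %||% (if ("gene_id" %in% names(calls)) "gene_id" else "probeset_id")
  truth_status <- if (positive_class == "CNE") "expanded" else "reduced"
  pred <- calls$cnd_class[match(truth$gene_id, calls[[id_col]])]
  n_missing <- sum(is.na(match(truth$gene_id, calls[[id_col]])))
  if (n_missing > 0) {
    warn(sprintf("%d truth gene(s) absent from the calls; counted as predicted-negative",
                 n_missing))
  }
  pred_pos <- !is.na(pred) & pred == positive_class
  truth_pos <- truth$status == truth_status
  tp <- sum(pred_pos & truth_pos)
  fp <- sum(pred_pos & !truth_pos)
  fn <- sum(!pred_pos & truth_pos)
  tn <- sum(!pred_pos & !truth_pos)
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  )
}

#' Head-to-head comparison of calling methods
#'
#' Runs each calling pipeline on the same dataset and scores it against
#' the same truth set, one row per method. A failing method is flagged in
#' its row without affecting the others.
#'
#' @param dataset Arbitrary object passed to each method function.
#' @param methods Named list of functions `dataset -> cnd_calls`.
#' @param truth Truth-set tibble.
#' @param positive_class `"CNE"` or `"CNR"`.
#' @param id_col Passed to [confusion_metrics()].
#' @return Tibble: `method`, `n_calls`, `tp` ... `precision`, `error`.
#' @export
method_comparison <- function(dataset, methods, truth,
                              positive_class = "CNE", id_col = NULL) {
  stopifnot(is.list(methods), !is.null(names(methods)))
  rows <- map(names(methods), function(nm) {
    res <- tryCatch({
      calls <- methods[[nm]](dataset)
      m <- confusion_metrics(calls, truth, positive_class, id_col = id_col)
      mutate(m,
             method = nm,
             n_calls = sum(calls$cnd_class %in% c("CNE", "CNR"), na.rm = TRUE),
             error = NA_character_)
    }, error = function(e) {
      tibble(tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
             fn = NA_integer_, sensitivity = NA_real_,
             specificity = NA_real_, precision = NA_real_,
             method = nm, n_calls = NA_integer_,
             error = conditionMessage(e))
    })
    res
  })
  bind_rows(rows) |>
    relocate(method, n_calls)
}
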