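# binary AUROC via the rank (Mann-Whitney) formulation with midrank tie
# correction; scores higher => more positive
auroc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro one-vs-rest AUROC report
#'
#' Computes per-class one-vs-rest AUROCs from four-class probability
#' scores via the rank/Mann-Whitney statistic with midrank tie correction,
#' and their unweighted mean (the macro average). Classes without both a
#' positive and a negative case have undefined AUROC and are excluded
#' from the macro average with a warning.
#'
#' @param labels True class labels (`CMS1`..`CMS4`).
#' @param scores Numeric matrix (or tibble) of class scores with one
#'   column per class (`p_CMS1`..`p_CMS4` or unnamed in class order).
#' @return A `cms_eval`: list with `per_class` (tibble), `macro_auroc`,
#'   `n_cases`.
#' @export
macro_auroc <- function(labels, scores) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    abort("AUROC needs at least two distinct classes among the labels.",
      class = "cms_validation_error")
  }
  S <- as.matrix(scores)
  if (ncol(S) != 4) abort("`scores` must have 4 columns.", class = "cms_validation_error")
  colnames(S) <- prob_cols()
  per <- tibble::tibble(
    class = CMS_CLASSES,
    n_pos = vapply(CMS_CLASSES, function(k) sum(labels == k), integer(1)),
    n_neg = vapply(CMS_CLASSES, function(k) sum(labels != k), integer(1)),
    auroc = vapply(seq_len(4), function(k) {
      auroc_rank(S[, k], labels == CMS_CLASSES[k])
    }, numeric(1))
  )
  if (any(is.na(per$auroc))) {
    warn(sprintf("AUROC undefined for class(es) %s; macro average over the rest.",
      paste(per$class[is.na(per$auroc)], collapse = ", ")))
  }
  structure(list(
    per_class = per,
    macro_auroc = mean(per$auroc, na.rm = TRUE),
    n_cases = length(labels)
  ), class = "cms_eval")
}

#' @export
print.cms_eval <- function(x, ...) {
  cat(sprintf("<cms_eval> macro-AUROC %.4f over %d cases\n", x$macro_auroc, x$n_cases))
  print(x$per_class)
  invisible(x)
}

#' @method tidy cms_eval
#' @export
tidy.cms_eval <- function(x, ...) x$per_class

#' @method glance cms_eval
#' @export
glance.cms_eval <- function(x, ...) {
  tibble::tibble(macro_auroc = x$macro_auroc, n_cases = x$n_cases,
    n_classes_defined = sum(!is.na(x$per_class$auroc)))
}

#' ROC curve points for one class (one-vs-rest)
#'
#' @param labels True class labels.
#' @param scores Score matrix as in [macro_auroc()].
#' @param class Class to treat as positive.
#' @return Tibble of `(fpr, tpr, threshold)` points.
#' @export
roc_points <- function(labels, scores, class) {
  S <- as.matrix(scores)
  colnames(S) <- prob_cols()
  s <- S[, paste0("p_", class)]
  pos <- as.character(labels) == class
  ths <- c(Inf, sort(unique(s), decreasing = TRUE))
  tibble::tibble(
    threshold = ths,
    tpr = vapply(ths, function(t) mean(s[pos] >= t), numeric(1)),
    fpr = vapply(ths, function(t) mean(s[!pos] >= t), numeric(1))
  )
}

#' Confusion matrix of case calls
#'
#' Rows are true classes, columns the predicted call including the
#' `"mixed"` ensemble outcome.
#'
#' @param calls Predicted calls (`CMS1`..`CMS4` or `mixed`).
#' @param labels True labels (`CMS1`..`CMS4`).
#' @return A 4 x 5 integer matrix.
#' @export
confusion_counts <- function(calls, labels) {
  tab <- table(
    factor(as.character(labels), levels = CMS_CLASSES),
    factor(as.character(calls), levels = CALL_LEVELS)
  )
  m <- matrix(as.integer(tab), nrow = 4, dimnames = dimnames(tab))
  names(dimnames(m)) <- c("true", "called")
  m
}

#' Top-confidence tile gallery
#'
#' Selects the `k` tiles with the highest probability for a class, subject
#' to one tile per patient (greedy in score order). Ties at the selection
#' boundary are broken deterministically by `(patient_id, x, y)`
#' lexicographic order.
#'
#' @param tile_probs Tile probability tibble with `patient_id`, `x`, `y`
#'   and probability columns.
#' @param class Class whose probability ranks the tiles.
#' @param k Gallery size (published galleries use 16).
#' @return Tibble of at most `k` rows (fewer, with a warning, when fewer
#'   eligible patients exist), sorted by decreasing score.
#' @export
top_tiles_gallery <- function(tile_probs, class, k = 16L) {
  stopifnot(class %in% CMS_CLASSES)
  score_col <- paste0("p_", class)
  ranked <- tile_probs %>%
    mutate(score = .data[[score_col]]) %>%
    arrange(desc(.data$score), .data$patient_id, .data$x, .data$y) %>%
    distinct(.data$patient_id, .keep_all = TRUE) %>%
    slice_head(n = k)
  if (nrow(ranked) < k) {
    warn(sprintf("Only %d eligible patients for a gallery of %d.", nrow(ranked), k))
  }
  ranked
}
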