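#' Slide-level aggregation of tile probabilities (stage 3)
#'
#' Averages the tile-level probability vectors of each slide (unweighted
#' arithmetic mean) and calls the class with the highest averaged score.
#' Exact argmax ties are broken towards the lowest class index and flagged
#' in the `tie` column so they remain auditable.
#'
#' @param tile_probs Tibble with `slide_id` and probability columns
#'   `p_CMS1`..`p_CMS4` (extra columns such as `cms_label` are carried
#'   through, taking each slide's first value).
#' @return One row per slide: `slide_id`, `n_tiles`, mean probabilities,
#'   `call`, `tie`.
#' @export
aggregate_slides <- function(tile_probs) {
  if (nrow(tile_probs) == 0) {
    abort("No tumor tiles: cannot aggregate an empty tile set.",
      class = "cms_empty_error")
  }
  pc <- prob_cols()
  carry <- intersect(c("cms_label", "patient_id", "cohort", "model_id"),
    names(tile_probs))
  out <- tile_probs %>%
    group_by(.data$slide_id) %>%
    summarise(
      n_tiles = dplyr::n(),
      across(all_of(pc), mean),
      across(all_of(carry), first),
      .groups = "drop"
    )
  am <- lapply(seq_len(nrow(out)), function(i) argmax_tie(as.numeric(out[i, pc])))
  out$call <- factor(CMS_CLASSES[vapply(am, `[[`, integer(1), "index")],
    levels = CMS_CLASSES)
  out$tie <- vapply(am, `[[`, logical(1), "tie")
  out
}

#' @rdname aggregate_slides
#' @details `aggregate_slide()` is the single-slide form; it errors on an
#'   empty tile set ("no tumor tiles").
#' @export
aggregate_slide <- function(tile_probs) {
  res <- aggregate_slides(tile_probs)
  if (nrow(res) != 1) {
    abort("aggregate_slide() expects tiles of exactly one slide.",
      class = "cms_validation_error")
  }
  res
}

#' Majority vote over ensemble member calls
#'
#' The case-level call is the unique strict plurality winner of the member
#' calls; any tie for the top count yields `"mixed"`.
#'
#' @param calls Character/factor vector of member calls, one per ensemble
#'   member.
#' @param n_expected Required number of members (arity check); `NULL`
#'   skips the check.
#' @return A length-1 factor with levels `CMS1`..`CMS4`, `mixed`.
#' @examples
#' majority_vote(c("CMS4", "CMS4", "CMS4", "CMS1", "CMS2")) # CMS4
#' majority_vote(c("CMS1", "CMS1", "CMS2", "CMS2", "CMS3")) # mixed
#' @export
majority_vote <- function(calls, n_expected = 5L) {
  calls <- as.character(calls)
  if (!is.null(n_expected) && length(calls) != n_expected) {
    abort(sprintf("Expected %d member calls, got %d.", n_expected, length(calls)),
      class = "cms_validation_error")
  }
  if (!all(calls %in% CMS_CLASSES)) {
    abort("Member calls must be CMS1..CMS4.", class = "cms_validation_error")
  }
  counts <- table(factor(calls, levels = CMS_CLASSES))
  top <- max(counts)
  winners <- names(counts)[counts == top]
  out <- if (length(winners) == 1) winners else "mixed"
  factor(out, levels = CALL_LEVELS)
}

#' Ensemble case calls
#'
#' Combines the per-member slide calls of each case: the continuous
#' ensemble score is the mean of the member probability vectors (used for
#' ROC analysis), while the categorical case call is the majority vote of
#' the member calls, with undecided majorities classified as `"mixed"`.
#'
#' @param member_calls Long tibble of per-member slide calls (one row per
#'   case x member) with `slide_id`, `model_id`, probability columns and
#'   `call`, e.g. member-wise [aggregate_slides()] output bound together.
#' @param n_members Required ensemble arity (default 5).
#' @return One row per case: mean probabilities, `member_calls`
#'   (list-column), `final_call`, `tie` (argmax tie in the mean
#'   probabilities).
#' @export
ensemble_calls <- function(member_calls, n_members = 5L) {
  pc <- prob_cols()
  carry <- intersect(c("cms_label", "patient_id", "cohort"), names(member_calls))
  grouped <- member_calls %>%
    group_by(.data$slide_id) %>%
    summarise(
      n_members_seen = dplyr::n(),
      across(all_of(pc), mean),
      member_calls = list(as.character(.data$call)),
      across(all_of(carry), first),
      .groups = "drop"
    )
  if (any(grouped$n_members_seen != n_members)) {
    bad <- grouped$slide_id[grouped$n_members_seen != n_members]
    abort(sprintf("Case(s) %s lack exactly %d member calls.",
      paste(bad, collapse = ", "), n_members), class = "cms_validation_error")
  }
  am <- lapply(seq_len(nrow(grouped)), function(i) argmax_tie(as.numeric(grouped[i, pc])))
  grouped$final_call <- do.call(c, lapply(grouped$member_calls, majority_vote,
    n_expected = n_members))
  grouped$tie <- vapply(am, `[[`, logical(1), "tie")
  grouped$n_members_seen <- NULL
  grouped
}
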