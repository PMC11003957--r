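#' Patient-level stratified cross-validation folds
#'
#' Splits the development patients into `n_folds` bins stratified jointly
#' by cohort and CMS class at the patient level: within every
#' (cohort x class) cell the patients are spread as evenly as possible
#' (cell counts per bin differ by at most one) while bin totals stay
#' balanced, and all slides of a patient land in exactly one bin. Each bin
#' serves once as the validation set of a fold.
#'
#' @param manifest Manifest tibble of labeled development slides.
#' @param n_folds Number of folds (>= 2; a single fold would make the
#'   validation set equal the training set).
#' @param seed RNG seed; the split is a pure function of (manifest, seed).
#' @return A tibble with one row per fold: `fold_id`, `train_patients`,
#'   `val_patients` (list-columns of patient id vectors).
#' @export
make_folds <- function(manifest, n_folds = 5L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (is.na(n_folds) || n_folds < 2L) {
    abort("`n_folds` must be >= 2: with one fold the validation set would equal the training set.",
      class = "cms_config_error")
  }
  if (any(manifest$cms_label == "unlabeled")) {
    abort("All development slides must carry a CMS label.", class = "cms_validation_error")
  }
  pts <- manifest %>%
    group_by(.data$patient_id) %>%
    summarise(
      cohort = first(.data$cohort),
      cms_label = {
        u <- unique(.data$cms_label)
        if (length(u) > 1) warn(sprintf(
          "Patient %s has slides with conflicting labels; using the first.",
          .data$patient_id[1]))
        u[1]
      },
      .groups = "drop"
    ) %>%
    arrange(.data$patient_id)
  if (nrow(pts) < n_folds) {
    abort(sprintf("Only %d patients for %d folds.", nrow(pts), n_folds),
      class = "cms_validation_error")
  }
  assignment <- integer(nrow(pts))
  load <- integer(n_folds)
  with_local_seed(seed, {
    cells <- pts %>%
      mutate(.row = row_number()) %>%
      group_by(.data$cohort, .data$cms_label) %>%
      group_split()
    for (cell in cells) {
      idx <- sample(cell$.row) # random order within the stratum
      if (length(idx) < n_folds) {
        warn(sprintf(
          "Stratum (%s, %s) has %d patient(s) for %d folds; best-effort assignment.",
          cell$cohort[1], cell$cms_label[1], length(idx), n_folds))
      }
      # deal round-robin over bins ordered by current load (ties: bin id)
      order_bins <- order(load, seq_len(n_folds))
      for (j in seq_along(idx)) {
        bin <- order_bins[((j - 1L) %% n_folds) + 1L]
        assignment[idx[j]] <- bin
        load[bin] <- load[bin] + 1L
      }
    }
  })
  tibble::tibble(
    fold_id = seq_len(n_folds),
    train_patients = lapply(seq_len(n_folds), function(f) pts$patient_id[assignment != f]),
    val_patients = lapply(seq_len(n_folds), function(f) pts$patient_id[assignment == f])
  )
}
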