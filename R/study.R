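#' End-to-end virtual-biopsy convergence study
#'
#' Runs the whole desk-scale experiment in one call: trains the five-fold
#' ensemble on a development cohort, scores a disjoint evaluation cohort of
#' fully imaged resections (the reference), then repeats the virtual-biopsy
#' sampling experiment over a range of fragment counts and summarises the
#' performance-vs-fragment-count convergence curve. Every ensemble member
#' is evaluated only on slides outside its training data because the
#' evaluation cohort is disjoint from the development cohort.
#'
#' @param train_cohort,eval_cohort `cms_synth_cohort` objects (or lists
#'   with `manifest`/`annotations` plus `image_dir`-readable slides). The
#'   two must not share patients.
#' @param shapes Fragment shape library tibble.
#' @param cfg A [pipeline_config()]; the desk-scale experiments use 64 px
#'   tiles at 2 um/px.
#' @param spec A [model_spec()].
#' @param m_values Fragment counts to simulate.
#' @param n_events_per_slide Sampling events per slide and fragment count.
#' @param seed Master seed for folds, training and sampling.
#' @return A list: `ensemble`, `eval_calls` (ensemble case calls on the
#'   evaluation cohort), `eval_report` (`cms_eval` of the ensemble scores),
#'   `reference` (per-member slide calls), `scored` (per-event member
#'   calls), `curve` (`cms_sim_curve`).
#' @export
virtual_biopsy_study <- function(train_cohort, eval_cohort, shapes,
                                 cfg = pipeline_config(tile_px = 64L),
                                 spec = model_spec(),
                                 m_values = 1:8,
                                 n_events_per_slide = 200L,
                                 seed = 1L) {
  overlap <- intersect(train_cohort$manifest$patient_id,
    eval_cohort$manifest$patient_id)
  if (length(overlap) > 0) {
    abort("Development and evaluation cohorts share patients.",
      class = "cms_validation_error")
  }
  # stage 2: tile scorer ensemble on the development cohort
  ft_train <- cohort_tile_features(train_cohort, cfg)
  folds <- make_folds(train_cohort$manifest, n_folds = cfg$n_folds, seed = seed)
  ensemble <- train_ensemble(ft_train, folds, spec)

  # reference: full-resection member and ensemble calls on the eval cohort
  ft_mask <- cohort_tile_features(eval_cohort, cfg)
  mask_probs <- predict_tiles_ensemble(ensemble, ft_mask)
  reference <- dplyr::bind_rows(lapply(split(mask_probs, mask_probs$model_id),
    aggregate_slides))
  eval_calls <- ensemble_calls(reference, n_members = cfg$n_folds)
  eval_report <- macro_auroc(eval_calls$cms_label,
    as.matrix(eval_calls[, prob_cols()]))

  # full candidate-grid probabilities for cheap per-event scoring
  ft_full <- cohort_tile_features(eval_cohort, cfg, grid = "full")
  grid_probs <- predict_tiles_ensemble(ensemble, ft_full)

  manifest <- eval_cohort$manifest
  masks <- lapply(setNames(manifest$slide_id, manifest$slide_id), function(sid) {
    mask <- effective_tumor_mask(eval_cohort$annotations, sid)
    scale_mask_to_target(mask,
      manifest$pixel_spacing_um[manifest$slide_id == sid], cfg)
  })
  labels <- setNames(manifest$cms_label, manifest$slide_id)

  scored <- dplyr::bind_rows(lapply(m_values, function(m) {
    sim <- simulate_biopsy_dataset(masks, shapes, m,
      n_events_per_slide = n_events_per_slide, cfg = cfg,
      seed = derive_seed(seed, 1000 + m))
    sc <- score_biopsy_samples(sim, grid_probs, cfg)
    sc$cms_label <- unname(labels[sc$slide_id])
    sc
  }))
  curve <- convergence_curve(scored, reference)
  list(ensemble = ensemble, eval_calls = eval_calls, eval_report = eval_report,
    reference = reference, scored = scored, curve = curve)
}
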