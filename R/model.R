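#' Tile scorer specification
#'
#' Hyper-parameters of the tile-level four-class probability scorer: a
#' compact single-hidden-layer neural network with a softmax head fitted on
#' tile descriptors (see [tile_descriptor()]). Training proceeds in
#' `rounds` warm-started optimisation rounds; after each round the
#' validation slide-level macro-AUROC is computed and the weights of the
#' best round are kept, mirroring validation-based checkpoint selection.
#'
#' @param hidden Hidden units.
#' @param decay L2 weight decay.
#' @param rounds Optimisation rounds (checkpoints).
#' @param iters_per_round BFGS iterations per round.
#' @param class_weights Balance classes by inverse-frequency case weights.
#' @param augmentation Augmentation policy used when building augmented
#'   training copies (consumed by the featurisation step, recorded here).
#' @param seed Base RNG seed; fold `f` trains with `seed + f`.
#' @return A `cms_model_spec`.
#' @export
model_spec <- function(hidden = 8L, decay = 1e-3, rounds = 6L,
                       iters_per_round = 40L, class_weights = TRUE,
                       augmentation = c("flip", "rotate"), seed = 1L) {
  structure(list(
    hidden = as.integer(hidden), decay = decay, rounds = as.integer(rounds),
    iters_per_round = as.integer(iters_per_round),
    class_weights = isTRUE(class_weights),
    augmentation = augmentation, seed = as.integer(seed)
  ), class = "cms_model_spec")
}

feature_matrix <- function(features) {
  as.matrix(features[, feature_names(), drop = FALSE])
}

#' Train the tile scorer of one fold
#'
#' Fits the scorer on the training patients' tiles (weakly labeled by
#' their slide's CMS label) and selects the round whose weights maximise
#' the validation slide-level macro one-vs-rest AUROC. Rows flagged
#' `augmented` (if present) contribute to training only; validation always
#' uses the original tiles.
#'
#' @param features Tile-descriptor tibble from [cohort_tile_features()]
#'   with `patient_id`, `slide_id`, `cms_label` and `ft_*` columns.
#' @param fold One row of [make_folds()] output (or a list with
#'   `fold_id`, `train_patients`, `val_patients`).
#' @param spec A [model_spec()].
#' @return A `cms_tile_model` with the fitted network, the feature
#'   standardisation, and a per-round training log.
#' @export
train_fold <- function(features, fold, spec = model_spec()) {
  fold_id <- fold$fold_id[[1]]
  train_pat <- unlist(fold$train_patients)
  val_pat <- unlist(fold$val_patients)
  if (length(intersect(train_pat, val_pat)) > 0) {
    abort("Fold leakage: train and validation patient sets overlap.",
      class = "cms_validation_error")
  }
  aug_col <- if ("augmented" %in% names(features)) features$augmented else
    rep(FALSE, nrow(features))
  tr <- features[features$patient_id %in% train_pat, ]
  va <- features[features$patient_id %in% val_pat & !aug_col, ]
  if (nrow(tr) == 0) abort("Empty training set.", class = "cms_validation_error")
  if (length(unique(tr$cms_label)) < 2) {
    abort("Training set contains a single class.", class = "cms_validation_error")
  }
  X <- feature_matrix(tr)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  y <- factor(tr$cms_label, levels = CMS_CLASSES)
  Y <- nnet::class.ind(y)
  w <- rep(1, nrow(tr))
  if (spec$class_weights) {
    freq <- pmax(as.numeric(table(y)), 1)
    w <- as.numeric(length(y) / (Y %*% (4 * freq)))
  }
  Xv <- if (nrow(va) > 0) {
    sweep(sweep(feature_matrix(va), 2, ctr), 2, scl, "/")
  } else NULL

  log_rows <- vector("list", spec$rounds)
  best <- list(auroc = -Inf, net = NULL, round = NA_integer_)
  net <- NULL
  with_local_seed(derive_seed(spec$seed, fold_id), {
    for (r in seq_len(spec$rounds)) {
      net <- if (is.null(net)) {
        nnet::nnet(Xs, Y, size = spec$hidden, softmax = TRUE, decay = spec$decay,
          maxit = spec$iters_per_round, weights = w, trace = FALSE, MaxNWts = 5000)
      } else {
        nnet::nnet(Xs, Y, size = spec$hidden, softmax = TRUE, decay = spec$decay,
          maxit = spec$iters_per_round, weights = w, trace = FALSE, MaxNWts = 5000,
          Wts = net$wts)
      }
      val_auroc <- NA_real_
      if (!is.null(Xv) && length(unique(va$cms_label)) >= 2) {
        pv <- predict(net, Xv)
        colnames(pv) <- prob_cols()
        calls <- aggregate_slides(dplyr::bind_cols(
          va[, c("slide_id", "cms_label")], tibble::as_tibble(pv)))
        val_auroc <- macro_auroc(calls$cms_label,
          as.matrix(calls[, prob_cols()]))$macro_auroc
      }
      log_rows[[r]] <- tibble::tibble(round = r, train_loss = net$value,
        val_macro_auroc = val_auroc)
      score <- if (is.na(val_auroc)) -net$value else val_auroc
      if (score > best$auroc) best <- list(auroc = score, net = net, round = r)
    }
  })
  structure(list(
    net = best$net, best_round = best$round, center = ctr, scale = scl,
    classes = CMS_CLASSES, fold_id = fold_id, spec = spec,
    log = dplyr::bind_rows(log_rows)
  ), class = "cms_tile_model")
}

#' @export
print.cms_tile_model <- function(x, ...) {
  cat(sprintf("<cms_tile_model> fold %d, %d hidden units, best round %d\n",
    x$fold_id, x$spec$hidden, x$best_round))
  invisible(x)
}

#' @method tidy cms_tile_model
#' @export
tidy.cms_tile_model <- function(x, ...) x$log

#' @method glance cms_tile_model
#' @export
glance.cms_tile_model <- function(x, ...) {
  tibble::tibble(
    fold_id = x$fold_id, best_round = x$best_round,
    n_weights = length(x$net$wts),
    val_macro_auroc = x$log$val_macro_auroc[x$best_round],
    train_loss = x$log$train_loss[x$best_round]
  )
}

#' Tile-level class probabilities
#'
#' Deterministic forward pass of a trained tile scorer: each tile receives
#' a four-class softmax probability vector (columns `p_CMS1`..`p_CMS4`),
#' in input order.
#'
#' @param model A `cms_tile_model`.
#' @param features Tile-descriptor tibble (or bare `ft_*` matrix).
#' @return `features` with probability columns appended (tibble input), or
#'   a probability matrix (matrix input).
#' @export
predict_tiles <- function(model, features) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  P <- predict(model$net, Xs)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  colnames(P) <- prob_cols()
  if (is.matrix(features)) return(P)
  dplyr::bind_cols(
    features[, setdiff(names(features), prob_cols()), drop = FALSE],
    tibble::as_tibble(P)
  )
}

#' Train the five-fold ensemble
#'
#' Runs [train_fold()] for every fold of a patient-level stratified split,
#' producing the member models of the slide-call ensemble.
#'
#' @param features Tile-descriptor tibble of the development cohort.
#' @param folds Output of [make_folds()].
#' @param spec A [model_spec()].
#' @return A `cms_ensemble` (list of `cms_tile_model`s plus the folds).
#' @export
train_ensemble <- function(features, folds, spec = model_spec()) {
  models <- lapply(seq_len(nrow(folds)), function(i) {
    train_fold(features, folds[i, ], spec)
  })
  structure(list(models = models, folds = folds, spec = spec),
    class = "cms_ensemble")
}

#' @export
print.cms_ensemble <- function(x, ...) {
  cat(sprintf("<cms_ensemble> %d member models\n", length(x$models)))
  invisible(x)
}

#' @method glance cms_ensemble
#' @export
glance.cms_ensemble <- function(x, ...) {
  dplyr::bind_rows(lapply(x$models, glance))
}

#' Tile probabilities from every ensemble member
#'
#' @param ensemble A `cms_ensemble`.
#' @param features Tile-descriptor tibble.
#' @return Long tibble: one copy of the tiles per member with a `model_id`
#'   column and probability columns.
#' @export
predict_tiles_ensemble <- function(ensemble, features) {
  dplyr::bind_rows(lapply(seq_along(ensemble$models), function(i) {
    out <- predict_tiles(ensemble$models[[i]], features)
    out$model_id <- i
    out
  }))
}
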