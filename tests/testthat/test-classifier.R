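balanced_manifest <- function(n_per_cell = 10, cohorts = c("A", "B")) {
  grid <- expand.grid(cohort = cohorts, cms_label = c("CMS1", "CMS2", "CMS3", "CMS4"),
    i = seq_len(n_per_cell), stringsAsFactors = FALSE)
  tibble::tibble(
    slide_id = sprintf("s%03d", seq_len(nrow(grid))),
    patient_id = sprintf("p%03d", seq_len(nrow(grid))),
    cohort = grid$cohort,
    specimen_type = "resection",
    pixel_spacing_um = 2,
    cms_label = grid$cms_label,
    qc_pass = TRUE
  )
}

test_that("folds partition patients with cohort x class stratification", {
  m <- balanced_manifest(10) # 80 patients, 8 cells of 10
  folds <- make_folds(m, n_folds = 5, seed = 3)
  val_sets <- folds$val_patients
  # validation sets partition all patients
  expect_equal(sort(unlist(val_sets)), sort(m$patient_id))
  expect_equal(anyDuplicated(unlist(val_sets)), 0)
  # bin sizes balanced
  sizes <- lengths(val_sets)
  expect_true(max(sizes) - min(sizes) <= 1)
  # per-cell counts per bin differ by at most one from n_per_cell / n_folds
  for (f in seq_len(5)) {
    sub <- m[m$patient_id %in% val_sets[[f]], ]
    cell_counts <- table(sub$cohort, sub$cms_label)
    expect_true(all(cell_counts >= 1 & cell_counts <= 3))
  }
  # train/val disjoint within every fold
  for (f in seq_len(5)) {
    expect_length(intersect(folds$train_patients[[f]], folds$val_patients[[f]]), 0)
  }
})

test_that("folds are deterministic in the seed and guard against leakage", {
  m <- balanced_manifest(5)
  expect_equal(make_folds(m, 5, seed = 11), make_folds(m, 5, seed = 11))
  expect_false(identical(make_folds(m, 5, seed = 11), make_folds(m, 5, seed = 12)))
  expect_error(make_folds(m, 1), class = "cms_config_error")
  # two slides of one patient end up in the same bin
  m2 <- m
  m2$patient_id[2] <- m2$patient_id[1]
  folds <- suppressWarnings(make_folds(m2, 5, seed = 1))
  bins <- vapply(folds$val_patients, function(v) m2$patient_id[1] %in% v, logical(1))
  expect_equal(sum(bins), 1)
  # sparse stratum warns (one message per sparse stratum)
  m3 <- balanced_manifest(1)
  w <- capture_warnings(make_folds(m3, 5, seed = 1))
  expect_true(any(grepl("best-effort", w)))
})

test_that("augmentation is identity under an empty policy and seed-reproducible", {
  patch <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_identical(augment_patch(patch, policy = character()), patch)
  set.seed(42); a <- augment_patch(patch)
  set.seed(42); b <- augment_patch(patch)
  expect_identical(a, b)
  # flips and rotations leave a symmetric (constant) patch unchanged
  const <- solid_patch(16, c(0.3, 0.6, 0.9))
  set.seed(1)
  expect_equal(augment_patch(const, policy = c("flip", "rotate")), const)
  # geometric transforms preserve the multiset of pixel values
  set.seed(7)
  g <- augment_patch(patch, policy = c("flip", "rotate"))
  expect_equal(sort(as.vector(g)), sort(as.vector(patch)))
  expect_error(augment_patch(patch, policy = "warp"), class = "cms_config_error")
})

test_that("photometric augmentations stay in range and move the right statistics", {
  patch <- array(runif(32 * 32 * 3, 0.2, 0.8), dim = c(32, 32, 3))
  set.seed(3)
  br <- augment_patch(patch, policy = "brightness")
  expect_true(all(br >= 0 & br <= 1))
  expect_gt(abs(mean(br) - mean(patch)), 1e-4)
  set.seed(3)
  bl <- augment_patch(patch, policy = "blur")
  expect_lt(sd(bl), sd(patch)) # blur reduces variance
})

test_that("training learns the synthetic textures and selects a checkpoint", {
  tc <- tiny_cohort()
  folds <- make_folds(tc$co$manifest, n_folds = 3, seed = 5)
  spec <- model_spec(rounds = 4, iters_per_round = 30, seed = 5)
  fit <- train_fold(tc$ft, folds[1, ], spec)
  log <- tidy(fit)
  expect_equal(nrow(log), 4)
  # optimisation reduces the training loss
  expect_lt(log$train_loss[4], log$train_loss[1])
  expect_true(fit$best_round %in% seq_len(4))
  # determinism: identical training trajectory under the same seed
  fit2 <- train_fold(tc$ft, folds[1, ], spec)
  expect_equal(tidy(fit2), log)
  expect_identical(fit2$net$wts, fit$net$wts)
})

test_that("a sufficiently large model memorises a tiny tile set", {
  tc <- tiny_cohort()
  set.seed(8)
  sub <- tc$ft[sample(nrow(tc$ft), 20), ]
  sub$patient_id <- paste0("tp", seq_len(20)) # one tile per pseudo-patient
  fold <- tibble::tibble(fold_id = 1,
    train_patients = list(sub$patient_id), val_patients = list(character()))
  fit <- train_fold(sub, fold, model_spec(hidden = 12, decay = 0,
    rounds = 10, iters_per_round = 100, seed = 2))
  probs <- predict_tiles(fit, sub)
  acc <- mean(c("CMS1", "CMS2", "CMS3", "CMS4")[
    apply(as.matrix(probs[, paste0("p_", c("CMS1", "CMS2", "CMS3", "CMS4"))]),
      1, which.max)] == sub$cms_label)
  expect_equal(acc, 1.0)
})

test_that("degenerate training sets are rejected", {
  tc <- tiny_cohort()
  fold_empty <- tibble::tibble(fold_id = 1, train_patients = list(character()),
    val_patients = list(unique(tc$ft$patient_id)))
  expect_error(train_fold(tc$ft, fold_empty, model_spec()),
    class = "cms_validation_error")
  one_class <- tc$ft[tc$ft$cms_label == "CMS1", ]
  fold_one <- tibble::tibble(fold_id = 1,
    train_patients = list(unique(one_class$patient_id)),
    val_patients = list(character()))
  expect_error(train_fold(one_class, fold_one, model_spec()),
    class = "cms_validation_error")
})

test_that("tile predictions are softmax rows, order-stable and duplicate-consistent", {
  tc <- tiny_cohort()
  folds <- make_folds(tc$co$manifest, n_folds = 3, seed = 5)
  fit <- train_fold(tc$ft, folds[1, ], model_spec(rounds = 2, seed = 5))
  p <- predict_tiles(fit, tc$ft[1:10, ])
  P <- as.matrix(p[, paste0("p_", c("CMS1", "CMS2", "CMS3", "CMS4"))])
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-6)
  expect_true(all(P >= 0 & P <= 1))
  # a duplicated tile gets an identical probability row
  dup <- tc$ft[c(1, 1), ]
  Pd <- as.matrix(predict_tiles(fit, dup)[, paste0("p_", c("CMS1", "CMS2", "CMS3", "CMS4"))])
  expect_equal(Pd[1, ], Pd[2, ])
})

test_that("a zeroed network returns the uniform distribution", {
  tc <- tiny_cohort()
  folds <- make_folds(tc$co$manifest, n_folds = 3, seed = 5)
  fit <- train_fold(tc$ft, folds[1, ], model_spec(rounds = 1, seed = 5))
  fit$net$wts[] <- 0
  P <- predict_tiles(fit, tc$ft[1:3, ])
  expect_equal(as.numeric(as.matrix(P[, paste0("p_", c("CMS1", "CMS2", "CMS3", "CMS4"))])),
    rep(0.25, 12), tolerance = 1e-12)
})

test_that("texture classes are discriminable at tile level (generator self-check)", {
  # gate for all downstream synthetic experiments: a small scorer separates
  # the four textures with near-perfect held-out tile AUROC
  co_train <- synth_cohort(synth_config(seed = 61, n_per_class = 2, image_px = 256,
    heterogeneity = 0))
  co_test <- synth_cohort(synth_config(seed = 62, n_per_class = 2, image_px = 256,
    heterogeneity = 0))
  cfg <- desk_cfg()
  ft_train <- cohort_tile_features(co_train, cfg)
  ft_test <- cohort_tile_features(co_test, cfg)
  expect_gt(nrow(ft_train), 200)
  fold <- tibble::tibble(fold_id = 1,
    train_patients = list(unique(ft_train$patient_id)),
    val_patients = list(character()))
  fit <- train_fold(ft_train, fold, model_spec(rounds = 4, seed = 1))
  probs <- predict_tiles(fit, ft_test)
  ev <- macro_auroc(probs$cms_label,
    as.matrix(probs[, paste0("p_", c("CMS1", "CMS2", "CMS3", "CMS4"))]))
  expect_gte(ev$macro_auroc, 0.99)
})
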