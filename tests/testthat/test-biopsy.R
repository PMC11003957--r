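rect_mask <- function(w, h = w) {
  region(list(list(x = c(0, w, w, 0), y = c(0, 0, h, h))))
}

small_library <- function(n = 20, seed = 3) {
  synth_shape_library(n, area_range_um2 = c(30000, 70000), seed = seed)
}

test_that("single fragments satisfy the containment rule on a generous mask", {
  shapes <- small_library()
  mask <- rect_mask(512)
  set.seed(1)
  for (i in 1:20) {
    placement <- sample_event(mask, shapes, 1, spacing_um = 2, slide_id = "s")
    expect_equal(nrow(placement), 1)
    ring <- placement$polygon[[1]]
    frac <- polyclip_overlap_area(ring, unclass(mask)[[1]]) / poly_area(ring)
    expect_gte(frac, 0.95 - 1e-6)
  }
})

test_that("infeasible placements raise an explicit error naming slide and m", {
  shapes <- small_library()
  # mask of roughly one fragment: two disjoint fragments cannot fit
  tiny <- rect_mask(80) # 160 um x 160 um at 2 um/px = 25,600 um^2
  set.seed(2)
  expect_error(
    sample_event(tiny, shapes, 2, spacing_um = 2, max_attempts = 200,
      slide_id = "slideX"),
    "slideX.*2 non-overlapping",
    class = "cms_placement_error"
  )
  expect_error(sample_event(region(list()), shapes, 1),
    class = "cms_placement_error")
  expect_error(sample_event(rect_mask(512), shapes[0, ], 1),
    class = "cms_placement_error")
})

test_that("sampled fragments never overlap (polygon-boolean oracle)", {
  shapes <- small_library()
  mask <- rect_mask(400)
  set.seed(7)
  for (i in 1:50) {
    placement <- sample_event(mask, shapes, 3, spacing_um = 2, slide_id = "s")
    rings <- placement$polygon
    for (a in 1:2) for (b in (a + 1):3) {
      expect_lt(polyclip_overlap_area(rings[[a]], rings[[b]]), 1e-6)
    }
  }
})

test_that("dataset simulation counts events, inherits determinism and flags infeasible slides", {
  shapes <- small_library()
  masks <- list(sA = rect_mask(400), sB = rect_mask(420))
  cfg <- desk_cfg()
  sim1 <- simulate_biopsy_dataset(masks, shapes, m = 2, n_events_per_slide = 10,
    cfg = cfg, seed = 5)
  expect_equal(nrow(sim1), 20)
  expect_equal(unname(table(sim1$slide_id)), c(10L, 10L), ignore_attr = TRUE)
  sim2 <- simulate_biopsy_dataset(masks, shapes, m = 2, n_events_per_slide = 10,
    cfg = cfg, seed = 5)
  expect_equal(sim1$placements, sim2$placements)

  masks$sC <- rect_mask(80) # too small for m = 2
  expect_warning(
    sim3 <- simulate_biopsy_dataset(masks, shapes, m = 2, n_events_per_slide = 5,
      cfg = cfg, seed = 5, max_attempts = 100),
    "infeasible"
  )
  expect_equal(attr(sim3, "infeasible"), "sC")
  expect_error(
    suppressWarnings(simulate_biopsy_dataset(list(sC = rect_mask(80)), shapes, 2,
      5, cfg, seed = 1, max_attempts = 100)),
    class = "cms_placement_error"
  )
})

grid_probs_for <- function(sid, w, cfg, probs = c(0.7, 0.1, 0.1, 0.1),
                           n_models = 2) {
  g <- expand.grid(x = seq.int(0L, w - cfg$tile_px, cfg$stride),
    y = seq.int(0L, w - cfg$tile_px, cfg$stride))
  base <- tibble::tibble(slide_id = sid, x = as.integer(g$x), y = as.integer(g$y),
    size_px = cfg$tile_px,
    p_CMS1 = probs[1], p_CMS2 = probs[2], p_CMS3 = probs[3], p_CMS4 = probs[4])
  dplyr::bind_rows(lapply(seq_len(n_models), function(m) {
    b <- base; b$model_id <- m; b
  }))
}

test_that("a sample covering the whole mask reproduces the full-slide call", {
  cfg <- desk_cfg()
  w <- 256L
  mask <- rect_mask(w)
  # fragment shaped exactly like the mask, in micrometres
  shapes <- tibble::tibble(
    shape_id = "full",
    polygon = list(list(x = c(-256, 256, 256, -256), y = c(-256, -256, 256, 256))),
    area_um2 = 512^2, source_cohort = "T"
  )
  set.seed(3)
  sample <- sample_event(mask, shapes, 1, spacing_um = 2, rotate = FALSE,
    mirror = FALSE, containment = 0.99, max_attempts = 5000, slide_id = "s1")
  samples <- tibble::tibble(sample_id = "e1", slide_id = "s1", event = 1L,
    m = 1L, placements = list(sample))
  gp <- grid_probs_for("s1", w, cfg)
  scored <- score_biopsy_samples(samples, gp, cfg)
  full <- aggregate_slides(gp[gp$model_id == 1, ])
  expect_equal(scored$n_tiles[1], full$n_tiles)
  expect_equal(scored$p_CMS1[1], full$p_CMS1)
  expect_equal(as.character(scored$call[1]), as.character(full$call))
})

test_that("disjoint fragments retain the sum of their per-fragment tiles", {
  cfg <- desk_cfg()
  w <- 512L
  gp <- grid_probs_for("s1", w, cfg, n_models = 1)
  # two hand-placed, well-separated square fragments of 96 px side
  f1 <- list(x = c(32, 128, 128, 32), y = c(32, 32, 128, 128))
  f2 <- list(x = c(320, 416, 416, 320), y = c(320, 320, 416, 416))
  both <- tibble::tibble(sample_id = "e", slide_id = "s1", event = 1L, m = 2L,
    placements = list(tibble::tibble(fragment_id = 1:2, shape_id = "x",
      angle = 0, mirrored = FALSE, cx = 0, cy = 0, polygon = list(f1, f2))))
  single1 <- both; single1$placements <- list(both$placements[[1]][1, ]); single1$m <- 1L
  single2 <- both; single2$placements <- list(both$placements[[1]][2, ]); single2$m <- 1L
  n_both <- score_biopsy_samples(both, gp, cfg)$n_tiles[1]
  n_1 <- score_biopsy_samples(single1, gp, cfg)$n_tiles[1]
  n_2 <- score_biopsy_samples(single2, gp, cfg)$n_tiles[1]
  expect_gt(n_1, 0)
  expect_equal(n_both, n_1 + n_2)
})

test_that("fragments smaller than half a tile are unscorable", {
  cfg <- desk_cfg()
  w <- 256L
  gp <- grid_probs_for("s1", w, cfg, n_models = 1)
  tiny <- list(x = c(100, 130, 130, 100), y = c(100, 100, 125, 125)) # 750 px^2 < 2048
  samples <- tibble::tibble(sample_id = "e", slide_id = "s1", event = 1L, m = 1L,
    placements = list(tibble::tibble(fragment_id = 1L, shape_id = "x",
      angle = 0, mirrored = FALSE, cx = 0, cy = 0, polygon = list(tiny))))
  scored <- score_biopsy_samples(samples, gp, cfg)
  expect_equal(scored$n_tiles[1], 0L)
  expect_true(is.na(scored$p_CMS1[1]))
})

test_that("the convergence curve summarises per-model AUROCs and the reference gap", {
  set.seed(14)
  # synthetic scored table: m = 1 noisy scores, m = 2 perfect scores
  mk <- function(m, sharp) {
    labels <- rep(c("CMS1", "CMS2", "CMS3", "CMS4"), each = 10)
    dplyr::bind_rows(lapply(1:2, function(model) {
      P <- score_matrix(labels, sharp = sharp)
      P <- P + matrix(runif(160, 0, if (m == 1) 0.8 else 0), 40, 4)
      P <- P / rowSums(P)
      tibble::tibble(sample_id = paste0("m", m, "_", seq_len(40)),
        slide_id = "s", m = m, model_id = model, n_tiles = 5L,
        p_CMS1 = P[, 1], p_CMS2 = P[, 2], p_CMS3 = P[, 3], p_CMS4 = P[, 4],
        call = factor("CMS1", levels = c("CMS1", "CMS2", "CMS3", "CMS4")),
        cms_label = labels)
    }))
  }
  scored <- dplyr::bind_rows(mk(1, 3), mk(2, 50))
  labels <- rep(c("CMS1", "CMS2", "CMS3", "CMS4"), each = 10)
  reference <- dplyr::bind_rows(lapply(1:2, function(model) {
    P <- score_matrix(labels, sharp = 50)
    tibble::tibble(model_id = model, cms_label = labels,
      p_CMS1 = P[, 1], p_CMS2 = P[, 2], p_CMS3 = P[, 3], p_CMS4 = P[, 4])
  }))
  curve <- convergence_curve(scored, reference)
  expect_equal(curve$m, c(1, 2))
  expect_equal(curve$reference_auroc, rep(1, 2))
  expect_lte(curve$mean_auroc[1], curve$mean_auroc[2])
  expect_equal(curve$relative_gap[2], 0, tolerance = 1e-9)
  expect_gte(curve$relative_gap[1], 0)
  expect_s3_class(autoplot(curve), "ggplot")
})
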