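test_that("cohort generation is deterministic and balanced", {
  cfg <- synth_config(seed = 7, n_per_class = 2, image_px = 192)
  a <- synth_cohort(cfg)
  b <- synth_cohort(cfg)
  expect_equal(a$manifest, b$manifest)
  expect_equal(a$layouts, b$layouts)
  expect_equal(nrow(a$manifest), 8)
  expect_equal(unname(table(a$manifest$cms_label)), rep(2L, 4), ignore_attr = TRUE)
  # pixels byte-identical across renders
  img1 <- synth_slide_image(a, a$manifest$slide_id[1])
  img2 <- synth_slide_image(a, a$manifest$slide_id[1])
  expect_identical(img1, img2)
})

test_that("ambiguous heterogeneity is rejected", {
  expect_error(synth_config(heterogeneity = 0.5), class = "cms_config_error")
  expect_error(synth_config(heterogeneity = -0.1), class = "cms_config_error")
})

test_that("zero heterogeneity paints a single class texture", {
  co <- synth_cohort(synth_config(seed = 3, n_per_class = 1, image_px = 192,
    heterogeneity = 0))
  for (sid in co$manifest$slide_id) {
    expect_equal(length(co$layouts[[sid]]$blobs), 0)
  }
})

test_that("realised minority-tile fraction tracks the heterogeneity parameter", {
  h <- 0.2
  cfg <- desk_cfg()
  co <- synth_cohort(synth_config(seed = 29, n_per_class = 3, image_px = 512,
    heterogeneity = h))
  fracs <- vapply(co$manifest$slide_id, function(sid) {
    lay <- co$layouts[[sid]]
    mask <- effective_tumor_mask(co$annotations, sid)
    tiles <- extract_tiles(mask, c(512, 512), cfg, sid)
    ctr_x <- tiles$x + cfg$tile_px / 2
    ctr_y <- tiles$y + cfg$tile_px / 2
    minority <- rep(FALSE, nrow(tiles))
    for (b in lay$blobs) {
      minority <- minority | ((ctr_x - b$cx)^2 + (ctr_y - b$cy)^2 <= b$r^2)
    }
    mean(minority)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - h), 0.05)
})

test_that("biopsy-type slides carry fragment-shaped annotations", {
  co <- synth_cohort(synth_config(seed = 13, n_per_class = 0,
    n_biopsy_per_class = 1, biopsy_image_px = 256))
  expect_equal(nrow(co$manifest), 4)
  expect_true(all(co$manifest$specimen_type == "biopsy"))
  for (sid in co$manifest$slide_id) {
    polys <- co$annotations$polygon[co$annotations$slide_id == sid]
    expect_gte(length(polys), 2)
    # fragments are the tissue: the image is non-background inside them
    img <- synth_slide_image(co, sid)
    mask <- slidecms:::rasterize_region(region(polys), 256, 256)
    inside <- img[, , 1][mask]
    expect_gt(sd(inside), 0.01) # textured, not glass
  }
})

test_that("the shape library respects its area contract", {
  lib <- synth_shape_library(60, area_range_um2 = c(30000, 70000), seed = 5)
  expect_equal(nrow(lib), 60)
  expect_true(all(lib$area_um2 >= 30000 - 1 & lib$area_um2 <= 70000 + 1))
  areas <- vapply(lib$polygon, poly_area, numeric(1))
  expect_equal(areas, lib$area_um2)
  # centred on the centroid
  ctr <- slidecms:::ring_centroid(lib$polygon[[1]])
  expect_equal(ctr, c(0, 0), tolerance = 1e-6)
  # determinism and error cases
  expect_equal(synth_shape_library(5, seed = 2), synth_shape_library(5, seed = 2))
  expect_error(synth_shape_library(0), class = "cms_config_error")
  expect_error(synth_shape_library(5, area_range_um2 = c(-1, 10)),
    class = "cms_config_error")
})

test_that("shape libraries round-trip through GeoJSON", {
  lib <- synth_shape_library(8, seed = 9)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_shape_library(lib, path)
  back <- read_shape_library(path)
  expect_equal(back$shape_id, lib$shape_id)
  expect_equal(back$area_um2, lib$area_um2, tolerance = 1e-9)
})

test_that("null outcome model reproduces the baseline pCR rate", {
  manifest <- tibble::tibble(
    slide_id = paste0("s", 1:2000), patient_id = paste0("p", 1:2000),
    cohort = "A", specimen_type = "resection", pixel_spacing_um = 2,
    cms_label = rep(c("CMS1", "CMS2", "CMS3", "CMS4"), 500), qc_pass = TRUE
  )
  out <- synth_outcomes(manifest, baseline_rate = 0.25,
    log_or = c(CMS1 = 0, CMS2 = 0, CMS3 = 0, CMS4 = 0),
    stage_effects = list(t = c(T2 = 0, T3 = 0, T4 = 0),
      n = c(N0 = 0, N1 = 0, N2 = 0), cohort = 0),
    seed = 99)
  # binomial(2000, 0.25): 3 SD is ~0.029
  expect_lt(abs(mean(out$pcr) - 0.25), 0.03)
  expect_equal(out, synth_outcomes(manifest, baseline_rate = 0.25,
    log_or = c(CMS1 = 0, CMS2 = 0, CMS3 = 0, CMS4 = 0),
    stage_effects = list(t = c(T2 = 0, T3 = 0, T4 = 0),
      n = c(N0 = 0, N1 = 0, N2 = 0), cohort = 0),
    seed = 99), ignore_attr = TRUE)
  expect_error(synth_outcomes(manifest, baseline_rate = 1.2),
    class = "cms_config_error")
})

test_that("written cohorts can be consumed by the file-based readers", {
  co <- synth_cohort(synth_config(seed = 17, n_per_class = 1, image_px = 128))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(m$slide_id, co$manifest$slide_id)
  ann <- read_annotations(file.path(dir, "annotations.geojson"))
  expect_equal(sort(unique(ann$slide_id)), sort(co$manifest$slide_id))
  img <- read_slide_image(file.path(dir, paste0(m$slide_id[1], ".png")))
  ref <- synth_slide_image(co, m$slide_id[1])
  expect_equal(dim(img), dim(ref))
  expect_lt(max(abs(img - ref)), 1 / 255) # 8-bit quantisation only
})
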