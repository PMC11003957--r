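make_manifest <- function(n = 3) {
  tibble::tibble(
    slide_id = paste0("s", seq_len(n)),
    patient_id = paste0("p", seq_len(n)),
    cohort = "A",
    specimen_type = "resection",
    pixel_spacing_um = 0.5,
    cms_label = rep(c("CMS1", "CMS2", "CMS3", "CMS4"), length.out = n),
    qc_pass = TRUE
  )
}

test_that("manifest round-trips through CSV field-identically", {
  m <- make_manifest(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, path)
  expect_equal(read_manifest(path), m)
})

test_that("manifest validation rejects invariant breaches with row context", {
  m <- make_manifest(3)
  m$slide_id[2] <- "s1"
  expect_error(validate_manifest(m), "s1", class = "cms_validation_error")
  m <- make_manifest(3)
  m$cms_label[3] <- "CMS5"
  expect_error(validate_manifest(m), "cms_label", class = "cms_validation_error")
  m <- make_manifest(3)
  m$pixel_spacing_um[1] <- -1
  expect_error(validate_manifest(m), "positive", class = "cms_validation_error")
  expect_error(validate_manifest(make_manifest(2)[, -3]), "cohort",
    class = "cms_schema_error")
})

test_that("annotation GeoJSON round-trips and validates geometry", {
  ann <- tibble::tibble(
    slide_id = c("s1", "s1"),
    kind = c("tumor", "exclusion"),
    polygon = list(
      list(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100)),
      list(x = c(10, 30, 30, 10), y = c(10, 10, 30, 30))
    )
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$kind, ann$kind)
  expect_equal(poly_area(back$polygon[[1]]), 10000)

  # empty collection -> empty tibble
  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
    path, auto_unbox = TRUE)
  expect_equal(nrow(read_annotations(path)), 0)
})

test_that("zero-area rings are dropped with a warning, not an error", {
  path <- withr::local_tempfile(fileext = ".geojson")
  degenerate <- tibble::tibble(slide_id = "s1", kind = "tumor",
    polygon = list(list(x = c(0, 50, 100), y = c(0, 0, 0))))
  write_annotations(degenerate, path)
  expect_warning(out <- read_annotations(path), "zero-area")
  expect_equal(nrow(out), 0)
})

test_that("self-intersecting rings are repaired into simple pieces", {
  path <- withr::local_tempfile(fileext = ".geojson")
  bowtie <- tibble::tibble(slide_id = "s1", kind = "tumor",
    polygon = list(list(x = c(0, 10, 0, 10), y = c(0, 10, 10, 0))))
  write_annotations(bowtie, path)
  out <- read_annotations(path)
  expect_equal(nrow(out), 2) # two triangles
  expect_equal(sum(vapply(out$polygon, poly_area, numeric(1))), 50)
})

test_that("effective tumour mask subtracts exclusions", {
  ann <- tibble::tibble(
    slide_id = "s1",
    kind = c("tumor", "exclusion"),
    polygon = list(
      list(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100)),
      list(x = c(0, 50, 50, 0), y = c(0, 0, 100, 100))
    )
  )
  expect_equal(region_area(effective_tumor_mask(ann)), 5000)

  # no exclusions: unchanged
  expect_equal(region_area(effective_tumor_mask(ann[1, ])), 10000)
  # fully covered: empty mask, and no annotation at all is also empty
  ann$polygon[[2]] <- ann$polygon[[1]]
  expect_equal(region_area(effective_tumor_mask(ann)), 0)
  expect_equal(region_area(effective_tumor_mask(ann[0, ])), 0)
})

test_that("mask area equals tumour minus overlap on random polygons (raster oracle)", {
  skip_if_not_installed("mgcv")
  set.seed(31)
  for (i in 1:15) {
    # all vertices inside the 600 px raster window (radius wobble <= 1.6x)
    tum <- random_simple_polygon(runif(1, 250, 350), runif(1, 250, 350), runif(1, 80, 150))
    exc <- random_simple_polygon(runif(1, 250, 350), runif(1, 250, 350), runif(1, 40, 90))
    ann <- tibble::tibble(slide_id = "s", kind = c("tumor", "exclusion"),
      polygon = list(tum, exc))
    mask <- effective_tumor_mask(ann)
    got <- region_area(mask)
    # identity in polygon space
    expected <- poly_area(tum) -
      region_intersect_area(region(list(tum)), region(list(exc)))
    expect_equal(got, expected, tolerance = 1e-6) # Clipper quantisation
    # raster pixel-count oracle within 1%
    ras <- raster_region_area(mask, 600, 600)
    expect_lt(abs(got - ras), 0.01 * max(poly_area(tum), 1))
  }
})

test_that("pipeline config enforces its invariants and round-trips", {
  cfg <- pipeline_config()
  expect_equal(cfg$tile_px, 318L)
  expect_equal(cfg$stride, 159L)
  expect_error(pipeline_config(tile_px = 0), class = "cms_config_error")
  expect_error(pipeline_config(overlap_fraction = 1), class = "cms_config_error")
  expect_error(pipeline_config(n_folds = 1), class = "cms_config_error")
  path <- withr::local_tempfile(fileext = ".json")
  write_config(pipeline_config(tile_px = 64, rng_seed = 9), path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$tile_px, 64L)
  expect_equal(cfg2$rng_seed, 9L)
})

test_that("outcome tables validate per-patient structure", {
  out <- tibble::tibble(patient_id = c("p1", "p2"), cohort = "A",
    pcr = c(TRUE, FALSE), t_stage = "T3", n_stage = "N1",
    imcms_call = c("CMS1", "mixed"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(out, path, row.names = FALSE)
  expect_equal(nrow(read_outcomes(path)), 2)
  out$patient_id[2] <- "p1"
  expect_error(slidecms:::validate_outcomes(out), "one row",
    class = "cms_validation_error")
  out$patient_id[2] <- "p2"; out$imcms_call[1] <- "CMS9"
  expect_error(slidecms:::validate_outcomes(out), class = "cms_validation_error")
})
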