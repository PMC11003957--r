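#' Synthetic cohort configuration
#'
#' Parameters of the synthetic-slide generator used throughout the test
#' suite and the desk-scale experiments. Each pseudo-slide carries one of
#' four procedural textures (oriented sinusoidal gratings distinguished by
#' their spatial frequency, under a shared H&E-like palette) as its
#' dominant, label-defining class; a configurable fraction of the annotated
#' area is covered by blob-shaped patches of the other classes, emulating
#' intratumoural heterogeneity of tile-level class appearance. Because the
#' class cue is spatial frequency, not orientation or colour, flips,
#' rotations and photometric jitter are label-preserving, as they are for
#' real H&E textures.
#'
#' Defaults are the desk-scale study conditions: 1024 px square resection
#' pseudo-slides at 2 um/px (so ~2 x 2 mm of virtual tissue) meant to be
#' tiled at 64 px, one slide per patient, annotation covering ~60% of the
#' slide, heterogeneity 0.2.
#'
#' @param seed Master seed; everything derived from the configuration is a
#'   pure function of it.
#' @param n_per_class Resection slides (= patients) per class per cohort.
#' @param cohorts Character vector of cohort names.
#' @param n_biopsy_per_class Biopsy-specimen slides per class per cohort
#'   (small multi-fragment images).
#' @param image_px Side length of resection pseudo-slides, pixels.
#' @param biopsy_image_px Side length of biopsy pseudo-slides, pixels.
#' @param pixel_spacing_um Native pixel spacing of the pseudo-slides.
#' @param heterogeneity Fraction of the annotated area covered by
#'   minority-class texture patches; must be < 0.5 so the slide label stays
#'   the unambiguous majority class.
#' @param annotation_coverage Approximate fraction of the slide covered by
#'   the tumour annotation polygon.
#' @param n_exclusions Exclusion polygons (artefact stand-ins) per slide.
#' @param texture List: `freqs` (4 spatial frequencies, cycles/px),
#'   `amplitude`, `noise_sd`, `base` grey level.
#' @return A `cms_synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_per_class = 10L,
                         cohorts = "SYNTH-A",
                         n_biopsy_per_class = 0L,
                         image_px = 1024L,
                         biopsy_image_px = 384L,
                         pixel_spacing_um = 2.0,
                         heterogeneity = 0.2,
                         annotation_coverage = 0.6,
                         n_exclusions = 0L,
                         texture = list()) {
  if (heterogeneity >= 0.5) {
    abort("`heterogeneity` must be < 0.5: the dominant class must keep the majority of the annotated area.",
      class = "cms_config_error")
  }
  if (heterogeneity < 0) abort("`heterogeneity` must be >= 0.", class = "cms_config_error")
  if (annotation_coverage <= 0 || annotation_coverage > 0.85) {
    abort("`annotation_coverage` must lie in (0, 0.85].", class = "cms_config_error")
  }
  tex <- modifyList(list(
    freqs = c(0.055, 0.11, 0.18, 0.28),
    amplitude = 0.18,
    noise_sd = 0.06,
    base = 0.55
  ), texture)
  structure(list(
    seed = as.integer(seed),
    n_per_class = as.integer(n_per_class),
    cohorts = cohorts,
    n_biopsy_per_class = as.integer(n_biopsy_per_class),
    image_px = as.integer(image_px),
    biopsy_image_px = as.integer(biopsy_image_px),
    pixel_spacing_um = pixel_spacing_um,
    heterogeneity = heterogeneity,
    annotation_coverage = annotation_coverage,
    n_exclusions = as.integer(n_exclusions),
    texture = tex
  ), class = "cms_synth_config")
}

# blobby closed ring: mean radius r0 modulated by a few random Fourier
# harmonics, centred at (cx, cy); star-shaped, hence simple
blobby_ring <- function(cx, cy, r0, wobble = 0.12, n_vertices = 48L) {
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  mod <- rep(1, n_vertices)
  for (h in 2:4) {
    mod <- mod + wobble * runif(1, 0.3, 1) * cos(h * phi + runif(1, 0, 2 * pi))
  }
  mod <- pmax(mod, 0.2)
  list(x = cx + r0 * mod * cos(phi), y = cy + r0 * mod * sin(phi))
}

circle_ring <- function(cx, cy, r, n = 24L) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = cx + r * cos(phi), y = cy + r * sin(phi))
}

# layout of one resection pseudo-slide: annotation ring, minority blobs,
# texture phases. Pure function of the RNG state.
synth_slide_layout <- function(cfg, class_idx) {
  w <- cfg$image_px
  r0 <- w * sqrt(cfg$annotation_coverage / pi)
  ring <- blobby_ring(w / 2, w / 2, r0, wobble = 0.10)
  # clip annotation to image bounds (wobble can poke outside)
  mask <- region_intersect(region(list(ring)), region(list(rect_ring(0, 0, w, w))))
  mask_area <- region_area(mask)
  target <- cfg$heterogeneity * mask_area
  blobs <- list()
  covered <- 0
  attempts <- 0L
  while (covered < target && attempts < 2000L) {
    attempts <- attempts + 1L
    r <- runif(1, w / 16, w / 8)
    cx <- runif(1, r, w - r)
    cy <- runif(1, r, w - r)
    disk <- region(list(circle_ring(cx, cy, r)))
    if (region_intersect_area(disk, mask) < 0.98 * region_area(disk)) next
    clash <- FALSE
    for (b in blobs) {
      if ((cx - b$cx)^2 + (cy - b$cy)^2 < (r + b$r)^2) { clash <- TRUE; break }
    }
    if (clash) next
    blobs[[length(blobs) + 1L]] <- list(
      cx = cx, cy = cy, r = r,
      class_idx = sample(setdiff(1:4, class_idx), 1L),
      theta = runif(1, 0, pi), phase = runif(1, 0, 2 * pi)
    )
    covered <- covered + region_area(disk)
  }
  exclusions <- list()
  if (cfg$n_exclusions > 0) {
    for (k in seq_len(cfg$n_exclusions)) {
      er <- runif(1, w / 24, w / 12)
      exclusions[[k]] <- circle_ring(runif(1, er, w - er), runif(1, er, w - er), er, n = 16L)
    }
  }
  list(
    annotation = ring, exclusions = exclusions, blobs = blobs,
    base_theta = runif(1, 0, pi), base_phase = runif(1, 0, 2 * pi),
    pixel_seed = sample.int(2^30, 1L)
  )
}

# layout of one biopsy pseudo-slide: 2-3 elongated fragments on background
synth_biopsy_layout <- function(cfg, class_idx) {
  w <- cfg$biopsy_image_px
  n_frag <- sample(2:3, 1L)
  frags <- list()
  guard <- 0L
  while (length(frags) < n_frag && guard < 500L) {
    guard <- guard + 1L
    len <- runif(1, w * 0.35, w * 0.55)
    wid <- len / runif(1, 2, 3.5)
    ring <- fragment_ring(len / 2, wid / 2)
    ring <- transform_ring(ring, angle = runif(1, 0, pi),
      dx = runif(1, len / 2, w - len / 2), dy = runif(1, len / 2, w - len / 2))
    cand <- region(list(ring))
    bb <- region_bbox(cand)
    if (bb["xmin"] < 2 || bb["ymin"] < 2 || bb["xmax"] > w - 2 || bb["ymax"] > w - 2) next
    ok <- TRUE
    for (f in frags) {
      if (region_intersect_area(cand, region(list(f))) > 0) { ok <- FALSE; break }
    }
    if (!ok) next
    frags[[length(frags) + 1L]] <- ring
  }
  list(
    fragments = frags,
    thetas = runif(length(frags), 0, pi), phases = runif(length(frags), 0, 2 * pi),
    pixel_seed = sample.int(2^30, 1L)
  )
}

# perturbed half-ellipse outline used for biopsy fragments (axes a >= b)
fragment_ring <- function(a, b, wobble = 0.12, n_vertices = 24L) {
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  mod <- rep(1, n_vertices)
  for (h in 2:3) {
    mod <- mod + wobble * runif(1, 0.3, 1) * cos(h * phi + runif(1, 0, 2 * pi))
  }
  mod <- pmax(mod, 0.3)
  list(x = a * mod * cos(phi), y = b * mod * sin(phi))
}

#' Generate a synthetic cohort
#'
#' Builds the manifest, annotations and per-slide texture layouts for a
#' seeded synthetic cohort. Pixel data are generated lazily by
#' [synth_slide_image()] so that arbitrarily many slides can be processed
#' in bounded memory; [write_cohort()] materialises everything to disk.
#'
#' @param cfg A [synth_config()].
#' @return A `cms_synth_cohort`: list with `manifest` (tibble),
#'   `annotations` (tibble), `layouts` (per-slide), and `config`.
#' @examples
#' co <- synth_cohort(synth_config(seed = 7, n_per_class = 1, image_px = 256))
#' co$manifest
#' @export
synth_cohort <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "cms_synth_config"))
  with_local_seed(cfg$seed, {
    rows <- list(); anns <- list(); layouts <- list()
    for (cohort in cfg$cohorts) {
      for (class_idx in 1:4) {
        for (i in seq_len(cfg$n_per_class)) {
          sid <- sprintf("%s_%s_R%02d", cohort, CMS_CLASSES[class_idx], i)
          lay <- synth_slide_layout(cfg, class_idx)
          lay$class_idx <- class_idx
          lay$specimen_type <- "resection"
          layouts[[sid]] <- lay
          rows[[length(rows) + 1L]] <- tibble::tibble(
            slide_id = sid, patient_id = paste0("PT_", sid), cohort = cohort,
            specimen_type = "resection",
            pixel_spacing_um = cfg$pixel_spacing_um,
            cms_label = CMS_CLASSES[class_idx], qc_pass = TRUE
          )
          anns[[length(anns) + 1L]] <- tibble::tibble(
            slide_id = sid, kind = "tumor", polygon = list(lay$annotation)
          )
          for (ex in lay$exclusions) {
            anns[[length(anns) + 1L]] <- tibble::tibble(
              slide_id = sid, kind = "exclusion", polygon = list(ex)
            )
          }
        }
        for (i in seq_len(cfg$n_biopsy_per_class)) {
          sid <- sprintf("%s_%s_B%02d", cohort, CMS_CLASSES[class_idx], i)
          lay <- synth_biopsy_layout(cfg, class_idx)
          lay$class_idx <- class_idx
          lay$specimen_type <- "biopsy"
          layouts[[sid]] <- lay
          rows[[length(rows) + 1L]] <- tibble::tibble(
            slide_id = sid, patient_id = paste0("PT_", sid), cohort = cohort,
            specimen_type = "biopsy",
            pixel_spacing_um = cfg$pixel_spacing_um,
            cms_label = CMS_CLASSES[class_idx], qc_pass = TRUE
          )
          for (fr in lay$fragments) {
            anns[[length(anns) + 1L]] <- tibble::tibble(
              slide_id = sid, kind = "tumor", polygon = list(fr)
            )
          }
        }
      }
    }
    structure(list(
      manifest = validate_manifest(dplyr::bind_rows(rows)),
      annotations = dplyr::bind_rows(anns),
      layouts = layouts,
      config = cfg
    ), class = "cms_synth_cohort")
  })
}

#' @export
print.cms_synth_cohort <- function(x, ...) {
  cat(sprintf("<cms_synth_cohort> %d slides (%d resection, %d biopsy), seed %d\n",
    nrow(x$manifest), sum(x$manifest$specimen_type == "resection"),
    sum(x$manifest$specimen_type == "biopsy"), x$config$seed))
  invisible(x)
}

# oriented sinusoid + white noise texture for one class over given
# pixel-centre coordinate matrices
texture_values <- function(xg, yg, tex, class_idx, theta, phase, noise) {
  f <- tex$freqs[class_idx]
  v <- tex$base + tex$amplitude *
    sin(2 * pi * f * (xg * cos(theta) + yg * sin(theta)) + phase) + noise
  v
}

he_palette <- function(v) {
  v <- clamp01(v)
  dark <- c(0.42, 0.18, 0.48) # haematoxylin-ish purple
  light <- c(0.96, 0.82, 0.90) # eosin-ish pink
  list(
    r = dark[1] + (light[1] - dark[1]) * v,
    g = dark[2] + (light[2] - dark[2]) * v,
    b = dark[3] + (light[3] - dark[3]) * v
  )
}

#' Render the pixels of one synthetic slide
#'
#' Deterministically regenerates a slide's RGB pixel array from its stored
#' layout and per-slide seed. Identical calls return byte-identical arrays.
#'
#' @param cohort A `cms_synth_cohort`.
#' @param slide_id Slide to render.
#' @return `H x W x 3` numeric array in `[0, 1]`.
#' @export
synth_slide_image <- function(cohort, slide_id) {
  lay <- cohort$layouts[[slide_id]]
  if (is.null(lay)) abort(sprintf("Unknown slide_id '%s'.", slide_id), class = "cms_io_error")
  cfg <- cohort$config
  tex <- cfg$texture
  w <- if (lay$specimen_type == "resection") cfg$image_px else cfg$biopsy_image_px
  with_local_seed(lay$pixel_seed, {
    xg <- matrix(rep(seq_len(w) - 0.5, each = w), nrow = w) # [row, col] = x of col
    yg <- matrix(rep(seq_len(w) - 0.5, times = w), nrow = w)
    noise <- matrix(rnorm(w * w, 0, tex$noise_sd), nrow = w)
    if (lay$specimen_type == "resection") {
      v <- texture_values(xg, yg, tex, lay$class_idx, lay$base_theta, lay$base_phase, noise)
      for (b in lay$blobs) {
        sel <- (xg - b$cx)^2 + (yg - b$cy)^2 <= b$r^2
        if (any(sel)) {
          v[sel] <- texture_values(xg[sel], yg[sel], tex, b$class_idx,
            b$theta, b$phase, noise[sel])
        }
      }
    } else {
      v <- matrix(NA_real_, w, w)
      for (k in seq_along(lay$fragments)) {
        # raster and v share the image indexing [row = y + 1, col = x + 1]
        fr <- rasterize_region(region(list(lay$fragments[[k]])), w, w)
        idx <- which(fr)
        if (length(idx) > 0) {
          # coordinates of those pixels
          rows <- ((idx - 1L) %% w) + 1L
          cols <- ((idx - 1L) %/% w) + 1L
          xs <- cols - 0.5; ys <- rows - 0.5
          v[idx] <- texture_values(xs, ys, tex, lay$class_idx,
            lay$thetas[k], lay$phases[k], noise[idx])
        }
      }
    }
    pal <- he_palette(v)
    img <- array(0.97, dim = c(w, w, 3)) # background: near-white glass
    bg <- is.na(v)
    img[, , 1][!bg] <- pal$r[!bg]
    img[, , 2][!bg] <- pal$g[!bg]
    img[, , 3][!bg] <- pal$b[!bg]
    img
  })
}

#' Write a synthetic cohort to disk
#'
#' Materialises the manifest (CSV), annotations (GeoJSON) and slide images
#' (PNG, named `<slide_id>.png`) of a synthetic cohort, producing exactly
#' the on-disk inputs the command-line pipeline consumes.
#'
#' @param cohort A `cms_synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.csv"))
  write_annotations(cohort$annotations, file.path(dir, "annotations.geojson"))
  for (sid in cohort$manifest$slide_id) {
    png::writePNG(synth_slide_image(cohort, sid), file.path(dir, paste0(sid, ".png")))
  }
  invisible(dir)
}

#' Generate a biopsy fragment shape library
#'
#' Emulates a library of real biopsy fragment outlines with elongated,
#' smoothly-perturbed ellipse polygons. Shapes are stored in local
#' micrometre coordinates centred at their area centroid; placement code
#' rotates, mirrors and translates them. The default library size matches
#' the published pool of 1580 annotated fragment outlines.
#'
#' @param n_shapes Number of shapes.
#' @param area_range_um2 Two-element range of fragment areas (um^2), sampled
#'   uniformly. The default 30,000-70,000 um^2 corresponds to 2-4 tile
#'   areas at the desk-scale working resolution.
#' @param elongation_range Range of the major/minor axis ratio.
#' @param source_cohort Cohort tag stored per shape.
#' @param seed RNG seed.
#' @return A tibble: `shape_id`, `polygon` (list of `list(x, y)` in um),
#'   `area_um2`, `source_cohort`.
#' @export
synth_shape_library <- function(n_shapes = 1580L,
                                area_range_um2 = c(30000, 70000),
                                elongation_range = c(1.5, 3),
                                source_cohort = "SYNTH-A",
                                seed = 1L) {
  if (n_shapes < 1) abort("`n_shapes` must be >= 1.", class = "cms_config_error")
  if (diff(range(area_range_um2)) < 0 || min(area_range_um2) <= 0) {
    abort("`area_range_um2` must be a positive, non-degenerate range.",
      class = "cms_config_error")
  }
  with_local_seed(seed, {
    shapes <- lapply(seq_len(n_shapes), function(i) {
      elong <- runif(1, elongation_range[1], elongation_range[2])
      ring <- fragment_ring(elong, 1)
      target <- runif(1, area_range_um2[1], area_range_um2[2])
      s <- sqrt(target / poly_area(ring))
      ring <- list(x = ring$x * s, y = ring$y * s)
      ctr <- ring_centroid(ring)
      list(x = ring$x - ctr[1], y = ring$y - ctr[2])
    })
    tibble::tibble(
      shape_id = sprintf("shape_%04d", seq_len(n_shapes)),
      polygon = shapes,
      area_um2 = vapply(shapes, poly_area, numeric(1)),
      source_cohort = source_cohort
    )
  })
}

#' Generate a synthetic outcome table
#'
#' Draws a pathological-complete-response (pCR) indicator for each patient
#' from a logistic model with designed per-class effects and categorical
#' T-stage, N-stage and cohort covariates, emulating the structure of the
#' clinical response analysis (two merged cohorts, pCR rates of order
#' 15-25%). The generating parameters are attached as `attr(x, "truth")`
#' so estimator-recovery tests can compare against them.
#'
#' @param manifest Manifest tibble (one patient per row is assumed for
#'   resection cohorts; duplicated patients are collapsed to their first
#'   slide's label).
#' @param baseline_rate pCR probability at the reference covariate level
#'   for a patient outside all elevated-risk classes.
#' @param log_or Named 4-vector of per-class log odds ratios (one-vs-rest).
#' @param stage_effects List with `t` and `n` named numeric vectors of
#'   stage effects on the log-odds scale, and `cohort` a scalar effect of
#'   the second cohort.
#' @param calls Optional vector of case-level calls to use instead of
#'   `cms_label` (may include `"mixed"`).
#' @param seed RNG seed.
#' @return Tibble of outcome records: `patient_id`, `cohort`, `pcr`,
#'   `t_stage`, `n_stage`, `imcms_call`.
#' @export
synth_outcomes <- function(manifest,
                           baseline_rate = 0.18,
                           log_or = c(CMS1 = log(2.69), CMS2 = 0, CMS3 = 0, CMS4 = log(0.25)),
                           stage_effects = list(
                             t = c(T2 = 0.3, T3 = 0, T4 = -0.5),
                             n = c(N0 = 0.3, N1 = 0, N2 = -0.4),
                             cohort = -0.2
                           ),
                           calls = NULL,
                           seed = 1L) {
  if (baseline_rate <= 0 || baseline_rate >= 1) {
    abort("`baseline_rate` must lie strictly inside (0, 1).", class = "cms_config_error")
  }
  pts <- manifest[!duplicated(manifest$patient_id), ]
  call <- if (is.null(calls)) pts$cms_label else as.character(calls)
  stopifnot(length(call) == nrow(pts))
  with_local_seed(seed, {
    t_stage <- sample(names(stage_effects$t), nrow(pts), replace = TRUE,
      prob = c(0.2, 0.6, 0.2))
    n_stage <- sample(names(stage_effects$n), nrow(pts), replace = TRUE,
      prob = c(0.4, 0.4, 0.2))
    cohort2 <- as.integer(pts$cohort != pts$cohort[1])
    eta <- qlogis(baseline_rate) +
      ifelse(call %in% names(log_or), log_or[call], 0) +
      stage_effects$t[t_stage] + stage_effects$n[n_stage] +
      stage_effects$cohort * cohort2
    out <- tibble::tibble(
      patient_id = pts$patient_id,
      cohort = pts$cohort,
      pcr = rbinom(nrow(pts), 1, plogis(eta)) == 1,
      t_stage = t_stage,
      n_stage = n_stage,
      imcms_call = call
    )
    attr(out, "truth") <- list(baseline_rate = baseline_rate, log_or = log_or,
      stage_effects = stage_effects)
    out
  })
}
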