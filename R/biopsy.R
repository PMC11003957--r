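#' Read / write a biopsy fragment shape library (GeoJSON)
#'
#' Shape libraries are GeoJSON FeatureCollections of polygons in local
#' micrometre coordinates (centred on the fragment centroid), with
#' properties `shape_id` and `source_cohort`.
#'
#' @param path GeoJSON file path.
#' @return A shape library tibble (`shape_id`, `polygon`, `area_um2`,
#'   `source_cohort`).
#' @export
read_shape_library <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map(gj$features, function(f) {
    ring_coords <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring_coords, function(pt) c(pt[[1]], pt[[2]])))
    ring <- as_ring(xy)
    tibble::tibble(
      shape_id = f$properties$shape_id,
      polygon = list(ring),
      area_um2 = poly_area(ring),
      source_cohort = f$properties$source_cohort %||% NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_shape_library
#' @param shapes A shape library tibble.
#' @export
write_shape_library <- function(shapes, path) {
  features <- purrr::pmap(shapes, function(shape_id, polygon, source_cohort, ...) {
    r <- as_ring(polygon)
    coords <- lapply(seq_along(r$x), function(k) list(r$x[k], r$y[k]))
    coords[[length(coords) + 1L]] <- coords[[1L]]
    list(type = "Feature",
      properties = list(shape_id = shape_id, source_cohort = source_cohort),
      geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Place one virtual biopsy sample
#'
#' Draws `m` fragment shapes uniformly with replacement from the library,
#' randomly rotates/mirrors each, and places them sequentially at
#' translations drawn uniformly over the tumour-mask bounding box,
#' rejecting placements that violate the containment rule (at least
#' `containment` of the fragment area inside the mask) or overlap a
#' previously placed fragment. Placement fails with an explicit
#' infeasibility error after `max_attempts` rejections for any fragment.
#'
#' @param mask `cms_region` tumour mask in working-resolution pixels.
#' @param shapes Shape library tibble (polygons in micrometres).
#' @param m Number of fragments.
#' @param spacing_um Working pixel spacing, to convert shape coordinates
#'   to pixels.
#' @param containment Minimum in-mask area fraction per fragment.
#' @param rotate,mirror Randomise fragment orientation / chirality.
#' @param max_attempts Rejection budget per fragment.
#' @param slide_id Used in error messages.
#' @return Tibble with one row per placed fragment: `fragment_id`,
#'   `shape_id`, `angle`, `mirrored`, `cx`, `cy` and `polygon` (the placed
#'   ring in working pixels).
#' @export
sample_event <- function(mask, shapes, m, spacing_um = 2.0,
                         containment = 0.95, rotate = TRUE, mirror = TRUE,
                         max_attempts = 1000L, slide_id = NA_character_) {
  if (length(mask) == 0) {
    abort("Cannot sample from an empty tumour mask.", class = "cms_placement_error")
  }
  if (nrow(shapes) == 0) abort("Empty shape library.", class = "cms_placement_error")
  stopifnot(m >= 1)
  bb <- region_bbox(mask)
  tris <- attr(mask, "triangles")
  if (is.null(tris)) tris <- region_triangles(mask)
  scale <- 1 / spacing_um
  placed <- vector("list", m)
  shape_id <- character(m); angle <- numeric(m); mirrored <- logical(m)
  cxs <- numeric(m); cys <- numeric(m)
  for (fragment in seq_len(m)) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      si <- sample.int(nrow(shapes), 1L)
      ang <- if (rotate) runif(1, 0, 2 * pi) else 0
      mir <- if (mirror) runif(1) < 0.5 else FALSE
      cx <- unname(runif(1, bb["xmin"], bb["xmax"]))
      cy <- unname(runif(1, bb["ymin"], bb["ymax"]))
      ring <- transform_ring(as_ring(shapes$polygon[[si]]), angle = ang,
        mirror = mir, dx = cx, dy = cy, scale = scale)
      a <- abs(ring_signed_area(ring))
      if (cpp_region_poly_area(tris, ring$x, ring$y) < containment * a) next
      clash <- FALSE
      for (p in placed) {
        if (is.null(p)) break
        if (cpp_polys_overlap(ring$x, ring$y, p$x, p$y)) { clash <- TRUE; break }
      }
      if (clash) next
      placed[[fragment]] <- ring
      shape_id[fragment] <- shapes$shape_id[si]
      angle[fragment] <- ang; mirrored[fragment] <- mir
      cxs[fragment] <- cx; cys[fragment] <- cy
      ok <- TRUE
      break
    }
    if (!ok) {
      abort(sprintf(
        "Infeasible placement: slide %s cannot host %d non-overlapping fragment(s) (fragment %d rejected %d times).",
        slide_id, m, fragment, max_attempts), class = "cms_placement_error")
    }
  }
  tibble::tibble(
    fragment_id = seq_len(m), shape_id = shape_id, angle = angle,
    mirrored = mirrored, cx = cxs, cy = cys, polygon = placed
  )
}

#' Simulate a virtual biopsy dataset
#'
#' Draws `n_events_per_slide` independent sampling events of `m` fragments
#' from every resection slide's tumour mask. Slides whose mask cannot host
#' `m` fragments are logged as infeasible (attribute `"infeasible"`) and
#' skipped; it is an error for every slide to be infeasible.
#'
#' @param masks Named list of `cms_region` masks (working pixels), one per
#'   slide.
#' @param shapes Shape library tibble.
#' @param m Fragments per sampling event.
#' @param n_events_per_slide Events per slide (the published experiment
#'   uses 10,000).
#' @param cfg A [pipeline_config()]; supplies the working spacing.
#' @param seed RNG seed.
#' @param ... Passed to [sample_event()].
#' @return Tibble: `sample_id`, `slide_id`, `event`, `m`, `placements`
#'   (list-column of placement tibbles).
#' @export
simulate_biopsy_dataset <- function(masks, shapes, m,
                                    n_events_per_slide = 10000L,
                                    cfg = pipeline_config(), seed = 1L, ...) {
  stopifnot(length(masks) > 0, !is.null(names(masks)))
  out <- list()
  infeasible <- character()
  with_local_seed(derive_seed(seed, m), {
    for (sid in names(masks)) {
      mask <- with_triangles(masks[[sid]])
      events <- vector("list", n_events_per_slide)
      failed <- FALSE
      for (e in seq_len(n_events_per_slide)) {
        res <- tryCatch(
          sample_event(mask, shapes, m,
            spacing_um = cfg$target_spacing_um, slide_id = sid, ...),
          cms_placement_error = function(cnd) cnd
        )
        if (inherits(res, "condition")) { failed <- TRUE; break }
        events[[e]] <- res
      }
      if (failed) {
        infeasible <- c(infeasible, sid)
        next
      }
      out[[sid]] <- tibble::tibble(
        sample_id = sprintf("%s_m%d_e%05d", sid, m, seq_len(n_events_per_slide)),
        slide_id = sid, event = seq_len(n_events_per_slide), m = m,
        placements = events
      )
    }
  })
  if (length(out) == 0) {
    abort(sprintf("All slides are infeasible for m = %d fragments.", m),
      class = "cms_placement_error")
  }
  if (length(infeasible) > 0) {
    warn(sprintf("Slide(s) infeasible for m = %d and skipped: %s", m,
      paste(infeasible, collapse = ", ")))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "infeasible") <- infeasible
  res
}

#' Score virtual biopsy samples
#'
#' Applies the classification pipeline to each sampling event: the union
#' of the placed fragments acts as the annotation mask, tiles are retained
#' under the same stage-1 rule (tile area inside the fragment union at or
#' above the retention threshold), and retained tile probabilities are
#' averaged into a slide call per ensemble member. Because the tile grid
#' is deterministic, tile probabilities are looked up from a precomputed
#' full-grid table rather than recomputed per event. Events retaining no
#' tile are recorded as unscorable (`n_tiles = 0`, `NA` probabilities).
#'
#' @param samples Output of [simulate_biopsy_dataset()].
#' @param grid_probs Long tibble of full-grid tile probabilities per
#'   ensemble member: `slide_id`, `x`, `y`, `size_px`, `model_id`,
#'   `p_CMS1`..`p_CMS4` (see [cohort_tile_features()] with
#'   `grid = "full"` and [predict_tiles_ensemble()]).
#' @param cfg A [pipeline_config()].
#' @return Long tibble: one row per sample x member with `n_tiles`, mean
#'   probabilities and `call`.
#' @export
score_biopsy_samples <- function(samples, grid_probs, cfg = pipeline_config()) {
  pc <- prob_cols()
  tpx <- cfg$tile_px
  tile_area <- as.numeric(tpx)^2
  out <- list()
  for (sid in unique(samples$slide_id)) {
    g <- grid_probs[grid_probs$slide_id == sid, ]
    if (nrow(g) == 0) {
      abort(sprintf("No grid probabilities for slide %s.", sid),
        class = "cms_validation_error")
    }
    models <- sort(unique(g$model_id))
    tiles <- g[g$model_id == models[1], c("x", "y")]
    P <- array(NA_real_, dim = c(nrow(tiles), 4, length(models)))
    for (mi in seq_along(models)) {
      gm <- g[g$model_id == models[mi], ]
      stopifnot(nrow(gm) == nrow(tiles))
      P[, , mi] <- as.matrix(gm[pc])
    }
    ss <- samples[samples$slide_id == sid, ]
    nm <- length(models)
    n_rows <- nrow(ss) * nm
    col_sample <- character(n_rows); col_m <- integer(n_rows)
    col_model <- integer(n_rows); col_ntiles <- integer(n_rows)
    col_probs <- matrix(NA_real_, n_rows, 4)
    col_call <- character(n_rows)
    for (i in seq_len(nrow(ss))) {
      rings <- ss$placements[[i]]$polygon
      # fragments are pairwise disjoint, so the union overlap is the sum of
      # per-fragment tile overlaps
      area <- numeric(nrow(tiles))
      for (r in rings) {
        cand <- which(tiles$x + tpx > min(r$x) & tiles$x < max(r$x) &
          tiles$y + tpx > min(r$y) & tiles$y < max(r$y))
        if (length(cand) > 0) {
          area[cand] <- area[cand] +
            cpp_rect_clip_areas(tiles$x[cand], tiles$y[cand], tpx, r$x, r$y)
        }
      }
      keep <- which(area / tile_area >= cfg$min_in_region_fraction)
      at <- (i - 1L) * nm + seq_len(nm)
      col_sample[at] <- ss$sample_id[i]
      col_m[at] <- ss$m[i]
      col_model[at] <- models
      col_ntiles[at] <- length(keep)
      if (length(keep) > 0) {
        probs <- t(apply(P[keep, , , drop = FALSE], c(2, 3), mean)) # model x class
        col_probs[at, ] <- probs
        col_call[at] <- CMS_CLASSES[apply(probs, 1, function(v) argmax_tie(v)$index)]
      } else {
        col_call[at] <- NA_character_
      }
    }
    out[[sid]] <- tibble::tibble(
      sample_id = col_sample, slide_id = sid, m = col_m, model_id = col_model,
      n_tiles = col_ntiles,
      p_CMS1 = col_probs[, 1], p_CMS2 = col_probs[, 2],
      p_CMS3 = col_probs[, 3], p_CMS4 = col_probs[, 4],
      call = factor(col_call, levels = CMS_CLASSES)
    )
  }
  dplyr::bind_rows(out)
}

#' Convergence of biopsy-sample performance towards full resections
#'
#' Summarises scored sampling events into the performance-vs-fragment-count
#' curve: for each fragment count `m` and ensemble member, the macro
#' one-vs-rest AUROC over all scored events (each event labeled with its
#' source slide's class); the curve reports mean and SD over members and
#' the relative gap to the full-resection reference AUROC.
#'
#' @param scored Scored events from [score_biopsy_samples()] (any number
#'   of `m` values bound together) joined with a `cms_label` column.
#' @param reference Per-member slide calls on the fully imaged resections:
#'   tibble with `model_id`, `cms_label` and probability columns.
#' @return A `cms_sim_curve` tibble: `m`, `mean_auroc`, `sd_auroc`,
#'   `reference_auroc`, `relative_gap`, plus attributes `per_model` and
#'   `n_unscorable`.
#' @export
convergence_curve <- function(scored, reference) {
  pc <- prob_cols()
  if (!"cms_label" %in% names(scored)) {
    abort("`scored` must carry a cms_label column (source-slide label).",
      class = "cms_validation_error")
  }
  n_unscorable <- sum(scored$n_tiles == 0) / max(1, length(unique(scored$model_id)))
  usable <- scored[scored$n_tiles > 0, ]
  ref_by_model <- reference %>%
    group_by(.data$model_id) %>%
    group_split() %>%
    purrr::map_dbl(function(d) macro_auroc(d$cms_label, as.matrix(d[pc]))$macro_auroc)
  reference_auroc <- mean(ref_by_model)
  per_model <- usable %>%
    group_by(.data$m, .data$model_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      tibble::tibble(m = d$m[1], model_id = d$model_id[1],
        macro_auroc = macro_auroc(d$cms_label, as.matrix(d[pc]))$macro_auroc,
        n_events = nrow(d))
    }) %>%
    dplyr::bind_rows()
  curve <- per_model %>%
    group_by(.data$m) %>%
    summarise(
      mean_auroc = mean(.data$macro_auroc),
      sd_auroc = sd(.data$macro_auroc),
      .groups = "drop"
    ) %>%
    mutate(
      reference_auroc = reference_auroc,
      relative_gap = (reference_auroc - .data$mean_auroc) / reference_auroc
    ) %>%
    arrange(.data$m)
  structure(curve, class = c("cms_sim_curve", class(curve)),
    per_model = per_model, n_unscorable = n_unscorable)
}
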