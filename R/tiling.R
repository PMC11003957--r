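#' Extract annotation-restricted tiles (stage 1)
#'
#' Enumerates the deterministic overlapping tile grid of a slide at the
#' working resolution and keeps the tiles whose overlap with the tumour
#' mask meets the retention threshold. The grid is anchored at pixel
#' `(0, 0)`, strides by `round(tile_px * (1 - overlap_fraction))`, and only
#' contains tiles fully inside the image bounds. The overlap fraction is
#' computed exactly in polygon space (tile rectangle intersected with the
#' mask region) rather than on a raster. Tiles are returned in row-major
#' order (by `y`, then `x`).
#'
#' With the default configuration (318 px tiles at 2 um/px, 50% overlap,
#' retention at >= 50% in-mask area) this reproduces the published stage-1
#' tiling: 636 um tile side and stride 159 px.
#'
#' @param mask `cms_region` tumour mask in working-resolution pixels (see
#'   [effective_tumor_mask()] and [scale_mask_to_target()]).
#' @param image_dim Integer `c(width, height)` of the slide at the working
#'   resolution.
#' @param cfg A [pipeline_config()].
#' @param slide_id Slide identifier copied into the output.
#' @return A tibble with columns `slide_id`, `x`, `y`, `size_px`,
#'   `in_region_fraction`.
#' @export
extract_tiles <- function(mask, image_dim, cfg = pipeline_config(),
                          slide_id = NA_character_) {
  w <- as.integer(image_dim[1])
  h <- as.integer(image_dim[2])
  t <- cfg$tile_px
  empty <- tibble::tibble(slide_id = character(), x = integer(), y = integer(),
    size_px = integer(), in_region_fraction = numeric())
  if (t > w || t > h) {
    warn(sprintf("Tile size %d px exceeds the %d x %d image; no tiles.", t, w, h))
    return(empty)
  }
  if (length(mask) == 0) return(empty)
  xs <- seq.int(0L, w - t, by = cfg$stride)
  ys <- seq.int(0L, h - t, by = cfg$stride)
  bb <- region_bbox(mask)
  # bounding-box prefilter: a tile disjoint from the mask bbox has fraction 0
  xs <- xs[xs + t > bb["xmin"] & xs < bb["xmax"]]
  ys <- ys[ys + t > bb["ymin"] & ys < bb["ymax"]]
  if (length(xs) == 0 || length(ys) == 0) return(empty)
  grid <- expand.grid(x = xs, y = ys) # x varies fastest -> row-major
  tile_area <- as.numeric(t)^2
  # exact polygon-space overlap: signed sum over rings of the clipped area
  area <- numeric(nrow(grid))
  for (r in mask) {
    s <- if (ring_signed_area(r) >= 0) 1 else -1
    area <- area + s * cpp_rect_clip_areas(grid$x, grid$y, t, r$x, r$y)
  }
  frac <- area / tile_area
  keep <- frac >= cfg$min_in_region_fraction
  tibble::tibble(
    slide_id = slide_id,
    x = as.integer(grid$x[keep]),
    y = as.integer(grid$y[keep]),
    size_px = t,
    in_region_fraction = pmin(frac[keep], 1)
  )
}

#' Rescale a native-pixel mask to the working resolution
#'
#' @param mask `cms_region` in native pixels.
#' @param native_spacing_um Native micrometres per pixel.
#' @param cfg A [pipeline_config()]; supplies the working spacing.
#' @return A `cms_region` in working-resolution pixels.
#' @export
scale_mask_to_target <- function(mask, native_spacing_um, cfg = pipeline_config()) {
  scale_region(mask, native_spacing_um / cfg$target_spacing_um)
}
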