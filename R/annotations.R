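#' Read and write region annotations (GeoJSON)
#'
#' Tumour-region and exclusion annotations are exchanged as a GeoJSON
#' `FeatureCollection` of `Polygon`/`MultiPolygon` features with properties
#' `slide_id` and `kind` (`"tumor"` or `"exclusion"`), coordinates in native
#' pixels of the annotated slide. On read, each ring is validated: zero-area
#' rings are dropped with a warning, self-intersecting rings are repaired by
#' splitting into simple pieces, and interior (hole) rings are honoured via
#' the even-odd fill rule.
#'
#' @param path Path to a GeoJSON file.
#' @return A tibble with columns `slide_id`, `kind` and `polygon` (a
#'   list-column of `list(x, y)` rings).
#' @export
read_annotations <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    abort("Annotation file must be a GeoJSON FeatureCollection.",
      class = "cms_schema_error")
  }
  rows <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    props <- f$properties
    if (is.null(props$slide_id) || is.null(props$kind)) {
      abort(sprintf("Feature %d lacks slide_id/kind properties.", i),
        class = "cms_schema_error")
    }
    if (!props$kind %in% c("tumor", "exclusion")) {
      abort(sprintf("Feature %d: kind must be 'tumor' or 'exclusion'.", i),
        class = "cms_validation_error")
    }
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      abort(sprintf("Feature %d: unsupported geometry type '%s'.", i, geom$type),
        class = "cms_schema_error")
    )
    for (poly in polys) {
      for (ring_coords in poly) {
        xy <- do.call(rbind, lapply(ring_coords, function(pt) c(pt[[1]], pt[[2]])))
        if (nrow(xy) < 4) { # open ring with < 3 distinct vertices
          warn(sprintf("Feature %d: ring with fewer than 3 vertices dropped.", i))
          next
        }
        cleaned <- clean_polygon(xy)
        if (length(cleaned) == 0) {
          warn(sprintf("Feature %d: zero-area ring dropped.", i))
          next
        }
        for (clean in cleaned) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            slide_id = as.character(props$slide_id),
            kind = props$kind,
            polygon = list(clean)
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(slide_id = character(), kind = character(),
      polygon = list()))
  }
  dplyr::bind_rows(rows)
}

#' @rdname read_annotations
#' @param annotations An annotation tibble (`slide_id`, `kind`, `polygon`).
#' @export
write_annotations <- function(annotations, path) {
  features <- purrr::pmap(annotations, function(slide_id, kind, polygon, ...) {
    r <- as_ring(polygon)
    coords <- lapply(seq_along(r$x), function(k) list(r$x[k], r$y[k]))
    coords[[length(coords) + 1L]] <- coords[[1L]] # close the ring
    list(
      type = "Feature",
      properties = list(slide_id = slide_id, kind = kind),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Effective tumour mask for one slide
#'
#' The scoring mask is the union of a slide's tumour polygons minus the
#' union of its exclusion polygons (folds, debris, artefacts). A slide with
#' no tumour annotation yields an empty mask, which downstream simply
#' produces zero tiles.
#'
#' @param annotations Annotation tibble from [read_annotations()].
#' @param slide_id Slide to extract; may be omitted when `annotations`
#'   already concerns a single slide.
#' @return A `cms_region` in the annotation's native pixel coordinates.
#' @examples
#' ann <- tibble::tibble(
#'   slide_id = "s1", kind = c("tumor", "exclusion"),
#'   polygon = list(list(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100)),
#'                  list(x = c(0, 50, 50, 0), y = c(0, 0, 100, 100)))
#' )
#' region_area(effective_tumor_mask(ann)) # 5000
#' @export
effective_tumor_mask <- function(annotations, slide_id = NULL) {
  if (!is.null(slide_id)) {
    annotations <- annotations[annotations$slide_id == slide_id, , drop = FALSE]
  }
  tumor <- annotations$polygon[annotations$kind == "tumor"]
  excl <- annotations$polygon[annotations$kind == "exclusion"]
  if (length(tumor) == 0) return(region_empty())
  mask <- region(tumor[1])
  for (p in tumor[-1]) mask <- region_union(mask, region(list(p)))
  for (p in excl) mask <- region_diff(mask, region(list(p)))
  mask
}

# rescale a native-pixel mask to working-resolution pixels
scale_region <- function(reg, factor) {
  new_region(lapply(unclass(reg), function(r) list(x = r$x * factor, y = r$y * factor)))
}
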