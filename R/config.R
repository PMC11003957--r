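#' Pipeline configuration
#'
#' Bundles the stage-1 tiling parameters and the experiment-level constants
#' shared by every module. The defaults reproduce the published pipeline:
#' 318 px tiles at a working resolution of 2 um/px (i.e. ~5x magnification,
#' tile side ~636 um), 50% tile overlap, tiles retained only when at least
#' half of their area lies inside the annotated tumour region, a five-fold
#' ensemble, and 10,000 virtual-biopsy sampling events per slide.
#'
#' @param tile_px Tile side length in pixels at the working resolution.
#' @param target_spacing_um Working pixel spacing in micrometres per pixel.
#'   Native-resolution images and annotations are rescaled to this spacing
#'   before tiling.
#' @param overlap_fraction Fractional overlap between neighbouring tiles in
#'   `[0, 1)`; the grid stride is `round(tile_px * (1 - overlap_fraction))`.
#' @param min_in_region_fraction Minimum fraction of a tile's area that must
#'   fall inside the tumour mask for the tile to be retained.
#' @param n_folds Number of cross-validation folds / ensemble members.
#' @param n_sampling_events Virtual-biopsy sampling events drawn per slide.
#' @param rng_seed Integer seed recorded alongside the configuration.
#'
#' @return An object of class `cms_config` (a named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$tile_px * cfg$target_spacing_um # physical tile side in um
#' @export
pipeline_config <- function(tile_px = 318L,
                            target_spacing_um = 2.0,
                            overlap_fraction = 0.5,
                            min_in_region_fraction = 0.5,
                            n_folds = 5L,
                            n_sampling_events = 10000L,
                            rng_seed = 1L) {
  tile_px <- as.integer(tile_px)
  if (is.na(tile_px) || tile_px <= 0L) {
    abort("`tile_px` must be a positive integer.", class = "cms_config_error")
  }
  if (!is.numeric(target_spacing_um) || target_spacing_um <= 0) {
    abort("`target_spacing_um` must be a positive real.", class = "cms_config_error")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("`overlap_fraction` must lie in [0, 1).", class = "cms_config_error")
  }
  if (min_in_region_fraction < 0 || min_in_region_fraction > 1) {
    abort("`min_in_region_fraction` must lie in [0, 1].", class = "cms_config_error")
  }
  n_folds <- as.integer(n_folds)
  if (is.na(n_folds) || n_folds < 2L) {
    abort("`n_folds` must be an integer >= 2 (a single fold has no held-out set).",
      class = "cms_config_error")
  }
  stride <- as.integer(round(tile_px * (1 - overlap_fraction)))
  if (stride < 1L) {
    abort("Configured overlap leaves a stride below 1 px.", class = "cms_config_error")
  }
  structure(
    list(
      tile_px = tile_px,
      target_spacing_um = target_spacing_um,
      overlap_fraction = overlap_fraction,
      min_in_region_fraction = min_in_region_fraction,
      n_folds = n_folds,
      n_sampling_events = as.integer(n_sampling_events),
      rng_seed = as.integer(rng_seed),
      stride = stride
    ),
    class = "cms_config"
  )
}

#' @export
print.cms_config <- function(x, ...) {
  cat("<cms_config>\n")
  cat(sprintf("  tile: %d px @ %.3g um/px (%.0f um side), overlap %.0f%%, stride %d px\n",
    x$tile_px, x$target_spacing_um, x$tile_px * x$target_spacing_um,
    100 * x$overlap_fraction, x$stride))
  cat(sprintf("  retention: >= %.0f%% of tile inside tumour mask\n",
    100 * x$min_in_region_fraction))
  cat(sprintf("  folds: %d, sampling events per slide: %d, seed: %d\n",
    x$n_folds, x$n_sampling_events, x$rng_seed))
  invisible(x)
}

#' Read / write a pipeline configuration
#'
#' Configurations serialise to a flat JSON object so that command-line runs
#' can be reproduced from a single file.
#'
#' @param path File path of the JSON configuration.
#' @return `read_config()` returns a `cms_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(vals), names(formals(pipeline_config)))
  do.call(pipeline_config, vals[keep])
}

#' @rdname read_config
#' @param cfg A `cms_config` object.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cms_config"))
  jsonlite::write_json(unclass(cfg)[names(cfg) != "stride"], path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
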