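# Tile descriptors for the tile-level scorer.
#
# The scorer consumes a compact, rotation- and flip-invariant descriptor of
# each tile: the radial power spectrum of the mean-centred grey image
# (fractions of spectral energy in log-spaced radial frequency bands),
# the log total spectral energy, and first-order colour statistics. The
# class-defining cue of both the synthetic textures and (coarsely) of H&E
# tissue architecture is characteristic spatial scale, which these bands
# capture; invariance to flips/rotations makes the standard geometric
# augmentations exactly label-preserving in descriptor space.

RADIAL_BINS <- 8L

radial_bin_cache <- new.env(parent = emptyenv())

radial_bin_index <- function(s) {
  key <- as.character(s)
  if (!is.null(radial_bin_cache[[key]])) return(radial_bin_cache[[key]])
  f1 <- c(seq(0, floor(s / 2)), seq(-(ceiling(s / 2) - 1), -1)) / s
  fr <- sqrt(outer(f1^2, f1^2, `+`))
  edges <- exp(seq(log(0.02), log(0.5), length.out = RADIAL_BINS + 1L))
  idx <- findInterval(fr, edges, rightmost.closed = TRUE)
  idx[fr < edges[1] | fr > edges[RADIAL_BINS + 1L]] <- 0L
  radial_bin_cache[[key]] <- idx
  idx
}

feature_names <- function() {
  c(paste0("ft_rp", seq_len(RADIAL_BINS)),
    "ft_log_energy", "ft_mean_r", "ft_mean_g", "ft_mean_b", "ft_sd_gray")
}

#' Tile descriptor
#'
#' Computes the spectral/colour descriptor of one tile (see the package
#' vignette for the rationale). Constant tiles yield an all-zero spectrum.
#'
#' @param patch `s x s x 3` numeric array in `[0, 1]`.
#' @return Named numeric vector of length `r length(feature_names())`.
#' @export
tile_descriptor <- function(patch) {
  s <- dim(patch)[1]
  gray <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  g0 <- gray - mean(gray)
  P <- Mod(fft(g0))^2
  idx <- radial_bin_index(s)
  tot <- sum(P[idx > 0L])
  rp <- if (tot > 0) {
    vapply(seq_len(RADIAL_BINS), function(b) sum(P[idx == b]) / tot, numeric(1))
  } else {
    rep(0, RADIAL_BINS)
  }
  out <- c(rp,
    log(tot / (s * s) + 1e-8),
    mean(patch[, , 1]), mean(patch[, , 2]), mean(patch[, , 3]),
    sd(gray))
  names(out) <- feature_names()
  out
}

#' Tile descriptors for a set of tiles on one slide
#'
#' @param img Slide pixels at the working resolution.
#' @param tiles Tile tibble from [extract_tiles()] (or any tibble with
#'   `x`, `y`, `size_px`).
#' @param augment Optional augmentation policy (see [augment_patch()])
#'   applied to each patch before the descriptor is computed.
#' @return `tiles` with the descriptor columns (`ft_*`) appended.
#' @export
compute_tile_features <- function(img, tiles, augment = NULL) {
  n <- nrow(tiles)
  M <- matrix(0, nrow = n, ncol = length(feature_names()),
    dimnames = list(NULL, feature_names()))
  for (i in seq_len(n)) {
    patch <- tile_image(img, tiles[i, ])
    if (!is.null(augment) && length(augment) > 0) {
      patch <- augment_patch(patch, policy = augment)
    }
    M[i, ] <- tile_descriptor(patch)
  }
  dplyr::bind_cols(tiles, tibble::as_tibble(M))
}

# full working-resolution grid of candidate tiles, ignoring any mask;
# used to score arbitrary sub-masks (virtual biopsies) cheaply
full_tile_grid <- function(image_dim, cfg, slide_id = NA_character_) {
  w <- as.integer(image_dim[1]); h <- as.integer(image_dim[2])
  t <- cfg$tile_px
  if (t > w || t > h) {
    return(tibble::tibble(slide_id = character(), x = integer(), y = integer(),
      size_px = integer()))
  }
  g <- expand.grid(x = seq.int(0L, w - t, by = cfg$stride),
    y = seq.int(0L, h - t, by = cfg$stride))
  tibble::tibble(slide_id = slide_id, x = as.integer(g$x), y = as.integer(g$y),
    size_px = t)
}

#' Featurise every slide of a cohort
#'
#' Convenience driver: for each slide, renders/loads the pixels, builds the
#' tumour mask, extracts either the annotation-restricted tiles or the full
#' candidate grid, and computes tile descriptors. Synthetic cohorts are
#' rendered lazily; on-disk cohorts are read from `image_dir`
#' (`<slide_id>.png`).
#'
#' @param cohort A `cms_synth_cohort`, or a list with `manifest` and
#'   `annotations` tibbles when `image_dir` is given.
#' @param cfg A [pipeline_config()].
#' @param grid `"mask"` for stage-1 annotation-restricted tiles,
#'   `"full"` for every in-bounds grid position (no mask filtering).
#' @param image_dir Directory of `<slide_id>.png` images for on-disk
#'   cohorts.
#' @param slides Optional subset of slide ids.
#' @param augment Optional augmentation policy applied to the patches
#'   (used to build augmented training copies).
#' @return Tibble: slide metadata + tile coordinates + `ft_*` descriptors.
#' @export
cohort_tile_features <- function(cohort, cfg = pipeline_config(),
                                 grid = c("mask", "full"),
                                 image_dir = NULL, slides = NULL,
                                 augment = NULL) {
  grid <- match.arg(grid)
  manifest <- cohort$manifest
  if (!is.null(slides)) manifest <- manifest[manifest$slide_id %in% slides, ]
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$slide_id[i]
    img <- if (is.null(image_dir)) {
      synth_slide_image(cohort, sid)
    } else {
      read_slide_image(file.path(image_dir, paste0(sid, ".png")))
    }
    img <- resample_to_spacing(img, manifest$pixel_spacing_um[i], cfg$target_spacing_um)
    dim_wh <- c(dim(img)[2], dim(img)[1])
    tiles <- if (grid == "mask") {
      mask <- effective_tumor_mask(cohort$annotations, sid)
      mask <- scale_mask_to_target(mask, manifest$pixel_spacing_um[i], cfg)
      extract_tiles(mask, dim_wh, cfg, slide_id = sid)
    } else {
      full_tile_grid(dim_wh, cfg, slide_id = sid)
    }
    if (nrow(tiles) == 0) { out[[i]] <- NULL; next }
    ft <- compute_tile_features(img, tiles, augment = augment)
    ft$patient_id <- manifest$patient_id[i]
    ft$cms_label <- manifest$cms_label[i]
    ft$cohort <- manifest$cohort[i]
    out[[i]] <- ft
  }
  dplyr::bind_rows(out)
}
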