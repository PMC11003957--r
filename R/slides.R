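#' Read a flat slide image
#'
#' Desk-scale reader for flat PNG/TIFF pseudo-slides; the native pixel
#' spacing comes from the manifest, not the file. Returns an
#' `height x width x 3` numeric array in `[0, 1]`. Greyscale images are
#' expanded to three channels; an alpha channel is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric array `[row, col, channel]` in `[0, 1]`.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("Reading TIFF slides requires the 'tiff' package.",
          class = "cms_io_error")
      }
      tiff::readTIFF(path)
    },
    abort(sprintf("Unsupported slide image format '.%s'.", ext),
      class = "cms_io_error")
  )
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Resample an image to the working pixel spacing
#'
#' Downsampling from the native to the working resolution (e.g. 0.5 to
#' 2 um/px, a 4x reduction) uses non-overlapping block averaging, which
#' acts as the box anti-aliasing filter appropriate for area-preserving
#' intensity statistics. Only integer reduction factors are supported; a
#' ratio of 1 returns the input unchanged. Trailing rows/columns that do
#' not fill a complete block are discarded.
#'
#' @param img `H x W x C` numeric array.
#' @param native_spacing_um Native micrometres per pixel.
#' @param target_spacing_um Desired micrometres per pixel.
#' @return The resampled array.
#' @export
resample_to_spacing <- function(img, native_spacing_um, target_spacing_um) {
  ratio <- target_spacing_um / native_spacing_um
  f <- round(ratio)
  if (abs(ratio - f) > 1e-6 || f < 1) {
    abort(sprintf(
      "Spacing ratio %.4f is not a positive integer; only integer block-average reductions are supported.",
      ratio), class = "cms_resample_error")
  }
  if (f == 1) return(img)
  d <- dim(img)
  h <- (d[1] %/% f) * f
  w <- (d[2] %/% f) * f
  out <- array(0, dim = c(h %/% f, w %/% f, d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[seq_len(h), seq_len(w), ch]
    # average f x f blocks: fold rows, then columns
    m <- matrix(colMeans(matrix(m, nrow = f)), nrow = h %/% f)
    m <- t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = w %/% f))
    out[, , ch] <- m
  }
  out
}

#' Extract one tile's pixels
#'
#' Crops the `size_px` square whose top-left corner is `(x, y)` in 0-based
#' working-resolution pixel coordinates from an image already resampled to
#' the working spacing.
#'
#' @param img `H x W x C` array at the working resolution.
#' @param tile A one-row tile tibble (or list) with `x`, `y`, `size_px`.
#' @return A `size_px x size_px x C` array.
#' @export
tile_image <- function(img, tile) {
  x <- as.integer(tile$x)
  y <- as.integer(tile$y)
  s <- as.integer(tile$size_px)
  d <- dim(img)
  if (x < 0 || y < 0 || x + s > d[2] || y + s > d[1]) {
    abort(sprintf("Tile (%d, %d, size %d) lies outside the %d x %d image.",
      x, y, s, d[2], d[1]), class = "cms_bounds_error")
  }
  img[(y + 1):(y + s), (x + 1):(x + s), , drop = FALSE]
}
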