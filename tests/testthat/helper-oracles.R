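# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's computational path: areas come from pixel-centre rasters
# (mgcv::in.out) or from polyclip booleans, never from the compiled
# clipping kernel; AUROC comes from O(n^2) pair counting; the plurality
# oracle enumerates counts directly.

desk_cfg <- function(...) {
  pipeline_config(tile_px = 64L, target_spacing_um = 2.0, ...)
}

# random simple polygon: perturbed star polygon around a centre
random_simple_polygon <- function(cx, cy, r_mean, n_vertices = 12L) {
  phi <- sort(runif(n_vertices, 0, 2 * pi))
  r <- r_mean * runif(n_vertices, 0.4, 1.6)
  list(x = cx + r * cos(phi), y = cy + r * sin(phi))
}

# pixel-count area of a region using mgcv::in.out on pixel centres
raster_region_area <- function(reg, width, height) {
  xs <- seq_len(width) - 0.5
  ys <- seq_len(height) - 0.5
  g <- expand.grid(x = xs, y = ys)
  inside <- rep(FALSE, nrow(g))
  for (r in reg) {
    bnd <- cbind(c(r$x, r$x[1]), c(r$y, r$y[1]))
    inside <- xor(inside, mgcv::in.out(bnd, as.matrix(g)))
  }
  sum(inside)
}

# raster estimate of the fraction of one tile inside a region
raster_tile_fraction <- function(reg, x, y, size) {
  xs <- x + seq_len(size) - 0.5
  ys <- y + seq_len(size) - 0.5
  g <- as.matrix(expand.grid(x = xs, y = ys))
  inside <- rep(FALSE, nrow(g))
  for (r in reg) {
    bnd <- cbind(c(r$x, r$x[1]), c(r$y, r$y[1]))
    inside <- xor(inside, mgcv::in.out(bnd, g))
  }
  mean(inside)
}

# brute-force stage-1 tiling: test every grid position independently with
# polyclip (not the compiled kernel) and the documented retention rule
brute_force_tiles <- function(mask, image_dim, cfg) {
  w <- image_dim[1]; h <- image_dim[2]
  t <- cfg$tile_px
  if (t > w || t > h || length(mask) == 0) {
    return(data.frame(x = integer(), y = integer()))
  }
  rows <- list()
  for (y in seq.int(0L, h - t, by = cfg$stride)) {
    for (x in seq.int(0L, w - t, by = cfg$stride)) {
      rect <- list(list(x = c(x, x + t, x + t, x), y = c(y, y, y + t, y + t)))
      pieces <- polyclip::polyclip(rect, unclass(mask), op = "intersection",
        fillA = "evenodd", fillB = "evenodd")
      a <- sum(vapply(pieces, function(p) {
        n <- length(p$x); j <- c(n, seq_len(n - 1L))
        0.5 * sum(p$x[j] * p$y - p$x * p$y[j])
      }, numeric(1)))
      if (a / t^2 >= cfg$min_in_region_fraction) {
        rows[[length(rows) + 1L]] <- data.frame(x = x, y = y)
      }
    }
  }
  if (length(rows) == 0) data.frame(x = integer(), y = integer()) else
    do.call(rbind, rows)
}

# O(n^2) pair-counting AUROC (concordant pairs + half ties)
pair_counting_auroc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# brute-force plurality with mixed on ties
plurality_oracle <- function(calls) {
  counts <- vapply(c("CMS1", "CMS2", "CMS3", "CMS4"),
    function(k) sum(calls == k), integer(1))
  top <- which(counts == max(counts))
  if (length(top) == 1) names(counts)[top] else "mixed"
}

# polyclip-based positive-overlap test between two rings (independent of
# the compiled placement path)
polyclip_overlap_area <- function(r1, r2) {
  pieces <- polyclip::polyclip(list(r1), list(r2), op = "intersection")
  sum(vapply(pieces, function(p) {
    n <- length(p$x); j <- c(n, seq_len(n - 1L))
    abs(0.5 * sum(p$x[j] * p$y - p$x * p$y[j]))
  }, numeric(1)))
}

# constant-colour patch
solid_patch <- function(size, rgb = c(0.5, 0.5, 0.5)) {
  array(rep(rgb, each = size * size), dim = c(size, size, 3))
}

# small cohort + features used by several classifier tests (cached)
tiny_cohort_env <- new.env()
tiny_cohort <- function() {
  if (is.null(tiny_cohort_env$co)) {
    tiny_cohort_env$co <- synth_cohort(synth_config(
      seed = 421, n_per_class = 3, image_px = 256, heterogeneity = 0.1))
    tiny_cohort_env$ft <- cohort_tile_features(tiny_cohort_env$co, desk_cfg())
  }
  list(co = tiny_cohort_env$co, ft = tiny_cohort_env$ft)
}

# near-one-hot score matrix for a label vector
score_matrix <- function(labels, sharp = 10) {
  K <- c(CMS1 = 1, CMS2 = 2, CMS3 = 3, CMS4 = 4)
  P <- matrix(1, length(labels), 4)
  P[cbind(seq_along(labels), K[labels])] <- sharp
  P / rowSums(P)
}
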