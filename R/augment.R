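#' Stochastic label-preserving patch augmentation
#'
#' Applies a random composition of standard histology training
#' augmentations to an 8-bit-equivalent RGB patch: horizontal/vertical
#' flips, multiples of 90 degree rotation, brightness/contrast/saturation/
#' hue jitter and mild Gaussian blur. The policy is a character subset of
#' `c("flip", "rotate", "brightness", "contrast", "saturation", "hue",
#' "blur")`; an empty policy returns the input unchanged. Randomness comes
#' from the R RNG, so a fixed seed reproduces the augmentation exactly.
#'
#' @param patch `s x s x 3` numeric array in `[0, 1]`.
#' @param policy Character vector of transform names (order applied as
#'   listed above, each independently randomised).
#' @param strength Scalar multiplier on all photometric jitter amplitudes.
#' @return Augmented patch, same shape, clamped to `[0, 1]`.
#' @export
augment_patch <- function(patch, policy = c("flip", "rotate", "brightness",
                                            "contrast", "saturation", "hue", "blur"),
                          strength = 1) {
  if (length(policy) == 0) return(patch)
  bad <- setdiff(policy, c("flip", "rotate", "brightness", "contrast",
    "saturation", "hue", "blur"))
  if (length(bad) > 0) {
    abort(paste0("Unknown augmentation transform(s): ", paste(bad, collapse = ", ")),
      class = "cms_config_error")
  }
  p <- patch
  if ("flip" %in% policy) {
    if (runif(1) < 0.5) p <- p[, rev(seq_len(dim(p)[2])), , drop = FALSE]
    if (runif(1) < 0.5) p <- p[rev(seq_len(dim(p)[1])), , , drop = FALSE]
  }
  if ("rotate" %in% policy) {
    k <- sample(0:3, 1)
    for (i in seq_len(k)) {
      # 90 degrees counter-clockwise
      p <- aperm(p, c(2, 1, 3))[rev(seq_len(dim(p)[2])), , , drop = FALSE]
    }
  }
  if ("brightness" %in% policy) p <- p + runif(1, -0.10, 0.10) * strength
  if ("contrast" %in% policy) {
    m <- mean(p)
    p <- m + (p - m) * (1 + runif(1, -0.15, 0.15) * strength)
  }
  if ("saturation" %in% policy) {
    gray <- (p[, , 1] + p[, , 2] + p[, , 3]) / 3
    s <- 1 + runif(1, -0.3, 0.3) * strength
    for (ch in 1:3) p[, , ch] <- gray + (p[, , ch] - gray) * s
  }
  if ("hue" %in% policy) {
    # rotate RGB vectors around the achromatic axis (Rodrigues formula)
    ang <- runif(1, -0.2, 0.2) * strength
    axis <- rep(1 / sqrt(3), 3)
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    d <- dim(p)
    m <- matrix(p, ncol = 3) %*% t(R)
    p <- array(m, dim = d)
  }
  if ("blur" %in% policy) {
    sigma <- runif(1, 0, 0.8)
    if (sigma > 0.05) for (ch in 1:3) p[, , ch] <- gaussian_blur(p[, , ch], sigma)
  }
  clamp01(p)
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(M) { # along rows (first dim)
    n <- nrow(M)
    Mp <- M[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(M))
    for (j in seq_along(k)) out <- out + k[j] * Mp[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}
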