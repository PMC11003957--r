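# evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible sub-seed (kept inside 32-bit integer range)
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  as.integer((sum(as.numeric(parts) * seq_along(parts) * 7919) + 1) %% 2147483629)
}

# index of the maximum with deterministic lowest-index tie-breaking,
# plus whether the maximum was tied
argmax_tie <- function(v, tol = 1e-12) {
  m <- max(v)
  hits <- which(v >= m - tol)
  list(index = hits[1L], tie = length(hits) > 1L)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

prob_cols <- function() paste0("p_", CMS_CLASSES)
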