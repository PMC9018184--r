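`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-module seed from a run seed
#'
#' A single run seed fans out deterministically to independent sub-seeds, one
#' per labelled stage, so any stage can be re-run in isolation with the same
#' stream. The result is always a positive integer below 2^31.
#'
#' @param seed integer run seed.
#' @param label character label of the consuming stage.
#' @return integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u) * 2654435.0) %% 2147483562
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483562 + 1)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Separable bilinear interpolation matrix mapping n_in samples to n_out,
# with centre-aligned sampling and edge clamping. Kept explicit (rather than
# an image-library resize) because training needs its exact linear adjoint.
interp_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    p <- (i - 0.5) * n_in / n_out + 0.5
    lo <- floor(p)
    w <- p - lo
    lo <- min(max(lo, 1), n_in)
    hi <- min(lo + 1, n_in)
    M[i, lo] <- M[i, lo] + (1 - w)
    M[i, hi] <- M[i, hi] + w
  }
  M
}

resize_bilinear <- function(img, out_h, out_w) {
  interp_matrix(nrow(img), out_h) %*% img %*% t(interp_matrix(ncol(img), out_w))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round-half-away-from-zero for non-negative input
round_half_up <- function(x) floor(x + 0.5)
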