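#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB. Identical images would be infinite, so
#' they return the documented ceiling of 100 dB with attribute
#' `identical = TRUE`.
#'
#' @param a,b images of identical shape (levels on the `[0, peak]` scale).
#' @param peak peak signal value (255 for 8-bit maps).
#' @param cap ceiling returned for identical images (default 100 dB).
#' @return PSNR in dB (attribute `identical` flags the capped case).
#' @export
psnr <- function(a, b, peak = 255, cap = 100) {
  check_same_shape(a, b)
  mse <- mean((a - b)^2)
  if (mse == 0) return(structure(cap, identical = TRUE))
  structure(min(10 * log10(peak^2 / mse), cap), identical = FALSE)
}

#' Structural similarity index
#'
#' Mean local SSIM with the original convention: 11x11 Gaussian window
#' (sigma 1.5), K1 = 0.01, K2 = 0.03, valid-mode windows.
#'
#' @param a,b images of identical shape, at least 11x11.
#' @param peak dynamic range (255 for 8-bit maps).
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, peak = 255) {
  check_same_shape(a, b)
  if (nrow(a) < 11 || ncol(a) < 11)
    stop("metric error: image smaller than the 11x11 SSIM window")
  g <- outer(stats::dnorm(-5:5, sd = 1.5), stats::dnorm(-5:5, sd = 1.5))
  g <- g / sum(g)
  f <- function(x) conv2_valid(x, g)
  mu_a <- f(a); mu_b <- f(b)
  saa <- f(a * a) - mu_a^2; sbb <- f(b * b) - mu_b^2
  sab <- f(a * b) - mu_a * mu_b
  c1 <- (0.01 * peak)^2; c2 <- (0.03 * peak)^2
  s <- ((2 * mu_a * mu_b + c1) * (2 * sab + c2)) /
       ((mu_a^2 + mu_b^2 + c1) * (saa + sbb + c2))
  mean(s)
}

# valid-mode 2-D convolution via the package conv kernel
conv2_valid <- function(x, k) {
  xa <- array(x, c(nrow(x), ncol(x), 1, 1))
  ka <- array(k, c(nrow(k), ncol(k), 1, 1))
  y <- cpp_conv_fwd(xa, ka, 0, 1L, 0L, 1L)
  matrix(y, dim(y)[1], dim(y)[2])
}

#' Signed surface deviation between two meshes
#'
#' For every vertex of `gen`, the signed point-to-surface distance to
#' `target` is computed (no re-registration: the shared adjacent-teeth frame
#' is taken as the common registration; set `icp = TRUE` for an optional
#' rigid pre-alignment). Returns the standard deviation and root mean
#' square of the distances.
#'
#' @param gen,target [tooth_mesh()]es in the same standardized frame.
#' @param icp logical; run a rigid ICP pre-alignment first.
#' @param icp_iter ICP iterations.
#' @return list with `sd_mm`, `rms_mm` and the per-vertex `distances`.
#' @export
surface_deviation <- function(gen, target, icp = FALSE, icp_iter = 10) {
  stopifnot(inherits(gen, "tooth_mesh"), inherits(target, "tooth_mesh"))
  if (nrow(gen$vertices) == 0 || nrow(target$vertices) == 0)
    stop("empty mesh")
  v <- gen$vertices
  if (icp) v <- icp_align(v, target, icp_iter)
  d <- cpp_point_mesh_signed_dist(v, target$vertices, target$faces)
  list(sd_mm = stats::sd(d), rms_mm = sqrt(mean(d^2)), distances = d)
}

# small rigid ICP: iterate closest-point correspondence + Kabsch
icp_align <- function(v, target, iters) {
  tv <- target$vertices; tf <- target$faces
  for (i in seq_len(iters)) {
    d <- cpp_point_mesh_signed_dist(v, tv, tf)
    # closest points approximated by foot points along the distance gradient
    # via nearest target vertices (adequate for a pre-alignment step)
    nn <- apply(v, 1, function(p)
      which.min(colSums((t(tv) - p)^2)))
    q <- tv[nn, , drop = FALSE]
    mv <- colMeans(v); mq <- colMeans(q)
    H <- t(sweep(v, 2, mv)) %*% sweep(q, 2, mq)
    sv <- svd(H)
    R <- sv$v %*% t(sv$u)
    if (det(R) < 0) { sv$v[, 3] <- -sv$v[, 3]; R <- sv$v %*% t(sv$u) }
    v <- sweep(sweep(v, 2, mv) %*% t(R), 2, mq, `+`)
  }
  v
}

#' Evaluate generated surfaces against their targets
#'
#' Runs the generator on each requested case, composites the defect region,
#' and reports PSNR, SSIM and FSIM on the 8-bit scale plus (optionally) the
#' SD/RMS surface deviation between the meshes reconstructed from the
#' generated and target depth maps.
#'
#' @param gen an [build_generator()] network.
#' @param data a `case_set` with in-memory cases.
#' @param which split to evaluate (`"test"`, `"val"`, `"train"`) or an
#'   integer vector of case indices.
#' @param with_meshes also reconstruct meshes and compute SD/RMS (slower).
#' @return data.frame with one row per case (`case`, `psnr`, `ssim`,
#'   `fsim`, and `sd_mm`, `rms_mm` when `with_meshes`).
#' @export
evaluate_cases <- function(gen, data, which = "test", with_meshes = FALSE) {
  stopifnot(inherits(data, "case_set"), !is.null(data$cases))
  idx <- if (is.character(which)) data$split[[which]] else as.integer(which)
  if (!length(idx)) stop("no cases in the requested split")
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    cs <- data$cases[[idx[k]]]
    out <- generate_surface(gen, cs$input_stack / 255,
                            defect_mask = cs$defect_mask)
    lv <- round_half_up(clamp(out, 0, 1) * 255)
    r <- data.frame(case = idx[k],
                    psnr = as.numeric(psnr(lv, cs$target_global)),
                    ssim = ssim(lv, cs$target_global),
                    fsim = fsim(lv, cs$target_global))
    if (with_meshes) {
      dm_g <- structure(list(pixels = matrix(as.integer(lv), nrow(lv)),
                             encoding = cs$encoding), class = "depth_map")
      dm_t <- structure(list(pixels = matrix(as.integer(cs$target_global),
                                             nrow(lv)),
                             encoding = cs$encoding), class = "depth_map")
      dev <- surface_deviation(reconstruct_mesh(dm_g), reconstruct_mesh(dm_t))
      r$sd_mm <- dev$sd_mm; r$rms_mm <- dev$rms_mm
    }
    rows[[k]] <- r
  }
  do.call(rbind, rows)
}
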