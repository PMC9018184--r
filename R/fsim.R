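#' Feature similarity index
#'
#' FSIM compares two images through two low-level feature maps: phase
#' congruency (PC, computed with a log-Gabor filter bank at 4 scales and 4
#' orientations) and gradient magnitude (GM, Scharr operator). Per pixel the
#' similarity `S = S_PC * S_GM` is weighted by `max(PC_a, PC_b)` and the
#' weighted mean is returned. Larger inputs are pre-downsampled by
#' `round(min(H, W) / 256)` averaging, following the reference convention.
#'
#' @param a,b images of identical shape (>= 32x32), 0-255 scale.
#' @param T1,T2 stabilizing constants for the PC and GM terms.
#' @return FSIM score in `[0, 1]` (1 for identical images).
#' @export
fsim <- function(a, b, T1 = 0.85, T2 = 160) {
  check_same_shape(a, b)
  if (nrow(a) < 32 || ncol(a) < 32) stop("metric error: fsim needs >= 32x32 input")
  f <- max(1, round(min(dim(a)) / 256))
  if (f > 1) {
    a <- box_downsample(a, f)
    b <- box_downsample(b, f)
  }
  pca <- phase_congruency(a)
  pcb <- phase_congruency(b)
  ga <- gradient_magnitude(a)
  gb <- gradient_magnitude(b)
  pcm <- pmax(pca, pcb)
  if (sum(pcm) == 0) {
    if (identical(a, b)) return(1)
    stop("metric error: zero phase congruency everywhere")
  }
  s_pc <- (2 * pca * pcb + T1) / (pca^2 + pcb^2 + T1)
  s_g <- (2 * ga * gb + T2) / (ga^2 + gb^2 + T2)
  sum(s_pc * s_g * pcm) / sum(pcm)
}

box_downsample <- function(x, f) {
  h <- (nrow(x) %/% f) * f; w <- (ncol(x) %/% f) * f
  x <- x[seq_len(h), seq_len(w), drop = FALSE]
  ix <- (seq_len(h) - 1) %/% f + 1; iy <- (seq_len(w) - 1) %/% f + 1
  t(rowsum(t(rowsum(x, ix)), iy)) / f^2
}

gradient_magnitude <- function(x) {
  sx <- matrix(c(3, 0, -3, 10, 0, -10, 3, 0, -3), 3, 3, byrow = TRUE) / 16
  gx <- conv2_same(x, sx)
  gy <- conv2_same(x, t(sx))
  sqrt(gx^2 + gy^2)
}

conv2_same <- function(x, k) {
  xa <- array(x, c(nrow(x), ncol(x), 1, 1))
  ka <- array(k, c(nrow(k), ncol(k), 1, 1))
  y <- cpp_conv_fwd(xa, ka, 0, 1L, as.integer((nrow(k) - 1) / 2), 1L)
  matrix(y, dim(y)[1], dim(y)[2])
}

# Phase congruency (Kovesi's PC2 measure summed over orientations):
# log-Gabor filter bank, 4 scales x 4 orientations, with an estimated noise
# threshold per orientation.
phase_congruency <- function(im, nscale = 4, norient = 4, min_wl = 6,
                             mult = 2, sigma_onf = 0.55, k = 2,
                             d_theta_sigma = 1.2) {
  rows <- nrow(im); cols <- ncol(im)
  IM <- stats::fft(im)
  # frequency grids (centred)
  fx <- ifelse(seq_len(cols) - 1 <= cols / 2, seq_len(cols) - 1,
               seq_len(cols) - 1 - cols) / cols
  fy <- ifelse(seq_len(rows) - 1 <= rows / 2, seq_len(rows) - 1,
               seq_len(rows) - 1 - rows) / rows
  u1 <- matrix(fx, rows, cols, byrow = TRUE)
  u2 <- matrix(fy, rows, cols)
  radius <- sqrt(u1^2 + u2^2)
  radius[1, 1] <- 1
  theta <- atan2(-u2, u1)
  sintheta <- sin(theta); costheta <- cos(theta)
  lp <- 1 / (1 + (radius / 0.45)^30)   # low-pass to kill FFT corner artefacts

  log_gabor <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    fo <- 1 / (min_wl * mult^(s - 1))
    lg <- exp(-(log(radius / fo))^2 / (2 * log(sigma_onf)^2)) * lp
    lg[1, 1] <- 0
    log_gabor[[s]] <- lg
  }
  theta_sigma <- pi / norient / d_theta_sigma
  eps <- 1e-4
  total_pc <- matrix(0, rows, cols)
  total_an <- matrix(0, rows, cols)
  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))
    sum_e <- matrix(0, rows, cols); sum_o <- matrix(0, rows, cols)
    sum_an <- matrix(0, rows, cols)
    e_list <- vector("list", nscale); o_list <- vector("list", nscale)
    tau <- 0
    for (s in seq_len(nscale)) {
      filt <- log_gabor[[s]] * spread
      eo <- stats::fft(IM * filt, inverse = TRUE) / length(im)
      e <- Re(eo); od <- Im(eo)
      an <- sqrt(e^2 + od^2)
      sum_e <- sum_e + e; sum_o <- sum_o + od; sum_an <- sum_an + an
      e_list[[s]] <- e; o_list[[s]] <- od
      if (s == 1) tau <- median(an) / sqrt(log(4))
    }
    x_energy <- sqrt(sum_e^2 + sum_o^2) + eps
    mean_e <- sum_e / x_energy; mean_o <- sum_o / x_energy
    energy <- matrix(0, rows, cols)
    for (s in seq_len(nscale)) {
      energy <- energy + e_list[[s]] * mean_e + o_list[[s]] * mean_o -
        abs(e_list[[s]] * mean_o - o_list[[s]] * mean_e)
    }
    total_tau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sigma <- total_tau * sqrt((4 - pi) / 2)
    t_thr <- noise_mean + k * noise_sigma
    energy <- pmax(energy - t_thr, 0)
    total_pc <- total_pc + energy
    total_an <- total_an + sum_an
  }
  total_pc / (total_an + eps)
}
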