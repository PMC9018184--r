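test_that("psnr reproduces closed forms, with a capped flag for identical inputs", {
  a <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  p <- psnr(a, a)
  expect_equal(as.numeric(p), 100)
  expect_true(attr(p, "identical"))
  b <- a + 1   # MSE exactly 1
  expect_equal(as.numeric(psnr(a, b)), 20 * log10(255), tolerance = 1e-9)
  expect_equal(as.numeric(psnr(matrix(0, 8, 8), matrix(255, 8, 8))), 0)
})

test_that("ssim attains 1 on identical images and matches the zero-variance closed form", {
  set.seed(1)
  a <- matrix(runif(32 * 32, 0, 255), 32, 32)
  expect_equal(ssim(a, a), 1)
  mu_a <- 100; mu_b <- 110
  c1 <- (0.01 * 255)^2
  closed <- (2 * mu_a * mu_b + c1) / (mu_a^2 + mu_b^2 + c1)
  expect_equal(ssim(matrix(mu_a, 16, 16), matrix(mu_b, 16, 16)), closed,
               tolerance = 1e-9)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("ssim of a binary image against its negative is negative", {
  set.seed(2)
  a <- matrix(255 * (runif(32 * 32) > 0.5), 32, 32)
  expect_lt(ssim(a, 255 - a), 0)
})

test_that("fsim is 1 on identical images, bounded, and ranks noise below blur", {
  dm <- project_mesh(generate_crown(crown_params(seed = 6)),
                     depth_encoding(mm_per_pixel = 11 / 64, width = 64,
                                    height = 64))
  img <- dm$pixels
  expect_equal(fsim(img, img), 1)
  set.seed(3)
  for (i in 1:3) {
    r1 <- matrix(runif(64 * 64, 0, 255), 64, 64)
    r2 <- matrix(runif(64 * 64, 0, 255), 64, 64)
    s <- fsim(r1, r2)
    expect_gte(s, 0); expect_lte(s, 1)
  }
  set.seed(4)
  salt <- img
  idx <- sample(length(img), round(0.2 * length(img)))
  salt[idx] <- sample(c(0, 255), length(idx), replace = TRUE)
  g <- outer(stats::dnorm(-2:2), stats::dnorm(-2:2)); g <- g / sum(g)
  blurred <- occlurec:::conv2_same(img, g)
  expect_lt(fsim(img, salt), fsim(img, blurred))
  expect_error(fsim(matrix(0, 16, 16), matrix(0, 16, 16)), "32x32")
})

test_that("psnr and ssim degrade monotonically with increasing noise", {
  dm <- project_mesh(generate_crown(crown_params(seed = 7)),
                     depth_encoding(mm_per_pixel = 11 / 64, width = 64,
                                    height = 64))
  img <- dm$pixels
  ps <- c(); ss <- c()
  for (s in c(1, 4, 16)) {
    noisy <- with_seed_test(42, pmin(pmax(img + rnorm(length(img), 0, s), 0), 255))
    ps <- c(ps, as.numeric(psnr(img, noisy)))
    ss <- c(ss, ssim(img, noisy))
  }
  expect_true(all(diff(ps) < 0))
  expect_true(all(diff(ss) < 0))
})

test_that("surface deviation has exact closed forms on planes", {
  pl <- plane_mesh(z = 0)
  expect_equal(surface_deviation(pl, pl)$rms_mm, 0)
  up <- tooth_mesh(pl$vertices + rep(c(0, 0, 0.1), each = nrow(pl$vertices)),
                   pl$faces, pose_standardized = TRUE)
  dev <- surface_deviation(up, pl)
  expect_equal(dev$rms_mm, 0.1, tolerance = 1e-12)
  expect_equal(dev$sd_mm, 0, tolerance = 1e-12)
  expect_true(all(dev$distances > 0))   # above the winding normal
  expect_error(surface_deviation(tooth_mesh(matrix(0, 0, 3),
                                            matrix(0L, 0, 3)), pl), "empty")
})

test_that("deviation through the 128x128 depth codec stays within twice the quantization bound", {
  m <- generate_crown(crown_params(seed = 10))
  enc <- depth_encoding(alpha = 2, h = 6, mm_per_pixel = 11 / 128,
                        width = 128, height = 128)
  rec <- reconstruct_mesh(project_mesh(m, enc))
  dev <- surface_deviation(rec, m)
  expect_lte(dev$rms_mm, 2 * depth_quantization_step(enc))
})
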