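test_that("pixel-distance mapping matches hand-evaluated values and is monotone", {
  enc <- depth_encoding(alpha = 2, h = 6)
  expect_equal(depth_to_pixel(0, enc), 255)
  expect_equal(depth_to_pixel(6, enc), 0)
  expect_equal(depth_to_pixel(3, enc), 191)   # 255 * 27/36 = 191.25, rounded
  expect_equal(pixel_to_depth(255, enc), 0)
  expect_equal(pixel_to_depth(0, enc), 6)
  expect_equal(depth_to_pixel(6.5, enc), 0)   # beyond the visual distance
  for (a in c(0.5, 1, 2, 4)) {
    e <- depth_encoding(alpha = a, h = 6)
    p <- depth_to_pixel(seq(0, 6, by = 0.005), e)
    expect_true(all(diff(p) <= 0))
  }
})

test_that("codec round trip stays within the brute-force quantization bound", {
  for (a in c(0.5, 1, 2, 4)) {
    enc <- depth_encoding(alpha = a, h = 6)
    bound <- depth_quantization_step(enc)
    d <- seq(0, 6, by = 0.01)
    err <- abs(pixel_to_depth(depth_to_pixel(d, enc), enc) - d)
    expect_lte(max(err), bound)
  }
})

test_that("image entropy reproduces closed forms and is permutation invariant", {
  expect_equal(image_entropy(matrix(7L, 10, 10)), 0)
  half <- matrix(c(0L, 255L), 16, 16)
  expect_equal(image_entropy(half), 1)
  expect_equal(image_entropy(matrix(0:255, 16, 16)), 8)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  perm <- matrix(sample(255:0)[img + 1L], 20, 20)   # relabel levels
  expect_equal(image_entropy(img), image_entropy(perm))
  expect_gte(image_entropy(img), 0)
  expect_lte(image_entropy(img), 8)
})

test_that("pose standardization is idempotent, centred, and undoes a known rotation", {
  m <- generate_crown(crown_params(seed = 5))
  s1 <- standardize_pose(m)
  s2 <- standardize_pose(s1)
  expect_lt(max(abs(s1$vertices - s2$vertices)), 1e-9)
  bb <- apply(s1$vertices, 2, range)
  expect_lt(max(abs(colMeans(bb))), 1e-9)

  R <- euler_rotation(30 * pi / 180, 45 * pi / 180, 10 * pi / 180)
  rot <- tooth_mesh(m$vertices %*% t(R) + 3, m$faces)
  srot <- standardize_pose(rot)
  expect_lt(max(abs(srot$vertices - s1$vertices)), 1e-6)
})

test_that("degenerate geometry is rejected by pose standardization", {
  line <- cbind(seq_len(5), seq_len(5), seq_len(5))
  expect_error(standardize_pose(tooth_mesh(line, matrix(c(1, 2, 3), 1))),
               "collinear")
})

test_that("projection renders planes and analytic height fields exactly", {
  enc <- depth_encoding(alpha = 2, h = 6, mm_per_pixel = 0.5,
                        width = 24, height = 24)
  top <- project_mesh(plane_mesh(z = 0), enc)
  expect_true(all(top$pixels == 255))
  # a plane h below the reference plane encodes to 0 everywhere
  low <- plane_mesh(z = 0)
  low$vertices[, 3] <- -6
  low <- tooth_mesh(low$vertices, low$faces, pose_standardized = TRUE)
  enc_low <- enc; enc_low$reference_z <- 0
  expect_true(all(project_mesh(low, enc_low)$pixels == 0))

  enc64 <- depth_encoding(alpha = 2, h = 6, mm_per_pixel = 0.25,
                          width = 64, height = 64)
  bm <- bump_mesh(enc64)
  dm <- project_mesh(bm$mesh, enc64)
  xs <- (seq_len(64) - 1 - 63 / 2) * 0.25
  expected <- depth_to_pixel(
    max(bm$mesh$vertices[, 3]) - outer(rev(xs), xs, function(y, x) bm$field(x, y)),
    enc64)
  expect_lte(max(abs(dm$pixels - expected)), 1)
})

test_that("projection of an out-of-frame mesh raises a geometry error", {
  enc <- depth_encoding(mm_per_pixel = 0.1, width = 8, height = 8)
  far <- plane_mesh(z = 0, ext = 2)
  far$vertices[, 1] <- far$vertices[, 1] + 100
  far <- tooth_mesh(far$vertices, far$faces, pose_standardized = TRUE)
  expect_error(project_mesh(far, enc), "empty projection")
})

test_that("alpha selection agrees with an exhaustive entropy scan and breaks ties low", {
  enc <- depth_encoding(mm_per_pixel = 0.25, width = 48, height = 48)
  m <- generate_crown(crown_params(seed = 9))
  cands <- c(0.5, 1, 2, 4)
  a <- select_alpha(m, cands, enc)
  ents <- vapply(cands, function(al) {
    e <- enc; e$alpha <- al
    image_entropy(project_mesh(m, e))
  }, 0)
  expect_equal(as.numeric(a), cands[which.max(ents)])
  expect_equal(as.numeric(select_alpha(m, 3.3, enc)), 3.3)
  # flat plane: all candidates give zero entropy, smallest alpha wins
  flat <- plane_mesh(z = 0, ext = 5)
  expect_equal(as.numeric(select_alpha(flat, c(4, 1, 2), enc)), 1)
})

test_that("mesh reconstruction inverts projection within the quantization bound", {
  enc <- depth_encoding(alpha = 2, h = 6, mm_per_pixel = 0.5,
                        width = 24, height = 24)
  pl <- plane_mesh(z = -2)
  pl <- tooth_mesh(pl$vertices, pl$faces, pose_standardized = TRUE)
  enc_pl <- enc; enc_pl$reference_z <- 0
  rec <- reconstruct_mesh(project_mesh(pl, enc_pl))
  expect_lte(max(abs(rec$vertices[, 3] + 2)), depth_quantization_step(enc))

  # interior hole: no face may span it
  dm <- project_mesh(pl, enc_pl)
  dm$pixels[12, 12] <- 0L
  rec2 <- reconstruct_mesh(dm)
  hole_xy <- c((12 - 1 - 23 / 2) * 0.5, (23 / 2 - (12 - 1)) * 0.5)
  for (f in seq_len(nrow(rec2$faces))) {
    v <- rec2$vertices[rec2$faces[f, ], 1:2, drop = FALSE]
    expect_false(all(abs(v[, 1] - hole_xy[1]) < 0.26) &&
                 all(abs(v[, 2] - hole_xy[2]) < 0.26))
  }
  expect_error(reconstruct_mesh(structure(list(
    pixels = matrix(0L, 8, 8), encoding = enc), class = "depth_map")),
    "foreground")
})

test_that("crown geometry survives the depth codec round trip", {
  m <- generate_crown(crown_params(seed = 3))
  enc <- depth_encoding(alpha = 2, h = 6, mm_per_pixel = 11 / 128,
                        width = 128, height = 128)
  dm <- project_mesh(m, enc)
  rec <- reconstruct_mesh(dm)
  dev <- surface_deviation(rec, m)
  expect_lte(dev$rms_mm, 2 * depth_quantization_step(enc))
})

test_that("depth maps round trip through PNG + JSON sidecar bit-exactly", {
  enc <- depth_encoding(alpha = 2, h = 6, mm_per_pixel = 0.25,
                        width = 48, height = 48)
  dm <- project_mesh(generate_crown(crown_params(seed = 2)), enc)
  p <- file.path(withr::local_tempdir(), "dm.png")
  write_depth_map(dm, p)
  back <- read_depth_map(p)
  expect_identical(back$pixels, dm$pixels)
  expect_equal(back$encoding$alpha, dm$encoding$alpha)
  expect_equal(back$encoding$reference_z, dm$encoding$reference_z)
})

test_that("rendered images at distinct alpha genuinely differ", {
  enc <- depth_encoding(mm_per_pixel = 0.25, width = 48, height = 48)
  m <- generate_crown(crown_params(seed = 4))
  imgs <- lapply(c(0.5, 1, 2, 4), function(a) {
    e <- enc; e$alpha <- a
    project_mesh(m, e)$pixels
  })
  for (i in 1:3) expect_false(identical(imgs[[i]], imgs[[i + 1]]))
})
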