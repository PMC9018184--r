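test_that("crown parameters are validated with the offending field named", {
  expect_error(crown_params(n_cusps = 3), "n_cusps")
  expect_error(crown_params(crown_diameter = -1), "crown_diameter")
  expect_error(crown_params(groove_depth = 2, cusp_height = 1.5), "groove_depth")
})

test_that("degenerate flat crown reduces to the base dome", {
  p <- crown_params(cusp_height = 0, groove_depth = 0, seed = 1)
  m <- generate_crown(p)
  expect_equal(max(m$vertices[, 3]), p$base_height, tolerance = 1e-9)
})

test_that("identical seed and parameters give bit-identical meshes", {
  p <- crown_params(seed = 21)
  m1 <- generate_crown(p)
  m2 <- generate_crown(p)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  m3 <- generate_crown(crown_params(seed = 22))
  expect_false(identical(m1$vertices, m3$vertices))
})

test_that("occlusal surface carries exactly n_cusps local height maxima", {
  # brute-force 8-neighbour scan on the rasterized analytic height field
  count_maxima <- function(params, n = 121) {
    fld <- occlurec:::crown_field(params)
    g <- seq(-fld$R, fld$R, length.out = n)
    hf <- outer(g, g, fld$f)
    k <- 0
    for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
      nb <- hf[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (hf[i, j] > 1e-6 && hf[i, j] == max(nb) && sum(nb == max(nb)) == 1)
        k <- k + 1
    }
    k
  }
  expect_equal(count_maxima(crown_params(n_cusps = 4, cusp_height = 2.0,
                                         seed = 7)), 4)
  expect_equal(count_maxima(crown_params(n_cusps = 5, seed = 12)), 5)
})

test_that("groove pixels lie strictly below the adjacent cusp maxima", {
  for (s in c(33, 54)) {
    cs <- generate_case(s)
    gx <- matrix((seq_len(64) - 1 - 63 / 2) * cs$encoding$mm_per_pixel,
                 64, 64, byrow = TRUE)
    gy <- matrix((63 / 2 - (seq_len(64) - 1)) * cs$encoding$mm_per_pixel,
                 64, 64)
    tf <- occlurec:::crown_field(cs$crown_params)
    h <- tf$f(gx, gy)
    # cusp-maximum pixels: local maxima of the finely rasterized field
    n <- 201
    g <- seq(-tf$R, tf$R, length.out = n)
    hf <- outer(g, g, tf$f)
    apex <- c()
    for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
      nb <- hf[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (hf[i, j] > 1e-6 && hf[i, j] == max(nb) && sum(nb == max(nb)) == 1)
        apex <- c(apex, hf[i, j])
    }
    expect_true(all(h[cs$groove_mask == 1] < min(apex)))
  }
})

test_that("generated cases satisfy their channel invariants across seeds", {
  for (s in c(3, 17, 98)) {
    cs <- generate_case(s)
    expect_true(validate_case(cs))
    expect_identical(dim(cs$input_stack)[1:2], dim(cs$target_global))
    expect_identical(dim(cs$local_input_stack)[1:2], dim(cs$target_local))
  }
  expect_error(generate_case(1, local_size = 64, image_size = 64),
               "local_size")
})

test_that("case generation is seed-isolated", {
  a <- generate_case(5); b <- generate_case(5); c <- generate_case(6)
  expect_identical(a$input_stack, b$input_stack)
  expect_identical(a$target_global, b$target_global)
  expect_false(identical(a$input_stack, c$input_stack))
})

test_that("zero contact threshold leaves c2 equal to the groove mask", {
  cs <- generate_case(4, contact_threshold = 0)
  expect_equal(sum(cs$fingerprint_mask), 0)
  expect_identical(cs$input_stack[, , 3], 255 * (cs$groove_mask + 0))
})

test_that("defect area matches brute-force integration of the analytic field", {
  cs <- generate_case(3, margin_fraction = 0.5)
  fld <- occlurec:::crown_field(cs$crown_params)
  n <- 801
  g <- seq(-fld$R, fld$R, length.out = n)
  hf <- outer(g, g, fld$f)
  foot <- outer(g, g, function(x, y) x^2 + y^2 <= fld$R^2)
  frac_analytic <- sum(hf > 0.5 * max(hf) & foot) / sum(foot)
  frac_pixels <- sum(cs$defect_mask) / sum(cs$tooth_footprint)
  expect_lt(abs(frac_pixels - frac_analytic), 0.02)
})

test_that("datasets are reproducible byte for byte with the documented split", {
  dir <- withr::local_tempdir()
  d1 <- file.path(dir, "a"); d2 <- file.path(dir, "b")
  generate_dataset(10, 1, out_dir = d1, image_size = 32, local_size = 16)
  generate_dataset(10, 1, out_dir = d2, image_size = 32, local_size = 16)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))

  ds <- generate_dataset(100, 2, image_size = 32, local_size = 16,
                         keep_cases = FALSE)
  expect_equal(ds$manifest$split_sizes,
               list(train = 85, val = 9, test = 6))

  one <- generate_dataset(1, 3, image_size = 32, local_size = 16)
  expect_equal(length(one$split$train), 1)
  expect_match(one$manifest$warnings, "degenerate split")
})
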