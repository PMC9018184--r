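test_that("generator output keeps input resolution, sigmoid range, and 1/4 bottleneck", {
  g <- build_generator(generator_spec(base_filters = 4), seed = 1)
  x <- array(runif(64 * 64 * 4), c(64, 64, 4))
  y <- generate_surface(g, x)
  expect_identical(dim(y), c(64L, 64L))
  expect_gte(min(y), 0)
  expect_lte(max(y), 1)
  fw <- occlurec:::generator_forward(g, occlurec:::as_batch(x))
  expect_equal(fw$bottleneck_dim[1:2], c(16, 16))   # 1/4 of the input
})

test_that("parameter count equals independent per-layer arithmetic", {
  spec <- generator_spec(in_channels = 4, base_filters = 8,
                         downsample_stages = 2, dilation_rates = c(1, 2, 4, 8),
                         kernel_size = 3)
  g <- build_generator(spec, seed = 2)
  # hand-computed: conv k*k*cin*cout + cout, bn 2*ch, merge 1x1, deconv k=4
  conv <- function(ci, co, k) k * k * ci * co + co
  bn <- function(ch) 2 * ch
  expected <- conv(4, 8, 3) + bn(8) + conv(8, 16, 3) + bn(16) +
    conv(16, 32, 3) + bn(32) + 3 * (conv(32, 32, 3) + bn(32)) +
    conv(128, 32, 1) + bn(32) +
    conv(32, 16, 4) + bn(16) + conv(16, 8, 4) + bn(8) +
    conv(8, 1, 1)
  expect_equal(n_parameters(g), expected)
})

test_that("dilated receptive field formula matches impulse-response support", {
  expect_equal(dilated_receptive_field(1, 3), 3)
  expect_equal(dilated_receptive_field(c(1, 2, 4, 8), 3), 31)
  expect_equal(dilated_receptive_field(2, 3), 5)
  # oracle: propagate a unit impulse through all-ones serial dilated convs
  # and measure the span of the response (a lone dilated kernel has holes)
  support <- function(rates, k, n = 71) {
    x <- array(0, c(n, n, 1, 1))
    x[(n + 1) / 2, (n + 1) / 2, 1, 1] <- 1
    for (r in rates) {
      l <- occlurec:::new_conv(1, 1, k, pad = r * ((k - 1) %/% 2), dil = r)
      l$W[] <- 1; l$b[] <- 0
      x <- occlurec:::fwd_layer(l, x)$y
    }
    diff(range(which(rowSums(x[, , 1, 1]) > 0))) + 1
  }
  expect_equal(support(c(1, 2, 4, 8), 3), 31)
  expect_equal(support(2, 3), 5)
  expect_equal(support(1, 3), 3)
})

test_that("masked compositing returns the preparation outside the defect", {
  g <- build_generator(generator_spec(base_filters = 4), seed = 3)
  x <- array(runif(32 * 32 * 4), c(32, 32, 4))
  zero_mask <- matrix(0, 32, 32)
  expect_identical(generate_surface(g, x, defect_mask = zero_mask), x[, , 1])
  m <- matrix(0, 32, 32); m[10:20, 10:20] <- 1
  y <- generate_surface(g, x, defect_mask = m)
  expect_identical(y[m == 0], x[, , 1][m == 0])
  expect_false(identical(y[m == 1], x[, , 1][m == 1]))
})

test_that("inference is deterministic and construction reproducible from seed", {
  g1 <- build_generator(generator_spec(base_filters = 4), seed = 7)
  g2 <- build_generator(generator_spec(base_filters = 4), seed = 7)
  expect_identical(g1$layers, g2$layers)
  x <- array(runif(32 * 32 * 4), c(32, 32, 4))
  expect_identical(generate_surface(g1, x), generate_surface(g1, x))
  expect_error(generate_surface(g1, array(0, c(32, 32, 3))), "channels")
})

test_that("the fully convolutional dilated core is translation covariant", {
  # serial dilated convs + pointwise nonlinearity, eval mode, interior crop
  set.seed(4)
  layers <- list()
  cin <- 1
  for (r in c(1, 2, 4, 8)) {
    layers <- c(layers, list(occlurec:::new_conv(cin, 3, 3, pad = r, dil = r),
                             occlurec:::new_act("lrelu", 0.2)))
    cin <- 3
  }
  x <- array(rnorm(48 * 48), c(48, 48, 1, 1))
  xs <- array(0, dim(x)); xs[2:48, , 1, 1] <- x[1:47, , 1, 1]  # shift down 1
  y <- occlurec:::seq_forward(layers, x)$out
  ys <- occlurec:::seq_forward(layers, xs)$out
  i <- 18:32
  expect_lt(max(abs(ys[i + 1, i, , 1] - y[i, i, , 1])), 1e-10)
})

test_that("one training step leaves live gradients in every dilated block", {
  g <- build_generator(generator_spec(base_filters = 4), seed = 5)
  x <- array(runif(32 * 32 * 4 * 2), c(32, 32, 4, 2))
  z <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  fw <- occlurec:::generator_forward(g, x, training = TRUE)
  gy <- sign(fw$out - z) / length(z)
  bw <- occlurec:::generator_backward(fw$gen, fw$caches, fw$block_channels, gy)
  for (blk in g$sec$blocks) {
    for (i in blk) {
      gr <- bw$grads[[i]]
      if (is.null(gr)) next   # activation layer
      for (p in names(gr)) expect_gt(sum(abs(gr[[p]])), 0)
    }
  }
})

test_that("invalid generator specifications fail at construction", {
  expect_error(generator_spec(downsample_stages = 0), "downsample_stages")
  expect_error(generator_spec(dilation_rates = c(1, 0)), "dilation")
  expect_error(generator_spec(kernel_size = 4), "odd")
})
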