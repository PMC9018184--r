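test_that("branch arithmetic: stride-2 stack halves to 4x4 and the local branch is 5 convs + FC", {
  spec <- discriminator_spec(base_filters = 16, image_size = 64,
                             local_size = 32)
  d <- build_dual_discriminator(spec, seed = 1)
  is_type <- function(idx, t) vapply(d$layers[idx], function(l) l$type == t, TRUE)
  expect_equal(sum(is_type(d$sec$gtrunk, "conv")), 4)   # 64 -> 4 by halving
  # flatten feeds a 4*4*(16*2^3)-dim FC layer
  fc_g <- d$layers[[d$sec$gfeat[2]]]
  expect_equal(ncol(fc_g$W), 4 * 4 * 128)
  expect_equal(sum(is_type(d$sec$ltrunk, "conv")), 5)
  expect_equal(sum(is_type(c(d$sec$lfeat, d$sec$lhead), "fc")), 2)
  expect_error(discriminator_spec(local_layers = 0), "positive")
})

test_that("scores are probabilities, deterministic in eval mode, and channel-checked", {
  d <- build_dual_discriminator(
    discriminator_spec(base_filters = 4, image_size = 32, local_size = 16),
    seed = 2)
  set.seed(1)
  gs <- array(runif(32 * 32 * 5 * 3), c(32, 32, 5, 3))
  ls <- array(runif(16 * 16 * 5 * 3), c(16, 16, 5, 3))
  pg <- global_score(d, gs)
  pl <- local_score(d, ls)
  pf <- fused_score(d, gs, ls)
  for (p in list(pg, pl, pf)) {
    expect_length(p, 3)
    expect_true(all(p > 0 & p < 1))
  }
  expect_identical(global_score(d, gs), pg)
  expect_identical(local_score(d, ls), pl)
  expect_error(global_score(d, array(0, c(32, 32, 4))), "channels")
  expect_error(local_score(d, array(0, c(16, 16, 6))), "channels")
})

test_that("stacked-channel call matches the array call", {
  d <- build_dual_discriminator(
    discriminator_spec(base_filters = 4, image_size = 32, local_size = 16),
    seed = 3)
  chans <- lapply(1:5, function(i) matrix(runif(32 * 32), 32, 32))
  stacked <- array(0, c(32, 32, 5))
  for (i in 1:5) stacked[, , i] <- chans[[i]]
  expect_equal(do.call(global_score, c(list(d), chans)),
               global_score(d, stacked))
})

test_that("finite differences confirm a live gradient on the crown channel", {
  d <- build_dual_discriminator(
    discriminator_spec(base_filters = 4, image_size = 32, local_size = 16),
    seed = 4)
  set.seed(2)
  gs <- array(runif(32 * 32 * 5), c(32, 32, 5))
  probes <- list(c(16, 16), c(12, 20), c(20, 12))
  eps <- 1e-4
  grads <- vapply(probes, function(p) {
    up <- gs; up[p[1], p[2], 5] <- up[p[1], p[2], 5] + eps
    dn <- gs; dn[p[1], p[2], 5] <- dn[p[1], p[2], 5] - eps
    (global_score(d, up) - global_score(d, dn)) / (2 * eps)
  }, 0)
  expect_gt(max(abs(grads)), 0)
  ls <- array(runif(16 * 16 * 5), c(16, 16, 5))
  gl <- vapply(probes, function(p) {
    up <- ls; up[p[1] %/% 2, p[2] %/% 2, 5] <- up[p[1] %/% 2, p[2] %/% 2, 5] + eps
    dn <- ls; dn[p[1] %/% 2, p[2] %/% 2, 5] <- dn[p[1] %/% 2, p[2] %/% 2, 5] - eps
    (local_score(d, up) - local_score(d, dn)) / (2 * eps)
  }, 0)
  expect_gt(max(abs(gl)), 0)
})

test_that("both branches influence the fused decision (ablation)", {
  d <- build_dual_discriminator(
    discriminator_spec(base_filters = 4, image_size = 32, local_size = 16),
    seed = 5)
  set.seed(3)
  gs <- array(runif(32 * 32 * 5), c(32, 32, 5))
  ls <- array(runif(16 * 16 * 5), c(16, 16, 5))
  bg <- occlurec:::disc_branch_forward(d, "global", gs)
  bl <- occlurec:::disc_branch_forward(bg$disc, "local", ls)
  full <- occlurec:::disc_head_forward(bl$disc, "fhead",
                                       rbind(bg$feat, bl$feat))$prob
  ablated <- occlurec:::disc_head_forward(bl$disc, "fhead",
                                          rbind(bg$feat, 0 * bl$feat))$prob
  expect_false(isTRUE(all.equal(full, ablated)))
})

test_that("crown and gap channels move the score differently", {
  d <- build_dual_discriminator(
    discriminator_spec(base_filters = 4, image_size = 32, local_size = 16),
    seed = 6)
  set.seed(4)
  gs <- array(runif(32 * 32 * 5), c(32, 32, 5))
  ls <- array(runif(16 * 16 * 5), c(16, 16, 5))
  base <- fused_score(d, gs, ls)
  noisy_crown <- gs; noisy_crown[, , 5] <- runif(32 * 32)
  const_gap <- gs; const_gap[, , 4] <- 0.5
  s_crown <- fused_score(d, noisy_crown, ls)
  s_gap <- fused_score(d, const_gap, ls)
  expect_false(isTRUE(all.equal(s_crown, base)))
  expect_false(isTRUE(all.equal(s_crown - base, s_gap - base)))
})

test_that("adversarial objectives reproduce their closed forms", {
  half <- list(G = 0.5, L = 0.5)
  ao <- adversarial_objectives(half, half)
  expect_equal(ao$loss_d, 2 * log(4), tolerance = 1e-9)
  expect_equal(ao$loss_g, 2 * log(2), tolerance = 1e-9)
  eps <- 1e-7
  sharp <- adversarial_objectives(list(G = 1 - eps, L = 1 - eps),
                                  list(G = eps, L = eps))
  expect_lt(sharp$loss_d, 1e-5)
  # batch form: means over per-sample probabilities
  ao2 <- adversarial_objectives(list(G = c(0.5, 0.5), L = c(0.5, 0.5)),
                                list(G = c(0.5, 0.5), L = c(0.5, 0.5)))
  expect_equal(ao2$loss_d, 2 * log(4), tolerance = 1e-9)
})
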