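# Shared fixtures, all generated in code.

with_seed_test <- function(seed, expr) occlurec:::with_seed(seed, expr)

# flat rectangular plane mesh at height z covering [-ext, ext]^2
plane_mesh <- function(z = 0, ext = 8, n = 17) {
  g <- seq(-ext, ext, length.out = n)
  hf <- matrix(z, n, n)
  occlurec:::mesh_from_height_grid(g, g, hf)
}

# small Gaussian bump height-field mesh sampled on the pixel grid of enc
bump_mesh <- function(enc, amp = 3, sigma = 2) {
  W <- enc$width; H <- enc$height
  xs <- (seq_len(W) - 1 - (W - 1) / 2) * enc$mm_per_pixel
  ys <- (seq_len(H) - 1 - (H - 1) / 2) * enc$mm_per_pixel
  hf <- outer(xs, ys, function(x, y) amp * exp(-(x^2 + y^2) / (2 * sigma^2)))
  list(mesh = occlurec:::mesh_from_height_grid(xs, ys, hf),
       field = function(x, y) amp * exp(-(x^2 + y^2) / (2 * sigma^2)))
}

tiny_train_setup <- function(n = 8, seed = 11, image_size = 32,
                             local_size = 16, base = 4) {
  data <- generate_dataset(n, seed, image_size = image_size,
                           local_size = local_size,
                           split = c(train = 0.75, val = 0.125, test = 0.125),
                           keep_cases = TRUE)
  gen <- build_generator(generator_spec(base_filters = base), seed = 1)
  disc <- build_dual_discriminator(
    discriminator_spec(base_filters = base, image_size = image_size,
                       local_size = local_size), seed = 2)
  list(data = data, gen = gen, disc = disc)
}

euler_rotation <- function(a, b, c) {
  rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

tiny_run_yaml <- function(path, n_cases = 8) {
  yaml::write_yaml(list(
    n_cases = n_cases, image_size = 32, local_size = 16,
    alpha_candidates = c(1, 2, 4), base_filters_g = 4, base_filters_d = 4,
    split = list(train = 0.75, val = 0.125, test = 0.125),
    train = list(stage_epochs = c(1, 1, 1), batch_size = 4)), path)
  path
}
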