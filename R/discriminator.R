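#' Dual discriminator specification
#'
#' Configures the global/local discriminative model. The global branch
#' judges the whole scene (preparation, adjacent teeth, conditioning
#' channels, crown image) with stacked 5x5 stride-2 convolutions; the local
#' branch judges the defect crop with exactly five convolutional layers plus
#' a fully connected layer. Each branch ends in a feature vector; the two
#' vectors are fused by concatenation into a single real/fake probability,
#' and per-branch heads are also exposed so the two adversarial objectives
#' can be computed separately (the default training mode).
#'
#' @param global_in_channels,local_in_channels input channels per branch
#'   (x1, c1, c2, d, crown / x1', c1', c3, d', crown').
#' @param base_filters filters of the first convolution; doubled per layer.
#' @param global_kernel,global_stride global-branch convolution geometry.
#' @param local_layers convolutions in the local branch (5).
#' @param feature_dim per-branch embedding size before fusion.
#' @param image_size,local_size input sizes in pixels (fix the flatten dims).
#' @param leaky_slope negative slope of the leaky ReLUs.
#' @return object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(global_in_channels = 5, local_in_channels = 5,
                               base_filters = 16, global_kernel = 5,
                               global_stride = 2, local_layers = 5,
                               feature_dim = 128, image_size = 64,
                               local_size = 32, leaky_slope = 0.2) {
  if (global_kernel < 1 || global_stride < 1 || local_layers < 1)
    stop("kernel, stride and layer counts must be positive")
  structure(list(global_in_channels = as.integer(global_in_channels),
                 local_in_channels = as.integer(local_in_channels),
                 base_filters = as.integer(base_filters),
                 global_kernel = as.integer(global_kernel),
                 global_stride = as.integer(global_stride),
                 local_layers = as.integer(local_layers),
                 feature_dim = as.integer(feature_dim),
                 image_size = as.integer(image_size),
                 local_size = as.integer(local_size),
                 leaky_slope = leaky_slope),
            class = "discriminator_spec")
}

conv_out_size <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1

#' Build the dual global/local discriminator
#'
#' @param spec a [discriminator_spec()].
#' @param seed integer seed for weight initialization.
#' @return object of class `occ_discriminator` with sections `gtrunk`,
#'   `gfeat`, `ghead`, `ltrunk`, `lfeat`, `lhead`, `fhead`.
#' @export
build_dual_discriminator <- function(spec = discriminator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  with_seed(seed, {
    sl <- spec$leaky_slope; k <- spec$global_kernel; st <- spec$global_stride
    pad <- (k - 1) %/% 2
    layers <- list(); sec <- list()
    add <- function(ls) {
      n0 <- length(layers)
      layers[seq_along(ls) + n0] <<- ls
      n0 + seq_along(ls)
    }
    # global branch: stride-2 convs until the map is ~4 px
    g_layers <- max(1, floor(log2(spec$image_size)) - 2)
    prev <- spec$global_in_channels
    sz <- spec$image_size
    idx <- integer(0)
    for (i in seq_len(g_layers)) {
      ch <- spec$base_filters * 2^(i - 1)
      ls <- list(new_conv(prev, ch, k, stride = st, pad = pad))
      if (i > 1) ls <- c(ls, list(new_bn(ch)))
      ls <- c(ls, list(new_act("lrelu", sl)))
      idx <- c(idx, add(ls))
      prev <- ch
      sz <- conv_out_size(sz, k, st, pad)
    }
    sec$gtrunk <- idx
    sec$gfeat <- add(list(new_flatten(), new_fc(sz * sz * prev, spec$feature_dim),
                          new_act("lrelu", sl)))
    sec$ghead <- add(list(new_fc(spec$feature_dim, 1), new_act("sigmoid")))
    # local branch: exactly local_layers convs + FC
    prev <- spec$local_in_channels
    sz <- spec$local_size
    idx <- integer(0)
    for (i in seq_len(spec$local_layers)) {
      ch <- spec$base_filters * 2^(min(i, 4) - 1)
      ls <- list(new_conv(prev, ch, k, stride = st, pad = pad))
      if (i > 1) ls <- c(ls, list(new_bn(ch)))
      ls <- c(ls, list(new_act("lrelu", sl)))
      idx <- c(idx, add(ls))
      prev <- ch
      sz <- conv_out_size(sz, k, st, pad)
    }
    if (sz < 1) stop("local_size too small for local_layers stride-2 convolutions")
    sec$ltrunk <- idx
    sec$lfeat <- add(list(new_flatten(), new_fc(sz * sz * prev, spec$feature_dim),
                          new_act("lrelu", sl)))
    sec$lhead <- add(list(new_fc(spec$feature_dim, 1), new_act("sigmoid")))
    sec$fhead <- add(list(new_fc(2 * spec$feature_dim, 1), new_act("sigmoid")))
    structure(list(spec = spec, layers = layers, sec = sec),
              class = "occ_discriminator")
  })
}

#' @export
print.occ_discriminator <- function(x, ...) {
  nconv <- function(idx) sum(vapply(x$layers[idx], function(l) l$type == "conv", TRUE))
  cat(sprintf(
    "occ_discriminator: global %d convs + FC, local %d convs + FC, feature dim %d, %d parameters\n",
    nconv(x$sec$gtrunk), nconv(x$sec$ltrunk), x$spec$feature_dim,
    n_parameters(x)))
  invisible(x)
}

# forward through one branch (trunk + feature); returns features + caches
disc_branch_forward <- function(disc, branch = c("global", "local"), x,
                                training = FALSE) {
  branch <- match.arg(branch)
  idx <- c(if (branch == "global") disc$sec$gtrunk else disc$sec$ltrunk,
           if (branch == "global") disc$sec$gfeat else disc$sec$lfeat)
  r <- seq_forward(disc$layers[idx], as_batch(x), training)
  disc$layers[idx] <- r$layers
  list(feat = r$out, caches = r$caches, idx = idx, disc = disc)
}

disc_head_forward <- function(disc, head, feat, training = FALSE) {
  idx <- disc$sec[[head]]
  r <- seq_forward(disc$layers[idx], feat, training)
  disc$layers[idx] <- r$layers
  list(prob = as.numeric(r$out), caches = r$caches, idx = idx, disc = disc)
}

check_channels <- function(x, expected, what) {
  x <- as_batch(x)
  if (dim(x)[3] != expected)
    stop(sprintf("%s expects %d channels, got %d", what, expected, dim(x)[3]))
  x
}

#' Per-branch real/fake probabilities
#'
#' `global_score()` scores the full-context stack (x1, c1, c2, d, crown);
#' `local_score()` scores the defect-crop stack (x1', c1', c3, d', crown');
#' `fused_score()` concatenates both branch embeddings and emits the joint
#' probability of the scene being a real dentist-designed crown.
#'
#' Inputs may be given as one stacked array (channels in the documented
#' order, `[0, 1]` scale) or as separate channel matrices.
#'
#' @param disc an [build_dual_discriminator()] network.
#' @param x stacked `H x W x C (x N)` array, or the first channel when the
#'   remaining channels are passed via `...`.
#' @param ... remaining channel matrices (stacked in order after `x`).
#' @return numeric probability vector (one per batch sample).
#' @export
global_score <- function(disc, x, ...) {
  stk <- stack_channels(x, ...)
  stk <- check_channels(stk, disc$spec$global_in_channels, "global discriminator")
  b <- disc_branch_forward(disc, "global", stk)
  disc_head_forward(b$disc, "ghead", b$feat)$prob
}

#' @rdname global_score
#' @export
local_score <- function(disc, x, ...) {
  stk <- stack_channels(x, ...)
  stk <- check_channels(stk, disc$spec$local_in_channels, "local discriminator")
  b <- disc_branch_forward(disc, "local", stk)
  disc_head_forward(b$disc, "lhead", b$feat)$prob
}

#' @rdname global_score
#' @param global_stack,local_stack the two branch inputs for the fused score.
#' @export
fused_score <- function(disc, global_stack, local_stack) {
  gs <- check_channels(global_stack, disc$spec$global_in_channels,
                       "global discriminator")
  ls <- check_channels(local_stack, disc$spec$local_in_channels,
                       "local discriminator")
  bg <- disc_branch_forward(disc, "global", gs)
  bl <- disc_branch_forward(bg$disc, "local", ls)
  feat <- rbind(bg$feat, bl$feat)
  disc_head_forward(bl$disc, "fhead", feat)$prob
}

stack_channels <- function(x, ...) {
  extra <- list(...)
  if (!length(extra)) return(x)
  xs <- c(list(x), extra)
  a <- array(0, c(dim(xs[[1]])[1], dim(xs[[1]])[2], length(xs)))
  for (i in seq_along(xs)) a[, , i] <- xs[[i]]
  a
}

#' Adversarial objectives of the dual-discriminator game
#'
#' For discriminators `k` in (global, local), the discriminator loss is the
#' sum over branches of `-(log D_k(real) + log(1 - D_k(fake)))` and the
#' generator adversarial loss is the non-saturating form
#' `-sum_k log D_k(fake)`. Probabilities are clipped to
#' `[eps, 1 - eps]` before the log; losses are means over the batch.
#'
#' @param d_real,d_fake lists with numeric probability vectors `G` (global)
#'   and `L` (local) on real and generated samples.
#' @param eps clipping constant (default 1e-7).
#' @return list with `loss_d` and `loss_g`.
#' @export
adversarial_objectives <- function(d_real, d_fake, eps = 1e-7) {
  cl <- function(p) clamp(p, eps, 1 - eps)
  loss_d <- mean(-(log(cl(d_real$G)) + log(1 - cl(d_fake$G)))) +
            mean(-(log(cl(d_real$L)) + log(1 - cl(d_fake$L))))
  loss_g <- mean(-log(cl(d_fake$G))) + mean(-log(cl(d_fake$L)))
  list(loss_d = loss_d, loss_g = loss_g)
}
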