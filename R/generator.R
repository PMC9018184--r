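#' Generator architecture specification
#'
#' Configures the encoder-decoder completion network: stride-2 convolutions
#' shrink the input to 1/4 resolution (with `downsample_stages = 2`), a
#' four-block multi-rate dilated-convolution bottleneck widens the receptive
#' field without further downsampling, the four block outputs are
#' concatenated channel-wise and merged, and transposed convolutions restore
#' the input resolution before a 1x1 convolution + sigmoid emits the
#' occlusal-surface image in `[0, 1]`. Every convolution except the last is
#' followed by batch normalization and a leaky ReLU.
#'
#' @param in_channels stacked conditioning channels (preparation, opposing
#'   tooth, morphology mask, gap field).
#' @param base_filters filters of the first encoder stage; stages double it
#'   (default 64 giving 64 -> 128 -> 256 at the bottleneck).
#' @param downsample_stages number of stride-2 encoder stages (>= 1).
#' @param dilation_rates dilation rate of each bottleneck block.
#' @param kernel_size convolution kernel size (odd).
#' @param leaky_slope negative slope of every leaky ReLU.
#' @param out_channels output channels (1).
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(in_channels = 4, base_filters = 64,
                           downsample_stages = 2,
                           dilation_rates = c(1, 2, 4, 8), kernel_size = 3,
                           leaky_slope = 0.2, out_channels = 1) {
  if (downsample_stages < 1) stop("downsample_stages must be >= 1")
  if (any(dilation_rates < 1)) stop("dilation rates must be strictly positive")
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  structure(list(in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 downsample_stages = as.integer(downsample_stages),
                 dilation_rates = as.integer(dilation_rates),
                 kernel_size = as.integer(kernel_size),
                 leaky_slope = leaky_slope,
                 out_channels = as.integer(out_channels)),
            class = "generator_spec")
}

#' Build the completion-network generator
#'
#' Instantiates the architecture of [generator_spec()] with He-initialized
#' weights. The construction is deterministic given `seed`.
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed for weight initialization.
#' @return object of class `occ_generator`.
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(seed, {
    k <- spec$kernel_size; sl <- spec$leaky_slope
    S <- spec$downsample_stages
    cb <- spec$base_filters * 2^S         # bottleneck width
    layers <- list(); sec <- list()
    add <- function(ls) {
      n0 <- length(layers)
      layers[seq_along(ls) + n0] <<- ls
      n0 + seq_along(ls)
    }
    prev <- spec$in_channels
    enc_idx <- integer(0)
    for (s in seq_len(S)) {
      ch <- spec$base_filters * 2^(s - 1)
      enc_idx <- c(enc_idx, add(list(
        new_conv(prev, ch, k, stride = 2), new_bn(ch), new_act("lrelu", sl))))
      prev <- ch
    }
    sec$enc <- enc_idx
    sec$blocks <- list()
    for (i in seq_along(spec$dilation_rates)) {
      r <- spec$dilation_rates[i]
      sec$blocks[[i]] <- add(list(
        new_conv(prev, cb, k, stride = 1, pad = r * ((k - 1) %/% 2), dil = r),
        new_bn(cb), new_act("lrelu", sl)))
      prev <- cb
    }
    ncat <- cb * length(spec$dilation_rates)
    sec$merge <- add(list(new_conv(ncat, cb, 1, pad = 0), new_bn(cb),
                          new_act("lrelu", sl)))
    prev <- cb
    dec_idx <- integer(0)
    for (s in rev(seq_len(S))) {
      ch <- spec$base_filters * 2^(s - 1)
      dec_idx <- c(dec_idx, add(list(
        new_convt(prev, ch, 4, stride = 2, pad = 1), new_bn(ch),
        new_act("lrelu", sl))))
      prev <- ch
    }
    sec$dec <- dec_idx
    sec$out <- add(list(new_conv(prev, spec$out_channels, 1, pad = 0),
                        new_act("sigmoid")))
    structure(list(spec = spec, layers = layers, sec = sec),
              class = "occ_generator")
  })
}

#' @export
print.occ_generator <- function(x, ...) {
  cat(sprintf(
    "occ_generator: %d-ch input, base %d, %d downsampling stages, dilations [%s], %d parameters\n",
    x$spec$in_channels, x$spec$base_filters, x$spec$downsample_stages,
    paste(x$spec$dilation_rates, collapse = ","), n_parameters(x)))
  invisible(x)
}

# Full forward pass. Returns out, per-section caches, updated layers (BN
# running stats) and the bottleneck feature dimensions.
generator_forward <- function(gen, x, training = FALSE) {
  x <- as_batch(x)
  sec <- gen$sec; L <- gen$layers
  run <- function(idx, x) {
    r <- seq_forward(L[idx], x, training)
    L[idx] <<- r$layers
    r
  }
  enc <- run(sec$enc, x)
  h <- enc$out
  blocks <- vector("list", length(sec$blocks))
  bouts <- vector("list", length(sec$blocks))
  for (i in seq_along(sec$blocks)) {
    blocks[[i]] <- run(sec$blocks[[i]], h)
    h <- blocks[[i]]$out
    bouts[[i]] <- h
  }
  cat_in <- cat_channels(bouts)
  merge <- run(sec$merge, cat_in)
  dec <- run(sec$dec, merge$out)
  out <- run(sec$out, dec$out)
  gen$layers <- L
  list(out = out$out, gen = gen,
       caches = list(enc = enc$caches, blocks = lapply(blocks, `[[`, "caches"),
                     merge = merge$caches, dec = dec$caches, out = out$caches),
       bottleneck_dim = dim(merge$out),
       block_channels = vapply(bouts, function(b) dim(b)[3], 0))
}

generator_backward <- function(gen, caches, block_channels, gy) {
  sec <- gen$sec; L <- gen$layers
  grads <- vector("list", length(L))
  back <- function(idx, cc, g) {
    r <- seq_backward(L[idx], cc, g)
    grads[idx] <<- r$grads
    r$gx
  }
  g <- back(sec$out, caches$out, gy)
  g <- back(sec$dec, caches$dec, g)
  g <- back(sec$merge, caches$merge, g)
  slices <- split_channels(g, block_channels)
  gnext <- NULL   # gradient flowing into the output of the previous block
  for (i in rev(seq_along(sec$blocks))) {
    gtot <- slices[[i]]
    if (!is.null(gnext)) gtot <- gtot + gnext
    gnext <- back(sec$blocks[[i]], caches$blocks[[i]], gtot)
  }
  gx <- back(sec$enc, caches$enc, gnext)
  list(gx = gx, grads = grads)
}

#' Theoretical receptive field of a serial dilated stack
#'
#' For kernel size `k` and dilation rates `r_i` applied in series, the
#' receptive field is `1 + sum_i r_i * (k - 1)` pixels.
#'
#' @param rates dilation rates (non-empty).
#' @param kernel kernel size.
#' @return receptive field in pixels.
#' @export
dilated_receptive_field <- function(rates, kernel) {
  if (length(rates) < 1) stop("rates must be non-empty")
  1 + sum(rates * (kernel - 1))
}

#' Synthesize the missing occlusal surface
#'
#' Runs a single forward pass of the generator in inference mode. When a
#' defect mask is supplied the output is composited as
#' `output * mask + preparation * (1 - mask)`, so only the missing region is
#' synthesized and everything outside the defect is returned unchanged (the
#' preparation channel is channel 1 of the stack, on the `[0, 1]` scale).
#'
#' @param gen an [build_generator()] network.
#' @param input_stack `H x W x C` array (or `H x W x C x N` batch) of
#'   conditioning channels scaled to `[0, 1]`.
#' @param defect_mask optional binary `H x W` matrix (or `H x W x N`).
#' @return `H x W` matrix in `[0, 1]` (or `H x W x N` for batches).
#' @export
generate_surface <- function(gen, input_stack, defect_mask = NULL) {
  stopifnot(inherits(gen, "occ_generator"))
  single <- length(dim(input_stack)) == 3
  x <- as_batch(input_stack)
  if (dim(x)[3] != gen$spec$in_channels)
    stop(sprintf("input has %d channels; generator expects %d",
                 dim(x)[3], gen$spec$in_channels))
  out <- generator_forward(gen, x, training = FALSE)$out
  y <- out[, , 1, , drop = TRUE]
  if (length(dim(y)) < 2) y <- matrix(y, dim(x)[1], dim(x)[2])
  if (!is.null(defect_mask)) {
    m <- defect_mask
    prep <- x[, , 1, , drop = TRUE]
    y <- y * m + prep * (1 - m)
  }
  if (single && length(dim(y)) == 3 && dim(y)[3] == 1) y <- y[, , 1]
  y
}
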