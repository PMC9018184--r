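# Minimal deterministic CPU layer engine. Activations are H x W x C x N
# arrays (column-major); conv kernels are kh x kw x Cin x Cout. Every layer
# is a plain list with a `type`; forward passes return caches that the
# matching backward pass consumes. He-style init draws from the R RNG, so a
# set.seed() before construction fixes the weights.

new_conv <- function(cin, cout, k, stride = 1, pad = floor(k / 2), dil = 1) {
  sd <- sqrt(2 / (k * k * cin))
  list(type = "conv", W = array(rnorm(k * k * cin * cout, 0, sd),
                                c(k, k, cin, cout)),
       b = numeric(cout), stride = as.integer(stride), pad = as.integer(pad),
       dil = as.integer(dil))
}

new_convt <- function(cin, cout, k = 4, stride = 2, pad = 1) {
  sd <- sqrt(2 / (k * k * cin))
  list(type = "convt", W = array(rnorm(k * k * cin * cout, 0, sd),
                                 c(k, k, cin, cout)),
       b = numeric(cout), stride = as.integer(stride), pad = as.integer(pad))
}

new_bn <- function(ch) {
  # running stats are warm-started from the first training batch (see
  # fwd_layer) so eval-mode behaviour is sensible from the first epoch
  list(type = "bn", gamma = rep(1, ch), beta = numeric(ch),
       rmean = numeric(ch), rvar = rep(1, ch), warm = FALSE,
       eps = 1e-5, momentum = 0.9)
}

new_act <- function(kind, slope = 0) list(type = "act", kind = kind, slope = slope)
new_flatten <- function() list(type = "flatten")

new_fc <- function(nin, nout) {
  list(type = "fc", W = matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nout, nin),
       b = numeric(nout))
}

# reshape (H, W, C, N) so each column is one channel across (H, W, N)
ch_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}
ch_unmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

fwd_layer <- function(l, x, training = FALSE) {
  switch(l$type,
    conv = list(y = cpp_conv_fwd(x, l$W, l$b, l$stride, l$pad, l$dil),
                cache = list(x = x), layer = l),
    convt = list(y = cpp_convt_fwd(x, l$W, l$b, l$stride, l$pad),
                 cache = list(x = x), layer = l),
    bn = {
      d <- dim(x)
      m <- ch_mat(x)
      if (training) {
        mu <- colMeans(m)
        xc <- sweep(m, 2, mu)
        va <- colMeans(xc^2)
        if (!isTRUE(l$warm)) {
          l$rmean <- mu; l$rvar <- va; l$warm <- TRUE
        } else {
          l$rmean <- l$momentum * l$rmean + (1 - l$momentum) * mu
          l$rvar <- l$momentum * l$rvar + (1 - l$momentum) * va
        }
      } else {
        mu <- l$rmean; va <- l$rvar
        xc <- sweep(m, 2, mu)
      }
      ivar <- 1 / sqrt(va + l$eps)
      xhat <- sweep(xc, 2, ivar, `*`)
      y <- sweep(sweep(xhat, 2, l$gamma, `*`), 2, l$beta, `+`)
      list(y = ch_unmat(y, d),
           cache = list(xhat = xhat, ivar = ivar, xc = xc, d = d,
                        training = training),
           layer = l)
    },
    act = {
      y <- switch(l$kind,
        relu = pmax(x, 0),
        lrelu = ifelse(x > 0, x, l$slope * x),
        sigmoid = 1 / (1 + exp(-x)))
      if (!is.null(dim(x))) dim(y) <- dim(x)
      list(y = y, cache = list(x = x, y = y), layer = l)
    },
    flatten = {
      d <- dim(x)
      list(y = matrix(x, ncol = d[4]), cache = list(d = d), layer = l)
    },
    fc = list(y = sweep(l$W %*% x, 1, l$b, `+`), cache = list(x = x), layer = l),
    stop("unknown layer type: ", l$type))
}

bwd_layer <- function(l, cache, gy) {
  switch(l$type,
    conv = {
      r <- cpp_conv_bwd(cache$x, l$W, gy, l$stride, l$pad, l$dil)
      list(gx = r$gx, grads = list(W = r$gw, b = r$gb))
    },
    convt = {
      r <- cpp_convt_bwd(cache$x, l$W, gy, l$stride, l$pad)
      list(gx = r$gx, grads = list(W = r$gw, b = r$gb))
    },
    bn = {
      d <- cache$d
      gm <- ch_mat(gy)
      gbeta <- colSums(gm)
      ggamma <- colSums(gm * cache$xhat)
      if (cache$training) {
        m <- nrow(gm)
        gxhat <- sweep(gm, 2, l$gamma, `*`)
        t1 <- sweep(gxhat, 2, colMeans(gxhat))
        t2 <- sweep(cache$xhat, 2, colMeans(gxhat * cache$xhat), `*`)
        gx <- sweep(t1 - t2, 2, cache$ivar, `*`)
      } else {
        gx <- sweep(sweep(gm, 2, l$gamma, `*`), 2, cache$ivar, `*`)
      }
      list(gx = ch_unmat(gx, d), grads = list(gamma = ggamma, beta = gbeta))
    },
    act = {
      gx <- switch(l$kind,
        relu = gy * (cache$x > 0),
        lrelu = gy * ifelse(cache$x > 0, 1, l$slope),
        sigmoid = gy * cache$y * (1 - cache$y))
      if (!is.null(dim(cache$x))) dim(gx) <- dim(cache$x)
      list(gx = gx, grads = NULL)
    },
    flatten = list(gx = array(gy, cache$d), grads = NULL),
    fc = list(gx = t(l$W) %*% gy,
              grads = list(W = gy %*% t(cache$x), b = rowSums(gy))))
}

seq_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- fwd_layer(layers[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- bwd_layer(layers[[i]], caches[[i]], gy)
    gy <- r$gx
    grads[i] <- list(r$grads)   # keep NULL placeholders for param-free layers
  }
  list(gx = gy, grads = grads)
}

layer_param_names <- function(l) {
  intersect(names(l), c("W", "b", "gamma", "beta"))
}

#' Number of trainable parameters of a network
#'
#' @param net an `occ_generator` or `occ_discriminator`.
#' @return integer count of trainable scalars.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$layers, function(l)
    sum(vapply(layer_param_names(l), function(p) length(l[[p]]), 0)), 0))
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    ps <- layer_param_names(l)
    if (!length(ps)) return(NULL)
    stats::setNames(lapply(ps, function(p)
      list(m = l[[p]] * 0, v = l[[p]] * 0)), ps)
  })
}

adam_step <- function(layers, grads, state, t, lr, beta1, beta2, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mh / (sqrt(vh) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

# sum two parallel grad lists (element-wise); either may be NULL
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) { a[i] <- list(b[[i]]); next }
    if (is.null(b[[i]])) next
    for (p in names(a[[i]])) a[[i]][[p]] <- a[[i]][[p]] + b[[i]][[p]]
  }
  a
}

scale_grads <- function(g, s) {
  lapply(g, function(l) if (is.null(l)) NULL else lapply(l, function(p) p * s))
}

cat_channels <- function(xs) {
  d1 <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], 0)
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0
  for (k in seq_along(xs)) {
    out[, , off + seq_len(cs[k]), ] <- xs[[k]]
    off <- off + cs[k]
  }
  out
}

split_channels <- function(g, sizes) {
  out <- vector("list", length(sizes))
  off <- 0
  for (k in seq_along(sizes)) {
    out[[k]] <- g[, , off + seq_len(sizes[k]), , drop = FALSE]
    off <- off + sizes[k]
  }
  out
}

as_batch <- function(x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L, 1L)
  x
}
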