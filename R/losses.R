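#' Loss weights of the composite objective
#'
#' The total generator objective is
#' `L_total = L_adv + lambda_L1 * L_L1 + lambda_mse * L_mse + lambda_per * L_per`
#' with defaults 100 / 50 / 50.
#'
#' @param lambda_L1,lambda_mse,lambda_per non-negative weights.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_L1 = 100, lambda_mse = 50, lambda_per = 50) {
  if (any(c(lambda_L1, lambda_mse, lambda_per) < 0))
    stop("loss weights must be >= 0")
  structure(list(lambda_L1 = lambda_L1, lambda_mse = lambda_mse,
                 lambda_per = lambda_per), class = "loss_weights")
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop("loss error: images have different shapes")
}

#' Pixel losses
#'
#' `mse_loss()` is the squared Frobenius norm of the difference normalized by
#' pixel count (mean-squared convention); `l1_loss()` is the mean absolute
#' difference.
#'
#' @param gen,target images (matrices or arrays) of identical shape.
#' @return scalar loss.
#' @export
mse_loss <- function(gen, target) {
  check_same_shape(gen, target)
  mean((gen - target)^2)
}

#' @rdname mse_loss
#' @export
l1_loss <- function(gen, target) {
  check_same_shape(gen, target)
  mean(abs(gen - target))
}

#' Perceptual loss on network features
#'
#' Sum over tagged feature maps of the mean L1 distance between the feature
#' responses of `gen` and `target`, each map normalized by its own
#' `C * H * W`. Tagged maps are the outputs of every convolutional layer of
#' `feature_net`. By default the training loop uses the frozen convolutional
#' trunk of the global discriminator as the feature network; any list of
#' layers with at least one convolution is accepted.
#'
#' @param gen,target images or channel stacks of identical shape.
#' @param feature_net an `occ_discriminator` (its global trunk is used) or a
#'   plain list of layers.
#' @return scalar loss.
#' @export
perceptual_loss <- function(gen, target, feature_net) {
  check_same_shape(gen, target)
  layers <- feature_layers(feature_net)
  fa <- tapped_features(layers, as_batch(gen))
  fb <- tapped_features(layers, as_batch(target))
  if (!length(fa$taps)) stop("configuration error: feature_net has no convolution layers")
  s <- 0
  for (i in seq_along(fa$taps))
    s <- s + mean(abs(fa$feats[[i]] - fb$feats[[i]]))
  s
}

feature_layers <- function(feature_net) {
  if (inherits(feature_net, "occ_discriminator"))
    return(feature_net$layers[feature_net$sec$gtrunk])
  if (is.list(feature_net) && !is.null(feature_net$layers))
    return(feature_net$layers)
  feature_net
}

# run layers, recording the output of each conv/convt layer
tapped_features <- function(layers, x) {
  feats <- list(); taps <- integer(0)
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- fwd_layer(layers[[i]], x, training = FALSE)
    x <- r$y
    caches[[i]] <- r$cache
    if (layers[[i]]$type %in% c("conv", "convt")) {
      feats[[length(feats) + 1]] <- x
      taps <- c(taps, i)
    }
  }
  list(feats = feats, taps = taps, caches = caches, out = x)
}

# loss and gradient w.r.t. `a` of the perceptual distance between a and b
perceptual_loss_grad <- function(a, b, layers) {
  fa <- tapped_features(layers, a)
  fb <- tapped_features(layers, b)
  loss <- 0
  tapg <- vector("list", length(layers))
  for (k in seq_along(fa$taps)) {
    d <- fa$feats[[k]] - fb$feats[[k]]
    loss <- loss + mean(abs(d))
    tapg[[fa$taps[k]]] <- sign(d) / length(d)
  }
  g <- NULL
  for (i in rev(seq_along(layers))) {
    if (!is.null(tapg[[i]])) g <- if (is.null(g)) tapg[[i]] else g + tapg[[i]]
    if (is.null(g)) next
    g <- bwd_layer(layers[[i]], fa$caches[[i]], g)$gx
  }
  list(loss = loss, gx = g)
}

#' Weighted total loss
#'
#' `adv + lambda_L1 * l1 + lambda_mse * mse + lambda_per * per`. A
#' non-finite component aborts with the component named.
#'
#' @param adv,l1,mse,per scalar loss components.
#' @param w a [loss_weights()].
#' @return scalar total loss.
#' @export
total_loss <- function(adv, l1, mse, per, w = loss_weights()) {
  comp <- c(adv = adv, l1 = l1, mse = mse, per = per)
  bad <- names(comp)[!is.finite(comp)]
  if (length(bad))
    stop("training abort: non-finite loss component: ", paste(bad, collapse = ", "))
  adv + w$lambda_L1 * l1 + w$lambda_mse * mse + w$lambda_per * per
}
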