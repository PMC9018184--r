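#' Training configuration
#'
#' Optimizer and schedule settings. Defaults follow the staged-training
#' recipe: Adam with learning rate 2e-4, beta1 = 0.5, beta2 = 0.999, leaky
#' ReLU slope 0.2.
#'
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param leaky_slope negative slope of leaky ReLUs (recorded here; applied
#'   at network construction).
#' @param stage_epochs integer vector `(e1, e2, e3)`: epochs of Stage I
#'   (generator pre-training), Stage II (discriminator warm-up against the
#'   frozen generator) and Stage III (joint adversarial training).
#' @param batch_size minibatch size.
#' @param seed RNG seed for shuffling and any stochastic choice in training.
#' @param adv_mode `"per-branch"` backpropagates the two per-branch
#'   probabilities (the sum-over-k objective); `"fused"` backpropagates the
#'   single fused probability.
#' @param stage2_mode `"adversarial"` trains the discriminators against the
#'   frozen generator during Stage II; `"frozen-validation"` only logs.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                         leaky_slope = 0.2, stage_epochs = c(5, 5, 10),
                         batch_size = 4, seed = 1L,
                         adv_mode = c("per-branch", "fused"),
                         stage2_mode = c("adversarial", "frozen-validation")) {
  if (lr <= 0) stop("lr must be > 0")
  if (any(stage_epochs < 0)) stop("stage_epochs must be >= 0")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 leaky_slope = leaky_slope,
                 stage_epochs = as.integer(stage_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 adv_mode = match.arg(adv_mode),
                 stage2_mode = match.arg(stage2_mode)),
            class = "train_config")
}

# per-case tensors on the [0,1] scale, with the local-crop operator
prep_case <- function(cs) {
  rows <- cs$bbox$rows; cols <- cs$bbox$cols
  l <- cs$local_size
  list(gin = cs$input_stack / 255,
       z = cs$target_global / 255,
       mask = cs$defect_mask,
       fp = cs$fingerprint_mask, gr = cs$groove_mask,
       lfix = cs$local_input_stack / 255,   # x1', c1', c3, d'
       zloc = cs$target_local / 255,
       rows = rows, cols = cols,
       Ry = interp_matrix(length(rows), l), Rx = interp_matrix(length(cols), l))
}

crop_local <- function(img, pc) pc$Ry %*% img[pc$rows, pc$cols] %*% t(pc$Rx)

scatter_local <- function(g, gloc, pc) {
  g[pc$rows, pc$cols] <- g[pc$rows, pc$cols] + t(pc$Ry) %*% gloc %*% pc$Rx
  g
}

make_batch <- function(pcs, idx) {
  H <- nrow(pcs[[idx[1]]]$z); W <- ncol(pcs[[idx[1]]]$z); B <- length(idx)
  gin <- array(0, c(H, W, 4, B)); z <- array(0, c(H, W, 1, B))
  mask <- array(0, c(H, W, 1, B))
  for (j in seq_along(idx)) {
    p <- pcs[[idx[j]]]
    gin[, , , j] <- p$gin; z[, , 1, j] <- p$z; mask[, , 1, j] <- p$mask
  }
  list(gin = gin, z = z, mask = mask, pcs = pcs[idx], B = B, H = H, W = W)
}

composite_batch <- function(out, bt) {
  prep <- bt$gin[, , 1, , drop = FALSE]
  dim(prep) <- dim(out)
  out * bt$mask + prep * (1 - bt$mask)
}

# global/local discriminator stacks for a batch, crown channel last
disc_stacks <- function(bt, crown) {
  B <- bt$B; l <- nrow(bt$pcs[[1]]$lfix)
  gs <- array(0, c(bt$H, bt$W, 5, B)); ls <- array(0, c(l, l, 5, B))
  for (j in seq_len(B)) {
    gs[, , 1:4, j] <- bt$gin[, , , j]
    gs[, , 5, j] <- crown[, , 1, j]
    ls[, , 1:4, j] <- bt$pcs[[j]]$lfix
    ls[, , 5, j] <- crop_local(crown[, , 1, j], bt$pcs[[j]])
  }
  list(gs = gs, ls = ls)
}

disc_forward_full <- function(disc, gs, ls, training = FALSE) {
  bg <- disc_branch_forward(disc, "global", gs, training)
  bl <- disc_branch_forward(bg$disc, "local", ls, training)
  hg <- disc_head_forward(bl$disc, "ghead", bg$feat, training)
  hl <- disc_head_forward(hg$disc, "lhead", bl$feat, training)
  hf <- disc_head_forward(hl$disc, "fhead", rbind(bg$feat, bl$feat), training)
  list(disc = hf$disc, pG = hg$prob, pL = hl$prob, pF = hf$prob,
       feat_g = bg$feat, feat_l = bl$feat,
       caches = list(g = bg$caches, l = bl$caches, hg = hg$caches,
                     hl = hl$caches, hf = hf$caches),
       idx = list(g = bg$idx, l = bl$idx, hg = hg$idx, hl = hl$idx,
                  hf = hf$idx))
}

# gpG/gpL/gpF: gradients w.r.t. the per-branch and fused probabilities
disc_backward_full <- function(disc, fw, gpG, gpL, gpF = NULL) {
  L <- disc$layers
  grads <- vector("list", length(L))
  put <- function(idx, g) grads[idx] <<- g
  fd <- disc$spec$feature_dim
  gfeat_g <- 0; gfeat_l <- 0
  rg <- seq_backward(L[fw$idx$hg], fw$caches$hg, matrix(gpG, 1))
  put(fw$idx$hg, rg$grads); gfeat_g <- gfeat_g + rg$gx
  rl <- seq_backward(L[fw$idx$hl], fw$caches$hl, matrix(gpL, 1))
  put(fw$idx$hl, rl$grads); gfeat_l <- gfeat_l + rl$gx
  if (!is.null(gpF)) {
    rf <- seq_backward(L[fw$idx$hf], fw$caches$hf, matrix(gpF, 1))
    put(fw$idx$hf, rf$grads)
    gfeat_g <- gfeat_g + rf$gx[seq_len(fd), , drop = FALSE]
    gfeat_l <- gfeat_l + rf$gx[fd + seq_len(fd), , drop = FALSE]
  }
  bg <- seq_backward(L[fw$idx$g], fw$caches$g, gfeat_g)
  put(fw$idx$g, bg$grads)
  bl <- seq_backward(L[fw$idx$l], fw$caches$l, gfeat_l)
  put(fw$idx$l, bl$grads)
  list(grads = grads, gin_g = bg$gx, gin_l = bl$gx)
}

#' Staged adversarial training
#'
#' Trains the completion network in three stages of increasing complexity:
#' \describe{
#'   \item{Stage I}{the generator alone minimizes `lambda_L1 * L1` plus two
#'     masked constraint terms -- an occlusion spatial constraint (L1 over
#'     the occlusal-fingerprint mask) and a biological-morphology constraint
#'     (L1 over the groove mask).}
#'   \item{Stage II}{the generator is frozen (bit-identical weights before
#'     and after) while both discriminators train from scratch against its
#'     outputs; MSE and perceptual losses are logged on each minibatch.}
#'   \item{Stage III}{generator and both discriminators train jointly, the
#'     generator with the full weighted objective
#'     `L_adv + lambda_L1 L_L1 + lambda_mse L_mse + lambda_per L_per`,
#'     alternating one discriminator and one generator update per batch.}
#' }
#' Perceptual features come from the frozen convolutional trunk of the
#' global discriminator. All updates use Adam with the settings in `cfg`.
#' Per-iteration loss records are kept for each loss over the stages in
#' which it enters the optimized objective; a divergent loss (non-finite, or
#' exceeding 1e4) aborts with the last stage checkpoint retained.
#'
#' @param data a `case_set` with in-memory cases (see [generate_dataset()]).
#' @param generator an [build_generator()] network.
#' @param discriminator an [build_dual_discriminator()] network.
#' @param cfg a [train_config()].
#' @param weights a [loss_weights()].
#' @param constraint_weights named vector with `occlusion` and `morphology`
#'   weights for the Stage-I masked L1 terms.
#' @param log_dir optional directory for the CSV training log.
#' @return object of class `occ_training`: final `generator` and
#'   `discriminator`, the per-iteration `log` data.frame, per-epoch Stage-I
#'   validation L1 (`val_l1`), stage-boundary generator `snapshots`, and a
#'   `status` string.
#' @export
train_staged <- function(data, generator, discriminator,
                         cfg = train_config(), weights = loss_weights(),
                         constraint_weights = c(occlusion = 1, morphology = 1),
                         log_dir = NULL) {
  stopifnot(inherits(data, "case_set"))
  if (is.null(data$cases))
    stop("data must carry in-memory cases (generate_dataset(keep_cases = TRUE))")
  set.seed(cfg$seed)
  pcs <- lapply(data$cases, prep_case)
  tr <- data$split$train; va <- data$split$val
  if (!length(tr)) stop("empty training split")
  B <- min(cfg$batch_size, length(tr))

  gen <- generator; disc <- discriminator
  ad_g <- adam_init(gen$layers); ad_d <- adam_init(disc$layers)
  tg <- 0L; td <- 0L
  log <- list(); it <- 0L
  val_l1 <- data.frame(stage = integer(0), epoch = integer(0), l1 = numeric(0))
  snapshots <- list()
  status <- "ok"
  eps <- 1e-7
  w_occ <- constraint_weights[["occlusion"]]
  w_mor <- constraint_weights[["morphology"]]

  push_log <- function(stage, l1 = NA, mse = NA, per = NA, adv = NA, d = NA) {
    it <<- it + 1L
    log[[it]] <<- data.frame(iteration = it, stage = stage, l_l1 = l1,
                             l_mse = mse, l_per = per, l_adv = adv, l_disc = d)
  }
  check_finite <- function(...) {
    v <- c(...)
    v <- v[!is.na(v)]
    if (any(!is.finite(v)) || any(v > 1e4)) {
      status <<- "diverged"
      TRUE
    } else FALSE
  }
  val_l1_now <- function() {
    if (!length(va)) return(NA_real_)
    s <- 0
    for (i in va) {
      bt <- make_batch(pcs, i)
      out <- generator_forward(gen, bt$gin, training = FALSE)$out
      s <- s + l1_loss(composite_batch(out, bt), bt$z)
    }
    s / length(va)
  }

  # ---- Stage I: generator pre-training -----------------------------------
  for (ep in seq_len(cfg$stage_epochs[1])) {
    ord <- sample(tr)
    for (b0 in seq(1, length(ord), by = B)) {
      idx <- ord[b0:min(b0 + B - 1, length(ord))]
      bt <- make_batch(pcs, idx)
      fw <- generator_forward(gen, bt$gin, training = TRUE)
      gen <- fw$gen
      comp <- composite_batch(fw$out, bt)
      diff <- comp - bt$z
      l1 <- mean(abs(diff))
      msev <- mean(diff^2)
      fpm <- array(0, dim(comp)); grm <- array(0, dim(comp))
      for (j in seq_len(bt$B)) {
        fpm[, , 1, j] <- bt$pcs[[j]]$fp; grm[, , 1, j] <- bt$pcs[[j]]$gr
      }
      nfp <- max(sum(fpm), 1); ngr <- max(sum(grm), 1)
      occ <- sum(abs(diff) * fpm) / nfp
      mor <- sum(abs(diff) * grm) / ngr
      gcomp <- weights$lambda_L1 * sign(diff) / length(diff) +
               w_occ * sign(diff) * fpm / nfp +
               w_mor * sign(diff) * grm / ngr
      bw <- generator_backward(gen, fw$caches, fw$block_channels,
                               gcomp * bt$mask)
      tg <- tg + 1L
      up <- adam_step(gen$layers, bw$grads, ad_g, tg, cfg$lr, cfg$beta1,
                      cfg$beta2)
      gen$layers <- up$layers; ad_g <- up$state
      push_log(1L, l1 = l1, mse = msev)
      if (check_finite(weights$lambda_L1 * l1 + w_occ * occ + w_mor * mor))
        break
    }
    if (status != "ok") break
    v <- val_l1_now()
    if (!is.na(v))
      val_l1 <- rbind(val_l1, data.frame(stage = 1L, epoch = ep, l1 = v))
  }
  snapshots$stage1 <- gen
  if (status != "ok")
    return(finish_training(gen, disc, log, val_l1, snapshots, status, log_dir))

  # ---- Stage II: discriminator warm-up against the frozen generator ------
  gen_frozen_hash <- param_fingerprint(gen)
  if (cfg$stage_epochs[2] > 0) {
    fakes <- vector("list", length(data$cases))
    for (i in tr) {
      bt <- make_batch(pcs, i)
      out <- generator_forward(gen, bt$gin, training = FALSE)$out
      fakes[[i]] <- composite_batch(out, bt)
    }
    for (ep in seq_len(cfg$stage_epochs[2])) {
      ord <- sample(tr)
      for (b0 in seq(1, length(ord), by = B)) {
        idx <- ord[b0:min(b0 + B - 1, length(ord))]
        bt <- make_batch(pcs, idx)
        fake <- array(0, c(bt$H, bt$W, 1, bt$B))
        for (j in seq_len(bt$B)) fake[, , 1, j] <- fakes[[idx[j]]][, , 1, 1]
        if (cfg$stage2_mode == "adversarial") {
          st <- disc_train_step(disc, ad_d, td, bt, fake, cfg, eps)
          disc <- st$disc; ad_d <- st$ad; td <- st$td
        } else {
          # frozen-validation reading: only measure, never update D
          real <- disc_stacks(bt, bt$z)
          fstk <- disc_stacks(bt, fake)
          fr <- disc_forward_full(disc, real$gs, real$ls, training = FALSE)
          ff <- disc_forward_full(disc, fstk$gs, fstk$ls, training = FALSE)
          st <- list(loss_d = adversarial_objectives(
                       list(G = fr$pG, L = fr$pL),
                       list(G = ff$pG, L = ff$pL), eps)$loss_d,
                     real_gs = real$gs, fake_gs = fstk$gs)
        }
        msev <- mse_loss(fake, bt$z)
        perv <- perceptual_loss(st$fake_gs, st$real_gs, disc)
        push_log(2L, l1 = l1_loss(fake, bt$z), mse = msev, per = perv,
                 d = st$loss_d)
        if (check_finite(msev, perv, st$loss_d)) break
      }
      if (status != "ok") break
    }
  }
  if (!identical(param_fingerprint(gen), gen_frozen_hash))
    stop("internal error: generator changed during Stage II")
  snapshots$stage2 <- gen
  if (status != "ok")
    return(finish_training(gen, disc, log, val_l1, snapshots, status, log_dir))

  # ---- Stage III: joint adversarial training -----------------------------
  for (ep in seq_len(cfg$stage_epochs[3])) {
    ord <- sample(tr)
    for (b0 in seq(1, length(ord), by = B)) {
      idx <- ord[b0:min(b0 + B - 1, length(ord))]
      bt <- make_batch(pcs, idx)
      fw <- generator_forward(gen, bt$gin, training = TRUE)
      gen <- fw$gen
      comp <- composite_batch(fw$out, bt)

      st <- disc_train_step(disc, ad_d, td, bt, comp, cfg, eps)
      disc <- st$disc; ad_d <- st$ad; td <- st$td

      # generator step against the updated discriminators (eval mode)
      stk <- disc_stacks(bt, comp)
      dfw <- disc_forward_full(disc, stk$gs, stk$ls, training = FALSE)
      if (cfg$adv_mode == "fused") {
        pF <- clamp(dfw$pF, eps, 1 - eps)
        adv <- mean(-log(pF))
        dbw <- disc_backward_full(disc, dfw, gpG = 0 * pF, gpL = 0 * pF,
                                  gpF = -1 / (pF * bt$B))
      } else {
        pG <- clamp(dfw$pG, eps, 1 - eps); pL <- clamp(dfw$pL, eps, 1 - eps)
        adv <- mean(-log(pG)) + mean(-log(pL))
        dbw <- disc_backward_full(disc, dfw, gpG = -1 / (pG * bt$B),
                                  gpL = -1 / (pL * bt$B))
      }
      gadv <- dfw_input_to_crown(dbw, bt)

      diff <- comp - bt$z
      l1 <- mean(abs(diff)); msev <- mean(diff^2)
      pg <- perceptual_loss_grad(stk$gs, st$real_gs,
                                 disc$layers[disc$sec$gtrunk])
      perv <- pg$loss
      gper <- pg$gx[, , 5, , drop = FALSE]
      gcomp <- gadv +
               weights$lambda_L1 * sign(diff) / length(diff) +
               weights$lambda_mse * 2 * diff / length(diff) +
               weights$lambda_per * gper
      bw <- generator_backward(gen, fw$caches, fw$block_channels,
                               gcomp * bt$mask)
      tg <- tg + 1L
      up <- adam_step(gen$layers, bw$grads, ad_g, tg, cfg$lr, cfg$beta1,
                      cfg$beta2)
      gen$layers <- up$layers; ad_g <- up$state
      push_log(3L, l1 = l1, mse = msev, per = perv, adv = adv, d = st$loss_d)
      tot <- tryCatch(total_loss(adv, l1, msev, perv, weights),
                      error = function(e) Inf)
      if (check_finite(tot)) break
    }
    if (status != "ok") break
  }
  snapshots$stage3 <- gen
  finish_training(gen, disc, log, val_l1, snapshots, status, log_dir)
}

# one discriminator update on batch bt with generated crowns `fake`
disc_train_step <- function(disc, ad_d, td, bt, fake, cfg, eps) {
  real <- disc_stacks(bt, bt$z)
  fstk <- disc_stacks(bt, fake)
  fr <- disc_forward_full(disc, real$gs, real$ls, training = TRUE)
  disc <- fr$disc
  ff <- disc_forward_full(disc, fstk$gs, fstk$ls, training = TRUE)
  disc <- ff$disc
  B <- bt$B
  if (cfg$adv_mode == "fused") {
    pRF <- clamp(fr$pF, eps, 1 - eps); pFF <- clamp(ff$pF, eps, 1 - eps)
    loss_d <- mean(-log(pRF)) + mean(-log(1 - pFF))
    br <- disc_backward_full(disc, fr, gpG = 0 * pRF, gpL = 0 * pRF,
                             gpF = -1 / (pRF * B))
    bf <- disc_backward_full(disc, ff, gpG = 0 * pFF, gpL = 0 * pFF,
                             gpF = 1 / ((1 - pFF) * B))
  } else {
    pRG <- clamp(fr$pG, eps, 1 - eps); pRL <- clamp(fr$pL, eps, 1 - eps)
    pFG <- clamp(ff$pG, eps, 1 - eps); pFL <- clamp(ff$pL, eps, 1 - eps)
    loss_d <- mean(-(log(pRG) + log(1 - pFG))) +
              mean(-(log(pRL) + log(1 - pFL)))
    br <- disc_backward_full(disc, fr, gpG = -1 / (pRG * B),
                             gpL = -1 / (pRL * B))
    bf <- disc_backward_full(disc, ff, gpG = 1 / ((1 - pFG) * B),
                             gpL = 1 / ((1 - pFL) * B))
  }
  grads <- add_grads(br$grads, bf$grads)
  td <- td + 1L
  up <- adam_step(disc$layers, grads, ad_d, td, cfg$lr, cfg$beta1, cfg$beta2)
  disc$layers <- up$layers
  list(disc = disc, ad = up$state, td = td, loss_d = loss_d,
       real_gs = real$gs, fake_gs = fstk$gs)
}

# map discriminator input gradients back onto the composited crown image
dfw_input_to_crown <- function(dbw, bt) {
  g <- dbw$gin_g[, , 5, , drop = FALSE]
  for (j in seq_len(bt$B)) {
    gj <- g[, , 1, j]
    gj <- scatter_local(gj, dbw$gin_l[, , 5, j], bt$pcs[[j]])
    g[, , 1, j] <- gj
  }
  g
}

param_fingerprint <- function(net) {
  vapply(net$layers, function(l) {
    ps <- layer_param_names(l)
    if (!length(ps)) return(0)
    sum(vapply(ps, function(p) sum(l[[p]]^2) + sum(l[[p]] * seq_along(l[[p]])), 0))
  }, 0)
}

finish_training <- function(gen, disc, log, val_l1, snapshots, status,
                            log_dir) {
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(iteration = integer(0), stage = integer(0), l_l1 = numeric(0),
               l_mse = numeric(0), l_per = numeric(0), l_adv = numeric(0),
               l_disc = numeric(0))
  if (!is.null(log_dir)) {
    dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(log, file.path(log_dir, "training_log.csv"), row.names = FALSE)
  }
  structure(list(generator = gen, discriminator = disc, log = log,
                 val_l1 = val_l1, snapshots = snapshots, status = status),
            class = "occ_training")
}

#' @export
print.occ_training <- function(x, ...) {
  cat(sprintf("occ_training: %d iterations, status '%s'\n", nrow(x$log),
              x$status))
  for (s in 1:3) {
    sl <- x$log[x$log$stage == s, ]
    if (nrow(sl))
      cat(sprintf("  stage %d: %d iterations, final L1 %.4f\n", s, nrow(sl),
                  sl$l_l1[nrow(sl)]))
  }
  invisible(x)
}

#' @export
plot.occ_training <- function(x, ...) {
  lg <- x$log
  cols <- c(l_l1 = "black", l_mse = "tomato", l_per = "steelblue",
            l_adv = "darkgreen")
  graphics::matplot(lg$iteration, as.matrix(lg[, names(cols)]), type = "l",
                    lty = 1, col = cols, xlab = "iteration", ylab = "loss",
                    main = "training losses", ...)
  graphics::legend("topright", legend = names(cols), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}

#' Smoothed loss-trajectory direction
#'
#' Smooths one logged loss with a rolling mean and reports whether the
#' median of its last quarter lies below the median of its first quarter --
#' the package's operational definition of a "decreasing trajectory".
#'
#' @param log training log data.frame from [train_staged()].
#' @param loss column name (`l_l1`, `l_mse`, `l_per`, `l_adv`, `l_disc`).
#' @param window rolling-mean window (default 5% of the span, >= 5).
#' @return list with `decreasing` (logical), `first` and `last` medians.
#' @export
loss_trajectory <- function(log, loss, window = NULL) {
  v <- log[[loss]]
  v <- v[!is.na(v)]
  if (length(v) < 8) stop("too few records for ", loss)
  window <- window %||% max(5, round(0.05 * length(v)))
  sm <- stats::filter(v, rep(1 / window, window), sides = 2)
  sm <- sm[!is.na(sm)]
  q <- floor(length(sm) / 4)
  first <- median(sm[seq_len(q)])
  last <- median(sm[seq(length(sm) - q + 1, length(sm))])
  list(decreasing = last < first, first = first, last = last)
}
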