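#' End-to-end run configuration
#'
#' Bundles every knob of a full run: dataset size and geometry, the depth
#' encoding candidates, network widths, loss weights and the training
#' schedule. A single `seed` fans out deterministically to dataset, weight
#' initialization and training (see [derive_seed()]), so any stage is
#' independently re-runnable.
#'
#' @param n_cases number of synthetic cases.
#' @param image_size,local_size global / local image sizes in pixels.
#' @param alpha_candidates candidate enhancement factors for the
#'   entropy-guided selection.
#' @param h visual distance in mm.
#' @param margin_fraction,contact_threshold scene parameters (see
#'   [generate_case()]).
#' @param split train/val/test ratios.
#' @param base_filters_g,base_filters_d generator / discriminator widths.
#' @param dilation_rates bottleneck dilation rates.
#' @param weights a [loss_weights()].
#' @param train a [train_config()].
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_cases = 60, image_size = 64, local_size = 32,
                       alpha_candidates = c(0.5, 1, 2, 4), h = 6,
                       margin_fraction = 0.5, contact_threshold = 0.15,
                       split = c(train = 0.85, val = 0.09, test = 0.06),
                       base_filters_g = 8, base_filters_d = 8,
                       dilation_rates = c(1, 2, 4, 8),
                       weights = loss_weights(), train = train_config(),
                       seed = 1L) {
  structure(list(n_cases = as.integer(n_cases),
                 image_size = as.integer(image_size),
                 local_size = as.integer(local_size),
                 alpha_candidates = alpha_candidates, h = h,
                 margin_fraction = margin_fraction,
                 contact_threshold = contact_threshold, split = split,
                 base_filters_g = as.integer(base_filters_g),
                 base_filters_d = as.integer(base_filters_d),
                 dilation_rates = as.integer(dilation_rates),
                 weights = weights, train = train, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Field names mirror [run_config()], [train_config()] and [loss_weights()]
#' (`weights:` and `train:` as nested maps).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  w <- do.call(loss_weights, y$weights %||% list())
  tc <- do.call(train_config, y$train %||% list())
  y$weights <- w; y$train <- tc
  if (!is.null(y$split)) y$split <- unlist(y$split)
  do.call(run_config, y)
}

#' Run the whole pipeline
#'
#' Executes: entropy-guided alpha selection on a reference synthetic crown,
#' dataset generation, staged training, inference on the test split,
#' depth-map to mesh reconstruction of generated and target crowns, and
#' metric evaluation. Everything lands under `out_dir`; re-running with the
#' same configuration and seed reproduces the outputs byte-identically.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `data`, `training`, `metrics`, the chosen
#'   `alpha` and the output paths.
#' @export
run_end_to_end <- function(cfg, out_dir, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create run directory: ", out_dir)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "alpha-selection"
  res <- tryCatch({
    ref <- generate_crown(crown_params(seed = derive_seed(cfg$seed, "alpha-ref")))
    enc0 <- depth_encoding(h = cfg$h,
                           mm_per_pixel = 1.2 * 10.5 / cfg$image_size,
                           width = cfg$image_size, height = cfg$image_size)
    alpha <- select_alpha(ref, cfg$alpha_candidates, enc0)
    say("selected alpha = %g", alpha)

    stage <- "dataset-generation"
    data <- generate_dataset(cfg$n_cases, derive_seed(cfg$seed, "data"),
                             out_dir = file.path(out_dir, "data"),
                             split = cfg$split, keep_cases = TRUE,
                             image_size = cfg$image_size,
                             local_size = cfg$local_size,
                             alpha = as.numeric(alpha), h = cfg$h,
                             margin_fraction = cfg$margin_fraction,
                             contact_threshold = cfg$contact_threshold)
    say("dataset: %d cases (train %d / val %d / test %d)", cfg$n_cases,
        length(data$split$train), length(data$split$val),
        length(data$split$test))

    stage <- "training"
    gen <- build_generator(
      generator_spec(base_filters = cfg$base_filters_g,
                     dilation_rates = cfg$dilation_rates,
                     leaky_slope = cfg$train$leaky_slope),
      seed = derive_seed(cfg$seed, "gen-init"))
    disc <- build_dual_discriminator(
      discriminator_spec(base_filters = cfg$base_filters_d,
                         image_size = cfg$image_size,
                         local_size = cfg$local_size,
                         leaky_slope = cfg$train$leaky_slope),
      seed = derive_seed(cfg$seed, "disc-init"))
    tc <- cfg$train; tc$seed <- derive_seed(cfg$seed, "train")
    trained <- train_staged(data, gen, disc, tc, cfg$weights,
                            log_dir = out_dir)
    if (trained$status != "ok")
      warning("training ended with status: ", trained$status)

    stage <- "inference"
    test_idx <- data$split$test
    if (!length(test_idx)) test_idx <- data$split$train[1]
    mesh_dir <- file.path(out_dir, "meshes")
    dir.create(mesh_dir, showWarnings = FALSE)
    for (i in test_idx) {
      cs <- data$cases[[i]]
      out <- generate_surface(trained$generator, cs$input_stack / 255,
                              defect_mask = cs$defect_mask)
      lv <- round_half_up(clamp(out, 0, 1) * 255)
      dm <- structure(list(pixels = matrix(as.integer(lv), nrow(lv)),
                           encoding = cs$encoding), class = "depth_map")
      write_depth_map(dm, file.path(out_dir, sprintf("gen_%04d.png", i)))
      stage <- "reconstruction"
      write_mesh(reconstruct_mesh(dm),
                 file.path(mesh_dir, sprintf("gen_%04d.obj", i)))
      stage <- "inference"
    }

    stage <- "evaluation"
    metrics <- evaluate_cases(trained$generator, data, test_idx,
                              with_meshes = TRUE)
    summary_rows <- data.frame(
      case = c(NA, NA),
      psnr = c(mean(metrics$psnr), stats::sd(metrics$psnr)),
      ssim = c(mean(metrics$ssim), stats::sd(metrics$ssim)),
      fsim = c(mean(metrics$fsim), stats::sd(metrics$fsim)),
      sd_mm = c(mean(metrics$sd_mm), stats::sd(metrics$sd_mm)),
      rms_mm = c(mean(metrics$rms_mm), stats::sd(metrics$rms_mm)))
    rownames(summary_rows) <- NULL
    out_csv <- rbind(cbind(row = as.character(metrics$case), metrics[-1]),
                     cbind(row = c("mean", "sd"), summary_rows[-1]))
    write.csv(out_csv, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(alpha = as.numeric(alpha), seed = cfg$seed,
           alpha_entropies = as.list(attr(alpha, "entropies")),
           status = trained$status,
           test_mean = list(psnr = mean(metrics$psnr),
                            ssim = mean(metrics$ssim),
                            fsim = mean(metrics$fsim),
                            rms_mm = mean(metrics$rms_mm))),
      file.path(out_dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
    say("test split: PSNR %.2f dB, SSIM %.3f, FSIM %.3f, RMS %.3f mm",
        mean(metrics$psnr), mean(metrics$ssim), mean(metrics$fsim),
        mean(metrics$rms_mm))
    list(data = data, training = trained, metrics = metrics,
         alpha = as.numeric(alpha), out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
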