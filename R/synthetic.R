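#' Parameters of a synthetic molar crown
#'
#' Defines a parametric height-field model of a mandibular first molar crown:
#' a smooth base dome carrying `n_cusps` Gaussian cusps arranged on a ring,
#' with a central groove valley crossing between the cusps. Per-cusp random
#' perturbations (position, height, width) of relative magnitude
#' `asymmetry_jitter` give each seed an individual anatomy. Identical
#' parameters and seed reproduce the crown bit-exactly.
#'
#' Defaults describe a plausible mandibular first molar: ~10.5 mm
#' mesiodistal diameter, five cusps (three buccal, two lingual), cusp relief
#' ~1.6 mm, central groove ~0.9 mm deep.
#'
#' @param n_cusps number of cusps, 4 or 5.
#' @param cusp_height cusp relief above the base dome, mm.
#' @param cusp_sigma Gaussian cusp width, mm.
#' @param groove_depth central groove depth, mm; must be `< cusp_height`
#'   unless both are zero.
#' @param groove_width groove half-width parameter, mm.
#' @param crown_diameter occlusal-view diameter, mm.
#' @param base_height height of the base dome at its centre, mm.
#' @param asymmetry_jitter dimensionless scale of per-cusp perturbations.
#' @param seed integer seed for the perturbations.
#' @return object of class `crown_params`.
#' @export
crown_params <- function(n_cusps = 5, cusp_height = 1.6, cusp_sigma = 1.2,
                         groove_depth = 0.9, groove_width = 0.6,
                         crown_diameter = 10.5, base_height = 4,
                         asymmetry_jitter = 0.08, seed = 1L) {
  if (!n_cusps %in% c(4L, 5L)) stop("invalid n_cusps: must be 4 or 5")
  for (f in c("cusp_sigma", "groove_width", "crown_diameter", "base_height")) {
    if (get(f) <= 0) stop("invalid ", f, ": must be > 0")
  }
  if (cusp_height < 0) stop("invalid cusp_height: must be >= 0")
  if (groove_depth < 0) stop("invalid groove_depth: must be >= 0")
  if (cusp_height > 0 && groove_depth >= cusp_height)
    stop("invalid groove_depth: must be < cusp_height")
  if (asymmetry_jitter < 0) stop("invalid asymmetry_jitter: must be >= 0")
  structure(list(n_cusps = as.integer(n_cusps), cusp_height = cusp_height,
                 cusp_sigma = cusp_sigma, groove_depth = groove_depth,
                 groove_width = groove_width, crown_diameter = crown_diameter,
                 base_height = base_height,
                 asymmetry_jitter = asymmetry_jitter,
                 seed = as.integer(seed)),
            class = "crown_params")
}

# Analytic occlusal height field for a crown. Returns a vectorized closure
# f(x, y) -> height (mm, 0 outside the footprint) plus the drawn cusp layout,
# so tests can integrate the exact surface independently of any raster.
crown_field <- function(params) {
  p <- params
  R <- p$crown_diameter / 2
  rc <- 0.60 * R
  # cusp layout keeps every apex clear of the central groove line (x = 0):
  # 4 cusps in a 2+2 arrangement, 5 cusps in the molar-like 3+2 arrangement
  # (two pairs flanking the groove plus a distal cusp on the ring end)
  ang <- if (p$n_cusps == 4L) c(45, 135, 225, 315) else
    c(50, 130, 180, 230, 310)
  ang <- ang * pi / 180
  jit <- with_seed(derive_seed(p$seed, "crown-jitter"), {
    matrix(runif(p$n_cusps * 4, -1, 1), ncol = 4)
  })
  a <- ang + p$asymmetry_jitter * 0.5 * jit[, 1]
  r <- rc * (1 + p$asymmetry_jitter * jit[, 2])
  hk <- p$cusp_height * (1 + p$asymmetry_jitter * jit[, 3])
  sk <- p$cusp_sigma * (1 + 0.3 * p$asymmetry_jitter * jit[, 4])
  cx <- r * cos(a); cy <- r * sin(a)
  wig <- p$asymmetry_jitter * 0.6 * jit[1, 4] * R   # groove path wiggle
  gd <- p$groove_depth; gw <- p$groove_width
  f <- function(x, y) {
    rr2 <- x^2 + y^2
    inside <- rr2 <= R^2
    base <- p$base_height * (1 - (rr2 / R^2)^3)
    cusps <- 0
    for (k in seq_len(p$n_cusps))
      cusps <- cusps + hk[k] * exp(-((x - cx[k])^2 + (y - cy[k])^2) / (2 * sk[k]^2))
    xg <- wig * sin(pi * y / R)
    carve <- gd * exp(-(x - xg)^2 / (2 * gw^2)) * pmax(1 - rr2 / R^2, 0)
    h <- pmax(base + cusps - carve, 0)
    h * inside
  }
  list(f = f, R = R, cusp_x = cx, cusp_y = cy, params = p)
}

#' Generate a synthetic molar crown mesh
#'
#' Rasterizes the analytic crown height field of `params` on a regular grid
#' and triangulates it into a height-field mesh (single-valued z over the
#' occlusal view; undercuts are out of scope). Coordinates are mm and the
#' mesh is returned in standard pose.
#'
#' @param params a [crown_params()].
#' @param grid_mm grid resolution in mm (default 0.2).
#' @return a [tooth_mesh()].
#' @export
generate_crown <- function(params, grid_mm = 0.2) {
  stopifnot(inherits(params, "crown_params"))
  fld <- crown_field(params)
  R <- fld$R
  g <- seq(-R, R, by = grid_mm)
  hf <- outer(g, g, function(x, y) fld$f(x, y))   # rows: x, cols: y
  mesh_from_height_grid(g, g, hf, footprint = outer(g, g, function(x, y)
    x^2 + y^2 <= R^2))
}

# Triangulates a height field sampled at xs (cols index) / ys into a mesh.
# Vertices only where footprint is TRUE; cells need all four corners inside.
mesh_from_height_grid <- function(xs, ys, hf, footprint = NULL) {
  nx <- length(xs); ny <- length(ys)
  if (is.null(footprint)) footprint <- matrix(TRUE, nx, ny)
  idx <- matrix(0L, nx, ny)
  idx[footprint] <- seq_len(sum(footprint))
  w <- which(footprint, arr.ind = TRUE)
  v <- cbind(xs[w[, 1]], ys[w[, 2]], hf[footprint])
  i <- seq_len(nx - 1); j <- seq_len(ny - 1)
  ok <- footprint[i, j, drop = FALSE] & footprint[i + 1, j, drop = FALSE] &
        footprint[i, j + 1, drop = FALSE] & footprint[i + 1, j + 1, drop = FALSE]
  cells <- which(ok, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("height grid has no complete cells")
  i11 <- idx[cbind(cells[, 1], cells[, 2])]
  i21 <- idx[cbind(cells[, 1] + 1, cells[, 2])]
  i12 <- idx[cbind(cells[, 1], cells[, 2] + 1)]
  i22 <- idx[cbind(cells[, 1] + 1, cells[, 2] + 1)]
  faces <- rbind(cbind(i11, i21, i22), cbind(i11, i22, i12))
  tooth_mesh(v, faces, pose_standardized = TRUE)
}

#' Generate one fully conditioned training case
#'
#' Builds a complete synthetic scene -- target crown, mesial and distal
#' adjacent crowns, and an opposing crown mirrored above with a sampled
#' inter-jaw clearance -- renders all depth channels, carves the preparation
#' by a hard horizontal cut at `margin_fraction` of the crown height, and
#' derives the conditioning channels:
#' \describe{
#'   \item{x1}{preparation with adjacent teeth (depth map).}
#'   \item{c1}{opposing tooth depth map.}
#'   \item{c2}{biological-morphology mask: occlusal-fingerprint patches
#'     (inter-jaw gap < `contact_threshold`) union the groove mask.}
#'   \item{d}{per-pixel inter-jaw gap clipped to `[0, h]` and stored as
#'     levels of `gap/h`.}
#'   \item{z1}{target crown with adjacent teeth (depth map).}
#' }
#' The local stack (`x1p`, `c1p`, `c3` = groove mask, `dp`) is the
#' axis-aligned bounding box of the defect mask padded by 10% and resized to
#' `local_size`. Outside the defect mask, `x1` equals `z1` exactly.
#'
#' @param seed integer case seed; fans out to crown, neighbours, opposing
#'   tooth and gap draw.
#' @param crown_params optional [crown_params()] template for the target
#'   crown (its seed field is replaced by the case seed).
#' @param image_size global image size in pixels.
#' @param local_size local crop size in pixels (< `image_size`).
#' @param alpha,h depth-encoding parameters (see [depth_encoding()]).
#' @param margin_fraction preparation margin as a fraction of crown height.
#' @param contact_threshold inter-jaw proximity (mm) defining occlusal
#'   fingerprint patches.
#' @param gap_range range (mm) from which the minimal inter-jaw clearance is
#'   drawn uniformly.
#' @return object of class `case_sample`; see [validate_case()] for its
#'   invariants.
#' @export
generate_case <- function(seed, crown_params = NULL, image_size = 64,
                          local_size = 32, alpha = 2, h = 6,
                          margin_fraction = 0.5, contact_threshold = 0.15,
                          gap_range = c(0.02, 0.12)) {
  if (local_size >= image_size) stop("local_size must be < image_size")
  cp <- crown_params %||% crown_params()
  cp$seed <- as.integer(derive_seed(seed, "target-crown"))
  scene_w <- 3.2 * cp$crown_diameter
  mpp <- scene_w / image_size
  enc <- depth_encoding(alpha = alpha, h = h, mm_per_pixel = mpp,
                        width = image_size, height = image_size)

  # pixel-centre grid (matches project_mesh's pixel coordinates)
  xs <- (seq_len(image_size) - 1 - (image_size - 1) / 2) * mpp
  ys <- ((image_size - 1) / 2 - (seq_len(image_size) - 1)) * mpp
  # height fields are evaluated with rows = image rows (y), cols = x
  grid_x <- matrix(xs, image_size, image_size, byrow = TRUE)
  grid_y <- matrix(ys, image_size, image_size)

  fld_t <- crown_field(cp)
  neigh <- function(lab) {
    q <- cp; q$seed <- as.integer(derive_seed(seed, lab))
    crown_field(q)
  }
  fld_m <- neigh("mesial-crown"); fld_d <- neigh("distal-crown")
  fld_o <- neigh("opposing-crown")
  off <- 1.05 * cp$crown_diameter

  h_t <- fld_t$f(grid_x, grid_y)
  h_m <- fld_m$f(grid_x + off, grid_y)
  h_d <- fld_d$f(grid_x - off, grid_y)
  h_o <- fld_o$f(-grid_x, grid_y)          # opposing crown, mirrored
  foot_t <- grid_x^2 + grid_y^2 <= fld_t$R^2

  zmax_t <- max(h_t)
  zm <- margin_fraction * zmax_t
  h_prep <- pmin(h_t, zm)
  defect <- foot_t & (h_t > zm)

  scene_full <- pmax(h_t, h_m, h_d)
  scene_prep <- pmax(h_prep, h_m, h_d)

  # opposing jaw: lower surface C - h_o, with min clearance over the target
  gap_min <- with_seed(derive_seed(seed, "jaw-gap"),
                       runif(1, gap_range[1], gap_range[2]))
  C <- max((h_o + scene_full)[foot_t]) + gap_min
  gap <- C - h_o - scene_full
  d_mm <- clamp(gap, 0, h)

  fingerprint <- foot_t & (gap < contact_threshold)
  groove <- groove_mask(fld_t, grid_x, grid_y)
  c2 <- fingerprint | groove

  enc$reference_z <- zmax_t
  render <- function(hf, foot, e) {
    m <- mesh_from_height_grid(xs, rev(ys),
                               t(hf[seq(nrow(hf), 1), , drop = FALSE]),
                               t(foot[seq(nrow(foot), 1), , drop = FALSE]))
    project_mesh(m, e)
  }
  any_foot <- scene_full > 0 | foot_t
  z1 <- render(scene_full, any_foot, enc)
  x1 <- render(scene_prep, any_foot, enc)
  enc_o <- enc; enc_o$reference_z <- max(h_o)
  c1 <- render(h_o, h_o > 0 | (grid_x^2 + grid_y^2 <= fld_o$R^2), enc_o)

  d_lvl <- round_half_up(255 * d_mm / h)            # gap normalized by h
  stack <- array(0, c(image_size, image_size, 4))
  stack[, , 1] <- x1$pixels
  stack[, , 2] <- c1$pixels
  stack[, , 3] <- 255 * c2
  stack[, , 4] <- d_lvl

  bbox <- defect_bbox(defect, pad_frac = 0.10)
  crop <- function(img) resize_bilinear(
    img[bbox$rows, bbox$cols, drop = FALSE], local_size, local_size)
  lstack <- array(0, c(local_size, local_size, 4))
  lstack[, , 1] <- round_half_up(crop(x1$pixels))
  lstack[, , 2] <- round_half_up(crop(c1$pixels))
  lstack[, , 3] <- 255 * (crop(groove + 0) >= 0.5)
  lstack[, , 4] <- round_half_up(crop(d_lvl))

  structure(list(
    input_stack = stack, local_input_stack = lstack,
    target_global = z1$pixels,
    target_local = round_half_up(crop(z1$pixels)),
    defect_mask = defect * 1L,
    defect_mask_local = (crop(defect + 0) >= 0.5) * 1L,
    fingerprint_mask = fingerprint * 1L, groove_mask = groove * 1L,
    tooth_footprint = foot_t * 1L,
    bbox = bbox, encoding = enc, seed = as.integer(seed),
    crown_params = cp, gap_min = gap_min,
    margin_fraction = margin_fraction, local_size = as.integer(local_size)),
    class = "case_sample")
}

# groove mask: pixels where the groove carve reaches at least half depth,
# restricted to the crown footprint interior
groove_mask <- function(fld, grid_x, grid_y) {
  p <- fld$params
  if (p$groove_depth <= 0) return(grid_x != grid_x)  # all FALSE
  jit <- with_seed(derive_seed(p$seed, "crown-jitter"),
                   matrix(runif(p$n_cusps * 4, -1, 1), ncol = 4))
  wig <- p$asymmetry_jitter * 0.6 * jit[1, 4] * fld$R
  xg <- wig * sin(pi * grid_y / fld$R)
  g <- exp(-(grid_x - xg)^2 / (2 * p$groove_width^2))
  (g > 0.5) & (grid_x^2 + grid_y^2 <= (0.8 * fld$R)^2)
}

defect_bbox <- function(mask, pad_frac = 0.10) {
  w <- which(mask > 0, arr.ind = TRUE)
  if (nrow(w) == 0) stop("geometry error: empty defect mask")
  r0 <- min(w[, 1]); r1 <- max(w[, 1]); c0 <- min(w[, 2]); c1 <- max(w[, 2])
  pr <- ceiling(pad_frac * (r1 - r0 + 1)); pc <- ceiling(pad_frac * (c1 - c0 + 1))
  list(rows = max(1, r0 - pr):min(nrow(mask), r1 + pr),
       cols = max(1, c0 - pc):min(ncol(mask), c1 + pc))
}

#' Check the invariants of a training case
#'
#' Asserts channel-size consistency, binary masks, `c2` = fingerprint union
#' groove, defect mask strictly inside the tooth footprint, and `x1 == z1`
#' outside the defect mask. Errors on the first violation.
#'
#' @param case a `case_sample`.
#' @return `TRUE` invisibly.
#' @export
validate_case <- function(case) {
  stopifnot(inherits(case, "case_sample"))
  s <- dim(case$input_stack); l <- dim(case$local_input_stack)
  if (!all(s[1:2] == dim(case$target_global))) stop("global stack size mismatch")
  if (!all(l[1:2] == dim(case$target_local))) stop("local stack size mismatch")
  for (m in list(case$defect_mask, case$fingerprint_mask, case$groove_mask))
    if (!all(m %in% c(0, 1))) stop("mask is not binary")
  if (!all((case$input_stack[, , 3] / 255) ==
           ((case$fingerprint_mask | case$groove_mask) * 1)))
    stop("c2 is not the union of fingerprint and groove masks")
  if (any(case$defect_mask == 1 & case$tooth_footprint == 0))
    stop("defect mask escapes the tooth footprint")
  if (sum(case$defect_mask) >= sum(case$tooth_footprint))
    stop("defect mask is not a strict subset of the footprint")
  diff_out <- (case$input_stack[, , 1] != case$target_global) &
              (case$defect_mask == 0)
  if (any(diff_out)) stop("x1 differs from z1 outside the defect mask")
  invisible(TRUE)
}

#' @export
print.case_sample <- function(x, ...) {
  cat(sprintf(
    "case_sample (seed %d): %dx%d global / %dx%d local, defect %d px, gap_min %.3f mm\n",
    x$seed, nrow(x$target_global), ncol(x$target_global),
    x$local_size, x$local_size, sum(x$defect_mask), x$gap_min))
  invisible(x)
}

#' Generate a dataset of training cases
#'
#' Draws `n` case seeds from `base_seed`, generates each case, writes every
#' channel as an 8-bit grayscale PNG plus a JSON manifest with per-case seeds
#' and a train/validation/test split. Default split ratios are 85/9/6
#' (percent). Re-running with the same arguments reproduces the files
#' byte-identically.
#'
#' @param n number of cases (>= 1).
#' @param base_seed integer seed for the whole dataset.
#' @param out_dir output directory (created if missing); `NULL` keeps the
#'   dataset in memory only.
#' @param split numeric train/val/test ratios (summing to 1).
#' @param keep_cases return the generated cases in memory.
#' @param ... forwarded to [generate_case()].
#' @return object of class `case_set`: list with `manifest` and (when
#'   `keep_cases`) `cases`.
#' @export
generate_dataset <- function(n, base_seed, out_dir = NULL,
                             split = c(train = 0.85, val = 0.09, test = 0.06),
                             keep_cases = is.null(out_dir), ...) {
  if (n < 1) stop("n must be >= 1")
  seeds <- with_seed(base_seed, sample.int(2147483646L, n))
  nv <- round(split[[2]] * n); nt <- round(split[[3]] * n)
  ntr <- n - nv - nt
  if (ntr < 1) stop("split leaves no training cases")
  ord <- with_seed(derive_seed(base_seed, "split"), sample.int(n))
  lab <- character(n)
  lab[ord[seq_len(ntr)]] <- "train"
  if (nv > 0) lab[ord[ntr + seq_len(nv)]] <- "val"
  if (nt > 0) lab[ord[ntr + nv + seq_len(nt)]] <- "test"
  warnings <- character(0)
  if (nv == 0 || nt == 0)
    warnings <- "degenerate split: validation and/or test split is empty"

  cases <- vector("list", n)
  records <- vector("list", n)
  enc <- NULL
  for (i in seq_len(n)) {
    cs <- generate_case(seeds[i], ...)
    if (is.null(enc)) enc <- cs$encoding
    id <- sprintf("case_%04d", i)
    rec <- list(case_id = id, seed = seeds[i], split = lab[i],
                bbox = list(rows = range(cs$bbox$rows), cols = range(cs$bbox$cols)))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
      chans <- list(x1 = cs$input_stack[, , 1], c1 = cs$input_stack[, , 2],
                    c2 = cs$input_stack[, , 3], d = cs$input_stack[, , 4],
                    z1 = cs$target_global, defect = 255 * cs$defect_mask,
                    fingerprint = 255 * cs$fingerprint_mask,
                    groove = 255 * cs$groove_mask)
      paths <- list()
      for (ch in names(chans)) {
        p <- file.path(out_dir, sprintf("%s_%s.png", id, ch))
        png::writePNG(chans[[ch]] / 255, p)
        paths[[ch]] <- basename(p)
      }
      rec$channels <- paths
    }
    records[[i]] <- rec
    if (keep_cases) cases[[i]] <- cs
  }
  manifest <- list(
    n = n, base_seed = base_seed,
    split_sizes = list(train = ntr, val = nv, test = nt),
    warnings = warnings,
    encoding = list(alpha = enc$alpha, h = enc$h,
                    mm_per_pixel = enc$mm_per_pixel,
                    width = enc$width, height = enc$height),
    cases = records)
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(manifest = manifest,
                 cases = if (keep_cases) cases else NULL,
                 split = list(train = which(lab == "train"),
                              val = which(lab == "val"),
                              test = which(lab == "test"))),
            class = "case_set")
}

#' @export
print.case_set <- function(x, ...) {
  s <- x$manifest$split_sizes
  cat(sprintf("case_set: %d cases (train %d / val %d / test %d)%s\n",
              x$manifest$n, s$train, s$val, s$test,
              if (length(x$manifest$warnings)) " [warnings in manifest]" else ""))
  invisible(x)
}
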