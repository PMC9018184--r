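#' Depth-map encoding parameters
#'
#' Parameters of the reversible pixel-distance mapping used to render a tooth
#' surface as an 8-bit depth map. A surface point at distance `d` mm below the
#' reference plane maps to gray level `round(255 * (h^alpha - d^alpha) / h^alpha)`
#' for `d <= h`; anything deeper than the visual distance `h` (and any pixel
#' with no surface under it) is encoded as 0.
#'
#' @param alpha image enhancement factor (> 0); exponent that reweights gray
#'   levels. `alpha = 2` preserves the most occlusal detail by image entropy.
#' @param h visual distance in mm (depth window below the reference plane).
#' @param mm_per_pixel lateral resolution of the grid, mm per pixel.
#' @param width,height image size in pixels.
#' @param reference_z height (mm) of the projection plane; `NULL` means the
#'   z-maximum of the projected mesh (the highest cusp has `d = 0`).
#' @return object of class `depth_encoding`.
#' @export
depth_encoding <- function(alpha = 2, h = 6, mm_per_pixel = 0.5,
                           width = 64, height = 64, reference_z = NULL) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (h <= 0) stop("h must be > 0")
  if (mm_per_pixel <= 0) stop("mm_per_pixel must be > 0")
  structure(list(alpha = alpha, h = h, mm_per_pixel = mm_per_pixel,
                 width = as.integer(width), height = as.integer(height),
                 reference_z = reference_z),
            class = "depth_encoding")
}

#' Pixel-distance bidirectional mapping
#'
#' `depth_to_pixel()` maps distances below the reference plane to 8-bit gray
#' levels; `pixel_to_depth()` is the inverse of the un-rounded mapping,
#' `h * (1 - p/255)^(1/alpha)`. Rounding is half-away-from-zero.
#' `depth_quantization_step()` returns the worst-case depth difference between
#' adjacent gray levels, i.e. the resolution limit of the codec, computed by
#' brute force over all 256 levels.
#'
#' @param d numeric distances in mm (vector, matrix or array), `d >= 0`.
#' @param p integer gray levels in `[0, 255]`.
#' @param enc a [depth_encoding()].
#' @return levels / distances with the shape of the input.
#' @export
depth_to_pixel <- function(d, enc) {
  a <- enc$alpha; h <- enc$h
  p <- round_half_up(255 * (h^a - clamp(d, 0, h)^a) / h^a)
  p[d > h] <- 0
  p
}

#' @rdname depth_to_pixel
#' @export
pixel_to_depth <- function(p, enc) {
  if (any(p < 0 | p > 255)) stop("pixel levels must lie in [0, 255]")
  enc$h * (1 - p / 255)^(1 / enc$alpha)
}

#' @rdname depth_to_pixel
#' @export
depth_quantization_step <- function(enc) {
  d <- pixel_to_depth(0:255, enc)
  max(abs(diff(d)))
}

#' Pose standardization of a tooth mesh
#'
#' Rotates the mesh so its principal axes align with the coordinate axes
#' (mesiodistal spread along +x, occlusal direction along +z) and translates
#' the bounding-box centre to the origin. The transform is rigid (no scaling).
#' Principal axes come from the vertex covariance; the three sign ambiguities
#' are resolved deterministically: the occlusal side is the one whose coarse
#' depth-map rendering has the higher image entropy (the detailed side faces
#' +z), the x sign makes the third moment of x non-negative, and y completes
#' a right-handed frame.
#'
#' @param mesh a [tooth_mesh()].
#' @return the standardized `tooth_mesh` (with `pose_standardized = TRUE`).
#' @export
standardize_pose <- function(mesh) {
  stopifnot(inherits(mesh, "tooth_mesh"))
  v <- mesh$vertices
  if (nrow(v) < 3) stop("degenerate geometry: fewer than 3 vertices")
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  sv <- svd(vc, nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("degenerate geometry: vertices are collinear")
  R <- sv$v                        # columns: decreasing-variance axes
  if (det(R) < 0) R[, 3] <- -R[, 3]
  vr <- vc %*% R
  if (sum(vr[, 1]^3) < 0) {        # pi about z keeps handedness
    vr[, 1] <- -vr[, 1]; vr[, 2] <- -vr[, 2]
  }
  if (flip_improves_entropy(vr, mesh$faces)) {   # pi about x
    vr[, 2] <- -vr[, 2]; vr[, 3] <- -vr[, 3]
  }
  bb <- apply(vr, 2, range)
  vr <- sweep(vr, 2, (bb[1, ] + bb[2, ]) / 2)
  tooth_mesh(vr, mesh$faces, pose_standardized = TRUE)
}

# TRUE when the mesh seen from -z (after a pi rotation about x) yields a
# strictly more informative coarse rendering than the current +z view.
flip_improves_entropy <- function(v, faces) {
  ext <- max(apply(v, 2, function(x) diff(range(x))))
  enc <- depth_encoding(alpha = 2, h = max(ext, 1e-6),
                        mm_per_pixel = max(ext / 30, 1e-6),
                        width = 32, height = 32)
  ent <- function(vv) {
    m <- tooth_mesh(vv, faces, pose_standardized = TRUE)
    image_entropy(project_mesh(m, enc))
  }
  vflip <- v
  vflip[, 2] <- -vflip[, 2]; vflip[, 3] <- -vflip[, 3]
  ent(vflip) > ent(v) + 1e-12
}

#' Render a depth map by orthogonal projection
#'
#' Projects a pose-standardized mesh along -z onto the pixel grid of `enc`.
#' Per pixel the highest surface hit is kept (z-buffer); its distance below
#' the reference plane is encoded with [depth_to_pixel()]. Pixels with no
#' surface, or deeper than the visual distance `h`, are 0.
#'
#' @param mesh a pose-standardized [tooth_mesh()].
#' @param enc a [depth_encoding()].
#' @return object of class `depth_map`: list with integer matrix `pixels`
#'   (`height x width`, levels 0-255) and the completed `encoding`.
#' @export
project_mesh <- function(mesh, enc) {
  stopifnot(inherits(mesh, "tooth_mesh"), inherits(enc, "depth_encoding"))
  if (!mesh$pose_standardized)
    stop("mesh must be pose-standardized before projection (see standardize_pose)")
  zbuf <- cpp_raster_zbuffer(mesh$vertices, mesh$faces,
                             enc$width, enc$height, enc$mm_per_pixel)
  hit <- is.finite(zbuf)
  if (!any(hit)) stop("empty projection: mesh lies outside the image frame")
  ref <- enc$reference_z %||% max(mesh$vertices[, 3])
  px <- matrix(0L, enc$height, enc$width)
  d <- ref - zbuf[hit]
  px[hit] <- as.integer(depth_to_pixel(d, enc))
  px[hit][d < 0] <- 255L   # above the reference plane clamps to full brightness
  enc$reference_z <- ref
  structure(list(pixels = px, encoding = enc), class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("depth_map: %d x %d, alpha = %g, h = %g mm, %.3g mm/px, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$encoding$alpha, x$encoding$h,
              x$encoding$mm_per_pixel, sum(x$pixels > 0)))
  invisible(x)
}

#' @export
plot.depth_map <- function(x, ...) {
  op <- graphics::par(mar = c(1, 1, 2, 1)); on.exit(graphics::par(op))
  graphics::image(t(x$pixels[nrow(x$pixels):1, ]), col = grDevices::gray.colors(256, 0, 1),
                  zlim = c(0, 255), axes = FALSE, main = "depth map", ...)
  invisible(x)
}

#' Shannon entropy of a depth map
#'
#' `H = -sum_t P_t log2 P_t` over gray levels `t` in 0..255, with
#' `0 * log 0 := 0`; `P_t` is the frequency of level `t` in the image.
#'
#' @param dm a `depth_map` or an integer matrix of levels.
#' @return entropy in bits, in `[0, 8]`.
#' @export
image_entropy <- function(dm) {
  px <- if (inherits(dm, "depth_map")) dm$pixels else dm
  if (length(px) == 0) stop("empty image")
  p <- tabulate(as.integer(px) + 1L, nbins = 256L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy-guided selection of the enhancement factor
#'
#' Renders `mesh` once per candidate `alpha` and returns the candidate whose
#' depth map has maximal image entropy (most retained detail). Ties break
#' toward the smallest alpha.
#'
#' @param mesh a pose-standardized [tooth_mesh()].
#' @param candidates numeric vector of alpha values (>= 1 element).
#' @param enc a [depth_encoding()] supplying all parameters except alpha.
#' @return the selected alpha, with the per-candidate entropies in the
#'   `"entropies"` attribute.
#' @export
select_alpha <- function(mesh, candidates, enc = depth_encoding()) {
  if (length(candidates) < 1) stop("at least one candidate alpha is required")
  ord <- order(candidates)
  ents <- numeric(length(candidates))
  best <- NA_real_; best_h <- -Inf
  for (i in ord) {
    e2 <- enc; e2$alpha <- candidates[i]
    ents[i] <- image_entropy(project_mesh(mesh, e2))
    if (ents[i] > best_h + 1e-12) { best_h <- ents[i]; best <- candidates[i] }
  }
  structure(best, entropies = stats::setNames(ents, candidates))
}

#' Back-project a depth map to a triangle mesh
#'
#' Each foreground pixel (level > 0) becomes a vertex at its pixel-centre
#' (x, y) with `z = reference_z - pixel_to_depth(level)`. Triangulation grows
#' over the pixel grid: every 2x2 cell whose four pixels are all foreground
#' and whose depth spread is below `max_step` contributes two triangles, so
#' background holes and depth discontinuities are never bridged.
#'
#' @param dm a `depth_map`.
#' @param max_step maximal |z| spread (mm) within a cell before it is treated
#'   as a discontinuity (default 0.5 mm).
#' @return a pose-standardized [tooth_mesh()].
#' @export
reconstruct_mesh <- function(dm, max_step = 0.5) {
  stopifnot(inherits(dm, "depth_map"))
  px <- dm$pixels; enc <- dm$encoding
  fg <- px > 0
  if (sum(fg) < 3) stop("degenerate geometry: fewer than 3 foreground pixels")
  H <- nrow(px); W <- ncol(px)
  ref <- enc$reference_z %||% 0
  idx <- matrix(0L, H, W)
  idx[fg] <- seq_len(sum(fg))
  rc <- which(fg, arr.ind = TRUE)
  x <- (rc[, 2] - 1 - (W - 1) / 2) * enc$mm_per_pixel
  y <- ((H - 1) / 2 - (rc[, 1] - 1)) * enc$mm_per_pixel
  z <- ref - pixel_to_depth(px[fg], enc)
  zmat <- matrix(NA_real_, H, W)
  zmat[fg] <- z

  r <- seq_len(H - 1); cc <- seq_len(W - 1)
  ok <- fg[r, cc, drop = FALSE] & fg[r + 1, cc, drop = FALSE] &
        fg[r, cc + 1, drop = FALSE] & fg[r + 1, cc + 1, drop = FALSE]
  if (any(ok)) {
    z11 <- zmat[r, cc, drop = FALSE]; z21 <- zmat[r + 1, cc, drop = FALSE]
    z12 <- zmat[r, cc + 1, drop = FALSE]; z22 <- zmat[r + 1, cc + 1, drop = FALSE]
    zmin <- pmin(z11, z21, z12, z22); zmax <- pmax(z11, z21, z12, z22)
    ok <- ok & (zmax - zmin <= max_step)
  }
  cells <- which(ok, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("no cells survive triangulation")
  i11 <- idx[cbind(cells[, 1], cells[, 2])]
  i21 <- idx[cbind(cells[, 1] + 1, cells[, 2])]
  i12 <- idx[cbind(cells[, 1], cells[, 2] + 1)]
  i22 <- idx[cbind(cells[, 1] + 1, cells[, 2] + 1)]
  faces <- rbind(cbind(i11, i21, i12), cbind(i21, i22, i12))
  # drop vertices isolated by the discontinuity rule (typically the steep
  # tooth walls): unreferenced points are hallucinated spikes, not surface
  keep <- sort(unique(as.integer(faces)))
  remap <- integer(sum(fg))
  remap[keep] <- seq_along(keep)
  tooth_mesh(cbind(x, y, z)[keep, , drop = FALSE],
             matrix(remap[faces], ncol = 3), pose_standardized = TRUE)
}

#' Read or write a depth map as PNG plus JSON sidecar
#'
#' The 8-bit grayscale PNG holds the pixel levels; a JSON sidecar (same path
#' with extension `.json`) carries the encoding parameters (alpha, h,
#' mm-per-pixel, reference plane) so the pixel-distance mapping stays
#' reversible bit-exactly.
#'
#' @param dm a `depth_map`.
#' @param path PNG file path.
#' @return `read_depth_map` returns a `depth_map`; `write_depth_map` returns
#'   `path` invisibly.
#' @export
write_depth_map <- function(dm, path) {
  stopifnot(inherits(dm, "depth_map"))
  png::writePNG(dm$pixels / 255, path)
  enc <- dm$encoding
  jsonlite::write_json(
    list(alpha = enc$alpha, h = enc$h, mm_per_pixel = enc$mm_per_pixel,
         width = enc$width, height = enc$height,
         reference_z = enc$reference_z),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_depth_map
#' @export
read_depth_map <- function(path) {
  if (!file.exists(path)) stop("depth map not found: ", path)
  px <- round(png::readPNG(path) * 255)
  if (length(dim(px)) == 3) px <- px[, , 1]
  js <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  enc <- depth_encoding(alpha = js$alpha, h = js$h,
                        mm_per_pixel = js$mm_per_pixel,
                        width = js$width, height = js$height,
                        reference_z = js$reference_z)
  structure(list(pixels = matrix(as.integer(px), nrow(px), ncol(px)),
                 encoding = enc), class = "depth_map")
}

sidecar_path <- function(path) sub("\\.png$", ".json", path, ignore.case = TRUE)
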