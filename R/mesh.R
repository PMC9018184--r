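#' Triangulated tooth surface
#'
#' A light container for a triangulated tooth surface in millimetres:
#' an `n x 3` vertex matrix, an `m x 3` matrix of 1-based vertex indices, and
#' a flag recording whether the mesh has been pose-standardized (occlusal
#' direction along +z, mesiodistal along +x, bounding-box centre at origin).
#'
#' Zero-area faces are dropped at construction; all coordinates must be
#' finite and all face indices in range.
#'
#' @param vertices numeric `n x 3` matrix (mm).
#' @param faces integer `m x 3` matrix of vertex indices (1-based).
#' @param pose_standardized logical flag.
#' @return object of class `tooth_mesh`.
#' @export
tooth_mesh <- function(vertices, faces, pose_standardized = FALSE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertices contain non-finite coordinates")
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      stop("face indices out of range")
    a <- vertices[faces[, 1], , drop = FALSE]
    u <- vertices[faces[, 2], , drop = FALSE] - a
    w <- vertices[faces[, 3], , drop = FALSE] - a
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    area2 <- sqrt(rowSums(cr^2))
    faces <- faces[area2 > 1e-12, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces,
                 pose_standardized = isTRUE(pose_standardized)),
            class = "tooth_mesh")
}

#' @export
print.tooth_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("tooth_mesh: %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (x$pose_standardized) "pose-standardized" else "raw pose"))
  cat(sprintf("  extent (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Read or write a tooth mesh
#'
#' Formats are chosen by file extension: Wavefront OBJ (`.obj`, ASCII),
#' Stanford PLY (`.ply`, ASCII) and STL (`.stl`, binary little-endian).
#'
#' @param path file path.
#' @param mesh a [tooth_mesh()].
#' @return `read_mesh` returns a `tooth_mesh`; `write_mesh` returns `path`
#'   invisibly.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    obj = read_obj(path),
    ply = read_ply(path),
    stl = read_stl(path),
    stop("unsupported mesh format: .", ext))
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tooth_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path),
    stl = write_stl(mesh, path),
    stop("unsupported mesh format: .", ext))
  invisible(path)
}

read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(s) as.numeric(s[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                             function(s) as.integer(sub("/.*$", "", s[1:3]))))
  tooth_mesh(v, f)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (ln[1] != "ply" || !any(grepl("format ascii", ln)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*vertex ", "", ln[grepl("element vertex", ln)]))
  nf <- as.integer(sub(".*face ", "", ln[grepl("element face", ln)]))
  hdr <- which(ln == "end_header")
  v <- do.call(rbind, lapply(strsplit(trimws(ln[hdr + seq_len(nv)]), "\\s+"),
                             function(s) as.numeric(s[1:3])))
  f <- do.call(rbind,
               lapply(strsplit(trimws(ln[hdr + nv + seq_len(nf)]), "\\s+"),
                      function(s) as.integer(s[2:4]) + 1L))
  tooth_mesh(v, f)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
}

write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  v <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    a <- v[mesh$faces[i, 1], ]; b <- v[mesh$faces[i, 2], ]
    cc <- v[mesh$faces[i, 3], ]
    n <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
           (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
           (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, a, b, cc)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  tri <- matrix(0, nf * 3, 3)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    tri[(i - 1) * 3 + 1:3, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "raw", 2)
  }
  key <- apply(round(tri, 7), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  v <- tri[!duplicated(key), , drop = FALSE]
  tooth_mesh(v, matrix(idx, ncol = 3, byrow = TRUE))
}
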