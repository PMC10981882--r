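#' Triangle mesh container
#'
#' A segmented surface (nerve or needle) in millimetres: vertices plus
#' triangular faces, as stored in STL files exported from threshold
#' segmentation.
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param name Free-text label.
#' @return An object of class \code{tri_mesh}.
#' @export
tri_mesh <- function(vertices, faces, name = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) .np_stopf("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) .np_stopf("faces must be an m x 3 matrix")
  if (nrow(faces) < 1L) .np_stopf("mesh is empty: at least 1 triangle required")
  if (any(!is.finite(vertices))) .np_stopf("vertices contain non-finite coordinates")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    .np_stopf("face indices must be in 1..%d", nrow(vertices))
  structure(list(vertices = vertices, faces = faces, name = as.character(name)[1]),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<tri_mesh> '%s': %d vertices, %d faces, bbox [%.2f,%.2f]x[%.2f,%.2f]x[%.2f,%.2f] mm\n",
              x$name, nrow(x$vertices), nrow(x$faces),
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Point cloud container
#'
#' Dense surface samples of a mesh in millimetres, together with the
#' guaranteed maximum nearest-sample spacing achieved.
#'
#' @param points n x 3 numeric matrix (mm).
#' @param spacing_mm Positive spacing bound (mm).
#' @return An object of class \code{point_cloud}.
#' @export
point_cloud <- function(points, spacing_mm) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || nrow(points) < 1L)
    .np_stopf("points must be a nonempty n x 3 matrix")
  if (any(!is.finite(points))) .np_stopf("points contain non-finite coordinates")
  spacing_mm <- as.numeric(spacing_mm)[1]
  if (!is.finite(spacing_mm) || spacing_mm <= 0)
    .np_stopf("spacing_mm must be > 0")
  structure(list(points = points, spacing_mm = spacing_mm),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, spacing <= %.4g mm\n",
              nrow(x$points), x$spacing_mm))
  invisible(x)
}

.stl_uint32 <- function(raw4) {
  sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))
}

#' Read an STL surface model
#'
#' Reads binary (80-byte header + little-endian uint32 triangle count +
#' 50-byte facet records) or ASCII ("solid ...") STL. Units are taken as
#' millimetres verbatim, the convention of CBCT-derived segmentations.
#' Exactly duplicated corner vertices are welded.
#'
#' @param path Path to an STL file.
#' @param name Mesh label; defaults to the file name.
#' @return A \code{tri_mesh}.
#' @export
read_stl <- function(path, name = NULL) {
  if (!file.exists(path)) .np_stopf("STL file not found: %s", path)
  if (is.null(name)) name <- basename(path)
  size <- file.info(path)$size
  if (size < 15) .np_stopf("malformed STL %s: only %d bytes", path, size)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(size, 84))

  is_binary <- FALSE
  if (size >= 84) {
    count <- .stl_uint32(head[81:84])
    if (size == 84 + 50 * count) is_binary <- TRUE
  }
  if (!is_binary) {
    lead <- rawToChar(head[1:5])
    if (!identical(tolower(lead), "solid")) {
      if (size >= 84) {
        count <- .stl_uint32(head[81:84])
        .np_stopf(
          "malformed binary STL %s: header declares %d triangles (needs %d bytes) but file has %d bytes (offset 80)",
          path, count, 84 + 50 * count, size)
      }
      .np_stopf("malformed STL %s: not ASCII ('solid') and too short for binary", path)
    }
    return(.read_stl_ascii(path, name))
  }

  count <- .stl_uint32(head[81:84])
  if (count == 0) .np_stopf("empty STL %s: zero triangles", path)
  body <- readBin(con, "raw", n = 50 * count)
  if (length(body) < 50 * count)
    .np_stopf("truncated binary STL %s: expected %d facet bytes at offset 84, found %d",
              path, 50 * count, length(body))
  # keep the 48 float bytes of every 50-byte record, drop 2 attribute bytes
  keep <- rep.int(seq_len(48), count) + rep(50 * (seq_len(count) - 1), each = 48)
  floats <- readBin(body[keep], "numeric", n = 12 * count, size = 4,
                    endian = "little")
  rec <- matrix(floats, nrow = 12)            # normal, v1, v2, v3 per column
  corners <- t(matrix(rec[4:12, , drop = FALSE], nrow = 3))
  .mesh_from_corners(corners, name)
}

.read_stl_ascii <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0) .np_stopf("empty STL %s: no facets", path)
  if (length(vlines) %% 3 != 0)
    .np_stopf("malformed ASCII STL %s: %d vertex lines (not a multiple of 3)",
              path, length(vlines))
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(x) {
    v <- suppressWarnings(as.numeric(x[-1]))
    if (length(v) != 3 || any(!is.finite(v)))
      .np_stopf("malformed ASCII STL %s: bad vertex line '%s'", path,
                paste(x, collapse = " "))
    v
  })
  verts <- do.call(rbind, nums)
  .mesh_from_corners(verts, name)
}

# corners: 3m x 3 matrix, consecutive triples form triangles; weld duplicates
.mesh_from_corners <- function(corners, name) {
  key <- paste(corners[, 1], corners[, 2], corners[, 3], sep = "\r")
  uid <- match(key, key)
  keep <- !duplicated(uid)
  vertices <- corners[keep, , drop = FALSE]
  remap <- match(uid, uid[keep])
  faces <- matrix(remap, ncol = 3, byrow = TRUE)
  tri_mesh(vertices, faces, name)
}

.face_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Write an STL surface model
#'
#' @param mesh A \code{tri_mesh}.
#' @param path Output path.
#' @param dialect \code{"binary"} (default; note binary STL stores float32,
#'   so coordinates round to ~1e-7 relative precision) or \code{"ascii"}.
#' @return \code{path}, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  if (!inherits(mesh, "tri_mesh")) mesh <- tri_mesh(mesh$vertices, mesh$faces)
  m <- nrow(mesh$faces)
  nrm <- .face_normals(mesh)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  if (dialect == "binary") {
    con <- tryCatch(file(path, "wb"),
                    error = function(e) .np_stopf("cannot open %s for writing", path))
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", substr(paste0("needleplace ", mesh$name), 1, 80)))
    writeBin(header[1:80], con)
    writeBin(as.integer(m), con, size = 4, endian = "little")
    rec <- t(cbind(nrm, a, b, c3))            # 12 floats per facet, column-wise
    fbytes <- writeBin(as.numeric(rec), raw(), size = 4, endian = "little")
    out <- raw(50 * m)
    at <- rep.int(seq_len(48), m) + rep(50 * (seq_len(m) - 1), each = 48)
    out[at] <- fbytes
    writeBin(out, con)
  } else {
    fmt <- function(v) sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
    lines <- c(sprintf("solid %s", mesh$name),
               paste0("  facet normal ", fmt(nrm), "\n",
                      "    outer loop\n",
                      "      vertex ", fmt(a), "\n",
                      "      vertex ", fmt(b), "\n",
                      "      vertex ", fmt(c3), "\n",
                      "    endloop\n",
                      "  endfacet"),
               sprintf("endsolid %s", mesh$name))
    tryCatch(writeLines(lines, path),
             error = function(e) .np_stopf("cannot write %s: %s", path, conditionMessage(e)))
  }
  invisible(path)
}

#' Sample a mesh surface into a dense point cloud
#'
#' Deterministic barycentric-grid subdivision of every triangle so that no
#' point of the surface is farther than \code{max_spacing_mm} from a sample
#' (the segmentation-analysis convention of consecutive coordinates at most
#' 0.01 mm apart). Repeated calls on the same input are bitwise identical.
#'
#' @param mesh A \code{tri_mesh}.
#' @param max_spacing_mm Maximum allowed nearest-sample spacing (mm).
#' @return A \code{point_cloud}; \code{spacing_mm} records the largest
#'   sub-edge length actually produced (always <= \code{max_spacing_mm}).
#' @export
sample_surface <- function(mesh, max_spacing_mm) {
  if (!is.numeric(max_spacing_mm) || max_spacing_mm <= 0)
    .np_stopf("max_spacing_mm must be > 0")
  res <- .cpp_sample_triangles(mesh$vertices, mesh$faces, max_spacing_mm)
  if (res$n_degenerate > 0)
    .np_warnf("skipped %d degenerate (zero-area) triangle(s)", res$n_degenerate)
  point_cloud(res$points, res$max_step)
}
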