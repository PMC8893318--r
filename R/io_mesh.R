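#' Construct a triangle surface mesh
#'
#' @param vertices N x 3 numeric matrix of vertex coordinates (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) .anf_stop("anf_format_error", "vertices must be N x 3")
  if (ncol(faces) != 3L) .anf_stop("anf_format_error", "faces must be M x 3")
  if (nrow(faces) < 1L) .anf_stop("anf_validation_error", "mesh has zero faces")
  if (any(!is.finite(vertices)))
    .anf_stop("anf_validation_error", "mesh has non-finite vertex coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    .anf_stop("anf_validation_error", "face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3]))
    .anf_stop("anf_validation_error", "a face repeats a vertex")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Merge duplicate vertices of a facet soup
#'
#' STL stores each triangle with its own three vertex records; this collapses
#' vertices that coincide within `tol` (mm) so faces share vertices. Merging
#' is by exact coincidence of coordinates quantised at `tol`.
#'
#' @param vertices N x 3 coordinates.
#' @param faces M x 3 indices into `vertices`.
#' @param tol Merge tolerance in mm.
#' @return A [surface_mesh()] with shared vertices.
#' @export
merge_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  idx <- match(key, key)                      # first occurrence per key
  keep <- sort(unique(idx))
  remap <- integer(nrow(vertices)); remap[keep] <- seq_along(keep)
  f <- matrix(remap[idx[faces]], ncol = 3L)
  surface_mesh(vertices[keep, , drop = FALSE], f)
}

#' Read an STL surface mesh (binary or ASCII)
#'
#' Both STL dialects are auto-detected. Duplicate vertices are merged within
#' 1e-6 mm so that faces share vertices; face (winding) orientation is kept
#' as stored.
#'
#' @param path Path to the STL file.
#' @param tol Vertex-merge tolerance in mm.
#' @return A [surface_mesh()].
#' @export
read_mesh_stl <- function(path, tol = 1e-6) {
  if (!file.exists(path))
    .anf_stop("anf_format_error", "file '%s' does not exist", path)
  head_raw <- readBin(path, "raw", n = 512L)
  txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  ascii <- grepl("facet\\s+normal", txt, useBytes = TRUE)
  tri <- if (ascii) .read_stl_ascii(path) else .read_stl_binary(path)
  if (nrow(tri) == 0L)
    .anf_stop("anf_validation_error", "'%s' contains zero facets", path)
  n_tri <- nrow(tri) / 3L
  faces <- matrix(seq_len(nrow(tri)), ncol = 3L, byrow = TRUE)
  mesh <- merge_vertices(tri, faces, tol = tol)
  mesh
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L) return(matrix(numeric(0), ncol = 3L))
  if (length(vl) %% 3L != 0L)
    .anf_stop("anf_format_error", "'%s': vertex count not a multiple of 3", path)
  nums <- strsplit(trimws(vl), "\\s+")
  m <- t(vapply(nums, function(x) as.numeric(x[2:4]), numeric(3)))
  if (any(!is.finite(m)))
    .anf_stop("anf_format_error", "'%s': unparseable vertex coordinates", path)
  m
}

.read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", n = 80L)                          # header
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(n) == 0L || is.na(n) || n < 0L || sz < 84 + n * 50)
    .anf_stop("anf_format_error", "'%s': truncated binary STL", path)
  payload <- readBin(con, "raw", n = n * 50L)
  if (length(payload) < n * 50L)
    .anf_stop("anf_format_error", "'%s': truncated binary STL", path)
  # facet record: 12 bytes normal + 36 bytes (3 vertices x 3 floats) + 2 attr
  off <- rep((seq_len(n) - 1L) * 50L, each = 36L) + rep(12L + 1:36, times = n)
  floats <- readBin(payload[off], "double", size = 4L, n = 9L * n,
                    endian = "little")
  matrix(floats, ncol = 3L, byrow = TRUE)
}

#' Write a surface mesh as STL
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @param ascii Write the ASCII dialect instead of binary.
#' @return The path, invisibly.
#' @export
write_mesh_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  nrm <- .row_cross(p2 - p1, p3 - p1)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (ascii) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid aneufuse", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf(" facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "  outer loop",
        sprintf("   vertex %.9g %.9g %.9g", p1[i, 1], p1[i, 2], p1[i, 3]),
        sprintf("   vertex %.9g %.9g %.9g", p2[i, 1], p2[i, 2], p2[i, 3]),
        sprintf("   vertex %.9g %.9g %.9g", p3[i, 1], p3[i, 2], p3[i, 3]),
        "  endloop", " endfacet"), con)
    }
    writeLines("endsolid aneufuse", con)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(c(charToRaw("aneufuse binary STL"), raw(80 - 19)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    tri <- cbind(nrm, p1, p2, p3)             # 12 floats per facet
    for (i in seq_len(nrow(f))) {
      writeBin(as.vector(tri[i, ], "double"), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

.row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
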