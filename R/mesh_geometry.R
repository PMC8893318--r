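# Discrete geometry on triangle meshes: oriented-bounding-box extents,
# surface area, enclosed volume, and per-vertex curvature estimators
# (angle-deficit Gaussian curvature, cotangent-Laplacian mean curvature,
# principal curvatures and curvedness), plus the 25-feature morphometric
# summary used by the fusion pipeline.

#' Unit icosphere mesh
#'
#' Builds a sphere mesh by recursive 4-way subdivision of an icosahedron with
#' projection onto the sphere. Used by the phantom generator (as the base
#' shape that gets radially deformed) and by geometry tests.
#'
#' @param subdivisions Number of subdivision rounds (0 = icosahedron).
#' @param radius Sphere radius (mm).
#' @param center Length-3 center (mm).
#' @return A [surface_mesh()] with outward-oriented faces.
#' @export
icosphere <- function(subdivisions = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    e1 <- cbind(f[, 1], f[, 2]); e2 <- cbind(f[, 2], f[, 3])
    e3 <- cbind(f[, 3], f[, 1])
    edges <- rbind(e1, e2, e3)
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uk <- unique(key)
    mid_idx <- nrow(v) + match(key, uk)
    ue <- edges[match(uk, key), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    a <- f[, 1]; b <- f[, 2]; cc <- f[, 3]
    ab <- mid_idx[1:nf]; bc <- mid_idx[nf + 1:nf]; ca <- mid_idx[2 * nf + 1:nf]
    f <- rbind(cbind(a, ab, ca), cbind(b, bc, ab), cbind(cc, ca, bc),
               cbind(ab, bc, ca))
  }
  v <- sweep(v * radius, 2, center, "+")
  surface_mesh(v, f)
}

# ---- topology helpers -----------------------------------------------------

.mesh_edge_keys <- function(faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Count open (boundary) edges of a mesh
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces.
#'
#' @param mesh A [surface_mesh()].
#' @return Integer count of edges not shared by exactly two faces.
#' @export
open_edge_count <- function(mesh) {
  tab <- table(.mesh_edge_keys(mesh$faces))
  sum(tab != 2L)
}

#' @rdname open_edge_count
#' @export
is_watertight <- function(mesh) open_edge_count(mesh) == 0L

#' Orient mesh faces consistently, outward
#'
#' Propagates a consistent winding across edge-adjacent faces (flood fill) and
#' then flips globally, if necessary, so that the signed enclosed volume is
#' positive (outward normals).
#'
#' @param mesh A watertight [surface_mesh()].
#' @return The mesh with consistent outward-facing winding.
#' @export
orient_faces <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  dir_edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  face_of <- rep(seq_len(nf), 3L)
  key <- paste(pmin(dir_edges[, 1], dir_edges[, 2]),
               pmax(dir_edges[, 1], dir_edges[, 2]))
  ord <- order(key)
  key_s <- key[ord]; face_s <- face_of[ord]
  first <- !duplicated(key_s)
  grp <- cumsum(first)
  # pair up the (exactly two) half-edges per undirected edge
  idx1 <- which(first)
  idx2 <- idx1 + 1L
  valid <- idx2 <= length(key_s) & key_s[idx1] == key_s[idx2]
  fa <- face_s[idx1[valid]]; fb <- face_s[idx2[valid]]
  # same directed orientation on both faces means inconsistent winding
  same_dir <- dir_edges[ord[idx1[valid]], 1] == dir_edges[ord[idx2[valid]], 1]
  adj_from <- c(fa, fb); adj_to <- c(fb, fa); adj_same <- c(same_dir, same_dir)
  adj <- split(seq_along(adj_from), adj_from)
  flip <- rep(NA, nf)
  queue <- integer(nf)
  for (seed in seq_len(nf)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    queue[1] <- seed; head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      for (s in adj[[as.character(cur)]]) {
        nb <- adj_to[s]
        want <- if (adj_same[s]) !flip[cur] else flip[cur]
        if (is.na(flip[nb])) {
          flip[nb] <- want; tail <- tail + 1L; queue[tail] <- nb
        }
      }
    }
  }
  f[flip, ] <- f[flip, c(1, 3, 2), drop = FALSE]
  m <- surface_mesh(mesh$vertices, f)
  if (.signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2), drop = FALSE]
  m
}

.signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(rowSums(p1 * .row_cross(p2, p3))) / 6
}

# ---- global morphometrics -------------------------------------------------

#' Oriented-bounding-box extents of a mesh
#'
#' Extents of the vertex cloud along the principal axes of its covariance,
#' sorted descending: a pose-invariant length/width/height.
#'
#' @param mesh A [surface_mesh()].
#' @return Numeric length-3 `(length, width, height)` in mm, descending.
#' @export
obb_extents <- function(mesh) {
  v <- mesh$vertices
  if (nrow(v) < 4L)
    .anf_stop("anf_geometry_error", "need at least 4 vertices for extents")
  cv <- stats::cov(v)
  ax <- eigen(cv, symmetric = TRUE)$vectors
  proj <- v %*% ax
  ext <- apply(proj, 2, function(x) diff(range(x)))
  ext <- sort(ext, decreasing = TRUE)
  if (ext[3] <= 1e-9 * max(ext[1], 1e-300))
    .anf_stop("anf_geometry_error", "degenerate (coplanar) vertex cloud")
  ext
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas (half cross-product norms).
#'
#' @param mesh A [surface_mesh()].
#' @return Area in mm^2.
#' @export
surface_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- .row_cross(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                  v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  sum(sqrt(rowSums(n^2))) / 2
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem signed-tetrahedron sum over consistently oriented faces;
#' the absolute value is returned.
#'
#' @param mesh A watertight [surface_mesh()].
#' @return Volume in mm^3.
#' @export
enclosed_volume <- function(mesh) {
  oec <- open_edge_count(mesh)
  if (oec > 0L)
    .anf_stop("anf_geometry_error",
              "mesh is not watertight (%d open edges); volume undefined", oec)
  abs(.signed_volume(orient_faces(mesh)))
}

# ---- curvature ------------------------------------------------------------

#' Per-vertex discrete curvatures
#'
#' Gaussian curvature `K` from the angle deficit divided by the mixed Voronoi
#' area; mean curvature `H` from the cotangent Laplace-Beltrami mean-curvature
#' normal, signed positive for a convex surface with outward normals;
#' principal curvatures `k1 >= k2 = H +/- sqrt(max(H^2 - K, 0))`; curvedness
#' `C = sqrt((k1^2 + k2^2) / 2)`.
#'
#' @param mesh A watertight manifold [surface_mesh()].
#' @return A data.frame with columns `k1`, `k2`, `K`, `H`, `C` (one row per
#'   vertex), and attribute `angle_deficit`.
#' @export
vertex_curvatures <- function(mesh) {
  if (!is_watertight(mesh))
    .anf_stop("anf_geometry_error", "curvature needs a watertight mesh (%d open edges)",
              open_edge_count(mesh))
  mesh <- orient_faces(mesh)
  v <- mesh$vertices; f <- mesh$faces
  nv <- nrow(v)
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  p1 <- v[i1, , drop = FALSE]; p2 <- v[i2, , drop = FALSE]
  p3 <- v[i3, , drop = FALSE]
  e12 <- p2 - p1; e13 <- p3 - p1; e23 <- p3 - p2
  cr <- .row_cross(e12, e13)
  a2 <- sqrt(rowSums(cr^2))                 # 2 * triangle area
  if (any(a2 <= 0))
    .anf_stop("anf_geometry_error", "zero-area face")
  # corner angles
  ang1 <- .vec_angle(e12, e13)
  ang2 <- .vec_angle(-e12, e23)
  ang3 <- pi - ang1 - ang2
  # cotangents at each corner
  cot1 <- 1 / tan(ang1); cot2 <- 1 / tan(ang2); cot3 <- 1 / tan(ang3)
  # squared edge lengths
  l12 <- rowSums(e12^2); l13 <- rowSums(e13^2); l23 <- rowSums(e23^2)
  area <- a2 / 2
  obtuse <- pmax(ang1, ang2, ang3) > pi / 2
  # mixed area contributions per corner (Meyer et al. discrete operators)
  amix1 <- ifelse(!obtuse, (l12 * cot3 + l13 * cot2) / 8,
                  ifelse(ang1 > pi / 2, area / 2, area / 4))
  amix2 <- ifelse(!obtuse, (l12 * cot3 + l23 * cot1) / 8,
                  ifelse(ang2 > pi / 2, area / 2, area / 4))
  amix3 <- ifelse(!obtuse, (l13 * cot2 + l23 * cot1) / 8,
                  ifelse(ang3 > pi / 2, area / 2, area / 4))
  A <- as.vector(rowsum(c(amix1, amix2, amix3), c(i1, i2, i3),
                        reorder = FALSE))
  vid <- as.integer(rownames(rowsum(c(amix1, amix2, amix3), c(i1, i2, i3),
                                    reorder = FALSE)))
  Amix <- numeric(nv); Amix[vid] <- A
  if (any(Amix <= 0))
    .anf_stop("anf_geometry_error", "vertex with zero mixed area")
  theta <- numeric(nv)
  ts <- rowsum(c(ang1, ang2, ang3), c(i1, i2, i3), reorder = FALSE)
  theta[as.integer(rownames(ts))] <- as.vector(ts)
  deficit <- 2 * pi - theta
  K <- deficit / Amix
  # cotangent mean-curvature normal: L_i = (1/(2A_i)) sum_j (cot a + cot b)(x_i - x_j)
  # accumulate per half-edge: for edge (i2,i3) the opposite angle is ang1, etc.
  wsum <- matrix(0, nv, 3)
  acc <- function(i, j, w) {
    d <- v[i, , drop = FALSE] - v[j, , drop = FALSE]
    dw <- d * w
    s <- rowsum(dw, i, reorder = FALSE)
    rid <- as.integer(rownames(s))
    wsum[rid, ] <<- wsum[rid, , drop = FALSE] + s
    s2 <- rowsum(-dw, j, reorder = FALSE)
    rid2 <- as.integer(rownames(s2))
    wsum[rid2, ] <<- wsum[rid2, , drop = FALSE] + s2
  }
  acc(i2, i3, cot1)
  acc(i1, i3, cot2)
  acc(i1, i2, cot3)
  Lvec <- wsum / (2 * Amix)
  Hmag <- sqrt(rowSums(Lvec^2)) / 2
  # outward vertex normals: area-weighted face normals
  nrm <- matrix(0, nv, 3)
  for (cix in 1:3) {
    s <- rowsum(cr, f[, cix], reorder = FALSE)
    rid <- as.integer(rownames(s))
    nrm[rid, ] <- nrm[rid, , drop = FALSE] + s
  }
  sgn <- sign(rowSums(Lvec * nrm))
  sgn[sgn == 0] <- 1
  H <- sgn * Hmag
  disc <- pmax(H^2 - K, 0)
  k1 <- H + sqrt(disc); k2 <- H - sqrt(disc)
  # where the two discrete estimates disagree (H^2 < K) the discriminant
  # clamp forces k1 = k2 = H; report K = k1*k2 there so the returned field
  # satisfies K = k1*k2 and H = (k1+k2)/2 at every vertex
  K_out <- k1 * k2
  C <- sqrt((k1^2 + k2^2) / 2)
  out <- data.frame(k1 = k1, k2 = k2, K = K_out, H = H, C = C)
  attr(out, "angle_deficit") <- deficit
  out
}

.vec_angle <- function(a, b) {
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  acos(pmin(pmax(num / den, -1), 1))
}

# ---- 25-feature summary ---------------------------------------------------

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' The 25 morphological features of a lesion surface mesh
#'
#' Five global measures (oriented-bounding-box length/width/height, surface
#' area, enclosed volume) plus max/min/mean/population-sd of five per-vertex
#' curvature scalars: the two principal curvatures, Gaussian curvature, mean
#' curvature and curvedness.
#'
#' @param mesh A watertight [surface_mesh()].
#' @param area_weighted Weight curvature statistics by mixed vertex area
#'   instead of treating vertices uniformly (default FALSE).
#' @return Named numeric vector of exactly 25 features.
#' @export
morphological_features <- function(mesh, area_weighted = FALSE) {
  ext <- obb_extents(mesh)
  curv <- vertex_curvatures(mesh)
  stats4 <- function(x, nm) {
    s <- c(max(x), min(x), mean(x), .pop_sd(x))
    names(s) <- paste0(nm, c("_max", "_min", "_mean", "_std"))
    s
  }
  if (area_weighted) {
    # area-weighted mean/sd, extrema unchanged
    w <- rep(1, nrow(curv))  # placeholder weights replaced below
    stats4 <- local({
      amesh <- mesh
      function(x, nm) {
        cw <- .vertex_area_weights(amesh)
        mu <- sum(cw * x) / sum(cw)
        sdv <- sqrt(sum(cw * (x - mu)^2) / sum(cw))
        s <- c(max(x), min(x), mu, sdv)
        names(s) <- paste0(nm, c("_max", "_min", "_mean", "_std"))
        s
      }
    })
  }
  out <- c(length = ext[1], width = ext[2], height = ext[3],
           surface_area = surface_area(mesh),
           volume = enclosed_volume(mesh),
           stats4(curv$k1, "kappa1"), stats4(curv$k2, "kappa2"),
           stats4(curv$K, "gauss"), stats4(curv$H, "meancurv"),
           stats4(curv$C, "curvedness"))
  stopifnot(length(out) == 25L)
  out
}

.vertex_area_weights <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- .row_cross(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                  v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  area <- sqrt(rowSums(n^2)) / 2
  w <- numeric(nrow(v))
  for (cix in 1:3) {
    s <- rowsum(area / 3, f[, cix], reorder = FALSE)
    w[as.integer(rownames(s))] <- w[as.integer(rownames(s))] + as.vector(s)
  }
  w
}
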