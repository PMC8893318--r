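# Isosurface extraction by marching tetrahedra on a Kuhn 6-tetrahedron
# decomposition of each grid cell. The decomposition is translation-invariant,
# so face diagonals agree between neighbouring cells and the triangulated
# level set is watertight. Triangles are wound with outward normals (pointing
# from values above the level toward values below), so the signed-tetrahedron
# volume sum is directly usable.

# cube corner offsets, corner ids 1..8 (0-based geometric offsets)
.mt_corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                     c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
# six tetrahedra sharing the 1-7 diagonal (1-based corner ids)
.mt_tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

#' Extract an isosurface from a 3D scalar grid
#'
#' Marching tetrahedra at `level`; grid node `(i, j, k)` (0-based) sits at
#' `origin + c(i, j, k) * spacing`. The grid is padded with a below-level
#' value so the surface is always closed.
#'
#' @param vals 3D numeric array of node values.
#' @param level Iso level.
#' @param spacing Length-3 voxel spacing (mm).
#' @param origin Length-3 world origin (mm).
#' @return A list with `mesh` (a watertight [surface_mesh()], or NULL when the
#'   level set is empty), `area` (mm^2) and `volume` (mm^3).
#' @export
isosurface <- function(vals, level = 0.5, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  stopifnot(length(dim(vals)) == 3L)
  pad <- level - 1
  d <- dim(vals)
  pv <- array(pad, dim = d + 2L)
  pv[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- vals
  dp <- dim(pv)
  nx <- dp[1]; ny <- dp[2]
  inside <- pv > level
  if (!any(inside)) return(list(mesh = NULL, area = 0, volume = 0))
  # candidate cells: any corner disagreement
  ii <- 1:(dp[1] - 1L); jj <- 1:(dp[2] - 1L); kk <- 1:(dp[3] - 1L)
  base <- inside[ii, jj, kk]
  agree <- base == inside[ii + 1L, jj, kk]
  agree <- agree & (base == inside[ii, jj + 1L, kk])
  agree <- agree & (base == inside[ii + 1L, jj + 1L, kk])
  agree <- agree & (base == inside[ii, jj, kk + 1L])
  agree <- agree & (base == inside[ii + 1L, jj, kk + 1L])
  agree <- agree & (base == inside[ii, jj + 1L, kk + 1L])
  agree <- agree & (base == inside[ii + 1L, jj + 1L, kk + 1L])
  cand <- which(!agree)
  if (length(cand) == 0L) return(list(mesh = NULL, area = 0, volume = 0))
  dcell <- dp - 1L
  ci <- (cand - 1L) %% dcell[1]
  cj <- ((cand - 1L) %/% dcell[1]) %% dcell[2]
  ck <- (cand - 1L) %/% (dcell[1] * dcell[2])        # all 0-based cell coords
  corner_off <- .mt_corners %*% c(1L, nx, nx * ny)
  base_lin <- ci + 1L + cj * nx + ck * (nx * ny)
  vals8 <- matrix(0, length(cand), 8L)
  for (c8 in 1:8) vals8[, c8] <- pv[base_lin + corner_off[c8]]
  # node world coordinates; padded index (1,1,1) is original node -1
  px <- (ci - 1) ; py <- (cj - 1); pz <- (ck - 1)    # 0-based original coords
  tris <- vector("list", 90L); nt <- 0L
  emit <- function(pa, pb, pc, inside_pt) {
    # orient so normal points away from the inside reference point
    nrm <- .row_cross(pb - pa, pc - pa)
    flip <- rowSums(nrm * ((pa + pb + pc) / 3 - inside_pt)) < 0
    tmp <- pb[flip, , drop = FALSE]
    pb[flip, ] <- pc[flip, , drop = FALSE]
    pc[flip, ] <- tmp
    nt <<- nt + 1L
    tris[[nt]] <<- cbind(pa, pb, pc)
  }
  interp <- function(pa, va, pb, vb) {
    t <- (level - va) / (vb - va)
    pa + (pb - pa) * t
  }
  for (tix in seq_len(nrow(.mt_tets))) {
    tc <- .mt_tets[tix, ]
    v <- vals8[, tc, drop = FALSE]
    ins <- v > level
    nin <- rowSums(ins)
    sel_any <- nin > 0 & nin < 4
    if (!any(sel_any)) next
    # tet vertex world positions
    P <- vector("list", 4L)
    for (q in 1:4) {
      off <- .mt_corners[tc[q], ]
      P[[q]] <- cbind((px + off[1]) * spacing[1] + origin[1],
                      (py + off[2]) * spacing[2] + origin[2],
                      (pz + off[3]) * spacing[3] + origin[3])
    }
    # single vertex on one side (inside if nin==1, outside if nin==3)
    for (apex in 1:4) {
      oth <- setdiff(1:4, apex)
      for (mode in c(1L, 3L)) {
        sel <- if (mode == 1L) which(nin == 1L & ins[, apex])
               else which(nin == 3L & !ins[, apex])
        if (!length(sel)) next
        pa <- P[[apex]][sel, , drop = FALSE]; va <- v[sel, apex]
        q1 <- interp(pa, va, P[[oth[1]]][sel, , drop = FALSE], v[sel, oth[1]])
        q2 <- interp(pa, va, P[[oth[2]]][sel, , drop = FALSE], v[sel, oth[2]])
        q3 <- interp(pa, va, P[[oth[3]]][sel, , drop = FALSE], v[sel, oth[3]])
        ref <- if (mode == 1L) pa else {
          # inside centroid = mean of the three non-apex (inside) vertices
          (P[[oth[1]]][sel, , drop = FALSE] + P[[oth[2]]][sel, , drop = FALSE] +
             P[[oth[3]]][sel, , drop = FALSE]) / 3
        }
        emit(q1, q2, q3, ref)
      }
    }
    # two inside, two outside
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (pr in seq_len(nrow(pairs))) {
      A <- pairs[pr, 1]; B <- pairs[pr, 2]
      CD <- setdiff(1:4, c(A, B))
      sel <- which(nin == 2L & ins[, A] & ins[, B])
      if (!length(sel)) next
      pA <- P[[A]][sel, , drop = FALSE]; vA <- v[sel, A]
      pB <- P[[B]][sel, , drop = FALSE]; vB <- v[sel, B]
      pC <- P[[CD[1]]][sel, , drop = FALSE]; vC <- v[sel, CD[1]]
      pD <- P[[CD[2]]][sel, , drop = FALSE]; vD <- v[sel, CD[2]]
      qAC <- interp(pA, vA, pC, vC); qAD <- interp(pA, vA, pD, vD)
      qBC <- interp(pB, vB, pC, vC); qBD <- interp(pB, vB, pD, vD)
      ref <- (pA + pB) / 2
      emit(qAC, qAD, qBD, ref)
      emit(qAC, qBD, qBC, ref)
    }
  }
  soup <- do.call(rbind, tris[seq_len(nt)])
  p1 <- soup[, 1:3, drop = FALSE]; p2 <- soup[, 4:6, drop = FALSE]
  p3 <- soup[, 7:9, drop = FALSE]
  cr <- .row_cross(p2 - p1, p3 - p1)
  area <- sum(sqrt(rowSums(cr^2))) / 2
  volume <- abs(sum(rowSums(p1 * .row_cross(p2, p3))) / 6)
  verts <- rbind(p1, p2, p3)
  m <- nrow(soup)
  faces <- cbind(seq_len(m), seq_len(m) + m, seq_len(m) + 2L * m)
  deg <- sqrt(rowSums(cr^2)) <= 0
  if (any(deg)) {                     # drop zero-area slivers (grazing nodes)
    keepf <- which(!deg)
    faces <- faces[keepf, , drop = FALSE]
  }
  mesh <- tryCatch(merge_vertices(verts, faces, tol = 1e-8),
                   error = function(e) NULL)
  list(mesh = mesh, area = area, volume = volume)
}
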