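# Texture-matrix builders on a discretized ROI. All five families are built
# from in-mask voxels only; out-of-mask neighbours are ignored.
#
# GLCM / GLRLM use the 13 unique 3D directions at Chebyshev distance 1
# (merged accumulation over directions); GLSZM zones and GLDM dependences use
# the full 26-neighbourhood; NGTDM uses the Chebyshev-1 neighbourhood.

#' The 13 unique 3D direction offsets at Chebyshev distance 1
#' @return 13 x 3 integer matrix.
#' @keywords internal
.directions13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  unname(g[keep, , drop = FALSE])
}

.directions26 <- function() {
  d <- .directions13()
  rbind(d, -d)
}

# compact-id bookkeeping shared by the run/zone builders
.roi_compact <- function(roi) {
  lv <- roi$levels
  dims <- dim(lv)
  inm <- which(!is.na(lv))
  cid <- array(0L, dim = dims)
  cid[inm] <- seq_along(inm)
  coords <- arrayInd(inm, dims)
  list(lv = lv, dims = dims, lin = inm, cid = cid, coords = coords,
       lev = lv[inm], n = length(inm))
}

.neighbor_cid <- function(cp, d) {
  # compact id of the neighbour at offset d for each in-mask voxel (0 if
  # out of grid or out of mask)
  nc <- sweep(cp$coords, 2, d, "+")
  ok <- nc[, 1] >= 1 & nc[, 1] <= cp$dims[1] &
        nc[, 2] >= 1 & nc[, 2] <= cp$dims[2] &
        nc[, 3] >= 1 & nc[, 3] <= cp$dims[3]
  out <- integer(cp$n)
  out[ok] <- cp$cid[nc[ok, , drop = FALSE]]
  out
}

#' Build a texture matrix for one family
#'
#' @param roi A `discretized_roi` from [discretize()].
#' @param family One of `"glcm"`, `"glrlm"`, `"glszm"`, `"ngtdm"`, `"gldm"`.
#' @param alpha GLDM dependence tolerance on the gray-level difference
#'   (default 0).
#' @return An object of class `texture_matrix` with fields `family`, `matrix`
#'   (GLCM: Ng x Ng symmetrized counts; GLRLM: Ng x max run length; GLSZM:
#'   Ng x max zone size; GLDM: Ng x max dependence size; NGTDM: Ng x 2 with
#'   columns `n` and `s`), `n_levels`, `n_voxels` and `params`.
#' @export
texture_matrix <- function(roi, family = c("glcm", "glrlm", "glszm",
                                           "ngtdm", "gldm"), alpha = 0) {
  stopifnot(inherits(roi, "discretized_roi"))
  family <- match.arg(family)
  m <- switch(family,
              glcm = .build_glcm(roi),
              glrlm = .build_glrlm(roi),
              glszm = .build_glszm(roi),
              ngtdm = .build_ngtdm(roi),
              gldm = .build_gldm(roi, alpha))
  structure(list(family = family, matrix = m, n_levels = roi$n_levels,
                 n_voxels = sum(!is.na(roi$levels)),
                 params = list(distance = 1, n_directions = 13, alpha = alpha)),
            class = "texture_matrix")
}

#' @export
print.texture_matrix <- function(x, ...) {
  cat(sprintf("<texture_matrix> %s, %d gray levels, %s counts\n",
              toupper(x$family), x$n_levels,
              paste(dim(x$matrix), collapse = "x")))
  invisible(x)
}

.build_glcm <- function(roi) {
  ng <- roi$n_levels
  lv <- roi$levels
  counts <- matrix(0, ng, ng)
  for (k in seq_len(nrow(.directions13()))) {
    d <- .directions13()[k, ]
    nb <- .shift_array(lv, d[1], d[2], d[3], fill = NA_integer_)
    ok <- !is.na(lv) & !is.na(nb)
    if (!any(ok)) next
    idx <- (lv[ok] - 1L) * ng + nb[ok]
    counts <- counts + matrix(tabulate(idx, nbins = ng * ng), ng, ng,
                              byrow = TRUE)
  }
  counts + t(counts)   # symmetrization P + t(P)
}

.build_glrlm <- function(roi) {
  cp <- .roi_compact(roi)
  ng <- roi$n_levels
  maxlen <- max(cp$dims)
  counts <- matrix(0, ng, maxlen)
  for (k in seq_len(nrow(.directions13()))) {
    d <- .directions13()[k, ]
    nxt <- .neighbor_cid(cp, d)
    prv <- .neighbor_cid(cp, -d)
    same_next <- nxt > 0L & cp$lev[pmax(nxt, 1L)] == cp$lev
    same_prev <- prv > 0L & cp$lev[pmax(prv, 1L)] == cp$lev
    nxt[!same_next] <- 0L
    # pointer jumping: run length from each voxel to the end of its run
    L <- rep(1L, cp$n); ptr <- nxt
    while (any(ptr > 0L)) {
      sel <- ptr > 0L
      L[sel] <- L[sel] + L[ptr[sel]]
      ptr[sel] <- ptr[ptr[sel]]
    }
    starts <- which(!same_prev)
    idx <- (cp$lev[starts] - 1L) * maxlen + L[starts]
    counts <- counts + matrix(tabulate(idx, nbins = ng * maxlen), ng, maxlen,
                              byrow = TRUE)
  }
  # trim empty trailing run lengths (keep at least one column)
  keep <- max(1L, max(which(colSums(counts) > 0, useNames = FALSE), 1L))
  counts[, seq_len(keep), drop = FALSE]
}

.build_glszm <- function(roi) {
  cp <- .roi_compact(roi)
  ng <- roi$n_levels
  edges <- list()
  for (k in seq_len(nrow(.directions13()))) {
    d <- .directions13()[k, ]
    nb <- .neighbor_cid(cp, d)
    ok <- nb > 0L & cp$lev[pmax(nb, 1L)] == cp$lev
    if (any(ok))
      edges[[length(edges) + 1L]] <- cbind(which(ok), nb[ok])
  }
  if (length(edges)) {
    el <- do.call(rbind, edges)
    g <- igraph::make_graph(t(el), n = cp$n, directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_len(cp$n)
  }
  zsize <- tabulate(memb)
  zlev <- cp$lev[match(seq_along(zsize), memb)]
  maxs <- max(zsize)
  counts <- matrix(0, ng, maxs)
  idx <- (zlev - 1L) * maxs + zsize
  counts <- counts + matrix(tabulate(idx, nbins = ng * maxs), ng, maxs,
                            byrow = TRUE)
  counts
}

.build_ngtdm <- function(roi) {
  lv <- roi$levels
  ng <- roi$n_levels
  nbsum <- array(0, dim = dim(lv))
  nbcnt <- array(0L, dim = dim(lv))
  for (k in seq_len(nrow(.directions26()))) {
    d <- .directions26()[k, ]
    sh <- .shift_array(lv, d[1], d[2], d[3], fill = NA_integer_)
    has <- !is.na(sh)
    nbsum[has] <- nbsum[has] + sh[has]
    nbcnt <- nbcnt + has
  }
  sel <- !is.na(lv) & nbcnt > 0L
  lev <- lv[sel]
  abar <- nbsum[sel] / nbcnt[sel]
  diffs <- abs(lev - abar)
  n_i <- tabulate(lev, nbins = ng)
  s_i <- numeric(ng)
  tmp <- rowsum(diffs, lev)
  s_i[as.integer(rownames(tmp))] <- as.vector(tmp)
  cbind(n = n_i, s = s_i)
}

.build_gldm <- function(roi, alpha = 0) {
  lv <- roi$levels
  ng <- roi$n_levels
  dep <- array(0L, dim = dim(lv))
  for (k in seq_len(nrow(.directions26()))) {
    d <- .directions26()[k, ]
    sh <- .shift_array(lv, d[1], d[2], d[3], fill = NA_integer_)
    ok <- !is.na(lv) & !is.na(sh) & abs(sh - lv) <= alpha
    dep <- dep + ok
  }
  sel <- !is.na(lv)
  lev <- lv[sel]
  j <- dep[sel] + 1L          # dependence size includes the center voxel
  maxd <- max(j)
  idx <- (lev - 1L) * maxd + j
  matrix(tabulate(idx, nbins = ng * maxd), ng, maxd, byrow = TRUE)
}
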