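# Independent brute-force oracles used to validate the fast implementations.
# Everything here is written as naive triple/quadruple loops over voxels so
# that correctness is obvious by inspection.

# All 26 integer offsets with Chebyshev distance 1.
oracle_offsets26 <- function() {
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ])
}

# 13 unique directions (one per +/- pair), matching the builders' convention.
oracle_offsets13 <- function() {
  o <- oracle_offsets26()
  keep <- o[, 3] > 0 | (o[, 3] == 0 & (o[, 2] > 0 | (o[, 2] == 0 & o[, 1] > 0)))
  o[keep, , drop = FALSE]
}

.oracle_in <- function(lv, i, j, k) {
  d <- dim(lv)
  i >= 1 && i <= d[1] && j >= 1 && j <= d[2] && k >= 1 && k <= d[3] &&
    !is.na(lv[i, j, k])
}

# GLCM: count level pairs over the 13 directions, then symmetrize (P + t(P)).
oracle_glcm <- function(lv, ng) {
  P <- matrix(0, ng, ng)
  offs <- oracle_offsets13()
  d <- dim(lv)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lv[i, j, k])) next
    for (r in seq_len(nrow(offs))) {
      ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
      if (.oracle_in(lv, ii, jj, kk))
        P[lv[i, j, k], lv[ii, jj, kk]] <- P[lv[i, j, k], lv[ii, jj, kk]] + 1
    }
  }
  P + t(P)
}

# GLRLM: walk maximal runs along each of the 13 directions.
oracle_glrlm <- function(lv, ng) {
  d <- dim(lv)
  maxlen <- max(d)
  R <- matrix(0, ng, maxlen)
  offs <- oracle_offsets13()
  for (r in seq_len(nrow(offs))) {
    dx <- offs[r, 1]; dy <- offs[r, 2]; dz <- offs[r, 3]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (is.na(lv[i, j, k])) next
      # run start: predecessor absent or different level
      pi <- i - dx; pj <- j - dy; pk <- k - dz
      if (.oracle_in(lv, pi, pj, pk) && lv[pi, pj, pk] == lv[i, j, k]) next
      len <- 1
      ci <- i + dx; cj <- j + dy; ck <- k + dz
      while (.oracle_in(lv, ci, cj, ck) && lv[ci, cj, ck] == lv[i, j, k]) {
        len <- len + 1
        ci <- ci + dx; cj <- cj + dy; ck <- ck + dz
      }
      R[lv[i, j, k], len] <- R[lv[i, j, k], len] + 1
    }
  }
  R[, seq_len(max(which(colSums(R) > 0))), drop = FALSE]
}

# GLSZM: flood-fill 26-connected equal-level zones.
oracle_glszm <- function(lv, ng) {
  d <- dim(lv)
  n <- prod(d)
  visited <- array(FALSE, dim = d)
  offs <- oracle_offsets26()
  sizes <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lv[i, j, k]) || visited[i, j, k]) next
    g <- lv[i, j, k]
    stack <- list(c(i, j, k)); visited[i, j, k] <- TRUE; size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        ii <- v[1] + offs[r, 1]; jj <- v[2] + offs[r, 2]; kk <- v[3] + offs[r, 3]
        if (.oracle_in(lv, ii, jj, kk) && !visited[ii, jj, kk] &&
            lv[ii, jj, kk] == g) {
          visited[ii, jj, kk] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj, kk)
        }
      }
    }
    sizes[[length(sizes) + 1L]] <- c(g, size)
  }
  zs <- do.call(rbind, sizes)
  Z <- matrix(0, ng, max(zs[, 2]))
  for (r in seq_len(nrow(zs))) Z[zs[r, 1], zs[r, 2]] <- Z[zs[r, 1], zs[r, 2]] + 1
  Z
}

# NGTDM: per level, count of contributing voxels n_i and summed absolute
# difference s_i between the voxel level and its in-mask neighborhood mean.
oracle_ngtdm <- function(lv, ng) {
  d <- dim(lv)
  offs <- oracle_offsets26()
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lv[i, j, k])) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
      if (.oracle_in(lv, ii, jj, kk)) nb <- c(nb, lv[ii, jj, kk])
    }
    if (length(nb) == 0) next
    g <- lv[i, j, k]
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb))
  }
  list(n = n_i, s = s_i)
}

# GLDM: dependence = 1 + number of in-mask neighbors with |level diff| <= alpha.
oracle_gldm <- function(lv, ng, alpha = 0) {
  d <- dim(lv)
  offs <- oracle_offsets26()
  deps <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lv[i, j, k])) next
    dep <- 1
    for (r in seq_len(nrow(offs))) {
      ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
      if (.oracle_in(lv, ii, jj, kk) &&
          abs(lv[ii, jj, kk] - lv[i, j, k]) <= alpha) dep <- dep + 1
    }
    deps[[length(deps) + 1L]] <- c(lv[i, j, k], dep)
  }
  dm <- do.call(rbind, deps)
  D <- matrix(0, ng, max(dm[, 2]))
  for (r in seq_len(nrow(dm))) D[dm[r, 1], dm[r, 2]] <- D[dm[r, 1], dm[r, 2]] + 1
  D
}

# Build a discretized_roi object directly from a small integer level array
# (NA outside the ROI), bypassing image preprocessing.
oracle_make_roi <- function(lv, ng = max(lv, na.rm = TRUE)) {
  structure(list(levels = lv, n_levels = as.integer(ng),
                 mask = !is.na(lv), spacing = c(1, 1, 1)),
            class = "discretized_roi")
}

# AUC by exhaustive positive-negative pair counting (ties worth 1/2).
oracle_auc_pairs <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Trapezoidal area under the empirical ROC curve.
oracle_auc_trapezoid <- function(y, s) {
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  # step through distinct thresholds
  tps <- c(0); fps <- c(0)
  i <- 1
  n <- length(y)
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1] == s[i]) j <- j + 1
    tps <- c(tps, tps[length(tps)] + sum(y[i:j] == 1))
    fps <- c(fps, fps[length(fps)] + sum(y[i:j] == 0))
    i <- j + 1
  }
  tpr <- tps / sum(y == 1); fpr <- fps / sum(y == 0)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Nearest-point vertex merge: greedy O(n^2) clustering within tolerance.
oracle_merge_vertices <- function(V, tol = 1e-6) {
  n <- nrow(V)
  rep_of <- integer(n)
  centers <- list()
  for (i in seq_len(n)) {
    hit <- 0L
    for (c in seq_along(centers)) {
      if (sqrt(sum((V[i, ] - centers[[c]])^2)) <= tol) { hit <- c; break }
    }
    if (hit == 0L) { centers[[length(centers) + 1L]] <- V[i, ]; hit <- length(centers) }
    rep_of[i] <- hit
  }
  list(n_unique = length(centers), map = rep_of)
}

# Small deterministic fixture helpers -------------------------------------

fixture_ball_mask <- function(r_vox = 6, dim3 = 2 * r_vox + 5, spacing = 1) {
  ctr <- (dim3 + 1) / 2
  idx <- expand.grid(i = 1:dim3, j = 1:dim3, k = 1:dim3)
  inside <- (idx$i - ctr)^2 + (idx$j - ctr)^2 + (idx$k - ctr)^2 <= r_vox^2
  seg_mask(array(as.integer(inside), dim = c(dim3, dim3, dim3)),
           spacing = rep(spacing, 3))
}

fixture_unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 face (outward -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 1 face (outward +z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  surface_mesh(v, f)
}

fixture_small_table <- function(n = 32, p = 10, seed = 99, signal = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  y <- rep(c(0L, 1L), length.out = n)
  if (signal) X[, 1] <- X[, 1] + 2.5 * y
  feature_table(sprintf("c%03d", seq_len(n)), X, y)
}
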