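# Small 3D array helpers shared by the phantom generator and the radiomics
# preprocessing: separable Gaussian smoothing and trilinear / nearest
# resampling onto an isotropic grid.

#' Separable 3D Gaussian smoothing
#'
#' Convolves along each axis with a discrete Gaussian kernel truncated at
#' 3 sigma; borders are zero-padded.
#'
#' @param a 3D numeric array.
#' @param sigma Kernel standard deviation in voxels.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(a, sigma = 1) {
  stopifnot(length(dim(a)) == 3L)
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  d <- dim(a)
  conv_first_axis <- function(x) {
    # x: array with the convolution axis first; zero-pad then filter columns
    dd <- dim(x)
    m <- matrix(x, nrow = dd[1])
    padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    fm <- stats::filter(padded, k, sides = 2)
    array(as.numeric(fm[(r + 1):(r + dd[1]), , drop = FALSE]), dim = dd)
  }
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(conv_first_axis(aperm(a, perm)), order(perm))
  }
  a
}

.shift_array <- function(a, dx, dy, dz, fill = NA) {
  # shift contents by (dx,dy,dz): out[i,j,k] = a[i+dx, j+dy, k+dz]
  d <- dim(a)
  out <- array(fill, dim = d)
  lo <- pmax(1, 1 + c(dx, dy, dz)); hi <- pmin(d, d + c(dx, dy, dz))
  if (any(lo > hi)) return(out)
  sx <- lo[1]:hi[1]; sy <- lo[2]:hi[2]; sz <- lo[3]:hi[3]
  out[sx - dx, sy - dy, sz - dz] <- a[sx, sy, sz]
  out
}

.trilinear_sample <- function(a, xi, yi, zi) {
  # sample array a at fractional 1-based voxel coordinates, clamped to grid
  d <- dim(a)
  xi <- pmin(pmax(xi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2])
  zi <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L)
  z0 <- pmin(floor(zi), d[3] - 1L)
  x0 <- pmax(x0, 1); y0 <- pmax(y0, 1); z0 <- pmax(z0, 1)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  lin <- function(i, j, k) a[cbind(i, j, k)]
  v000 <- lin(x0, y0, z0);       v100 <- lin(x0 + 1, y0, z0)
  v010 <- lin(x0, y0 + 1, z0);   v110 <- lin(x0 + 1, y0 + 1, z0)
  v001 <- lin(x0, y0, z0 + 1);   v101 <- lin(x0 + 1, y0, z0 + 1)
  v011 <- lin(x0, y0 + 1, z0 + 1); v111 <- lin(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

.nearest_sample <- function(a, xi, yi, zi) {
  d <- dim(a)
  i <- pmin(pmax(round(xi), 1), d[1])
  j <- pmin(pmax(round(yi), 1), d[2])
  k <- pmin(pmax(round(zi), 1), d[3])
  a[cbind(i, j, k)]
}
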