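#' Radiomics preprocessing: isotropic resampling and intensity rescaling
#'
#' Resamples the image trilinearly (mask by nearest neighbour) onto an
#' isotropic grid of `target_spacing` mm anchored at the original origin,
#' with output size `ceil(extent / target_spacing)` per axis, then min-max
#' rescales the intensities of the whole image to `intensity_range`
#' (default \[0, 100\]). A constant image maps to 0 everywhere.
#'
#' @param volume A [volume_image()].
#' @param mask A [seg_mask()] aligned with `volume`.
#' @param target_spacing Isotropic voxel size in mm (default 0.5).
#' @param intensity_range Length-2 output intensity range.
#' @return A list with resampled, rescaled `volume` and resampled `mask`.
#' @export
preprocess <- function(volume, mask, target_spacing = 0.5,
                       intensity_range = c(0, 100)) {
  stopifnot(inherits(volume, "volume_image"), inherits(mask, "seg_mask"))
  .check_aligned(volume, mask)
  d <- dim(volume$data); sp <- volume$spacing
  if (max(abs(sp - target_spacing)) < 1e-9) {
    vdat <- volume$data
    mdat <- mask$data
    out_sp <- sp
  } else {
    out_dim <- pmax(1L, as.integer(ceiling(d * sp / target_spacing)))
    gx <- (0:(out_dim[1] - 1)) * target_spacing / sp[1] + 1
    gy <- (0:(out_dim[2] - 1)) * target_spacing / sp[2] + 1
    gz <- (0:(out_dim[3] - 1)) * target_spacing / sp[3] + 1
    xi <- rep(gx, times = out_dim[2] * out_dim[3])
    yi <- rep(rep(gy, each = out_dim[1]), times = out_dim[3])
    zi <- rep(gz, each = out_dim[1] * out_dim[2])
    vdat <- array(.trilinear_sample(volume$data, xi, yi, zi), dim = out_dim)
    mdat <- array(as.integer(.nearest_sample(mask$data + 0, xi, yi, zi) >= 0.5),
                  dim = out_dim)
    out_sp <- rep(target_spacing, 3)
  }
  if (sum(mdat) == 0L)
    .anf_stop("anf_roi_error", "mask empty after resampling")
  lo <- min(vdat); hi <- max(vdat)
  if (hi > lo) {
    vdat <- (vdat - lo) / (hi - lo) * diff(intensity_range) + intensity_range[1]
  } else {
    vdat <- array(0, dim = dim(vdat))   # degenerate constant image
  }
  list(volume = volume_image(vdat, out_sp, volume$origin),
       mask = seg_mask(mdat, out_sp, mask$origin))
}

#' Fixed-bin-count discretization of the region of interest
#'
#' Gray level of an in-mask voxel with intensity `x` is
#' `min(floor((x - min) / w) + 1, n_bins)` where `w = (max - min) / n_bins`
#' over the in-mask range. A constant ROI gets a single level.
#'
#' @param volume Preprocessed [volume_image()].
#' @param mask Aligned [seg_mask()] with at least one foreground voxel.
#' @param n_bins Number of gray levels (>= 2).
#' @return An object of class `discretized_roi`: `levels` (3D integer array,
#'   `NA` outside the mask), `n_levels`, `mask`, `spacing`.
#' @export
discretize <- function(volume, mask, n_bins = 32) {
  stopifnot(inherits(volume, "volume_image"), inherits(mask, "seg_mask"))
  .check_aligned(volume, mask)
  if (n_bins < 2) .anf_stop("anf_validation_error", "n_bins must be >= 2")
  sel <- mask$data == 1L
  if (!any(sel)) .anf_stop("anf_roi_error", "empty region of interest")
  x <- volume$data[sel]
  lo <- min(x); hi <- max(x)
  lv <- array(NA_integer_, dim = dim(volume$data))
  if (hi == lo) {
    lv[sel] <- 1L
    ng <- 1L
  } else {
    w <- (hi - lo) / n_bins
    lv[sel] <- pmin(as.integer(floor((x - lo) / w)) + 1L, as.integer(n_bins))
    ng <- as.integer(n_bins)
  }
  structure(list(levels = lv, n_levels = ng, mask = mask,
                 spacing = volume$spacing),
            class = "discretized_roi")
}
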