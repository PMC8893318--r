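#' Extract the 107-feature radiomics battery
#'
#' Runs preprocessing (isotropic 0.5 mm resampling, intensity rescale to
#' \[0, 100\]), fixed-bin-count discretization, and all seven feature
#' families: 18 first-order, 14 3D shape, 24 GLCM, 16 GLRLM, 16 GLSZM,
#' 5 NGTDM and 14 GLDM features — 107 named, finite values.
#'
#' @param volume A raw [volume_image()].
#' @param mask An aligned [seg_mask()].
#' @param n_bins Gray levels for discretization (default 32).
#' @param target_spacing Isotropic resampling target in mm (default 0.5).
#' @return Named numeric vector of 107 features, with a `families` attribute
#'   tagging each value with its family.
#' @export
extract_radiomics <- function(volume, mask, n_bins = 32, target_spacing = 0.5) {
  pre <- preprocess(volume, mask, target_spacing = target_spacing)
  roi <- discretize(pre$volume, pre$mask, n_bins = n_bins)
  fo <- first_order_features(pre$volume, pre$mask, n_bins = n_bins)
  names(fo) <- paste0("firstorder_", names(fo))
  sh <- shape3d_features(pre$mask)
  names(sh) <- paste0("shape_", names(sh))
  tex <- c(texture_features(texture_matrix(roi, "glcm")),
           texture_features(texture_matrix(roi, "glrlm")),
           texture_features(texture_matrix(roi, "glszm")),
           texture_features(texture_matrix(roi, "ngtdm")),
           texture_features(texture_matrix(roi, "gldm")))
  out <- c(fo, sh, tex)
  fam <- c(rep("first_order", length(fo)), rep("shape3d", length(sh)),
           sub("_.*$", "", names(tex)))
  if (length(out) != 107L)
    .anf_stop("anf_validation_error",
              "radiomics battery produced %d features (expected 107)",
              length(out))
  if (any(!is.finite(out)))
    .anf_stop("anf_validation_error", "non-finite radiomics feature(s): %s",
              paste(names(out)[!is.finite(out)], collapse = ", "))
  attr(out, "families") <- fam
  out
}

#' Family composition of the radiomics battery
#'
#' @return Named integer vector of per-family feature counts (sums to 107).
#' @export
radiomics_family_counts <- function() {
  c(first_order = 18L, shape3d = 14L, glcm = 24L, glrlm = 16L,
    glszm = 16L, ngtdm = 5L, gldm = 14L)
}
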