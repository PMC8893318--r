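# Output transforms over a pluggable 2-score deep-feature extractor. The
# trained 3D CNN itself is out of scope; the extractor is a contract
# (volume, mask) -> 2 raw scores, with a deterministic stub for pipeline
# testing. Three variants of the exposed features: the raw scores
# ("no_sigmoid"), their logistic transform ("sigmoid"), and the thresholded
# logistic transform ("binarization", boundary 0.5 mapped to 1).

.check_pair <- function(scores) {
  if (length(scores) != 2L || any(!is.finite(scores)))
    .anf_stop("anf_contract_error",
              "extractor contract violated: need exactly 2 finite scores (got %d)",
              length(scores))
  as.numeric(scores)
}

#' Identity transform of the two raw extractor scores
#' @param scores Numeric length-2 raw scores.
#' @return A `deep_feature_pair`: list with `values` and `variant`.
#' @export
dl_no_sigmoid <- function(scores) {
  structure(list(values = .check_pair(scores), variant = "no_sigmoid"),
            class = "deep_feature_pair")
}

#' Elementwise logistic transform of the two raw scores
#' @inheritParams dl_no_sigmoid
#' @return A `deep_feature_pair` with values in (0, 1).
#' @export
dl_sigmoid <- function(scores) {
  structure(list(values = stats::plogis(.check_pair(scores)),
                 variant = "sigmoid"),
            class = "deep_feature_pair")
}

#' Binarize two probabilities at 0.5 (boundary goes to 1)
#' @param probabilities Numeric length-2 values in \[0, 1\].
#' @return A `deep_feature_pair` with values in \{0, 1\}.
#' @export
dl_binarize <- function(probabilities) {
  p <- .check_pair(probabilities)
  if (any(p < 0 | p > 1))
    .anf_stop("anf_domain_error", "binarization input must lie in [0, 1]")
  structure(list(values = as.numeric(p >= 0.5), variant = "binarization"),
            class = "deep_feature_pair")
}

#' Apply a named deep-feature variant to raw scores
#' @param scores Numeric length-2 raw extractor scores.
#' @param variant One of `"no_sigmoid"`, `"sigmoid"`, `"binarization"`.
#' @return A `deep_feature_pair`.
#' @export
dl_transform <- function(scores, variant = c("sigmoid", "no_sigmoid",
                                             "binarization")) {
  variant <- match.arg(variant)
  switch(variant,
         no_sigmoid = dl_no_sigmoid(scores),
         sigmoid = dl_sigmoid(scores),
         binarization = dl_binarize(dl_sigmoid(scores)$values))
}

#' Deterministic stub extractor
#'
#' Stands in for a trained image network. NOT a learned model: returns two
#' scores built from cheap summary statistics — the scaled mean in-mask
#' intensity and a log-volume score — plus small seeded Gaussian noise so
#' distinct cases get distinct scores deterministically.
#'
#' @param volume A [volume_image()].
#' @param mask An aligned [seg_mask()].
#' @param seed Integer seed for the additive noise.
#' @return Numeric length-2 raw scores.
#' @export
stub_extractor <- function(volume, mask, seed = 0L) {
  stopifnot(inherits(volume, "volume_image"), inherits(mask, "seg_mask"))
  .check_aligned(volume, mask)
  sel <- mask$data == 1L
  if (!any(sel)) .anf_stop("anf_roi_error", "empty region of interest")
  mu <- mean(volume$data[sel])
  vol_mm3 <- sum(sel) * prod(mask$spacing)
  .with_seed(seed, {
    c((mu - mean(volume$data)) / (stats::sd(as.vector(volume$data)) + 1e-12) +
        stats::rnorm(1, 0, 0.1),
      (log(vol_mm3) - log(250)) + stats::rnorm(1, 0, 0.1))
  })
}

#' Resolve an extractor from a configuration key
#'
#' `"stub"` gives [stub_extractor()]; `"external:<command>"` wraps a shell
#' command that receives the volume and mask paths as arguments and prints
#' two numbers.
#'
#' @param key Configuration string.
#' @return A function `(volume, mask, seed) -> 2 raw scores`.
#' @export
resolve_extractor <- function(key = "stub") {
  if (identical(key, "stub")) return(stub_extractor)
  if (startsWith(key, "external:")) {
    cmd <- sub("^external:", "", key)
    return(function(volume, mask, seed = 0L) {
      vf <- tempfile(fileext = ".nii.gz"); mf <- tempfile(fileext = ".nii.gz")
      on.exit(unlink(c(vf, mf)))
      write_volume(volume, vf); write_volume(mask, mf)
      out <- system(paste(cmd, shQuote(vf), shQuote(mf)), intern = TRUE)
      .check_pair(as.numeric(strsplit(paste(out, collapse = " "),
                                      "\\s+")[[1]][1:2]))
    })
  }
  .anf_stop("anf_parameter_error", "unknown extractor key '%s'", key)
}
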