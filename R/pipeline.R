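# End-to-end convenience layer: extract all four feature groups for a case
# and assemble the fused 136-column table for a whole cohort, either from
# in-memory phantom cases or from a manifest on disk.

#' Extract all feature groups for one case
#'
#' Morphological features from the surface mesh, radiomics from the
#' volume/mask pair, and the two deep features from a pluggable extractor
#' (see [resolve_extractor()]) run through the chosen output transform.
#'
#' @param volume A [volume_image()].
#' @param mask An aligned [seg_mask()].
#' @param mesh A watertight [surface_mesh()].
#' @param extractor Extractor key or function (default `"stub"`).
#' @param dl_variant Deep-feature transform: `"sigmoid"`, `"no_sigmoid"` or
#'   `"binarization"`.
#' @param n_bins Discretization bin count for texture features.
#' @param target_spacing Isotropic resampling spacing in mm.
#' @param seed Integer seed forwarded to the extractor.
#' @return Named list with numeric vectors `morph` (25), `radiomics` (107),
#'   `deep` (2).
#' @export
extract_case_features <- function(volume, mask, mesh, extractor = "stub",
                                  dl_variant = "sigmoid", n_bins = 32L,
                                  target_spacing = 0.5, seed = 0L) {
  if (is.character(extractor)) extractor <- resolve_extractor(extractor)
  morph <- morphological_features(mesh)
  rad <- extract_radiomics(volume, mask, n_bins = n_bins,
                           target_spacing = target_spacing)
  raw <- extractor(volume, mask, seed)
  dl <- dl_transform(raw, dl_variant)$values
  names(dl) <- c("score1", "score2")
  list(morph = morph, radiomics = rad, deep = dl)
}

#' Build the fused feature table for an in-memory phantom cohort
#'
#' @param cohort A cohort as returned by [generate_cohort()].
#' @param ... Passed to [extract_case_features()].
#' @param progress Print one line per case (default FALSE).
#' @return A labelled 136-column [feature_table()].
#' @export
cohort_feature_table <- function(cohort, ..., progress = FALSE) {
  cases <- cohort$cases
  n <- length(cases)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- cases[[i]]
    rows[[i]] <- extract_case_features(cs$volume, cs$mask, cs$mesh,
                                       seed = i, ...)
    if (progress)
      message(sprintf("[%d/%d] %s", i, n, cs$clinical$case_id))
  }
  ids <- vapply(cases, function(cs) cs$clinical$case_id, "")
  stack <- function(part) {
    m <- do.call(rbind, lapply(rows, `[[`, part))
    rownames(m) <- ids
    m
  }
  clinical <- data.frame(
    case_id = ids,
    sex = vapply(cases, function(cs) cs$clinical$sex, ""),
    age = vapply(cases, function(cs) cs$clinical$age, 0),
    ruptured = vapply(cases, function(cs) as.integer(cs$clinical$ruptured),
                      0L),
    stringsAsFactors = FALSE)
  fuse_features(stack("morph"), stack("radiomics"), stack("deep"), clinical)
}

#' Build the fused feature table from a cohort manifest on disk
#'
#' Reads each case's volume, mask and mesh as referenced by the manifest
#' (see [read_cohort()]) and extracts all feature groups.
#'
#' @param manifest Path to a manifest CSV.
#' @param ... Passed to [extract_case_features()].
#' @param progress Print one line per case (default FALSE).
#' @return A labelled 136-column [feature_table()].
#' @export
manifest_feature_table <- function(manifest, ..., progress = FALSE) {
  entries <- read_cohort(manifest)
  n <- length(entries)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    e <- entries[[i]]
    volume <- read_volume(e$volume)
    mask <- read_mask(e$mask)
    mesh <- read_mesh_stl(e$mesh)
    rows[[i]] <- extract_case_features(volume, mask, mesh, seed = i, ...)
    if (progress) message(sprintf("[%d/%d] %s", i, n, e$case_id))
  }
  ids <- vapply(entries, `[[`, "", "case_id")
  stack <- function(part) {
    m <- do.call(rbind, lapply(rows, `[[`, part))
    rownames(m) <- ids
    m
  }
  clinical <- data.frame(
    case_id = ids,
    sex = vapply(entries, function(e) e$clinical$sex, ""),
    age = vapply(entries, function(e) e$clinical$age, 0),
    ruptured = vapply(entries, function(e) as.integer(e$clinical$ruptured),
                      0L),
    stringsAsFactors = FALSE)
  fuse_features(stack("morph"), stack("radiomics"), stack("deep"), clinical)
}
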