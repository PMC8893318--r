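#' Construct a 3D scalar volume with physical geometry
#'
#' A `volume_image` is the radiomics substrate: a 3D intensity array plus the
#' voxel spacing (mm) and world origin (mm). Voxel indices are 0-based; the
#' world position of index `(i, j, k)` is `origin + c(i, j, k) * spacing`.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin Numeric length-3, world position (mm) of voxel (0, 0, 0).
#' @return An object of class `volume_image` with fields `data`, `spacing`,
#'   `origin`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    .anf_stop("anf_format_error", "volume data must be a 3D array (got %s dims)",
              length(dim(data)))
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    .anf_stop("anf_validation_error", "spacing must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    .anf_stop("anf_validation_error", "origin must be 3 finite values")
  if (any(!is.finite(data)))
    .anf_stop("anf_validation_error", "volume contains non-finite intensities")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' Construct a binary segmentation mask aligned to a volume
#'
#' @param data 3D array over \{0, 1\} (logical or numeric).
#' @param spacing,origin As in [volume_image()].
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    .anf_stop("anf_format_error", "mask data must be a 3D array")
  storage.mode(data) <- "integer"
  if (any(!data %in% c(0L, 1L)))
    .anf_stop("anf_validation_error", "mask values must be 0 or 1")
  v <- volume_image(data + 0, spacing, origin)  # reuse geometry validation
  structure(list(data = data, spacing = v$spacing, origin = v$origin),
            class = "seg_mask")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels, %d foreground, spacing (%s) mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

.check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data)))
    .anf_stop("anf_validation_error",
              "volume (%s) and mask (%s) dimensions differ",
              paste(dim(volume$data), collapse = "x"),
              paste(dim(mask$data), collapse = "x"))
  invisible(TRUE)
}

# ---- NIfTI ----------------------------------------------------------------

.read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    .anf_stop("anf_format_error", "cannot read NIfTI file '%s': %s",
              path, conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    .anf_stop("anf_format_error", "'%s' is %dD; a 3D volume is required",
              path, length(dim(arr)))
  arr <- array(as.numeric(arr), dim = dim(arr))   # drop RNifti attributes
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else abs(xf[1:3, 4])
  volume_image(arr, sp, org)
}

.write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- MetaImage (.mhd/.mha) ------------------------------------------------
# Minimal MetaImage support: uncompressed raw payload, local or embedded.

.mhd_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                MET_SHORT = "integer", MET_USHORT = "integer",
                MET_INT = "integer", MET_UINT = "integer",
                MET_FLOAT = "double", MET_DOUBLE = "double")
.mhd_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
                MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

.read_mhd_volume <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- list(); data_offset <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      .anf_stop("anf_format_error", "'%s': header ended before ElementDataFile", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L)
      .anf_stop("anf_format_error", "'%s': malformed header line '%s'", path, line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") { data_offset <- seek(con); break }
  }
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    .anf_stop("anf_format_error", "'%s': compressed MetaImage not supported", path)
  ndims <- as.integer(hdr$NDims %||% "0")
  if (ndims != 3L)
    .anf_stop("anf_format_error", "'%s' is %dD; a 3D volume is required", path, ndims)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% hdr$ElementSize %||% "1 1 1",
                            "\\s+")[[1]])
  org <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% "0 0 0", "\\s+")[[1]])
  type <- hdr$ElementType %||% "MET_FLOAT"
  if (!type %in% names(.mhd_types))
    .anf_stop("anf_format_error", "'%s': unsupported ElementType %s", path, type)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, .mhd_types[[type]], n = n, size = .mhd_sizes[[type]],
                   endian = "little")
  } else {
    close(con); on.exit()
    dfile <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(dfile))
      .anf_stop("anf_format_error", "'%s': data file '%s' not found", path, dfile)
    dcon <- file(dfile, "rb"); on.exit(close(dcon))
    raw <- readBin(dcon, .mhd_types[[type]], n = n, size = .mhd_sizes[[type]],
                   endian = "little")
  }
  if (length(raw) < n)
    .anf_stop("anf_format_error", "'%s': truncated payload (%d of %d values)",
              path, length(raw), n)
  volume_image(array(as.numeric(raw), dim = dims), sp, org)
}

.write_mhd_volume <- function(vol, path) {
  stopifnot(grepl("\\.mhd$|\\.mha$", path, ignore.case = TRUE))
  embedded <- grepl("\\.mha$", path, ignore.case = TRUE)
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c(
    "ObjectType = Image", "NDims = 3", "BinaryData = True",
    "BinaryDataByteOrderMSB = False", "CompressedData = False",
    sprintf("DimSize = %s", paste(dim(vol$data), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(vol$spacing, digits = 17),
                                         collapse = " ")),
    sprintf("Offset = %s", paste(format(vol$origin, digits = 17), collapse = " ")),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", if (embedded) "LOCAL" else raw_name))
  con <- file(path, "wb"); on.exit(close(con))
  writLines <- paste0(paste(hdr, collapse = "\n"), "\n")
  writeBin(charToRaw(writLines), con)
  if (embedded) {
    writeBin(as.vector(vol$data, "double"), con, size = 8, endian = "little")
  } else {
    close(con); on.exit()
    dcon <- file(file.path(dirname(path), raw_name), "wb"); on.exit(close(dcon))
    writeBin(as.vector(vol$data, "double"), dcon, size = 8, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- public entry points --------------------------------------------------

#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supports `.nii`, `.nii.gz` (via RNifti) and uncompressed `.mhd`/`.mha`.
#' Spacing is taken from the header; the file must be 3-dimensional.
#'
#' @param path Path to the image file.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    .anf_stop("anf_format_error", "file '%s' does not exist", path)
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) .read_nifti_volume(path)
  else if (grepl("\\.mhd$|\\.mha$", low)) .read_mhd_volume(path)
  else .anf_stop("anf_format_error",
                 "'%s': unrecognised volume format (need .nii[.gz]/.mhd/.mha)", path)
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' @param vol A [volume_image()] or [seg_mask()].
#' @param path Output path ending in `.nii`, `.nii.gz`, `.mhd` or `.mha`.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image") || inherits(vol, "seg_mask"))
  v <- volume_image(vol$data + 0, vol$spacing, vol$origin)
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) .write_nifti_volume(v, path)
  else if (grepl("\\.mhd$|\\.mha$", low)) .write_mhd_volume(v, path)
  else .anf_stop("anf_format_error", "'%s': unrecognised output format", path)
}

#' Read a binary segmentation mask
#'
#' Reads a volume file and validates that it is binary (values 0/1 after
#' rounding intensities within 1e-6 of an integer).
#'
#' @inheritParams read_volume
#' @return A [seg_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  d <- round(v$data)
  if (max(abs(v$data - d)) > 1e-6 || !all(d %in% c(0, 1)))
    .anf_stop("anf_validation_error", "'%s' is not a binary mask", path)
  seg_mask(array(as.integer(d), dim = dim(d)), v$spacing, v$origin)
}
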