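# Synthetic phantom cohorts: a randomly oriented ellipsoidal lesion perturbed
# by a degree-2 real spherical-harmonic lobulation, rendered as (a) a binary
# mask on the voxel grid, (b) a noisy smoothed intensity volume, and (c) a
# watertight surface mesh (radially deformed icosphere). Labels carry a
# planted morphology signal: the log-odds of rupture are linear in the
# standardized maximum radius and lobulation amplitude.

#' Parameters of the phantom cohort generator
#'
#' Defaults emulate a small-vessel aneurysm cohort on a 48^3 grid at 0.5 mm:
#' lesion semi-axes 2.5-7 mm, lobulation amplitude up to 0.3 (dimensionless
#' fraction of the local radius), bright lesion (100) on dark background (10)
#' with additive Gaussian noise (sd 5), balanced prevalence, and a strong
#' morphology signal (log-odds coefficients 3 on standardized maximum radius
#' and 2 on standardized lobulation amplitude).
#'
#' @param grid_shape Integer length-3 voxel grid.
#' @param spacing Isotropic voxel size in mm.
#' @param lesion_radii Length-2 range (mm) the three semi-axes are drawn from.
#' @param lobulation_amplitude Maximum lobulation amplitude in \[0, 1).
#' @param intensity_fg,intensity_bg Foreground / background intensity.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param signal_coefficients Length-2 log-odds weights on (standardized max
#'   radius, standardized lobulation amplitude).
#' @param prevalence_target Target fraction of ruptured cases in (0, 1).
#' @param seed Cohort-level seed.
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(48L, 48L, 48L), spacing = 0.5,
                           lesion_radii = c(2.5, 7),
                           lobulation_amplitude = 0.3,
                           intensity_fg = 100, intensity_bg = 10,
                           noise_sd = 5,
                           signal_coefficients = c(size = 3, lobulation = 2),
                           prevalence_target = 0.5, seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    .anf_stop("anf_parameter_error", "grid_shape must be 3 integers >= 4")
  if (spacing <= 0) .anf_stop("anf_parameter_error", "spacing must be > 0")
  if (length(lesion_radii) != 2L || any(lesion_radii <= 0) ||
      lesion_radii[1] > lesion_radii[2])
    .anf_stop("anf_parameter_error", "lesion_radii must be an increasing positive range")
  if (lobulation_amplitude < 0 || lobulation_amplitude >= 1)
    .anf_stop("anf_parameter_error", "lobulation_amplitude must be in [0, 1)")
  if (noise_sd < 0) .anf_stop("anf_parameter_error", "noise_sd must be >= 0")
  if (prevalence_target <= 0 || prevalence_target >= 1)
    .anf_stop("anf_parameter_error", "prevalence_target must be in (0, 1)")
  max_extent <- 2 * lesion_radii[2] * (1 + lobulation_amplitude)
  if (max_extent >= min(grid_shape) * spacing - 4 * spacing)
    .anf_stop("anf_parameter_error",
              "lesion (max extent %.1f mm) does not fit inside the grid",
              max_extent)
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 lesion_radii = lesion_radii,
                 lobulation_amplitude = lobulation_amplitude,
                 intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                 noise_sd = noise_sd,
                 signal_coefficients = as.numeric(signal_coefficients),
                 prevalence_target = prevalence_target,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# degree-2 real spherical-harmonic combination, normalized to max |S| = 1
.sh2_fun <- function(coef) {
  basis <- function(u) {
    x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
    cbind(x * y, y * z, z * x, x^2 - y^2, 3 * z^2 - 1)
  }
  ref <- icosphere(2, radius = 1)$vertices
  ref <- ref / sqrt(rowSums(ref^2))
  s_ref <- basis(ref) %*% coef
  scale <- max(abs(s_ref))
  if (scale == 0) scale <- 1
  function(u) as.vector(basis(u) %*% coef) / scale
}

.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a single phantom case
#'
#' @param params A [phantom_params()].
#' @param case_seed Integer seed; the whole case is a pure function of
#'   `(params, case_seed)`.
#' @param case_id Case identifier string.
#' @return A list with `volume` ([volume_image()]), `mask` ([seg_mask()]),
#'   `mesh` (watertight [surface_mesh()]), `clinical` ([clinical_record()],
#'   label unset) and `signal` (named vector: max radius mm, lobulation
#'   amplitude).
#' @export
generate_case <- function(params, case_seed, case_id = sprintf("case_%06d", case_seed)) {
  stopifnot(inherits(params, "phantom_params"))
  .with_seed(case_seed, {
    gs <- params$grid_shape; sp <- params$spacing
    radii <- stats::runif(3, params$lesion_radii[1], params$lesion_radii[2])
    amp <- stats::runif(1, 0, params$lobulation_amplitude)
    rot <- .random_rotation()
    shc <- stats::rnorm(5)
    S <- .sh2_fun(shc)
    center <- (gs - 1) / 2 * sp + stats::runif(3, -sp, sp)
    # implicit surface: |x - c| = rho_ellipsoid(u) * (1 + amp * S(u)),
    # directions taken in the lesion (body) frame
    radius_at <- function(u_world) {
      ub <- u_world %*% rot                      # world -> body
      q <- sqrt((ub[, 1] / radii[1])^2 + (ub[, 2] / radii[2])^2 +
                  (ub[, 3] / radii[3])^2)
      (1 / q) * (1 + amp * S(ub))
    }
    # mask
    ax <- (0:(gs[1] - 1)) * sp - center[1]
    ay <- (0:(gs[2] - 1)) * sp - center[2]
    az <- (0:(gs[3] - 1)) * sp - center[3]
    rmax <- max(radii) * (1 + amp)
    xw <- rep(ax, times = gs[2] * gs[3])
    yw <- rep(rep(ay, each = gs[1]), times = gs[3])
    zw <- rep(az, each = gs[1] * gs[2])
    r <- sqrt(xw^2 + yw^2 + zw^2)
    cand <- which(r <= rmax & r > 0)
    inside <- logical(prod(gs))
    inside[r == 0] <- TRUE
    if (length(cand)) {
      u <- cbind(xw[cand], yw[cand], zw[cand]) / r[cand]
      inside[cand] <- r[cand] <= radius_at(u)
    }
    mask <- seg_mask(array(as.integer(inside), dim = gs),
                     spacing = rep(sp, 3))
    # intensity volume: binary render, smoothed, plus noise
    clean <- array(ifelse(inside, params$intensity_fg, params$intensity_bg),
                   dim = gs)
    vol <- gaussian_smooth_3d(clean, sigma = 1)
    if (params$noise_sd > 0)
      vol <- vol + array(stats::rnorm(prod(gs), 0, params$noise_sd), dim = gs)
    volume <- volume_image(vol, spacing = rep(sp, 3))
    # mesh: radially deformed icosphere (star-shaped, hence watertight)
    ico <- icosphere(3, radius = 1)
    udir <- ico$vertices / sqrt(rowSums(ico$vertices^2))
    verts <- udir * radius_at(udir) + matrix(center, nrow(udir), 3, byrow = TRUE)
    mesh <- surface_mesh(verts, ico$faces)
    clinical <- clinical_record(
      case_id,
      sex = if (stats::runif(1) < 0.5) "female" else "male",
      age = stats::runif(1, 30, 80))
    list(volume = volume, mask = mask, mesh = mesh, clinical = clinical,
         signal = c(size = max(radii), lobulation = amp))
  })
}

.case_seed <- function(cohort_seed, index) {
  as.integer((as.numeric(cohort_seed) * 1000003 + index * 7919) %% 2147483629)
}

#' Generate a phantom cohort with a planted morphology signal
#'
#' Labels are Bernoulli with log-odds linear in the cohort-standardized
#' maximum radius and lobulation amplitude plus an intercept tuned by
#' bisection so the empirical prevalence is within 0.05 of the target.
#'
#' @param n Number of cases (>= 16 so stratified 8-fold CV is possible).
#' @param params A [phantom_params()].
#' @param out_dir If non-NULL, volumes (NIfTI), masks, meshes (binary STL)
#'   and a `manifest.csv` consumable by [read_cohort()] are written there.
#' @return A list with `cases` (per-case lists as in [generate_case()], with
#'   the label filled into `clinical$ruptured`), `labels`, `signal` (n x 2
#'   matrix), `manifest` (data.frame; paths filled when `out_dir` is given).
#' @export
generate_cohort <- function(n, params, out_dir = NULL) {
  stopifnot(inherits(params, "phantom_params"))
  if (n < 16L)
    .anf_stop("anf_parameter_error",
              "n = %d too small: need >= 16 for stratified 8-fold CV", n)
  ids <- sprintf("case_%03d", seq_len(n))
  cases <- lapply(seq_len(n), function(i)
    generate_case(params, .case_seed(params$seed, i), case_id = ids[i]))
  sig <- t(vapply(cases, `[[`, numeric(2), "signal"))
  z <- scale(sig)
  z[is.nan(z)] <- 0
  eta0 <- as.vector(z %*% params$signal_coefficients)
  u <- .with_seed(.case_seed(params$seed, 0L), stats::runif(n))
  draw <- function(b0) as.integer(u < stats::plogis(eta0 + b0))
  target <- params$prevalence_target
  lo <- -20; hi <- 20
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    prev <- mean(draw(mid))
    if (abs(prev - target) <= 0.05) break
    if (prev < target) lo <- mid else hi <- mid
  }
  labels <- draw(mid)
  for (i in seq_len(n)) cases[[i]]$clinical$ruptured <- labels[i]
  manifest <- data.frame(
    case_id = ids,
    volume = paste0(ids, ".nii.gz"), mask = paste0(ids, "_mask.nii.gz"),
    mesh = paste0(ids, ".stl"),
    sex = vapply(cases, function(cs) cs$clinical$sex, ""),
    age = vapply(cases, function(cs) cs$clinical$age, 0),
    ruptured = labels, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_volume(cases[[i]]$volume, file.path(out_dir, manifest$volume[i]))
      write_volume(cases[[i]]$mask, file.path(out_dir, manifest$mask[i]))
      write_mesh_stl(cases[[i]]$mesh, file.path(out_dir, manifest$mesh[i]))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(cases = cases, labels = labels, signal = sig, manifest = manifest,
       intercept = mid)
}
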