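# Texture features per family, computed from the matrices built by
# texture_matrix(). Formulas follow the standard IBSI definitions. Every
# feature with a vanishing denominator has a documented degenerate value
# (see the per-family notes below); outputs are always finite.

#' Compute the texture features of one matrix family
#'
#' Feature counts per family: GLCM 24, GLRLM 16, GLSZM 16, NGTDM 5, GLDM 14.
#'
#' Degenerate rules (constant ROI / single gray level): GLCM correlation and
#' MCC are 1, IMC1/IMC2 are 0, inverse variance is 0; NGTDM contrast,
#' busyness and complexity are 0 and coarseness is capped at 1e6; variances
#' and entropies of one-entry distributions are 0.
#'
#' @param tm A `texture_matrix` from [texture_matrix()].
#' @return Named numeric vector (names prefixed with the family).
#' @export
texture_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix"))
  out <- switch(tm$family,
                glcm = .feat_glcm(tm),
                glrlm = .feat_run(tm, "glrlm"),
                glszm = .feat_zone(tm),
                ngtdm = .feat_ngtdm(tm),
                gldm = .feat_gldm(tm))
  stopifnot(all(is.finite(out)))
  out
}

.entropy2 <- function(p) { p <- p[p > 0]; if (!length(p)) 0 else -sum(p * log2(p)) }

.feat_glcm <- function(tm) {
  cnt <- tm$matrix
  ng <- nrow(cnt)
  tot <- sum(cnt)
  p <- if (tot > 0) cnt / tot else cnt
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)          # equal by symmetry
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal and cross-diagonal distributions
  k_sum <- 2:(2 * ng); k_diff <- 0:(ng - 1)
  pxy_sum <- vapply(k_sum, function(k) sum(p[i + j == k]), numeric(1))
  pxy_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  da <- sum(k_diff * pxy_diff)
  hx <- .entropy2(px); hy <- .entropy2(py)
  hxy <- .entropy2(as.vector(p))
  pp <- outer(px, py)
  nz <- p > 0
  hxy1 <- -sum(p[nz & pp > 0] * log2(pp[nz & pp > 0]))
  hxy2 <- .entropy2(as.vector(pp))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- { d <- hxy2 - hxy; if (d <= 0) 0 else sqrt(1 - exp(-2 * d)) }
  corr <- if (sx > 0 && sy > 0)
    (sum(i * j * p) - mux * muy) / (sx * sy) else 1
  # maximal correlation coefficient via the Q matrix
  mcc <- if (ng > 1 && all(px > 0)) {
    Q <- matrix(0, ng, ng)
    for (a in seq_len(ng)) for (b in seq_len(ng))
      Q[a, b] <- sum(p[a, ] * p[b, ] / (px[a] * py))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2) sqrt(max(ev[2], 0)) else 1
  } else 1
  c(glcm_autocorrelation = sum(i * j * p),
    glcm_joint_average = mux,
    glcm_cluster_prominence = sum((i + j - mux - muy)^4 * p),
    glcm_cluster_shade = sum((i + j - mux - muy)^3 * p),
    glcm_cluster_tendency = sum((i + j - mux - muy)^2 * p),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_correlation = corr,
    glcm_difference_average = da,
    glcm_difference_entropy = .entropy2(pxy_diff),
    glcm_difference_variance = sum((k_diff - da)^2 * pxy_diff),
    glcm_joint_energy = sum(p^2),
    glcm_joint_entropy = hxy,
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_idm = sum(p / (1 + (i - j)^2)),
    glcm_idmn = sum(p / (1 + ((i - j) / ng)^2)),
    glcm_id = sum(p / (1 + abs(i - j))),
    glcm_idn = sum(p / (1 + abs(i - j) / ng)),
    glcm_inverse_variance = sum(p[i != j] / (i[i != j] - j[i != j])^2),
    glcm_maximum_probability = max(p),
    glcm_sum_average = sum(k_sum * pxy_sum),
    glcm_sum_entropy = .entropy2(pxy_sum),
    glcm_sum_squares = sum((i - mux)^2 * p),
    glcm_mcc = mcc)
}

.feat_run <- function(tm, prefix) {
  P <- tm$matrix
  ng <- nrow(P); nl <- ncol(P)
  i <- row(P); j <- col(P)
  nr <- sum(P)
  if (nr == 0) nr <- 1
  np_tot <- sum(j * P)                        # voxels x directions
  p <- P / sum(P)
  mui <- sum(i * p); muj <- sum(j * p)
  vals <- c(
    short_run_emphasis = sum(P / j^2) / nr,
    long_run_emphasis = sum(P * j^2) / nr,
    gray_level_non_uniformity = sum(rowSums(P)^2) / nr,
    gray_level_non_uniformity_normalized = sum(rowSums(P)^2) / nr^2,
    run_length_non_uniformity = sum(colSums(P)^2) / nr,
    run_length_non_uniformity_normalized = sum(colSums(P)^2) / nr^2,
    run_percentage = if (np_tot > 0) nr / np_tot else 0,
    gray_level_variance = sum(p * (i - mui)^2),
    run_variance = sum(p * (j - muj)^2),
    run_entropy = .entropy2(as.vector(p)),
    low_gray_level_run_emphasis = sum(P / i^2) / nr,
    high_gray_level_run_emphasis = sum(P * i^2) / nr,
    short_run_low_gray_level_emphasis = sum(P / (i^2 * j^2)) / nr,
    short_run_high_gray_level_emphasis = sum(P * i^2 / j^2) / nr,
    long_run_low_gray_level_emphasis = sum(P * j^2 / i^2) / nr,
    long_run_high_gray_level_emphasis = sum(P * i^2 * j^2) / nr)
  names(vals) <- paste0(prefix, "_", names(vals))
  vals
}

.feat_zone <- function(tm) {
  P <- tm$matrix
  i <- row(P); j <- col(P)
  nz <- sum(P)
  if (nz == 0) nz <- 1
  nvox <- tm$n_voxels
  p <- P / sum(P)
  mui <- sum(i * p); muj <- sum(j * p)
  c(glszm_small_area_emphasis = sum(P / j^2) / nz,
    glszm_large_area_emphasis = sum(P * j^2) / nz,
    glszm_gray_level_non_uniformity = sum(rowSums(P)^2) / nz,
    glszm_gray_level_non_uniformity_normalized = sum(rowSums(P)^2) / nz^2,
    glszm_size_zone_non_uniformity = sum(colSums(P)^2) / nz,
    glszm_size_zone_non_uniformity_normalized = sum(colSums(P)^2) / nz^2,
    glszm_zone_percentage = nz / nvox,
    glszm_gray_level_variance = sum(p * (i - mui)^2),
    glszm_zone_variance = sum(p * (j - muj)^2),
    glszm_zone_entropy = .entropy2(as.vector(p)),
    glszm_low_gray_level_zone_emphasis = sum(P / i^2) / nz,
    glszm_high_gray_level_zone_emphasis = sum(P * i^2) / nz,
    glszm_small_area_low_gray_level_emphasis = sum(P / (i^2 * j^2)) / nz,
    glszm_small_area_high_gray_level_emphasis = sum(P * i^2 / j^2) / nz,
    glszm_large_area_low_gray_level_emphasis = sum(P * j^2 / i^2) / nz,
    glszm_large_area_high_gray_level_emphasis = sum(P * i^2 * j^2) / nz)
}

.feat_ngtdm <- function(tm) {
  M <- tm$matrix
  n_i <- M[, "n"]; s_i <- M[, "s"]
  N <- sum(n_i)
  present <- which(n_i > 0)
  p_i <- n_i / N
  ngp <- length(present)
  lev <- seq_len(nrow(M))
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6
  if (ngp > 1) {
    pi_p <- p_i[present]; li <- lev[present]; si <- s_i[present]
    dif2 <- outer(li, li, function(a, b) (a - b)^2)
    contrast <- (sum(outer(pi_p, pi_p) * dif2) / (ngp * (ngp - 1))) *
      (sum(s_i) / N)
    ipd <- abs(outer(li * pi_p, li * pi_p, "-"))
    bus_den <- sum(ipd)
    busyness <- if (bus_den > 0) sum(pi_p * si) / bus_den else 0
    psum <- outer(pi_p, pi_p, "+")
    pss <- outer(pi_p * si, pi_p * si, "+")
    complexity <- sum(abs(outer(li, li, "-")) * pss / psum) / N
    s_tot <- sum(si)
    strength <- if (s_tot > 0) sum(psum * dif2) / s_tot else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

.feat_gldm <- function(tm) {
  P <- tm$matrix
  i <- row(P); j <- col(P)
  nz <- sum(P)
  if (nz == 0) nz <- 1
  p <- P / sum(P)
  mui <- sum(i * p); muj <- sum(j * p)
  c(gldm_small_dependence_emphasis = sum(P / j^2) / nz,
    gldm_large_dependence_emphasis = sum(P * j^2) / nz,
    gldm_gray_level_non_uniformity = sum(rowSums(P)^2) / nz,
    gldm_dependence_non_uniformity = sum(colSums(P)^2) / nz,
    gldm_dependence_non_uniformity_normalized = sum(colSums(P)^2) / nz^2,
    gldm_gray_level_variance = sum(p * (i - mui)^2),
    gldm_dependence_variance = sum(p * (j - muj)^2),
    gldm_dependence_entropy = .entropy2(as.vector(p)),
    gldm_low_gray_level_emphasis = sum(P / i^2) / nz,
    gldm_high_gray_level_emphasis = sum(P * i^2) / nz,
    gldm_small_dependence_low_gray_level_emphasis = sum(P / (i^2 * j^2)) / nz,
    gldm_small_dependence_high_gray_level_emphasis = sum(P * i^2 / j^2) / nz,
    gldm_large_dependence_low_gray_level_emphasis = sum(P * j^2 / i^2) / nz,
    gldm_large_dependence_high_gray_level_emphasis = sum(P * i^2 * j^2) / nz)
}
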