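# Offline rotation expansion and online stochastic augmentation.
#
# Offline: each VOI is rotated ten times in the slice plane, angles drawn
# uniformly from (-90, +90) degrees, expanding the training pool tenfold.
# Online (training batches only): contrast/brightness jitter, additive
# Gaussian noise, in-plane flipping and small integer voxel translations
# whose per-modality limits all correspond to +-6 mm at the native spacings.

#' Augmentation configuration
#'
#' Defaults follow the stated augmentation protocol: ten offline rotations
#' in (-90, +90) degrees; online contrast factor ~ N(1, 0.75^2), brightness
#' shift ~ N(0, 0.1^2), voxelwise noise ~ N(0, 0.01^2); translation limits
#' of +-12 in-plane voxels for T2W, +-4 for K-Trans (DCE), +-3 for DWI/ADC
#' and +-2 slices for all, i.e. +-6 mm per axis at the native spacings.
#'
#' @param n_offline_rotations offline replicates per VOI
#' @param rotation_range_deg length-2 numeric, uniform angle range (degrees)
#' @param contrast_sigma,brightness_sigma,noise_sigma standard deviations of
#'   the online intensity perturbations
#' @param flip_probability probability of a left-right in-plane flip
#' @param translation_limits named list, modality group -> c(in-plane, slice)
#'   maximum absolute voxel translation
#' @return object of class `augment_config`
#' @export
augment_config <- function(n_offline_rotations = 10L,
                           rotation_range_deg = c(-90, 90),
                           contrast_sigma = 0.75,
                           brightness_sigma = 0.1,
                           noise_sigma = 0.01,
                           flip_probability = 0.5,
                           translation_limits = list(T2W = c(12L, 2L),
                                                     KTRANS = c(4L, 2L),
                                                     DWI = c(3L, 2L),
                                                     ADC = c(3L, 2L))) {
  stopifnot(n_offline_rotations >= 1L,
            length(rotation_range_deg) == 2L,
            rotation_range_deg[1] >= -90, rotation_range_deg[2] <= 90,
            rotation_range_deg[1] <= rotation_range_deg[2],
            contrast_sigma >= 0, brightness_sigma >= 0, noise_sigma >= 0,
            flip_probability >= 0, flip_probability <= 1,
            all(unlist(translation_limits) >= 0))
  structure(list(n_offline_rotations = as.integer(n_offline_rotations),
                 rotation_range_deg = rotation_range_deg,
                 contrast_sigma = contrast_sigma,
                 brightness_sigma = brightness_sigma,
                 noise_sigma = noise_sigma,
                 flip_probability = flip_probability,
                 translation_limits = translation_limits),
            class = "augment_config")
}

# modality tag -> translation-limit group
.limit_group <- function(modality) {
  if (startsWith(modality, "T2W")) "T2W" else modality
}

#' Translation limit in millimetres
#'
#' Converts a modality's voxel translation limits to a physical bound using
#' the voxel spacing; at the native mpMRI spacings every modality's bound is
#' 6 mm on each axis.
#'
#' @param modality modality tag (see [MODALITIES]) or group name
#' @param config an [augment_config()]
#' @param spacing_mm numeric 3-vector of voxel spacings
#' @return numeric 3-vector of per-axis mm bounds
#' @export
#' @examples
#' translation_limit_mm("T2W_tra", spacing_mm = c(0.5, 0.5, 3))  # 6 6 6
translation_limit_mm <- function(modality, config = augment_config(),
                                 spacing_mm) {
  grp <- .limit_group(modality)
  lim <- config$translation_limits[[grp]]
  if (is.null(lim))
    stop("no translation limit configured for modality ", modality)
  c(lim[1] * spacing_mm[1], lim[1] * spacing_mm[2], lim[2] * spacing_mm[3])
}

## ---- in-plane rotation -----------------------------------------------------

#' Rotate a VOI grid in the slice plane
#'
#' Bilinear resampling within each slice about the grid centre; slices are
#' independent (3D rotation is ill-posed at 3 mm slice spacing).  Coordinates
#' falling outside the grid are clamped to the nearest edge voxel.
#'
#' @param grid 3D numeric array
#' @param angle_deg rotation angle in degrees
#' @return rotated array of identical shape
#' @export
rotate_inplane <- function(grid, angle_deg) {
  d <- dim(grid)
  if (angle_deg == 0) return(grid)
  th <- angle_deg * pi / 180
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  tx <- rep(seq_len(d[1]), d[2]) - cx
  ty <- rep(seq_len(d[2]), each = d[1]) - cy
  # inverse rotation: source = R(-theta) %*% target
  sx <- cos(th) * tx + sin(th) * ty + cx
  sy <- -sin(th) * tx + cos(th) * ty + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  cl <- function(i, n) pmin(pmax(i, 1), n)
  i00 <- cbind(cl(x0, d[1]), cl(y0, d[2]))
  i10 <- cbind(cl(x0 + 1, d[1]), cl(y0, d[2]))
  i01 <- cbind(cl(x0, d[1]), cl(y0 + 1, d[2]))
  i11 <- cbind(cl(x0 + 1, d[1]), cl(y0 + 1, d[2]))
  out <- grid
  for (z in seq_len(d[3])) {
    sl <- grid[, , z]
    out[, , z] <- (1 - fx) * (1 - fy) * sl[i00] + fx * (1 - fy) * sl[i10] +
      (1 - fx) * fy * sl[i01] + fx * fy * sl[i11]
  }
  out
}

#' Offline rotation expansion of one VOI
#'
#' Produces `n_offline_rotations` rotated copies of the VOI, each with an
#' angle drawn uniformly from `rotation_range_deg`.  Uses the current RNG
#' stream; set the seed for reproducibility.
#'
#' @param voi a [extract_voi()] object or bare 3D array
#' @param config an [augment_config()]
#' @return list of rotated copies (same class as the input)
#' @export
offline_expand <- function(voi, config = augment_config()) {
  grid <- if (inherits(voi, "voi")) voi$grid else voi
  stopifnot(all(dim(grid)[1:2] >= 2L))
  angles <- stats::runif(config$n_offline_rotations,
                         config$rotation_range_deg[1],
                         config$rotation_range_deg[2])
  lapply(angles, function(a) {
    g <- rotate_inplane(grid, a)
    if (inherits(voi, "voi")) { v <- voi; v$grid <- g; v } else g
  })
}

#' Offline expansion of a multiparametric sample
#'
#' Rotates all six VOIs of a finding with a shared angle per replicate, so
#' the anatomy stays consistent across modalities.
#'
#' @param sample an [mp_sample()]
#' @param config an [augment_config()]
#' @return list of `n_offline_rotations` augmented [mp_sample()] objects;
#'   each carries the rotation angle as attribute `"angle_deg"`
#' @export
offline_expand_sample <- function(sample, config = augment_config()) {
  angles <- stats::runif(config$n_offline_rotations,
                         config$rotation_range_deg[1],
                         config$rotation_range_deg[2])
  lapply(angles, function(a) {
    s <- sample
    s$vois <- lapply(s$vois, rotate_inplane, angle_deg = a)
    attr(s, "angle_deg") <- a
    s
  })
}

#' Offline expansion of a cohort
#'
#' @param samples list of [mp_sample()]
#' @param config an [augment_config()]
#' @return flat list of `length(samples) * n_offline_rotations` samples
#' @export
offline_expand_cohort <- function(samples, config = augment_config()) {
  unlist(lapply(samples, offline_expand_sample, config = config),
         recursive = FALSE)
}

## ---- online augmentation ---------------------------------------------------

# shift a grid by integer voxels with replicate-edge padding (re-crop from
# the edge-padded grid, so no wrap-around)
translate_grid <- function(grid, shift) {
  d <- dim(grid)
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  grid[cl(seq_len(d[1]) + shift[1], d[1]),
       cl(seq_len(d[2]) + shift[2], d[2]),
       cl(seq_len(d[3]) + shift[3], d[3]), drop = FALSE]
}

#' Online stochastic augmentation of one sample
#'
#' Applied to training batches only (never to validation data).  Per VOI:
#' contrast scaling about the post-normalisation midpoint 0.5 with factor
#' ~ N(1, contrast_sigma^2), brightness shift ~ N(0, brightness_sigma^2),
#' i.i.d. voxel noise ~ N(0, noise_sigma^2); then an in-plane left-right
#' flip shared across all six VOIs (probability `flip_probability`), and an
#' integer voxel translation drawn per modality within its configured
#' limits.  Output intensities are clamped to \[0, 1\].
#'
#' @param sample an [mp_sample()] with intensities in \[0, 1\]
#' @param config an [augment_config()]
#' @return augmented [mp_sample()]
#' @export
online_augment <- function(sample, config = augment_config()) {
  flip <- stats::runif(1) < config$flip_probability
  sample$vois <- lapply(names(sample$vois), function(m) {
    g <- sample$vois[[m]]
    f <- stats::rnorm(1, 1, config$contrast_sigma)
    b <- stats::rnorm(1, 0, config$brightness_sigma)
    g <- f * (g - 0.5) + 0.5 + b
    if (config$noise_sigma > 0)
      g <- g + array(stats::rnorm(length(g), 0, config$noise_sigma), dim(g))
    if (flip) g <- g[rev(seq_len(dim(g)[1])), , , drop = FALSE]
    lim <- config$translation_limits[[.limit_group(m)]]
    if (any(lim > 0)) {
      shift <- c(sample.int(2L * lim[1] + 1L, 1L) - lim[1] - 1L,
                 sample.int(2L * lim[1] + 1L, 1L) - lim[1] - 1L,
                 sample.int(2L * lim[2] + 1L, 1L) - lim[2] - 1L)
      g <- translate_grid(g, shift)
    }
    pmin(pmax(g, 0), 1)
  })
  names(sample$vois) <- MODALITIES
  sample
}
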