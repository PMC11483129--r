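#' Subject specification for the synthetic cohort
#'
#' Bundles the generative per-subject parameters: the U-fiber density scale
#' planted in the ROI, the subject's mean absolute asynchrony level, the
#' linear phase-correction gain, Wing-Kristofferson timekeeper and motor
#' noise, and the indifference interval toward which self-paced tapping is
#' biased.
#'
#' @param tan_amplitude unitless tangential (U-fiber) density scale applied
#'   inside the planted ROI
#' @param asynchrony_scale ms, magnitude of the subject's mean (negative)
#'   asynchrony
#' @param phase_correction_alpha phase-correction gain, must lie in (0, 2)
#'   for a stable synchronization process
#' @param timekeeper_sd ms, central timekeeper noise SD
#' @param motor_sd ms, peripheral motor-delay noise SD
#' @param indifference_interval ms, target duration at which the constant
#'   error crosses zero (default 654 ms)
#' @param seed integer, drives all randomness attached to this subject
#' @return object of class `subject_spec`
#' @export
subject_spec <- function(tan_amplitude = 1, asynchrony_scale = 40,
                         phase_correction_alpha = 0.7, timekeeper_sd = 20,
                         motor_sd = 10, indifference_interval = 654,
                         seed = 1) {
  if (phase_correction_alpha <= 0 || phase_correction_alpha >= 2)
    stop("phase_correction_alpha must lie in (0, 2)")
  if (timekeeper_sd < 0 || motor_sd < 0) stop("noise SDs must be nonnegative")
  structure(list(tan_amplitude = tan_amplitude,
                 asynchrony_scale = asynchrony_scale,
                 phase_correction_alpha = phase_correction_alpha,
                 timekeeper_sd = timekeeper_sd, motor_sd = motor_sd,
                 indifference_interval = indifference_interval,
                 seed = as.integer(seed)),
            class = "subject_spec")
}

#' Default depth profiles for the planted fiber populations
#'
#' The radial (long-range) population has a flat density through the
#' superficial depth range; the tangential (U-fiber) population follows a
#' Gaussian bump peaking at 1.5 mm below the gray/white boundary, the depth
#' at which the U-fiber system is densest.
#'
#' @param d depth below the gray/white boundary, mm
#' @return nonnegative apparent fiber density (arbitrary units)
#' @export
default_radial_profile <- function(d) rep(0.5, length(d))

#' @rdname default_radial_profile
#' @export
default_tangential_profile <- function(d) 0.4 * exp(-(d - 1.5)^2 / (2 * 0.6^2))

#' Plant a two-population fixel field in a phantom
#'
#' Every white-matter voxel at depth d below the outer boundary receives a
#' radially oriented fixel with density `radial_profile(d)` and a tangential
#' fixel (azimuthal unit vector of the local spherical frame, deterministic;
#' poles fall back to a fixed axis) with density `tangential_profile(d)`,
#' the latter scaled by `subject$tan_amplitude` inside the radial sector of
#' the planted ROI. A small seeded multiplicative log-normal jitter
#' (`noise_sd` relative SD, mean 1) emulates measurement noise; zero-density
#' fixels are dropped. Depths beyond 5 mm evaluate the profiles at 5 mm.
#'
#' @param phantom a [make_phantom()] phantom
#' @param radial_profile,tangential_profile vectorized depth (mm) to density
#'   functions, nonnegative on `[0, 5]`
#' @param subject a [subject_spec()]
#' @param roi_id integer ROI label whose radial sector carries the planted
#'   amplitude (0 = none)
#' @param noise_sd relative SD of the multiplicative density jitter (0
#'   disables it)
#' @return object of class `fixel_field`: columnar fixel table (`vox` linear
#'   voxel index, `dir` n x 3 unit axial directions, `afd`), per-voxel
#'   `count`/`offset` index volumes, and grid metadata
#' @export
plant_fixel_field <- function(phantom,
                              radial_profile = default_radial_profile,
                              tangential_profile = default_tangential_profile,
                              subject = subject_spec(),
                              roi_id = 0L, noise_sd = 0.05) {
  U <- which(phantom$wm_mask)
  ctr <- index_to_world(arrayInd(U, phantom$dim), phantom$origin, phantom$voxel_size)
  depth <- pmax(0, pmin(5, depth_below_surface(phantom, ctr)))
  afd_r <- radial_profile(depth)
  afd_t <- tangential_profile(depth)
  if (any(afd_r < 0) || any(afd_t < 0)) stop("profiles must be nonnegative")

  ## local spherical frame about the nearest hemisphere center
  d2 <- sapply(seq_len(nrow(phantom$centers)), function(h)
    rowSums(sweep(ctr, 2, phantom$centers[h, ], "-")^2))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  hh <- max.col(-d2)
  rel <- ctr - phantom$centers[hh, , drop = FALSE]
  rhat <- unitize(rel)
  az <- cbind(-rel[, 2], rel[, 1], 0)
  pole <- rowSums(az^2) < 1e-12
  if (any(pole)) {
    ## fixed fallback axis, projected into the tangent plane
    fb <- matrix(rep(c(1, 0, 0), each = sum(pole)), ncol = 3)
    fb <- fb - rhat[pole, , drop = FALSE] * rowSums(fb * rhat[pole, , drop = FALSE])
    az[pole, ] <- fb
  }
  that <- unitize(az)

  if (roi_id > 0) {
    in_roi <- roi_labels_at(phantom, ctr) == roi_id
    afd_t[in_roi] <- afd_t[in_roi] * subject$tan_amplitude
  }
  if (noise_sd > 0) {
    s <- sqrt(log(1 + noise_sd^2))
    jit <- with_seed(subject$seed, exp(rnorm(2 * length(U), -s^2 / 2, s)))
    afd_r <- afd_r * jit[seq_along(U)]
    afd_t <- afd_t * jit[length(U) + seq_along(U)]
  }

  vox <- c(U, U)
  dir <- rbind(rhat, that)
  afd <- c(afd_r, afd_t)
  keep <- afd > 0
  fixel_field(vox[keep], dir[keep, , drop = FALSE], afd[keep],
              dim = phantom$dim, origin = phantom$origin,
              voxel_size = phantom$voxel_size)
}

#' Columnar fixel field container
#'
#' Stores all fixels of a volume as one table (voxel linear index, unit
#' axial direction, density) plus per-voxel count and offset volumes, the
#' in-memory analogue of the on-disk fixel-directory convention.
#'
#' @param vox integer linear (1-based) voxel indices, one per fixel
#' @param dir n x 3 unit axial directions
#' @param afd nonnegative densities
#' @param dim,origin,voxel_size grid metadata
#' @return object of class `fixel_field`
#' @export
fixel_field <- function(vox, dir, afd, dim, origin, voxel_size) {
  stopifnot(length(vox) == nrow(dir), length(afd) == length(vox))
  if (any(afd < 0)) stop("afd must be nonnegative")
  if (length(afd) && any(abs(sqrt(rowSums(dir^2)) - 1) > 1e-6))
    stop("fixel directions must be unit vectors")
  ord <- order(vox)
  vox <- vox[ord]; dir <- dir[ord, , drop = FALSE]; afd <- afd[ord]
  count <- array(0L, dim)
  tb <- tabulate(vox, nbins = prod(dim))
  count[] <- tb
  offset <- array(0L, dim)
  offset[] <- cumsum(c(0L, tb[-length(tb)]))
  structure(list(vox = vox, dir = dir, afd = afd, count = count,
                 offset = offset, dim = dim, origin = origin,
                 voxel_size = voxel_size),
            class = "fixel_field")
}

#' @export
print.fixel_field <- function(x, ...) {
  cat(sprintf("fixel field: %d fixels in %d voxels (grid %s, voxel %g mm)\n",
              length(x$afd), sum(x$count > 0), paste(x$dim, collapse = "x"),
              x$voxel_size))
  invisible(x)
}

#' Fixels of one voxel
#'
#' @param field a `fixel_field`
#' @param lin linear voxel index
#' @return list with `dir` (m x 3) and `afd` (length m; m may be 0)
#' @export
voxel_fixels <- function(field, lin) {
  m <- field$count[lin]
  if (m == 0) return(list(dir = matrix(numeric(0), 0, 3), afd = numeric(0)))
  rows <- field$offset[lin] + seq_len(m)
  list(dir = field$dir[rows, , drop = FALSE], afd = field$afd[rows])
}
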