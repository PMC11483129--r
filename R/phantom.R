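#' Synthetic white-matter phantom
#'
#' Builds a parametric stand-in for a cortical hemisphere: a gray/white
#' boundary surface (subdivided icosphere, optionally radially perturbed by a
#' smooth angular "gyrification" field), an inner ventricle sphere, and the
#' voxel masks between them. With `hemispheres = 2` the mesh is duplicated
#' with a lateral offset along x, mirroring the two-hemisphere surface
#' template convention (order-5 meshes then total 20,484 vertices).
#'
#' The outer radius of the boundary at unit direction d (relative to the
#' hemisphere center) is `outer_radius * (1 + gyrification_amplitude * f(d))`
#' where f is a fixed smooth angular perturbation drawn once from `seed`
#' (a low-order combination of spherical harmonics, scaled to max |f| = 1).
#' White matter is every voxel whose center lies between the ventricle sphere
#' and that boundary.
#'
#' @param outer_radius gray/white boundary radius, mm
#' @param inner_radius ventricle radius, mm; must be positive and smaller than
#'   `outer_radius`
#' @param voxel_size isotropic voxel edge, mm
#' @param gyrification_amplitude relative amplitude of the radial perturbation
#'   (0 = perfect sphere, with an exact Laplace solution)
#' @param mesh_order icosphere subdivision order of the boundary mesh
#' @param hemispheres 1 or 2
#' @param n_roi number of angular-sector ROI labels painted on the surface
#' @param seed integer seed fixing the perturbation field
#' @return object of class `phantom`: voxel grid (`dim`, `origin`,
#'   `voxel_size`), `wm_mask` and `ventricle_mask` logical arrays, `surface`
#'   (vertices/faces/normals/hemisphere), `roi_labels` (per vertex, 0 = none),
#'   `centers`, radii and the perturbation definition
#' @export
make_phantom <- function(outer_radius = 20, inner_radius = 10, voxel_size = 1,
                         gyrification_amplitude = 0, mesh_order = 3,
                         hemispheres = 1, n_roi = 8, seed = 1) {
  if (inner_radius <= 0) stop("inner_radius must be positive")
  if (inner_radius >= outer_radius) stop("inner_radius must be smaller than outer_radius")
  stopifnot(hemispheres %in% c(1, 2), voxel_size > 0)

  gyr <- make_gyrification(gyrification_amplitude, seed)
  rmax <- outer_radius * (1 + abs(gyrification_amplitude))

  offset <- if (hemispheres == 2) 1.15 * rmax else 0
  centers <- if (hemispheres == 2) {
    rbind(c(-offset, 0, 0), c(offset, 0, 0))
  } else {
    matrix(0, 1, 3)
  }

  half <- rmax + 2 * voxel_size + offset
  n_half <- ceiling(half / voxel_size)
  dims <- c(2 * n_half + 1, 0, 0)
  dims[2] <- dims[3] <- 2 * ceiling((rmax + 2 * voxel_size) / voxel_size) + 1
  origin <- -c(n_half, (dims[2] - 1) / 2, (dims[3] - 1) / 2) * voxel_size
  if (any(origin + (dims - 1) * voxel_size < c(rmax + offset, rmax, rmax) + voxel_size))
    stop("voxel grid too small to contain the outer surface with margin")

  ## voxel-center coordinates
  xs <- origin[1] + (seq_len(dims[1]) - 1) * voxel_size
  ys <- origin[2] + (seq_len(dims[2]) - 1) * voxel_size
  zs <- origin[3] + (seq_len(dims[3]) - 1) * voxel_size
  cx <- array(rep(xs, times = dims[2] * dims[3]), dims)
  cy <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  cz <- array(rep(zs, each = dims[1] * dims[2]), dims)

  wm <- array(FALSE, dims)
  vent <- array(FALSE, dims)
  for (h in seq_len(nrow(centers))) {
    dx <- cx - centers[h, 1]; dy <- cy - centers[h, 2]; dz <- cz - centers[h, 3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    router <- outer_radius * (1 + eval_gyrification(gyr, cbind(as.vector(dx), as.vector(dy), as.vector(dz)) / pmax(as.vector(r), 1e-12)))
    router <- array(router, dims)
    vent <- vent | (r <= inner_radius)
    wm <- wm | (r > inner_radius & r < router)
  }
  wm <- wm & !vent

  ## boundary surface mesh, one icosphere per hemisphere
  ico <- make_icosphere(mesh_order, 1)
  verts <- NULL; faces <- NULL; hemi <- NULL
  for (h in seq_len(nrow(centers))) {
    rad <- outer_radius * (1 + eval_gyrification(gyr, ico$vertices))
    vh <- ico$vertices * rad
    vh <- sweep(vh, 2, centers[h, ], "+")
    faces <- rbind(faces, ico$faces + if (is.null(verts)) 0L else nrow(verts))
    verts <- rbind(verts, vh)
    hemi <- c(hemi, rep(h, nrow(vh)))
  }
  normals <- vertex_normals(verts, faces)

  ph <- structure(list(
    voxel_size = voxel_size, dim = dims, origin = origin,
    wm_mask = wm, ventricle_mask = vent,
    surface = list(vertices = verts, faces = faces, normals = normals,
                   hemisphere = hemi),
    roi_labels = integer(nrow(verts)),
    centers = centers, outer_radius = outer_radius,
    inner_radius = inner_radius, gyr = gyr, n_roi = n_roi,
    mesh_order = mesh_order, hemispheres = hemispheres, seed = seed
  ), class = "phantom")
  ph$roi_labels <- roi_labels_at(ph, verts)
  ph
}

## Smooth angular perturbation: fixed random low-order harmonic combination
## in (theta, phi), scaled so max |f| over a probe grid is 1.
make_gyrification <- function(amplitude, seed) {
  if (amplitude == 0) return(list(amplitude = 0))
  co <- with_seed(seed, rnorm(6))
  g <- list(amplitude = amplitude, co = co, scale = 1)
  probe <- make_icosphere(3, 1)$vertices
  g$scale <- 1 / max(abs(eval_gyrification_raw(g, probe)))
  g
}

eval_gyrification_raw <- function(g, dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  g$co[1] * (3 * z^2 - 1) / 2 +
    g$co[2] * x * y * 3 +
    g$co[3] * z * x * 3 +
    g$co[4] * (x^2 - y^2) * 1.5 +
    g$co[5] * z * (5 * z^2 - 3) / 2 +
    g$co[6] * x * (x^2 - 3 * y^2)
}

eval_gyrification <- function(g, dirs) {
  if (g$amplitude == 0) return(rep(0, nrow(dirs)))
  g$amplitude * g$scale * eval_gyrification_raw(g, dirs)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d hemisphere(s), outer %g mm / inner %g mm, voxel %g mm\n",
              x$hemispheres, x$outer_radius, x$inner_radius, x$voxel_size))
  cat(sprintf("  grid %s | wm voxels %d | ventricle voxels %d\n",
              paste(x$dim, collapse = "x"), sum(x$wm_mask), sum(x$ventricle_mask)))
  cat(sprintf("  surface: %d vertices, %d faces, %d ROI labels\n",
              nrow(x$surface$vertices), nrow(x$surface$faces),
              length(unique(x$roi_labels[x$roi_labels > 0]))))
  invisible(x)
}

#' ROI label of arbitrary world points
#'
#' Labels partition each hemisphere into `n_roi` angular sectors (polar bands
#' crossed with azimuth sectors about the hemisphere center), so a surface
#' vertex and the white-matter voxels radially beneath it share a label.
#'
#' @param phantom a `phantom`
#' @param points n x 3 world-mm coordinates
#' @return integer labels (1-based; 0 only for degenerate zero directions)
#' @export
roi_labels_at <- function(phantom, points) {
  n_roi <- phantom$n_roi
  n_band <- if (n_roi >= 8) 2L else 1L
  n_az <- max(1L, n_roi %/% n_band)
  ## nearest hemisphere center
  d2 <- sapply(seq_len(nrow(phantom$centers)), function(h)
    rowSums(sweep(points, 2, phantom$centers[h, ], "-")^2))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  h <- max.col(-d2)
  rel <- points - phantom$centers[h, , drop = FALSE]
  r <- sqrt(rowSums(rel^2))
  ct <- ifelse(r > 1e-12, rel[, 3] / r, 1)
  band <- pmin(n_band, 1L + floor((ct + 1) / 2 * n_band))
  az <- atan2(rel[, 2], rel[, 1])
  sec <- pmin(n_az, 1L + floor((az + pi) / (2 * pi) * n_az))
  lab <- as.integer((band - 1L) * n_az + sec)
  lab[r <= 1e-12] <- 0L
  lab
}

## Depth below the outer boundary (mm) of world points, measured radially
## from the nearest hemisphere center; negative outside white matter.
depth_below_surface <- function(phantom, points) {
  d2 <- sapply(seq_len(nrow(phantom$centers)), function(h)
    rowSums(sweep(points, 2, phantom$centers[h, ], "-")^2))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  h <- max.col(-d2)
  rel <- points - phantom$centers[h, , drop = FALSE]
  r <- sqrt(rowSums(rel^2))
  dirs <- unitize(rel)
  router <- phantom$outer_radius * (1 + eval_gyrification(phantom$gyr, dirs))
  router - r
}
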