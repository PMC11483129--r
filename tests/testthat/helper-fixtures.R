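## Shared fixtures, built once per test run on first use.

.fix <- new.env()

## one-hemisphere sphere phantom (outer 20 / inner 10 mm, 1 mm voxels)
sphere_phantom <- function(order = 2) {
  key <- paste0("ph", order)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- make_phantom(20, 10, 1, mesh_order = order, seed = 1)
  .fix[[key]]
}

sphere_field <- function(order = 2) {
  key <- paste0("fld", order)
  if (is.null(.fix[[key]])) .fix[[key]] <- solve_laplace(sphere_phantom(order))
  .fix[[key]]
}

sphere_gradient <- function(order = 2) {
  key <- paste0("grad", order)
  if (is.null(.fix[[key]])) .fix[[key]] <- gradient_field(sphere_field(order))
  .fix[[key]]
}

sphere_streamlines <- function(order = 2) {
  key <- paste0("sl", order)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- trace_streamlines(sphere_phantom(order), sphere_gradient(order))
  .fix[[key]]
}

## slab pseudo-phantom: white matter between z = 2 and z = 12 planes (world
## mm), "ventricle" below; exercises the mask-only solver path
slab_phantom <- function() {
  if (!is.null(.fix$slab)) return(.fix$slab)
  dm <- c(17L, 17L, 17L)
  origin <- c(0, 0, 0)
  zs <- array(rep(origin[3] + (seq_len(dm[3]) - 1), each = dm[1] * dm[2]), dm)
  ph <- structure(list(
    voxel_size = 1, dim = dm, origin = origin,
    wm_mask = zs > 2 & zs < 12, ventricle_mask = zs <= 2,
    centers = matrix(c(8, 8, 0), 1), outer_radius = 12, inner_radius = 2,
    gyr = list(amplitude = 0)), class = "phantom")
  .fix$slab <- ph
  ph
}

## small phantom for I/O and quick checks
tiny_phantom <- function() {
  if (is.null(.fix$tiny)) .fix$tiny <- make_phantom(10, 5, 1, mesh_order = 1)
  .fix$tiny
}

## world radius of a point set (one-hemisphere phantom at the origin)
radius_of <- function(p) sqrt(rowSums(p^2))

## internal helpers used across tests
itw <- function(idx, origin, voxel_size) ufiber:::index_to_world(idx, origin, voxel_size)
unit_rows <- function(m) ufiber:::unitize(m)
voxel_centers <- function(ph, which_mask = ph$wm_mask) {
  itw(arrayInd(which(which_mask), ph$dim), ph$origin, ph$voxel_size)
}
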