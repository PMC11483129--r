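#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd qt pt rnorm runif quantile complete.cases coef
#' @importFrom utils write.csv read.csv head tail
NULL

## World coordinates are mm; voxel indices are 1-based in R with the voxel-center
## convention: world = origin + (index - 1) * voxel_size, applied per axis.

world_to_index <- function(points, origin, voxel_size) {
  sweep(points, 2, origin, "-") / voxel_size + 1
}

index_to_world <- function(idx, origin, voxel_size) {
  sweep((idx - 1) * voxel_size, 2, origin, "+")
}

#' Normalize rows of a matrix to unit length
#'
#' Rows with norm below `eps` are returned as zero vectors.
#' @param m numeric matrix (n x 3)
#' @param eps smallest norm treated as nonzero
#' @return matrix of the same shape with unit (or zero) rows
#' @keywords internal
unitize <- function(m, eps = 1e-12) {
  n <- sqrt(rowSums(m^2))
  scale <- ifelse(n > eps, 1 / n, 0)
  m * scale
}

## Trilinear interpolation of one or more scalar volumes at world-mm points.
## `vols` is a list of 3D arrays sharing dim/origin; `valid` an optional logical
## array marking voxels whose values may be used. Weights of invalid or
## out-of-grid corners are dropped and the remainder renormalized; points with
## no valid corner get NA.
interp_trilinear <- function(vols, points, origin, voxel_size, valid = NULL) {
  dm <- dim(vols[[1L]])
  cont <- world_to_index(points, origin, voxel_size)
  i0 <- floor(cont)
  fr <- cont - i0
  n <- nrow(points)
  acc <- vector("list", length(vols))
  for (k in seq_along(vols)) acc[[k]] <- numeric(n)
  wsum <- numeric(n)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ci <- i0[, 1] + dx; cj <- i0[, 2] + dy; ck <- i0[, 3] + dz
    w <- (if (dx == 1) fr[, 1] else 1 - fr[, 1]) *
         (if (dy == 1) fr[, 2] else 1 - fr[, 2]) *
         (if (dz == 1) fr[, 3] else 1 - fr[, 3])
    inside <- ci >= 1 & ci <= dm[1] & cj >= 1 & cj <= dm[2] & ck >= 1 & ck <= dm[3]
    lin <- rep(NA_integer_, n)
    lin[inside] <- ci[inside] + dm[1] * (cj[inside] - 1L + dm[2] * (ck[inside] - 1L))
    ok <- inside
    if (!is.null(valid)) ok[inside] <- valid[lin[inside]]
    w[!ok] <- 0
    wsum <- wsum + w
    use <- which(w > 0)
    if (length(use)) {
      for (k in seq_along(vols)) {
        acc[[k]][use] <- acc[[k]][use] + w[use] * vols[[k]][lin[use]]
      }
    }
  }
  out <- matrix(NA_real_, n, length(vols))
  pos <- wsum > 1e-12
  for (k in seq_along(vols)) out[pos, k] <- acc[[k]][pos] / wsum[pos]
  attr(out, "support") <- wsum
  out
}

## Linear (1-based) voxel index of the voxel containing each world point; NA outside grid.
containing_voxel <- function(points, origin, voxel_size, dm) {
  idx <- round(world_to_index(points, origin, voxel_size))
  ok <- idx[, 1] >= 1 & idx[, 1] <= dm[1] &
        idx[, 2] >= 1 & idx[, 2] <= dm[2] &
        idx[, 3] >= 1 & idx[, 3] <= dm[3]
  lin <- rep(NA_integer_, nrow(points))
  lin[ok] <- as.integer(idx[ok, 1] + dm[1] * (idx[ok, 2] - 1 + dm[2] * (idx[ok, 3] - 1)))
  lin
}

## Seed helper: every exported stochastic operation takes an explicit seed and
## restores the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}
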