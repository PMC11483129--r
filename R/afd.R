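#' Split apparent fiber density against a streamline tangent
#'
#' Total density is the sum over fixels. The parallel component is the
#' density of the single fixel whose axial angle to the tangent is smallest,
#' counted only when that angle is below `angle_cutoff` (otherwise no fixel
#' is considered parallel and the parallel density is 0). The tangential
#' (U-fiber) component is defined as total minus parallel, so the identity
#' `tan = total - par` holds exactly.
#'
#' @param fixels list with `dir` (m x 3 unit axial vectors) and `afd`
#' @param tangent unit 3-vector (local streamline direction)
#' @param angle_cutoff degrees
#' @return named numeric `c(total = , par = , tan = )`
#' @export
classify_afd <- function(fixels, tangent, angle_cutoff = 45) {
  m <- length(fixels$afd)
  if (m == 0) return(c(total = 0, par = 0, tan = 0))
  total <- sum(fixels$afd)
  ang <- acos(pmin(1, abs(as.vector(fixels$dir %*% tangent))))
  best <- which.min(ang)
  par <- if (ang[best] < angle_cutoff * pi / 180) fixels$afd[best] else 0
  c(total = total, par = par, tan = total - par)
}

#' Sample total/parallel/tangential AFD along streamlines at fixed depths
#'
#' At each depth point the fixel list of the containing voxel is classified
#' against the local streamline tangent (central difference of the
#' bracketing polyline points). Samples are missing where the depth point
#' is missing (truncated streamline) or the voxel holds no fixels and lies
#' outside the field.
#'
#' @param fixel_field a [fixel_field()]
#' @param streamlines a `streamline_set` on the same grid
#' @param depths mm below the gray/white boundary
#' @param angle_cutoff degrees, see [classify_afd()]
#' @return object of class `depth_samples`: array
#'   `[n_vertices, n_depths, 3]` with metric slices `total`, `par`, `tan`,
#'   plus `depths`
#' @export
sample_depth_profiles <- function(fixel_field, streamlines,
                                  depths = c(0, 0.5, 1, 1.5, 2),
                                  angle_cutoff = 45) {
  pts <- depth_points(streamlines, depths)
  tg <- depth_tangents(streamlines, depths)
  nv <- dim(pts)[1]; nd <- dim(pts)[2]
  out <- array(NA_real_, c(nv, nd, 3),
               dimnames = list(NULL, NULL, c("total", "par", "tan")))
  dm <- fixel_field$dim
  cutoff <- angle_cutoff * pi / 180
  for (j in seq_len(nd)) {
    P <- pts[, j, , drop = TRUE]
    if (nv == 1) P <- matrix(P, 1, 3)
    Tj <- tg[, j, , drop = TRUE]
    if (nv == 1) Tj <- matrix(Tj, 1, 3)
    ok <- which(!is.na(P[, 1]) & !is.na(Tj[, 1]))
    if (!length(ok)) next
    lin <- containing_voxel(P[ok, , drop = FALSE], fixel_field$origin,
                            fixel_field$voxel_size, dm)
    cnt <- ifelse(is.na(lin), 0L, fixel_field$count[ifelse(is.na(lin), 1L, lin)])
    ## vectorized gather of every candidate fixel row
    samp <- rep(seq_along(ok), cnt)
    if (length(samp)) {
      rows <- sequence(cnt[cnt > 0]) + rep(fixel_field$offset[lin[cnt > 0]], cnt[cnt > 0])
      dots <- abs(rowSums(fixel_field$dir[rows, , drop = FALSE] *
                          Tj[ok[samp], , drop = FALSE]))
      ang <- acos(pmin(1, dots))
      afd <- fixel_field$afd[rows]
      tot <- rowsum_fill(afd, samp, length(ok))
      ## best (smallest axial angle) fixel per sample
      o <- order(samp, ang)
      first <- !duplicated(samp[o])
      bi <- o[first]
      par <- numeric(length(ok))
      par[samp[bi]] <- ifelse(ang[bi] < cutoff, afd[bi], 0)
      out[ok, j, 1] <- tot
      out[ok, j, 2] <- par
      out[ok, j, 3] <- tot - par
    }
    ## voxels with zero fixels but inside the grid: explicit zeros
    zero <- ok[!is.na(lin) & cnt == 0]
    out[zero, j, ] <- 0
  }
  structure(out, depths = depths, class = c("depth_samples", "array"))
}

#' Smooth a per-vertex scalar map on a surface mesh
#'
#' Iterated neighbor averaging (heat-kernel approximation): each iteration
#' replaces a vertex value by a blend of itself and the mean of its
#' non-missing one-ring neighbors. The iteration count is calibrated from
#' the mesh's mean edge length so the impulse response has approximately the
#' requested full width at half maximum. Missing vertices are excluded from
#' the averages and stay missing; constant fields are preserved exactly;
#' `fwhm = 0` returns the input unchanged.
#'
#' @param surface list with `vertices` and `faces` (e.g. `phantom$surface`)
#' @param values per-vertex numeric with NA for missing
#' @param fwhm smoothing kernel full width at half maximum, mm
#' @param blend per-iteration neighbor weight in (0, 1]
#' @return smoothed per-vertex numeric
#' @export
smooth_surface_metric <- function(surface, values, fwhm = 15, blend = 0.5) {
  if (fwhm < 0) stop("fwhm must be nonnegative")
  if (fwhm == 0) return(values)
  edges <- mesh_edges(surface$faces)
  nv <- nrow(surface$vertices)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nv)
  if (any(deg == 0)) warning("disconnected vertices left unsmoothed")
  el2 <- rowSums((surface$vertices[edges[, 1], , drop = FALSE] -
                  surface$vertices[edges[, 2], , drop = FALSE])^2)
  h2 <- mean(el2)
  ## per-iteration 2D displacement variance ~ blend * h2; a 2D Gaussian of
  ## per-axis sd s has radial FWHM 2.3548 s and total variance 2 s^2
  s2 <- (fwhm / 2.3548)^2
  n_iter <- max(1L, as.integer(round(2 * s2 / (blend * h2))))
  miss <- is.na(values)
  x <- values
  src <- c(edges[, 1], edges[, 2])
  dst <- c(edges[, 2], edges[, 1])
  for (it in seq_len(n_iter)) {
    xv <- x; xv[miss] <- 0
    cnt_ok <- rowsum_fill(as.numeric(!miss[src]), dst, nv)
    acc <- rowsum_fill(ifelse(miss[src], 0, x[src]), dst, nv)
    nbmean <- ifelse(cnt_ok > 0, acc / cnt_ok, x)
    x <- (1 - blend) * x + blend * nbmean
    x[miss] <- NA_real_
  }
  x
}
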