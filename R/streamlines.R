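#' Trace laminar streamlines from every surface vertex
#'
#' Seeds one trajectory at each gray/white-boundary vertex and propagates it
#' toward the ventricles along the trilinearly interpolated, renormalized
#' gradient of the Laplace potential, with fixed 0.1 mm Euler steps and
#' truncation at 5 mm of arc length. A streamline also stops on entering the
#' ventricle mask, on leaving the white-matter mask, or when the interpolated
#' gradient magnitude falls below 1e-8 (stalled). If the seed itself has no
#' usable gradient it is nudged 0.05 mm inward along the vertex normal once
#' before being marked stalled.
#'
#' @param phantom a [make_phantom()] phantom
#' @param gradient a [gradient_field()] result on the same grid
#' @param step step length, mm
#' @param max_length truncation arc length, mm
#' @return object of class `streamline_set`: `points` (array
#'   `[max_points, 3, n_seeds]`, NA beyond each trajectory's end),
#'   `n_points`, `arc_length`, `termination` (one of `max_length`,
#'   `reached_ventricle`, `left_mask`, `stalled`) per seed, `seed_vertex_id`,
#'   and `step`
#' @export
trace_streamlines <- function(phantom, gradient, step = 0.1, max_length = 5.0) {
  stopifnot(step > 0, max_length >= 0)
  seeds <- phantom$surface$vertices
  n <- nrow(seeds)
  max_steps <- if (max_length == 0) 0L else ceiling(max_length / step - 1e-9)
  pts <- array(NA_real_, c(max_steps + 1L, 3L, n))
  pts[1, , ] <- t(seeds)
  arc <- numeric(n)
  npts <- rep(1L, n)
  term <- rep(NA_character_, n)
  dm <- gradient$dim

  cur <- seeds
  active <- rep(TRUE, n)
  if (max_length == 0) {
    term[] <- "max_length"
    active[] <- FALSE
  }

  interp_dir <- function(p) {
    g <- interp_trilinear(list(gradient$gx, gradient$gy, gradient$gz), p,
                          gradient$origin, gradient$voxel_size,
                          valid = gradient$valid)
    g[is.na(g)] <- 0
    g
  }

  ## seed rescue: vertices whose interpolated gradient is (near) zero get one
  ## 0.05 mm inward nudge along the vertex normal
  if (any(active)) {
    g0 <- interp_dir(cur)
    dead <- active & sqrt(rowSums(g0^2)) < 1e-8
    if (any(dead)) {
      nudged <- cur[dead, , drop = FALSE] - 0.05 * phantom$surface$normals[dead, , drop = FALSE]
      g1 <- interp_dir(nudged)
      still <- sqrt(rowSums(g1^2)) < 1e-8
      cur[dead, ] <- nudged
      pts[1, , dead] <- t(nudged)
      idx_dead <- which(dead)
      if (any(still)) {
        term[idx_dead[still]] <- "stalled"
        active[idx_dead[still]] <- FALSE
      }
    }
  }

  k <- 1L
  while (any(active) && k <= max_steps) {
    idx <- which(active)
    g <- interp_dir(cur[idx, , drop = FALSE])
    mag <- sqrt(rowSums(g^2))
    stall <- mag < 1e-8
    if (any(stall)) {
      term[idx[stall]] <- "stalled"
      active[idx[stall]] <- FALSE
      idx <- idx[!stall]
      g <- g[!stall, , drop = FALSE]
      mag <- mag[!stall]
    }
    if (!length(idx)) break
    dir <- g / mag
    this_step <- pmin(step, max_length - arc[idx])
    nxt <- cur[idx, , drop = FALSE] + dir * this_step
    lin <- containing_voxel(nxt, gradient$origin, gradient$voxel_size, dm)
    in_vent <- !is.na(lin) & phantom$ventricle_mask[ifelse(is.na(lin), 1L, lin)]
    ## a point still counts as inside while its interpolation stencil has
    ## meaningful white-matter support (the voxelized boundary is jagged)
    gnxt <- interp_dir(nxt)
    supp <- attr(gnxt, "support")
    in_wm <- (!is.na(lin) & phantom$wm_mask[ifelse(is.na(lin), 1L, lin)]) |
      (if (is.null(supp)) FALSE else supp > 0.01)

    k <- k + 1L
    pts[k, , idx] <- t(nxt)
    cur[idx, ] <- nxt
    arc[idx] <- arc[idx] + this_step
    npts[idx] <- k

    done_len <- arc[idx] >= max_length - 1e-9
    term[idx[done_len]] <- "max_length"
    term[idx[in_vent & !done_len]] <- "reached_ventricle"
    term[idx[!in_vent & !in_wm & !done_len]] <- "left_mask"
    active[idx[done_len | in_vent | !in_wm]] <- FALSE
  }
  term[is.na(term)] <- "max_length"

  structure(list(points = pts, n_points = npts, arc_length = arc,
                 termination = term, seed_vertex_id = seq_len(n),
                 step = step, max_length = max_length),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("%d laminar streamlines, step %g mm, truncation %g mm\n",
              length(x$n_points), x$step, x$max_length))
  print(table(x$termination))
  invisible(x)
}

#' Extract one streamline from a set
#'
#' @param set a `streamline_set`
#' @param i seed vertex index
#' @return object of class `laplacian_streamline` with `points` (m x 3),
#'   `arc_length`, `termination`, `step`, `seed_vertex_id`
#' @export
get_streamline <- function(set, i) {
  m <- set$n_points[i]
  structure(list(seed_vertex_id = i,
                 points = set$points[seq_len(m), , i, drop = FALSE][, , 1, drop = TRUE],
                 step = set$step, arc_length = set$arc_length[i],
                 termination = set$termination[i]),
            class = "laplacian_streamline")
}

#' Locate points at fixed arc-length depths along streamlines
#'
#' Linear interpolation along each polyline at the requested arc lengths.
#' Depths beyond a streamline's arc length are returned as NA rows (missing
#' marker), never an error.
#'
#' @param streamlines a `streamline_set` or a single `laplacian_streamline`
#' @param depths sorted nonnegative arc lengths, mm
#' @return for a set, an array `[n_streamlines, n_depths, 3]` of world-mm
#'   points; for a single streamline, an `n_depths x 3` matrix
#' @export
depth_points <- function(streamlines, depths = c(0, 0.5, 1, 1.5, 2)) {
  if (any(depths < 0)) stop("depths must be nonnegative")
  if (is.unsorted(depths)) stop("depths must be sorted increasing")
  single <- inherits(streamlines, "laplacian_streamline")
  if (single) {
    set <- list(points = array(t(streamlines$points),
                               c(nrow(streamlines$points), 3, 1)),
                n_points = nrow(streamlines$points),
                arc_length = streamlines$arc_length, step = streamlines$step)
  } else set <- streamlines
  n <- length(set$n_points)
  out <- array(NA_real_, c(n, length(depths), 3))
  step <- set$step
  for (j in seq_along(depths)) {
    d <- depths[j]
    ## arc length at point k is (k-1)*step except possibly the final partial
    ## step; handle the regular part by index arithmetic, the tail exactly
    ok <- d <= set$arc_length + 1e-9
    if (!any(ok)) next
    seg <- pmin(floor(d / step + 1e-9), set$n_points - 2L)
    seg[set$n_points == 1L] <- 0L
    base_arc <- seg * step
    last_arc <- set$arc_length
    for (i in which(ok)) {
      m <- set$n_points[i]
      if (m == 1L) { out[i, j, ] <- set$points[1, , i]; next }
      s <- seg[i]
      a0 <- s * step
      a1 <- if (s + 2L >= m) last_arc[i] else (s + 1) * step
      fr <- if (a1 > a0) (d - a0) / (a1 - a0) else 0
      fr <- min(max(fr, 0), 1)
      out[i, j, ] <- (1 - fr) * set$points[s + 1L, , i] + fr * set$points[s + 2L, , i]
    }
  }
  if (single) matrix(out[1, , ], ncol = 3) else out
}

#' Local streamline tangents at fixed depths
#'
#' Central difference of the points bracketing each depth, normalized; used
#' as the reference direction for the parallel/tangential fiber split.
#'
#' @inheritParams depth_points
#' @return array `[n_streamlines, n_depths, 3]` of unit tangents (NA where
#'   the depth is missing)
#' @export
depth_tangents <- function(streamlines, depths = c(0, 0.5, 1, 1.5, 2)) {
  set <- streamlines
  n <- length(set$n_points)
  out <- array(NA_real_, c(n, length(depths), 3))
  step <- set$step
  for (j in seq_along(depths)) {
    d <- depths[j]
    for (i in seq_len(n)) {
      m <- set$n_points[i]
      if (d > set$arc_length[i] + 1e-9 || m < 2L) next
      s <- min(floor(d / step + 1e-9), m - 2L)
      lo <- max(1L, s)          # bracketing points around the depth
      hi <- min(m, s + 2L)
      t <- set$points[hi, , i] - set$points[lo, , i]
      nt <- sqrt(sum(t^2))
      if (nt > 1e-12) out[i, j, ] <- t / nt
    }
  }
  out
}
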