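## Real even-order spherical-harmonic machinery for fiber orientation
## distributions (FODs). The basis is orthonormal on the sphere; antipodal
## symmetry of fiber populations restricts it to even degrees l = 0, 2, ...,
## lmax, giving (lmax + 1)(lmax + 2) / 2 coefficients.

## Evaluate the real even SH basis at unit directions. Column order:
## l = 0, 2, ..., lmax; within l, m = -l ... l (sin terms for m < 0, cos for
## m > 0). Uses associated Legendre functions from pracma.
sh_basis <- function(dirs, lmax = 8) {
  if (lmax %% 2 != 0) stop("lmax must be even")
  ct <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  ncoef <- (lmax + 1) * (lmax + 2) / 2
  Y <- matrix(0, n, ncoef)
  col <- 0L
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, ct)          # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    for (m in -l:l) {
      col <- col + 1L
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      Plm <- P[am + 1, ]
      Y[, col] <- if (m < 0) {
        sqrt(2) * N * Plm * sin(am * phi)
      } else if (m == 0) {
        N * Plm
      } else {
        sqrt(2) * N * Plm * cos(am * phi)
      }
    }
  }
  Y
}

## Dense symmetric sphere sampling with quadrature weights: icosphere
## vertices, each weighted by one third of its adjacent triangle areas
## (weights sum to 4 pi). Cached per order.
.tess_cache <- new.env(parent = emptyenv())
sphere_tessellation <- function(order = 4) {
  key <- as.character(order)
  if (!is.null(.tess_cache[[key]])) return(.tess_cache[[key]])
  ico <- make_icosphere(order, 1)
  v <- ico$vertices; f <- ico$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  w <- numeric(nrow(v))
  for (c in 1:3) {
    s <- rowsum(area / 3, f[, c])
    w[as.integer(rownames(s))] <- w[as.integer(rownames(s))] + s[, 1]
  }
  w <- w * 4 * pi / sum(w)
  out <- list(dirs = v, weights = w, faces = f, edges = mesh_edges(f))
  .tess_cache[[key]] <- out
  out
}

#' Render fixels as a spherical-harmonic FOD
#'
#' Each fixel contributes an axially symmetric non-negative lobe (Gaussian
#' in axial angle, antipodally symmetric) centered on its direction and
#' scaled so the lobe's spherical integral equals the fixel's density; the
#' lobes are summed and projected onto the real even SH basis by quadrature
#' on a dense tessellation. The construction is linear in the densities.
#'
#' @param fixels list with `dir` (m x 3 unit axial vectors) and `afd`
#'   (nonnegative), e.g. from [voxel_fixels()]
#' @param lmax even SH order (default 8)
#' @param kernel_width angular SD of the lobe in degrees; the default 25
#'   keeps the truncated expansion non-negative while separating crossing
#'   populations
#' @param tessellation_order icosphere order of the projection quadrature
#' @return object of class `fod`: `sh_coeffs` and `lmax`
#' @export
fixels_to_sh <- function(fixels, lmax = 8, kernel_width = 25,
                         tessellation_order = 4) {
  if (lmax %% 2 != 0) stop("lmax must be even")
  tess <- sphere_tessellation(tessellation_order)
  Y <- sh_basis_cached(tessellation_order, lmax)
  vals <- numeric(nrow(tess$dirs))
  m <- length(fixels$afd)
  if (m > 0) {
    sig <- kernel_width * pi / 180
    ct <- abs(tess$dirs %*% t(fixels$dir))   # |cos| of axial angle
    ang <- acos(pmin(ct, 1))
    K <- exp(-ang^2 / (2 * sig^2))
    Z <- colSums(tess$weights * K)           # per-lobe spherical integral
    vals <- as.vector(K %*% (fixels$afd / Z))
  }
  coeffs <- as.vector(crossprod(Y, tess$weights * vals))
  structure(list(sh_coeffs = coeffs, lmax = lmax), class = "fod")
}

.basis_cache <- new.env(parent = emptyenv())
sh_basis_cached <- function(order, lmax) {
  key <- paste(order, lmax)
  if (is.null(.basis_cache[[key]]))
    .basis_cache[[key]] <- sh_basis(sphere_tessellation(order)$dirs, lmax)
  .basis_cache[[key]]
}

#' Spherical integral of an FOD
#'
#' Exactly \eqn{\sqrt{4\pi}} times the degree-0 coefficient.
#' @param fod an `fod`
#' @return total apparent fiber density
#' @export
fod_integral <- function(fod) sqrt(4 * pi) * fod$sh_coeffs[1]

#' Segment an FOD into fixels (discrete watershed on the sphere)
#'
#' The FOD is rendered on a dense symmetric tessellation; local maxima above
#' `peak_rel_threshold` times the global maximum become candidate fixel
#' directions, every tessellation point is assigned to its uphill peak, and
#' each fixel's density is the quadrature-weighted sum of FOD values over
#' its catchment, so the fixel densities sum to the full spherical integral.
#' Catchments of sub-threshold peaks are folded into the nearest retained
#' peak; antipodal peak pairs are merged into single axial fixels.
#'
#' @param fod an `fod` (class with `sh_coeffs`, `lmax`)
#' @param tessellation_order icosphere order (>= 3 gives >= 1280 symmetric
#'   directions)
#' @param peak_rel_threshold relative peak height cutoff
#' @return list with `dir` (k x 3 unit axial directions) and `afd`; empty
#'   for an all-zero FOD
#' @export
segment_fod <- function(fod, tessellation_order = 4, peak_rel_threshold = 0.1) {
  tess <- sphere_tessellation(tessellation_order)
  Y <- sh_basis_cached(tessellation_order, fod$lmax)
  vals <- as.vector(Y %*% fod$sh_coeffs)
  if (all(abs(vals) < 1e-14)) return(list(dir = matrix(numeric(0), 0, 3), afd = numeric(0)))
  nv <- length(vals)
  total <- sum(tess$weights * vals)
  if (max(vals) - min(vals) < 1e-12 * max(abs(vals))) {
    ## no directional structure: one fixel carrying all mass
    return(list(dir = tess$dirs[1, , drop = FALSE], afd = max(0, total)))
  }

  ## uphill pointer: steepest-ascent neighbor (self if none larger)
  nb <- adjacency_list(tess$edges, nv)
  ptr <- seq_len(nv)
  for (i in seq_len(nv)) {
    ni <- nb[[i]]
    j <- ni[which.max(vals[ni])]
    if (vals[j] > vals[i]) ptr[i] <- j
  }
  ## path-compress to peaks
  repeat {
    nxt <- ptr[ptr]
    if (identical(nxt, ptr)) break
    ptr <- nxt
  }
  peaks <- sort(unique(ptr))
  mass <- rowsum_fill(tess$weights * vals, ptr, nv)[peaks]
  keep <- vals[peaks] >= peak_rel_threshold * max(vals)
  if (!any(keep)) keep[which.max(vals[peaks])] <- TRUE
  if (any(!keep)) {
    ## fold sub-threshold catchments into the angularly nearest kept peak
    kd <- tess$dirs[peaks[keep], , drop = FALSE]
    for (qi in which(!keep)) {
      ct <- abs(kd %*% tess$dirs[peaks[qi], ])
      tgt <- which.max(ct)
      mass[which(keep)[tgt]] <- mass[which(keep)[tgt]] + mass[qi]
    }
    peaks <- peaks[keep]; mass <- mass[keep]
  }
  ## merge antipodal lobe pairs into axial fixels
  dirs <- tess$dirs[peaks, , drop = FALSE]
  used <- rep(FALSE, length(peaks))
  od <- NULL; oa <- NULL
  ord <- order(-vals[peaks])
  for (i in ord) {
    if (used[i]) next
    used[i] <- TRUE
    m <- mass[i]; d <- dirs[i, ]
    if (any(!used)) {
      ct <- -(dirs[!used, , drop = FALSE] %*% d)   # cos to the antipode
      j <- which(!used)[which.max(ct)]
      if (max(ct) > cos(15 * pi / 180)) {
        m <- m + mass[j]
        used[j] <- TRUE
      }
    }
    od <- rbind(od, d); oa <- c(oa, m)
  }
  list(dir = unitize(od), afd = pmax(0, oa))
}

adjacency_list <- function(edges, nv) {
  nb <- vector("list", nv)
  all_i <- c(edges[, 1], edges[, 2])
  all_j <- c(edges[, 2], edges[, 1])
  o <- order(all_i)
  split(all_j[o], all_i[o])
}
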