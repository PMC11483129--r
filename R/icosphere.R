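#' Recursively subdivided icosahedral sphere mesh
#'
#' Builds the standard icosphere used as the surface template: the 12-vertex
#' icosahedron subdivided `order` times (each triangle split into four, new
#' vertices projected back to the sphere), giving `10 * 4^order + 2` vertices.
#' Order 5 yields 10,242 vertices per hemisphere, so two hemispheres match the
#' 20,484-vertex template convention used for surface registration.
#'
#' @param order non-negative integer subdivision order
#' @param radius sphere radius in mm
#' @return list with `vertices` (V x 3, world mm) and `faces` (F x 3, 1-based,
#'   counter-clockwise seen from outside)
#' @examples
#' ico <- make_icosphere(2)
#' nrow(ico$vertices)  # 162
#' @export
make_icosphere <- function(order = 3, radius = 1) {
  stopifnot(order >= 0, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- unitize(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(order)) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- !duplicated(key)
    mid_id <- match(key, key[uk]) + nrow(v)
    mids <- unitize((v[e[uk, 1], , drop = FALSE] + v[e[uk, 2], , drop = FALSE]) / 2)
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    f <- rbind(
      cbind(f[, 1], m12, m31),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23),
      cbind(m12, m23, m31))
  }
  storage.mode(f) <- "integer"
  dimnames(f) <- NULL
  list(vertices = v * radius, faces = f)
}

## Area-weighted outward vertex normals of a triangle mesh.
vertex_normals <- function(vertices, faces) {
  a <- vertices[faces[, 2], ] - vertices[faces[, 1], ]
  b <- vertices[faces[, 3], ] - vertices[faces[, 1], ]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  vn <- matrix(0, nrow(vertices), 3)
  for (c in 1:3) {
    for (ax in 1:3) {
      acc <- rowsum(fn[, ax], faces[, c])
      vn[as.integer(rownames(acc)), ax] <- vn[as.integer(rownames(acc)), ax] + acc[, 1]
    }
  }
  unitize(vn)
}

## Undirected unique edge list of a triangle mesh (m x 2, v1 < v2).
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(paste(e[, 1], e[, 2])), , drop = FALSE]
}

## Euler characteristic V - E + F (2 per closed genus-0 component).
euler_characteristic <- function(vertices, faces) {
  nrow(vertices) - nrow(mesh_edges(faces)) + nrow(faces)
}
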