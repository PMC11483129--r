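test_that("one streamline per vertex, first segment perpendicular to the surface", {
  sl <- sphere_streamlines()
  ph <- sphere_phantom()
  expect_equal(length(sl$n_points), nrow(ph$surface$vertices))
  expect_identical(sl$seed_vertex_id, seq_len(nrow(ph$surface$vertices)))
  p0 <- t(sl$points[1, , ]); p1 <- t(sl$points[2, , ])
  seg <- unit_rows(p1 - p0)
  ang <- acos(pmin(1, rowSums(seg * (-ph$surface$normals)))) * 180 / pi
  expect_gte(mean(ang < 5), 0.99)
})

test_that("streamlines are radial: depth-1.5 points at 18.5 mm, 5 mm endpoint near r = 15", {
  sl <- sphere_streamlines()
  dp <- depth_points(sl, c(0, 0.5, 1, 1.5, 2))
  r15 <- radius_of(dp[, 4, ])
  expect_true(all(abs(r15 - 18.5) <= 0.1))
  ## endpoint after the full 5 mm of arc: within 0.15 mm of the radial target
  ph <- sphere_phantom()
  ends <- t(sapply(seq_along(sl$n_points), function(i) sl$points[sl$n_points[i], , i]))
  targets <- unit_rows(t(sapply(seq_along(sl$n_points), function(i) sl$points[1, , i]))) * 15
  expect_lt(max(sqrt(rowSums((ends - targets)^2))), 0.15)
})

test_that("trajectories stay on the seed ray and never cross", {
  sl <- sphere_streamlines()
  dev <- vapply(seq_along(sl$n_points), function(i) {
    P <- sl$points[seq_len(sl$n_points[i]), , i, drop = FALSE][, , 1, drop = TRUE]
    u <- P[1, ] / sqrt(sum(P[1, ]^2))
    lat <- P - (P %*% u) %*% t(u)
    max(sqrt(rowSums(lat^2)))
  }, numeric(1))
  expect_lt(max(dev), 0.2)
})

test_that("arc-length bookkeeping is exact step arithmetic", {
  sl <- sphere_streamlines()
  expect_equal(sl$arc_length, (sl$n_points - 1) * sl$step, tolerance = 1e-12)
  ## consecutive point spacing equals the step
  i <- which.max(sl$n_points)
  P <- sl$points[seq_len(sl$n_points[i]), , i, drop = FALSE][, , 1, drop = TRUE]
  d <- sqrt(rowSums(diff(P)^2))
  expect_equal(d, rep(sl$step, length(d)), tolerance = 1e-9)
})

test_that("max_length = 0 returns single seed points terminated at max_length", {
  ph <- sphere_phantom()
  sl0 <- trace_streamlines(ph, sphere_gradient(), max_length = 0)
  expect_true(all(sl0$n_points == 1))
  expect_true(all(sl0$termination == "max_length"))
  expect_true(all(sl0$arc_length == 0))
})

test_that("depth interpolation: depth 0 is the seed, beyond-arc depths are missing", {
  sl <- sphere_streamlines()
  dp <- depth_points(sl, c(0, 1.5))
  p0 <- t(sl$points[1, , ])
  expect_equal(dp[, 1, ], p0, tolerance = 1e-12)
  ## a truncated streamline yields NA at deeper samples, no error
  short <- get_streamline(sl, 1)
  short$points <- short$points[1:13, , drop = FALSE]  # 1.2 mm of arc
  short$arc_length <- 1.2
  out <- depth_points(short, c(0, 1, 2))
  expect_false(anyNA(out[1:2, ]))
  expect_true(all(is.na(out[3, ])))
  expect_error(depth_points(sl, c(-1, 0)), "nonnegative")
})

test_that("slab streamlines are straight and perpendicular to the boundary plane", {
  ph <- slab_phantom()
  ## seed from a small set of synthetic "vertices" on the top plane
  f <- solve_laplace(ph, boundary = "voxel")
  g <- gradient_field(f)
  ph$surface <- list(vertices = cbind(seq(5, 11), 8, 11),
                     normals = matrix(rep(c(0, 0, 1), 7), ncol = 3, byrow = TRUE))
  sl <- trace_streamlines(ph, g, max_length = 4)
  for (i in seq_len(7)) {
    P <- sl$points[seq_len(sl$n_points[i]), , i, drop = FALSE][, , 1, drop = TRUE]
    expect_lt(max(abs(P[, 1] - P[1, 1])), 0.1)   # no lateral drift
    expect_lt(max(abs(P[, 2] - P[1, 2])), 0.1)
    expect_true(all(diff(P[, 3]) < 0))           # descends toward the ventricle plane
  }
})
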