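test_that("classify_afd handles the canonical configurations", {
  radial_tangential <- list(dir = rbind(c(0, 0, 1), c(1, 0, 0)), afd = c(0.4, 0.3))
  expect_equal(classify_afd(radial_tangential, c(0, 0, 1)),
               c(total = 0.7, par = 0.4, tan = 0.3))
  ## single fixel beyond the 45 degree cutoff: all mass is tangential
  deg60 <- list(dir = matrix(c(sin(pi / 3), 0, cos(pi / 3)), 1), afd = 0.5)
  expect_equal(classify_afd(deg60, c(0, 0, 1)), c(total = 0.5, par = 0, tan = 0.5))
  expect_equal(classify_afd(list(dir = matrix(numeric(0), 0, 3), afd = numeric(0)),
                            c(0, 0, 1)),
               c(total = 0, par = 0, tan = 0))
})

test_that("single-winner rule picks the closest fixel (exhaustive check)", {
  ang <- c(10, 20, 50, 80) * pi / 180
  fx <- list(dir = cbind(sin(ang), 0, cos(ang)), afd = c(0.1, 0.9, 0.3, 0.2))
  got <- classify_afd(fx, c(0, 0, 1))
  ## brute force: among fixels within the cutoff, only the minimum-angle one
  ## may be parallel, whatever its density
  within <- which(ang < pi / 4)
  expect_equal(unname(got["par"]), fx$afd[within[which.min(ang[within])]])
  expect_equal(unname(got["total"] - got["par"]), unname(got["tan"]))
})

test_that("classification is invariant to sign flips and list order", {
  fx <- list(dir = rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)), afd = c(0.4, 0.3, 0.2))
  base <- classify_afd(fx, c(0, 0, 1))
  flipped <- list(dir = -fx$dir, afd = fx$afd)
  expect_equal(classify_afd(flipped, c(0, 0, 1)), base)
  perm <- sample(3)
  reord <- list(dir = fx$dir[perm, ], afd = fx$afd[perm])
  expect_equal(classify_afd(reord, c(0, 0, 1)), base)
  expect_equal(classify_afd(fx, -c(0, 0, 1)), base)
})

test_that("a pure radial field samples as zero tangential density everywhere", {
  ph <- sphere_phantom()
  ff <- plant_fixel_field(ph, tangential_profile = function(d) rep(0, length(d)),
                          subject = subject_spec(seed = 2), noise_sd = 0)
  ds <- sample_depth_profiles(ff, sphere_streamlines())
  expect_lt(max(abs(ds[, , "tan"]), na.rm = TRUE), 1e-9)
  expect_identical(attr(ds, "depths"), c(0, 0.5, 1, 1.5, 2))
})

test_that("sampled tangential density matches the generator profile at 1.5 mm", {
  ph <- sphere_phantom()
  sp <- subject_spec(tan_amplitude = 1.5, seed = 3)
  ff <- plant_fixel_field(ph, subject = sp, roi_id = 3, noise_sd = 0)
  ds <- sample_depth_profiles(ff, sphere_streamlines())
  dp <- depth_points(sphere_streamlines(), c(0, 0.5, 1, 1.5, 2))
  roi <- roi_labels_at(ph, dp[, 4, ])
  tan15 <- ds[, 4, "tan"]
  expect_equal(median(tan15[roi == 3], na.rm = TRUE),
               default_tangential_profile(1.5) * 1.5, tolerance = 0.05)
  expect_equal(median(tan15[roi != 3], na.rm = TRUE),
               default_tangential_profile(1.5), tolerance = 0.05)
  ## tan = total - par holds to machine precision at every sample
  expect_equal(ds[, , "tan"], ds[, , "total"] - ds[, , "par"], tolerance = 1e-15)
})

test_that("a single-depth request gives the boundary classification only", {
  ph <- tiny_phantom()
  ff <- plant_fixel_field(ph, subject = subject_spec(seed = 1), noise_sd = 0)
  f <- solve_laplace(ph)
  sl <- trace_streamlines(ph, gradient_field(f))
  ds <- sample_depth_profiles(ff, sl, depths = 0)
  expect_equal(dim(ds), c(nrow(ph$surface$vertices), 1, 3))
})

test_that("surface smoothing: identity at fwhm 0, exact constant preservation", {
  ph <- sphere_phantom()
  v <- rnorm(nrow(ph$surface$vertices))
  expect_identical(smooth_surface_metric(ph$surface, v, fwhm = 0), v)
  cons <- rep(3.7, length(v))
  expect_equal(smooth_surface_metric(ph$surface, cons, fwhm = 10), cons,
               tolerance = 1e-12)
  ## missing vertices stay missing, others remain finite
  v[c(5, 50)] <- NA
  sm <- smooth_surface_metric(ph$surface, v, fwhm = 10)
  expect_true(all(is.na(sm[c(5, 50)])))
  expect_false(anyNA(sm[-c(5, 50)]))
})

test_that("impulse response width is within 15% of the requested FWHM", {
  ph <- sphere_phantom(3)
  nv <- nrow(ph$surface$vertices)
  imp <- numeric(nv); imp[1] <- 1
  sm <- smooth_surface_metric(ph$surface, imp, fwhm = 15)
  ## brute-force geodesic distances along mesh edges
  e <- ufiber:::mesh_edges(ph$surface$faces)
  w <- sqrt(rowSums((ph$surface$vertices[e[, 1], ] - ph$surface$vertices[e[, 2], ])^2))
  g <- igraph::make_graph(t(e), n = nv, directed = FALSE)
  d <- as.vector(igraph::distances(g, v = 1, weights = w))
  half <- max(sm) / 2
  ## FWHM = twice the radius where the response crosses half maximum
  ord <- order(d)
  below <- ord[which(sm[ord] <= half)]
  r_half <- d[below[1]]
  fw <- 2 * r_half
  expect_lt(abs(fw - 15) / 15, 0.15)
})
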