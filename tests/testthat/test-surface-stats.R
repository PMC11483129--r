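test_that("vertex-wise correlation recovers exact and degenerate cases", {
  set.seed(4)
  n <- 12; nv <- 6
  Y <- matrix(rnorm(n * nv), n)
  beh <- Y[, 3]                       # identity at vertex 3
  vs <- vertexwise_correlation(Y, beh)
  expect_equal(vs$r_map[3], 1)
  expect_equal(vs$r2_map, vs$r_map^2)
  ## zero-variance vertex is missing and counted
  Y2 <- Y; Y2[, 5] <- 2
  vs2 <- vertexwise_correlation(Y2, rnorm(n))
  expect_true(is.na(vs2$r_map[5]))
  expect_gte(vs2$n_zero_variance, 1)
  ## fewer than 4 complete subjects -> missing
  Y3 <- Y; Y3[1:10, 2] <- NA
  vs3 <- vertexwise_correlation(Y3, beh)
  expect_true(is.na(vs3$r_map[2]))
})

test_that("r map is invariant under affine rescaling of the behavior", {
  set.seed(5)
  Y <- matrix(rnorm(20 * 8), 20)
  b <- rnorm(20)
  r1 <- vertexwise_correlation(Y, b)$r_map
  r2 <- vertexwise_correlation(Y, 3 * b - 100)$r_map
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("critical r matches the quoted threshold and a bisection oracle", {
  expect_equal(round(critical_r(29, 0.05), 3), 0.355)
  expect_equal(critical_r(29, 1), 0)
  ## bisection of the p-value function at df = 8
  pfun <- function(r, df) 2 * pt(-abs(r * sqrt(df / (1 - r^2))), df)
  lo <- 0; hi <- 0.999999
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (pfun(mid, 8) > 0.05) lo <- mid else hi <- mid
  }
  expect_equal(critical_r(8, 0.05), hi, tolerance = 1e-6)
})

test_that("type-I error rate of the vertex test is nominal under the null", {
  set.seed(6)
  n <- 40; nv <- 4000
  Y <- matrix(rnorm(n * nv), n)
  vs <- vertexwise_correlation(Y, rnorm(n))
  expect_lt(abs(mean(vs$p_map < 0.05) - 0.05), 0.012)
})

test_that("cluster correction finds a planted patch and leaves the null empty", {
  ph <- sphere_phantom()
  nv <- nrow(ph$surface$vertices)
  roi <- ph$roi_labels
  set.seed(7)
  n <- 60
  b <- rnorm(n)
  Y <- matrix(rnorm(n * nv), n)
  Y[, roi == 2] <- Y[, roi == 2] + 2 * b   # strong planted association
  vs <- vertexwise_correlation(Y, b)
  vc <- cluster_correction(vs, ph$surface, p_cft = 0.001, n_perm = 199,
                           alpha_cluster = 0.05, seed = 1)
  expect_gte(length(vc$clusters), 1)
  sig <- vc$clusters[vapply(vc$clusters, `[[`, logical(1), "significant")]
  expect_gte(length(sig), 1)
  hit <- rep(FALSE, nv); for (cl in sig) hit[cl$vertices] <- TRUE
  expect_gt(2 * sum(hit & roi == 2) / (sum(hit) + sum(roi == 2)), 0.5)
  ## every cluster vertex passes the forming threshold; sets are disjoint
  allv <- unlist(lapply(vc$clusters, `[[`, "vertices"))
  expect_false(any(duplicated(allv)))
  expect_true(all(vs$p_map[allv] < 0.001))
  ## permutation p values live on the admissible grid
  ps <- vapply(vc$clusters, `[[`, numeric(1), "p_cluster")
  expect_true(all(ps >= 1 / 200 & ps <= 1))
  ## reproducibility under the seed
  vc2 <- cluster_correction(vs, ph$surface, p_cft = 0.001, n_perm = 199,
                            alpha_cluster = 0.05, seed = 1)
  expect_identical(vc$null_max_size, vc2$null_max_size)
})

test_that("constant behavior yields an empty, crash-free result", {
  ph <- tiny_phantom()
  nv <- nrow(ph$surface$vertices)
  Y <- matrix(rnorm(10 * nv), 10)
  vs <- vertexwise_correlation(Y, rep(1, 10))
  expect_true(all(is.na(vs$r_map)))
  vc <- cluster_correction(vs, ph$surface, n_perm = 100, seed = 1)
  expect_equal(length(vc$clusters), 0)
})

test_that("ROI aggregation equals brute-force counting on a toy labeling", {
  ph <- tiny_phantom()
  nv <- nrow(ph$surface$vertices)
  labels <- rep(1:3, length.out = nv)
  fake <- list(r_map = seq(-1, 1, length.out = nv),
               clusters = list(list(vertices = 1:10, significant = TRUE),
                               list(vertices = 20:25, significant = FALSE)))
  rs <- roi_aggregate(fake, labels)
  for (k in 1:3) {
    vs <- which(labels == k)
    expect_equal(rs$n_vertices[k], length(vs))
    expect_equal(rs$n_significant[k], sum(vs %in% 1:10))
    expect_equal(rs$fraction_significant[k], sum(vs %in% 1:10) / length(vs))
  }
  ## no significant clusters -> all fractions zero
  rs0 <- roi_aggregate(list(r_map = fake$r_map, clusters = list()), labels)
  expect_true(all(rs0$fraction_significant == 0))
})
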