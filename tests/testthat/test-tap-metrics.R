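test_that("tap-stimulus pairing: arithmetic, tie rule, and assignment optimality", {
  p <- pair_taps(c(0, 750, 1500), c(-50, 700, 1480), 750)
  expect_equal(p$pairs$asynchrony, c(-50, -50, -20))
  ## tap exactly at the midpoint boundary goes to the earlier stimulus
  p2 <- pair_taps(c(0, 750), 375, 750)
  expect_equal(p2$pairs$stimulus, 0)
  ## jittered streams match the exhaustive minimum-cost monotone assignment
  set.seed(11)
  for (rep in 1:20) {
    stim <- (0:9) * 600
    taps <- stim + runif(10, -140, 140)
    got <- pair_taps(stim, taps, 600)
    ## DP oracle over monotone one-to-one assignments with |d| <= 300:
    ## maximize matches, then minimize total |d| (lexicographic)
    n <- 10
    cost <- abs(outer(taps, stim, "-"))
    BIG <- 1e7
    score <- matrix(0, n + 1, n + 1)   # taps x stimuli
    for (i in 1:n) for (j in 1:n) {
      match_sc <- if (cost[i, j] <= 300) score[i, j] + BIG - cost[i, j] else -Inf
      score[i + 1, j + 1] <- max(match_sc, score[i, j + 1], score[i + 1, j])
    }
    oracle_matches <- floor(score[n + 1, n + 1] / BIG + 0.5)
    oracle_cost <- oracle_matches * BIG - score[n + 1, n + 1]
    expect_equal(nrow(got$pairs), oracle_matches)
    expect_equal(sum(abs(got$pairs$asynchrony)), oracle_cost, tolerance = 1e-6)
  }
})

test_that("absolute asynchrony is the mean unsigned stimulus-tap difference", {
  p <- pair_taps(c(0, 750, 1500), c(-50, 700, 1480), 750)
  expect_equal(absolute_asynchrony(p), 40)
  perfect <- pair_taps(c(0, 750, 1500), c(0, 750, 1500), 750)
  expect_equal(absolute_asynchrony(perfect), 0)
  expect_true(is.na(absolute_asynchrony(data.frame(asynchrony = numeric(0))[0, , drop = FALSE])))
})

test_that("constant error and temporal variability use the stated conventions", {
  expect_equal(constant_error(c(760, 800, 780), 750), 30)
  expect_equal(constant_error(rep(750, 6), 750), 0)
  expect_true(is.na(constant_error(numeric(0), 750)))
  expect_equal(temporal_variability(rep(700, 6)), 0)
  expect_equal(temporal_variability(c(700, 800)), 70.71, tolerance = 1e-3)
})

test_that("lag-1 autocorrelation: hand value, trend sign, bounds", {
  expect_equal(as.numeric(lag1_autocorrelation(list(c(600, 700, 600, 700, 600, 700)))),
               -12500 / 15000, tolerance = 1e-12)
  expect_gt(as.numeric(lag1_autocorrelation(list(seq(600, 700, by = 20)))), 0)
  set.seed(2)
  for (i in 1:50) {
    r <- as.numeric(lag1_autocorrelation(list(rnorm(6))))
    expect_true(r >= -1 && r <= 1)
  }
  z <- lag1_autocorrelation(list(rep(5, 6), c(600, 700, 600, 700, 600, 700)))
  expect_equal(attr(z, "n_skipped"), 1)
})

test_that("trial validity applies the 30% / 40% thresholds", {
  iv <- c(700, 800, 760, 740, 755, 976)    # 976 deviates by 226 > 0.3 * 750
  v <- validate_trial(list(target_ms = 750, sync_intervals = iv, cont_intervals = iv))
  expect_false(v[["sync"]])
  expect_true(v[["cont"]])                  # 226 < 0.4 * 750 = 300
  v2 <- validate_trial(list(target_ms = 750, sync_intervals = rep(750, 6),
                            cont_intervals = rep(750, 6)))
  expect_true(all(v2))
})

test_that("subject summary equals hand-computed metrics on a built session", {
  mk_trial <- function(id, stim, sync_taps, cont_taps, target) {
    data.frame(trial_id = id, modality = "auditory", target_ms = target,
               epoch = c(rep("sync", length(stim) + length(sync_taps)),
                         rep("cont", length(cont_taps))),
               event_type = c(rep("stimulus", length(stim)),
                              rep("tap", length(sync_taps) + length(cont_taps))),
               onset_ms = c(stim, sync_taps, cont_taps))
  }
  stim <- (0:6) * 750
  t1 <- mk_trial(1, stim, stim - 30, max(stim) - 30 + cumsum(rep(760, 6)), 750)
  t2 <- mk_trial(2, stim, stim - 50, max(stim) - 50 + cumsum(c(700, 720, 740, 760, 780, 800)), 750)
  sess <- structure(list(events = rbind(t1, t2), subject_id = 1,
                         modality = "auditory", target_intervals = 750),
                    class = "tapping_session")
  sm <- summarize_subject(sess)
  expect_equal(sm$mean_abs_asynchrony, 40)               # (30 + 50) / 2
  expect_equal(sm$constant_error_sync, 0)                # taps shifted rigidly
  expect_equal(sm$constant_error_cont, mean(c(10, 0)))   # 760 vs 750 and mean 750
  expect_equal(sm$temporal_variability_cont, mean(c(0, sd(c(700, 720, 740, 760, 780, 800)))))
  expect_equal(sm$n_valid_trials, 2)
  ## a session of identical perfect trials gives all-zero metrics
  t3 <- mk_trial(1, stim, stim, max(stim) + cumsum(rep(750, 6)), 750)
  perf <- structure(list(events = t3, subject_id = 1, modality = "auditory",
                         target_intervals = 750), class = "tapping_session")
  sp <- summarize_subject(perf)
  expect_equal(sp$mean_abs_asynchrony, 0)
  expect_equal(sp$constant_error_sync, 0)
  expect_equal(sp$temporal_variability_sync, 0)
})

test_that("metrics are invariant to a global time shift", {
  sess <- simulate_tapping_session(subject_spec(seed = 5), "auditory",
                                   target_intervals = c(650, 750),
                                   trials_per_interval = 3)
  sm1 <- summarize_subject(sess)
  shifted <- sess
  shifted$events$onset_ms <- shifted$events$onset_ms + 12345
  sm2 <- summarize_subject(shifted)
  for (col in c("mean_abs_asynchrony", "constant_error_sync", "constant_error_cont",
                "temporal_variability_sync", "temporal_variability_cont", "lag1_autocorr"))
    expect_equal(sm1[[col]], sm2[[col]], tolerance = 1e-9)
})

test_that("absolute asynchrony dominates the signed mean (triangle inequality)", {
  set.seed(3)
  for (i in 1:20) {
    stim <- (0:6) * 700
    taps <- stim + rnorm(7, -40, 30)
    p <- pair_taps(stim, taps, 700)
    expect_gte(absolute_asynchrony(p) + 1e-12, abs(mean(p$pairs$asynchrony)))
  }
})
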