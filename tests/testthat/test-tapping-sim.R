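test_that("noise-free limit: constant asynchronies and exact timekeeper intervals", {
  sp <- subject_spec(asynchrony_scale = 40, phase_correction_alpha = 1,
                     timekeeper_sd = 0, motor_sd = 0)
  s <- simulate_tapping_session(sp, "auditory", target_intervals = 750,
                                trials_per_interval = 2)
  tr <- ufiber:::session_trials(s)[[1]]
  a <- tr$sync_taps - tr$stimulus_onsets
  expect_equal(a, rep(-40, length(a)), tolerance = 1e-9)
  ## continuation intervals equal the regressed timekeeper mean exactly
  expect_equal(unique(round(tr$cont_intervals, 9)), 750 + 0.3 * (654 - 750))
})

test_that("phase-correction gain outside (0,2) is rejected as unstable", {
  expect_error(subject_spec(phase_correction_alpha = 2), "0, 2")
  expect_error(subject_spec(phase_correction_alpha = 0), "0, 2")
  sp <- subject_spec()
  sp$phase_correction_alpha <- 2.5
  expect_error(simulate_tapping_session(sp, "auditory"), "unstable")
})

test_that("mean asynchrony is negative in both modalities, larger for visual", {
  sp <- subject_spec(seed = 21)
  aud <- simulate_tapping_session(sp, "auditory", trials_per_interval = 5, seed = 1)
  vis <- simulate_tapping_session(sp, "visual", trials_per_interval = 5, seed = 1)
  signed <- function(s) {
    mean(unlist(lapply(ufiber:::session_trials(s), function(tr)
      tr$sync_taps - tr$stimulus_onsets)))
  }
  expect_lt(signed(aud), 0)
  expect_lt(signed(vis), 0)
  ma <- mean(summarize_subject(aud)$mean_abs_asynchrony)
  mv <- mean(summarize_subject(vis)$mean_abs_asynchrony)
  expect_gt(mv, ma)
})

test_that("continuation lag-1 autocorrelation matches the two-level closed form", {
  lag1_mc <- function(sp, n_trials, len, seed0) {
    s <- simulate_tapping_session(sp, "auditory", target_intervals = 750,
                                  trials_per_interval = n_trials,
                                  n_cont = len, seed = seed0)
    mean(vapply(ufiber:::session_trials(s), function(tr) {
      d <- tr$cont_intervals - mean(tr$cont_intervals)
      sum(d[-length(d)] * d[-1]) / sum(d^2)
    }, numeric(1)))
  }
  ## motor noise only: -0.5 in the long-trial limit
  r_motor <- lag1_mc(subject_spec(timekeeper_sd = 0, motor_sd = 10), 400, 100, 5)
  expect_lt(abs(r_motor - (-0.5)), 0.02)
  ## equal noise: -sigma_M^2 / (sigma_T^2 + 2 sigma_M^2) = -1/3
  r_equal <- lag1_mc(subject_spec(timekeeper_sd = 10, motor_sd = 10), 400, 100, 6)
  expect_lt(abs(r_equal - (-1 / 3)), 0.02)
})

test_that("constant error line crosses zero at the configured indifference interval", {
  sp <- subject_spec(indifference_interval = 654, seed = 31)
  s <- simulate_tapping_session(sp, "auditory", trials_per_interval = 40, seed = 2)
  sm <- summarize_subject(s)
  expect_equal(unname(indifference_interval(sm)), 654, tolerance = 10)
  ## bias effect: overestimate short, underestimate long targets
  expect_gt(sm$constant_error_cont[sm$target_ms == 550], 0)
  expect_lt(sm$constant_error_cont[sm$target_ms == 950], 0)
})

test_that("sessions are byte-identical under a fixed seed", {
  sp <- subject_spec(seed = 8)
  a <- simulate_tapping_session(sp, "auditory", trials_per_interval = 2, seed = 3)
  b <- simulate_tapping_session(sp, "auditory", trials_per_interval = 2, seed = 3)
  expect_identical(a$events, b$events)
  c <- simulate_tapping_session(sp, "auditory", trials_per_interval = 2, seed = 4)
  expect_false(identical(a$events, c$events))
})

test_that("simulated absolute asynchrony tracks the subject's planted level", {
  levels <- c(25, 35, 45, 60)
  got <- vapply(seq_along(levels), function(i) {
    sp <- subject_spec(asynchrony_scale = levels[i], seed = 100 + i)
    s <- simulate_tapping_session(sp, "auditory", trials_per_interval = 10, seed = 1)
    mean(summarize_subject(s)$mean_abs_asynchrony)
  }, numeric(1))
  expect_true(all(diff(got) > 0))
  expect_equal(got, levels, tolerance = 0.15)
})
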