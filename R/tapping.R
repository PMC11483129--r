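#' Simulate one synchronization-continuation tapping session
#'
#' The synchronization epoch follows a linear phase-correction process on
#' the asynchronies,
#' \deqn{A_{n+1} = (1 - \alpha) A_n + T_n + M_{n+1} - M_n,}
#' with timekeeper noise T and differenced motor noise M, offset so the mean
#' asynchrony is negative with magnitude `asynchrony_scale` (taps anticipate
#' the metronome). The continuation epoch follows the two-level
#' timekeeper/motor model \eqn{I_n = C_n + M_{n+1} - M_n} whose timekeeper
#' mean is regressed toward the indifference interval with weight
#' `central_tendency`, producing the short-overestimate / long-underestimate
#' bias with zero constant error at the indifference interval. Visual
#' metronomes scale the mean asynchrony by `visual_scale` and both noise
#' sources by `visual_noise` (visual synchronization is less accurate and
#' more variable than auditory).
#'
#' @param subject a [subject_spec()]
#' @param modality `"auditory"` or `"visual"`
#' @param target_intervals ms, metronome intervals (default the five-tempo
#'   set 550...950 ms)
#' @param trials_per_interval trials per target interval
#' @param n_sync,n_cont intervals per epoch (>= 2)
#' @param seed integer session seed (combined with the subject seed)
#' @param visual_scale,visual_noise multipliers applied in visual mode (> 1)
#' @param central_tendency weight in [0, 1) of the regression toward the
#'   indifference interval
#' @return object of class `tapping_session`: `events` data frame with
#'   columns trial_id, modality, target_ms, epoch (sync/cont), event_type
#'   (stimulus/tap), onset_ms, plus `subject_id`
#' @export
simulate_tapping_session <- function(subject, modality = c("auditory", "visual"),
                                     target_intervals = c(550, 650, 750, 850, 950),
                                     trials_per_interval = 10,
                                     n_sync = 6, n_cont = 6, seed = 1,
                                     visual_scale = 1.5, visual_noise = 1.5,
                                     central_tendency = 0.3) {
  modality <- match.arg(modality)
  if (any(target_intervals <= 0)) stop("target intervals must be positive")
  if (n_sync < 2 || n_cont < 2) stop("n_sync and n_cont must be >= 2")
  a <- subject$phase_correction_alpha
  if (a <= 0 || a >= 2) stop("phase-correction gain outside (0, 2): unstable")

  lvl <- subject$asynchrony_scale
  sT <- subject$timekeeper_sd
  sM <- subject$motor_sd
  if (modality == "visual") {
    lvl <- lvl * visual_scale
    sT <- sT * visual_noise
    sM <- sM * visual_noise
  }
  ## asynchrony_scale is the subject's mean ABSOLUTE asynchrony level: pick
  ## the (negative) offset whose folded stationary distribution has that
  ## mean. Stationary variance of A_{n+1} = (1-a) A_n + T_n + M_{n+1} - M_n:
  b <- 1 - a
  sA <- sqrt((sT^2 + 2 * sM^2 * (1 - b)) / (1 - b^2))
  off <- solve_abs_offset(lvl, sA)

  sess_seed <- (as.numeric(subject$seed) * 1000003 + as.numeric(seed)) %% 2147483647
  ev <- with_seed(sess_seed, {
    rows <- vector("list", length(target_intervals) * trials_per_interval)
    trial <- 0L
    for (target in target_intervals) {
      mu_c <- target + central_tendency * (subject$indifference_interval - target)
      for (rep in seq_len(trials_per_interval)) {
        trial <- trial + 1L
        ## synchronization: n_sync + 1 metronome onsets, one tap each
        stim <- (0:n_sync) * target
        A <- numeric(n_sync + 1)
        nb <- 20L  # burn-in to reach the stationary law of the recursion
        M <- rnorm(nb + n_sync + 2, 0, sM)
        Tn <- rnorm(nb + n_sync + 1, 0, sT)
        a0 <- 0
        for (k in seq_len(nb)) a0 <- (1 - a) * a0 + Tn[k] + M[k + 1] - M[k]
        A[1] <- a0
        for (k in seq_len(n_sync)) {
          A[k + 1] <- (1 - a) * A[k] + Tn[nb + k] + M[nb + k + 1] - M[nb + k]
        }
        taps_sync <- stim + A - off
        ## continuation: n_cont self-paced intervals from the last sync tap
        C <- rnorm(n_cont, mu_c, sT)
        Mc <- rnorm(n_cont + 1, 0, sM)
        I <- C + Mc[-1] - Mc[-(n_cont + 1)]
        taps_cont <- taps_sync[n_sync + 1] + cumsum(I)
        rows[[trial]] <- data.frame(
          trial_id = trial,
          modality = modality,
          target_ms = target,
          epoch = c(rep("sync", 2 * (n_sync + 1)), rep("cont", n_cont)),
          event_type = c(rep("stimulus", n_sync + 1), rep("tap", n_sync + 1),
                         rep("tap", n_cont)),
          onset_ms = c(stim, taps_sync, taps_cont))
      }
    }
    do.call(rbind, rows)
  })
  structure(list(events = ev, subject_id = subject$seed, modality = modality,
                 n_sync = n_sync, n_cont = n_cont,
                 target_intervals = target_intervals),
            class = "tapping_session")
}

## Mean of |N(-o, s)| as a function of the offset o >= 0.
folded_mean <- function(o, s) {
  if (s == 0) return(o)
  s * sqrt(2 / pi) * exp(-o^2 / (2 * s^2)) + o * (1 - 2 * stats::pnorm(-o / s))
}

## Offset o with folded mean equal to `level`; 0 when the noise floor
## s * sqrt(2/pi) already exceeds the requested level.
solve_abs_offset <- function(level, s) {
  if (s == 0) return(level)
  if (level <= folded_mean(0, s)) return(0)
  stats::uniroot(function(o) folded_mean(o, s) - level,
                 lower = 0, upper = level + 4 * s, tol = 1e-8)$root
}

#' @export
print.tapping_session <- function(x, ...) {
  cat(sprintf("tapping session (%s): %d trials, targets %s ms\n", x$modality,
              max(x$events$trial_id), paste(x$target_intervals, collapse = "/")))
  invisible(x)
}

#' Generate a multi-subject cohort with a planted brain-behavior association
#'
#' Draws per-subject pairs (tangential amplitude, asynchrony scale) from a
#' bivariate normal and orthogonalizes them so the empirical correlation
#' equals `rho_planted` exactly (before unit conversion), then simulates
#' auditory and visual tapping sessions per subject and, optionally, plants
#' the per-subject fixel field. Subjects with higher U-fiber amplitude get
#' asynchronies closer to zero when `rho_planted < 0`, the association the
#' downstream statistics must recover.
#'
#' @param n_subjects >= 4
#' @param rho_planted target correlation in [-1, 1] between tangential
#'   amplitude and asynchrony scale
#' @param roi_id planted ROI label
#' @param seed integer cohort seed
#' @param phantom phantom in which fields are planted
#' @param make_fields if FALSE, skip field construction (use
#'   [plant_fixel_field()] with `truth$subject_specs[[i]]` on demand; avoids
#'   holding every subject's field in memory at large n)
#' @param sessions `"both"`, `"auditory"`, or `"none"`
#' @param trials_per_interval passed to [simulate_tapping_session()]
#' @return list with `fixel_fields` (or NULL), `sessions` (per subject, a
#'   list with `$auditory` / `$visual`), and `truth` (class `cohort_truth`:
#'   `rho_planted`, `roi_id`, `subject_specs`, `tan_amplitude`,
#'   `asynchrony_scale`)
#' @export
generate_cohort <- function(n_subjects, rho_planted = -0.6, roi_id = 3L,
                            seed = 1, phantom = NULL, make_fields = TRUE,
                            sessions = c("both", "auditory", "none"),
                            trials_per_interval = 10) {
  sessions <- match.arg(sessions)
  if (n_subjects < 4) stop("need at least 4 subjects")
  if (abs(rho_planted) > 1) stop("|rho_planted| must be <= 1")
  z <- with_seed(seed, matrix(rnorm(2 * n_subjects), ncol = 2))
  z1 <- as.vector(scale(z[, 1]))
  if (abs(rho_planted) == 1) {
    z2 <- sign(rho_planted) * z1
  } else {
    e <- stats::residuals(stats::lm(z[, 2] ~ z1))
    e <- as.vector(scale(e))
    z2 <- rho_planted * z1 + sqrt(1 - rho_planted^2) * e
  }
  amp <- 1 + 0.2 * z1
  async <- 40 + 12 * z2
  if (abs(rho_planted) < 1) {
    ## floor just above the simulator noise floor so the planted level is
    ## always realizable as a mean absolute asynchrony; skipped in the
    ## degenerate |rho| = 1 case where the relation must stay exactly affine
    amp <- pmax(0.05, amp)
    async <- pmax(22, async)
  }

  specs <- lapply(seq_len(n_subjects), function(i)
    subject_spec(tan_amplitude = amp[i], asynchrony_scale = async[i],
                 seed = seed * 1000L + i))
  truth <- structure(list(rho_planted = rho_planted, roi_id = roi_id,
                          subject_specs = specs, tan_amplitude = amp,
                          asynchrony_scale = async),
                     class = "cohort_truth")

  ses <- NULL
  if (sessions != "none") {
    ses <- lapply(specs, function(sp) {
      out <- list(auditory = simulate_tapping_session(
        sp, "auditory", trials_per_interval = trials_per_interval, seed = seed))
      if (sessions == "both")
        out$visual <- simulate_tapping_session(
          sp, "visual", trials_per_interval = trials_per_interval, seed = seed + 1)
      out
    })
  }
  fields <- NULL
  if (make_fields) {
    if (is.null(phantom)) phantom <- make_phantom()
    fields <- lapply(specs, function(sp)
      plant_fixel_field(phantom, subject = sp, roi_id = roi_id))
  }
  list(fixel_fields = fields, sessions = ses, truth = truth)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("cohort truth: %d subjects, planted rho %.2f in ROI %d (empirical %.3f)\n",
              length(x$subject_specs), x$rho_planted, x$roi_id,
              stats::cor(x$tan_amplitude, x$asynchrony_scale)))
  invisible(x)
}
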