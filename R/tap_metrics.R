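#' Pair taps with metronome stimuli
#'
#' Each tap is matched to its nearest stimulus provided the unsigned
#' difference is at most half the target interval; when two stimuli are
#' equidistant the earlier one wins, and when several taps claim one
#' stimulus the closest tap wins (the others stay unmatched).
#'
#' @param stimulus_onsets,tap_onsets ms, strictly increasing
#' @param target_ms metronome interval, ms
#' @return list with `pairs` (data frame stimulus, tap, asynchrony = tap -
#'   stimulus), `unmatched_taps`, `unmatched_stimuli`
#' @export
pair_taps <- function(stimulus_onsets, tap_onsets, target_ms) {
  stopifnot(length(stimulus_onsets) > 0, length(tap_onsets) > 0)
  s <- sort(stimulus_onsets)
  cand <- rep(NA_integer_, length(tap_onsets))
  if (length(s) == 1) {
    cand[] <- 1L
  } else {
    mids <- (s[-1] + s[-length(s)]) / 2
    i <- findInterval(tap_onsets, mids)
    ## findInterval puts a tap exactly on a midpoint into the later bin;
    ## the tie rule assigns it to the earlier stimulus
    on_mid <- i >= 1 & abs(tap_onsets - mids[pmax(i, 1)]) <= 1e-9
    cand <- i + 1L
    cand[on_mid] <- i[on_mid]
  }
  d <- abs(tap_onsets - s[cand])
  ok <- d <= target_ms / 2 + 1e-9
  cand[!ok] <- NA_integer_

  keep <- rep(FALSE, length(tap_onsets))
  for (st in unique(stats::na.omit(cand))) {
    claim <- which(!is.na(cand) & cand == st)
    keep[claim[which.min(d[claim])]] <- TRUE
  }
  pairs <- data.frame(stimulus = s[cand[keep]], tap = tap_onsets[keep])
  pairs$asynchrony <- pairs$tap - pairs$stimulus
  list(pairs = pairs,
       unmatched_taps = tap_onsets[!keep],
       unmatched_stimuli = setdiff(s, pairs$stimulus))
}

#' Mean absolute (unsigned) asynchrony
#'
#' @param pairs result of [pair_taps()] or a data frame with an
#'   `asynchrony` column
#' @return ms; NA when there are no pairs
#' @export
absolute_asynchrony <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- pairs$pairs
  if (is.null(pairs) || nrow(pairs) == 0) return(NA_real_)
  mean(abs(pairs$asynchrony))
}

#' Constant error (period accuracy)
#'
#' Mean produced interval minus the target interval.
#' @param produced_intervals ms
#' @param target ms
#' @return ms; NA for an empty list
#' @export
constant_error <- function(produced_intervals, target) {
  if (length(produced_intervals) == 0) return(NA_real_)
  mean(produced_intervals) - target
}

#' Temporal variability (period precision)
#'
#' Sample standard deviation (n - 1 denominator) of the produced intervals.
#' @param produced_intervals ms
#' @return ms; NA with fewer than 2 intervals
#' @export
temporal_variability <- function(produced_intervals) {
  if (length(produced_intervals) < 2) return(NA_real_)
  stats::sd(produced_intervals)
}

#' Lag-1 autocorrelation of produced intervals, averaged across trials
#'
#' Per trial, the mean-subtracted biased sample autocorrelation
#' \eqn{r_1 = \sum_t (x_t - \bar x)(x_{t+1} - \bar x) / \sum_t (x_t - \bar x)^2};
#' the trial values are then averaged arithmetically (no Fisher transform).
#' Zero-variance trials are skipped and counted.
#'
#' @param trial_interval_series list of numeric interval series (each of
#'   length >= 3)
#' @return unitless value in [-1, 1]; attribute `n_skipped` counts
#'   zero-variance trials
#' @export
lag1_autocorrelation <- function(trial_interval_series) {
  if (!is.list(trial_interval_series)) trial_interval_series <- list(trial_interval_series)
  r1 <- vapply(trial_interval_series, function(x) {
    if (length(x) < 3) stop("each series needs at least 3 intervals")
    d <- x - mean(x)
    den <- sum(d^2)
    if (den == 0) return(NA_real_)
    sum(d[-length(d)] * d[-1]) / den
  }, numeric(1))
  out <- mean(r1, na.rm = TRUE)
  attr(out, "n_skipped") <- sum(is.na(r1))
  out
}

#' Trial validity filter
#'
#' A trial epoch is valid when every produced interval deviates from the
#' target by less than `tol * target`: 30% during synchronization, 40%
#' during continuation.
#'
#' @param trial list with `target_ms`, `sync_intervals`, `cont_intervals`
#'   (either may be NULL)
#' @param sync_tol,cont_tol relative tolerances
#' @return named logical vector `c(sync = , cont = )` (NA for an absent
#'   epoch)
#' @export
validate_trial <- function(trial, sync_tol = 0.30, cont_tol = 0.40) {
  chk <- function(iv, tol) {
    if (is.null(iv) || length(iv) == 0) return(NA)
    all(abs(iv - trial$target_ms) < tol * trial$target_ms)
  }
  c(sync = chk(trial$sync_intervals, sync_tol),
    cont = chk(trial$cont_intervals, cont_tol))
}

## Split a session's events into per-trial stimulus/tap streams and
## produced-interval series.
session_trials <- function(session) {
  ev <- session$events
  lapply(split(ev, ev$trial_id), function(tr) {
    stim <- tr$onset_ms[tr$event_type == "stimulus"]
    tap_s <- tr$onset_ms[tr$event_type == "tap" & tr$epoch == "sync"]
    tap_c <- tr$onset_ms[tr$event_type == "tap" & tr$epoch == "cont"]
    list(trial_id = tr$trial_id[1], target_ms = tr$target_ms[1],
         modality = tr$modality[1],
         stimulus_onsets = stim, sync_taps = tap_s, cont_taps = tap_c,
         sync_intervals = diff(tap_s),
         cont_intervals = diff(c(tail(tap_s, 1), tap_c)))
  })
}

#' Per-subject behavioral summary
#'
#' Computes the four rhythmic-performance metrics per modality and target
#' interval on valid trials only: mean absolute asynchrony (phase accuracy,
#' synchronization epoch), constant error (period accuracy) and temporal
#' variability (period precision) for both epochs (per-trial values averaged
#' across trials), and the lag-1 autocorrelation of the synchronization
#' inter-tap intervals. Epoch validity follows [validate_trial()]; cells
#' with no valid trial are NA with a warning.
#'
#' @param session a [simulate_tapping_session()] session (or any object with
#'   the same `events` layout)
#' @param sync_tol,cont_tol validity tolerances, see [validate_trial()]
#' @return data frame of class `behavioral_summary`, one row per (subject,
#'   modality, target): `mean_abs_asynchrony`, `constant_error_sync`,
#'   `constant_error_cont`, `temporal_variability_sync`,
#'   `temporal_variability_cont`, `lag1_autocorr`, `n_valid_trials`,
#'   `n_trials`
#' @export
summarize_subject <- function(session, sync_tol = 0.30, cont_tol = 0.40) {
  trials <- session_trials(session)
  targets <- sort(unique(vapply(trials, `[[`, numeric(1), "target_ms")))
  out <- lapply(targets, function(tg) {
    tt <- Filter(function(tr) tr$target_ms == tg, trials)
    valid <- t(vapply(tt, validate_trial, c(sync = TRUE, cont = TRUE),
                      sync_tol = sync_tol, cont_tol = cont_tol))
    vs <- which(valid[, "sync"] %in% TRUE)
    vc <- which(valid[, "cont"] %in% TRUE)
    if (length(vs) == 0 || length(vc) == 0)
      warning(sprintf("no valid trials for target %g ms", tg))
    asyn <- if (length(vs)) mean(vapply(tt[vs], function(tr)
      absolute_asynchrony(pair_taps(tr$stimulus_onsets, tr$sync_taps, tg)),
      numeric(1))) else NA_real_
    ce_s <- if (length(vs)) mean(vapply(tt[vs], function(tr)
      constant_error(tr$sync_intervals, tg), numeric(1))) else NA_real_
    ce_c <- if (length(vc)) mean(vapply(tt[vc], function(tr)
      constant_error(tr$cont_intervals, tg), numeric(1))) else NA_real_
    tv_s <- if (length(vs)) mean(vapply(tt[vs], function(tr)
      temporal_variability(tr$sync_intervals), numeric(1))) else NA_real_
    tv_c <- if (length(vc)) mean(vapply(tt[vc], function(tr)
      temporal_variability(tr$cont_intervals), numeric(1))) else NA_real_
    l1 <- if (length(vs)) as.numeric(lag1_autocorrelation(
      lapply(tt[vs], `[[`, "sync_intervals"))) else NA_real_
    data.frame(subject_id = session$subject_id, modality = session$modality,
               target_ms = tg, mean_abs_asynchrony = asyn,
               constant_error_sync = ce_s, constant_error_cont = ce_c,
               temporal_variability_sync = tv_s,
               temporal_variability_cont = tv_c,
               lag1_autocorr = l1,
               n_valid_trials = sum(valid[, "sync"] & valid[, "cont"], na.rm = TRUE),
               n_trials = length(tt))
  })
  out <- do.call(rbind, out)
  class(out) <- c("behavioral_summary", class(out))
  out
}

#' Estimate the indifference interval from continuation constant errors
#'
#' Fits the linear trend of constant error against target interval
#' (continuation epoch) and returns its zero crossing: the target duration
#' that is neither over- nor underestimated.
#'
#' @param summary a [summarize_subject()] data frame (or several rbind-ed)
#' @return ms
#' @export
indifference_interval <- function(summary) {
  fit <- stats::lm(constant_error_cont ~ target_ms, data = summary)
  -coef(fit)[1] / coef(fit)[2]
}
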