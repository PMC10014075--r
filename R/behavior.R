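#' Calibrated tail-deflection trace
#'
#' @param deflection_mm signed tail deflection in mm (negative = away from the
#'   stimulated eye), uniformly sampled.
#' @param fps sampling rate, Hz.
#' @param px_per_mm pixel calibration (> 0), or `NA` for an uncalibrated trace
#'   in pixels.
#' @param t0 time of the first sample, seconds (default 0).
#' @return An object of class `tail_trace`.
#' @export
tail_trace <- function(deflection_mm, fps, px_per_mm = NA_real_, t0 = 0) {
  stopifnot(is.numeric(deflection_mm), fps > 0)
  if (!is.na(px_per_mm) && px_per_mm <= 0) stop("`px_per_mm` must be > 0")
  structure(list(deflection = as.numeric(deflection_mm), fps = fps,
                 px_per_mm = px_per_mm, t0 = t0,
                 calibrated = !is.na(px_per_mm)),
            class = "tail_trace")
}

#' @export
print.tail_trace <- function(x, ...) {
  cat(sprintf("<tail_trace> %d samples at %g Hz (%.1f s), %s\n",
              length(x$deflection), x$fps, length(x$deflection) / x$fps,
              if (x$calibrated) "calibrated (mm)" else "uncalibrated (px)"))
  invisible(x)
}

trace_times <- function(trace) trace$t0 + (seq_along(trace$deflection) - 1) / trace$fps

#' Tail deflection from tracked tail points
#'
#' The tail deflection of a head-embedded larva is the signed mean
#' perpendicular distance of 10 equidistant tail points from the midline
#' (the embedded head axis), converted to mm.
#'
#' @param points numeric matrix or data.frame with 20 columns
#'   `x1..x10, y1..y10` (pixel coordinates per frame).
#' @param midline list with `point = c(x, y)` and `direction = c(dx, dy)`
#'   defining the head axis; the sign of the deflection is the sign of the
#'   cross product `direction x (p - point)`.
#' @param fps frame rate, Hz.
#' @param px_per_mm pixel calibration.
#' @param max_gap maximum run of missing frames (NA in any coordinate) to
#'   interpolate linearly; longer gaps stay NA.
#' @return A [tail_trace()]; frames that were interpolated are flagged in the
#'   `interpolated` attribute of the deflection.
#' @export
tail_deflection <- function(points, midline, fps, px_per_mm, max_gap = 3) {
  points <- as.matrix(points)
  if (ncol(points) != 20)
    stop("`points` must have 20 columns: x1..x10 then y1..y10")
  d <- midline$direction / sqrt(sum(midline$direction^2))
  px <- points[, 1:10, drop = FALSE] - midline$point[1]
  py <- points[, 11:20, drop = FALSE] - midline$point[2]
  # signed perpendicular distance: cross product of unit axis with point vector
  perp <- d[1] * py - d[2] * px
  defl <- rowMeans(perp)
  bad <- !is.finite(defl)
  interp <- logical(length(defl))
  if (any(bad)) {
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ok <- which(!bad)
    for (i in which(r$values)) {
      if (r$lengths[i] <= max_gap && starts[i] > 1 && ends[i] < length(defl)) {
        idx <- starts[i]:ends[i]
        defl[idx] <- stats::approx(ok, defl[ok], xout = idx)$y
        interp[idx] <- TRUE
      }
    }
  }
  tr <- tail_trace(defl / px_per_mm, fps = fps, px_per_mm = px_per_mm)
  attr(tr$deflection, "interpolated") <- interp
  tr
}

#' Detect tail flicks in a deflection trace
#'
#' A flick is detected when the absolute tail deflection exceeds the peak
#' threshold (0.4 mm, i.e. 20 px); its onset is the last upward crossing of
#' the onset threshold (0.2 mm / 10 px) before the peak, located by linear
#' interpolation between samples. Peaks closer together than the refractory
#' gap are merged into the larger event. The counter-bend is the largest
#' opposite-sign excursion within a short window after the peak.
#'
#' @param trace a [tail_trace()]. If uncalibrated, the thresholds are applied
#'   in pixels (10/20 px) with a warning.
#' @param peak_thresh_mm,onset_thresh_mm detection thresholds, mm.
#' @param refractory_s minimum separation between event peaks, s.
#' @param counter_window_s search window after the peak for the counter-bend, s.
#' @param smooth_s moving-average width applied before detection, s (0
#'   disables). A tail bend lasts ~0.2 s; a 50 ms low-pass suppresses
#'   single-sample noise excursions past the peak threshold at high frame
#'   rates while attenuating the bend peak by under 2%.
#' @return A data.frame of class `flick_events` with columns `onset_s`,
#'   `peak_s`, `peak_amp_mm` (signed), `counter_peak_amp_mm` (signed or NA)
#'   and `provenance` (filled by [assign_responses()], `NA` here).
#' @export
detect_flicks <- function(trace, peak_thresh_mm = 0.4, onset_thresh_mm = 0.2,
                          refractory_s = 0.5, counter_window_s = 0.3,
                          smooth_s = 0.05) {
  stopifnot(inherits(trace, "tail_trace"))
  if (!trace$calibrated) {
    warning("uncalibrated trace: applying thresholds in pixels (10 / 20 px)")
    peak_thresh_mm <- 20
    onset_thresh_mm <- 10
  }
  d <- trace$deflection
  kw <- round(smooth_s * trace$fps)
  if (kw > 1) {
    pad <- c(numeric(kw), d, numeric(kw))
    d <- as.numeric(stats::filter(pad, rep(1 / kw, kw), sides = 2))[kw + seq_along(d)]
  }
  a <- abs(d)
  n <- length(d)
  tt <- trace_times(trace)
  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      peak_amp_mm = numeric(0), counter_peak_amp_mm = numeric(0),
                      provenance = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("flick_events", "data.frame")
  if (n < 3) return(empty)
  # local maxima of |deflection| above threshold (earliest sample on plateaus)
  cand <- which(a[2:(n - 1)] >= a[1:(n - 2)] & a[2:(n - 1)] > a[3:n] &
                  a[2:(n - 1)] >= peak_thresh_mm) + 1L
  if (!length(cand)) return(empty)
  # greedy refractory suppression, strongest peak first
  keep <- logical(length(cand))
  ord <- order(a[cand], decreasing = TRUE)
  taken <- numeric(0)
  for (i in ord) {
    if (!length(taken) || all(abs(tt[cand[i]] - taken) >= refractory_s)) {
      keep[i] <- TRUE
      taken <- c(taken, tt[cand[i]])
    }
  }
  peaks <- sort(cand[keep])
  ev <- lapply(peaks, function(p) {
    # onset: last upward crossing of the onset threshold before the peak
    below <- which(a[1:p] < onset_thresh_mm)
    onset <- if (length(below)) {
      j <- max(below)  # a[j] < thr <= a[j+1]
      frac <- (onset_thresh_mm - a[j]) / (a[j + 1] - a[j])
      tt[j] + frac / trace$fps
    } else tt[1]
    # counter-bend: largest opposite-sign excursion after the peak
    w_end <- min(n, p + round(counter_window_s * trace$fps))
    counter <- NA_real_
    if (w_end > p) {
      seg <- d[(p + 1):w_end]
      opp <- seg * sign(d[p]) < 0
      if (any(opp)) {
        cmax <- max(abs(seg[opp]))
        if (cmax >= onset_thresh_mm) counter <- -sign(d[p]) * cmax
      }
    }
    c(onset, tt[p], d[p], counter)
  })
  ev <- do.call(rbind, ev)
  out <- data.frame(onset_s = ev[, 1], peak_s = ev[, 2], peak_amp_mm = ev[, 3],
                    counter_peak_amp_mm = ev[, 4], provenance = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("flick_events", "data.frame")
  out
}

# per-trial validity/exclusion windows for a train
trial_windows <- function(train, mode = c("main", "first_encounter"),
                          theta_valid_deg = 5, late_s = 1, fe_late_s = 5) {
  mode <- match.arg(mode)
  p <- train$params
  w <- expansion_window(p)
  # time from onset at which the stimulus reaches theta_valid_deg
  t5 <- if (p$theta_init >= theta_valid_deg) 0 else
    unname(w[1]) - p$l_over_v / tan(theta_valid_deg / 2 * pi / 180)
  exp_end <- train$onsets_s + unname(w[1] - w[2])
  valid_start <- train$onsets_s + t5
  valid_end <- if (mode == "main") train$collision_s + late_s else exp_end + fe_late_s
  nxt <- c(train$onsets_s[-1], Inf)
  if (any(valid_end > nxt))
    stop("response windows overlap the next trial (ISI too short for mode '", mode, "')")
  data.frame(trial = seq_len(train$n_trials), onset_s = train$onsets_s,
             collision_s = train$collision_s, stim_end_s = train$end_s,
             valid_start_s = valid_start, valid_end_s = valid_end)
}

#' Assign flick events to stimulus trials
#'
#' A trial counts as responded if at least one event onset falls inside its
#' validity window: from the moment the stimulus reaches 5 degrees of angular
#' size until 1 s after the projected collision (`mode = "main"`), or until
#' 5 s after the end of expansion (`mode = "first_encounter"`). Events between
#' trial onset and the 5-degree time are tagged `excluded_early`; events after
#' the window but before the stimulus disappears are `excluded_late`; all
#' other events are `spontaneous`.
#'
#' @param events a `flick_events` data.frame from [detect_flicks()].
#' @param train a [stimulus_train()] on the same clock.
#' @param mode validity-window convention, see above.
#' @return A list of class `response_assignment` with `trials` (one row per
#'   trial: `trial`, `onset_s`, `collision_s`, `kind`, `eye`, `responded`,
#'   `response_time_rel_collision_s`, `peak_amp_mm` — zero when not
#'   responded — and `window_s`, the validity-window length) and `events`
#'   (the input events with `provenance` and `trial` filled in).
#' @export
assign_responses <- function(events, train, mode = c("main", "first_encounter")) {
  mode <- match.arg(mode)
  win <- trial_windows(train, mode)
  ev <- as.data.frame(events)
  ev$provenance <- rep("spontaneous", nrow(ev))
  ev$trial <- rep(NA_integer_, nrow(ev))
  trials <- data.frame(trial = win$trial, onset_s = win$onset_s,
                       collision_s = win$collision_s,
                       kind = train$params$kind, eye = train$params$eye,
                       responded = FALSE,
                       response_time_rel_collision_s = NA_real_,
                       peak_amp_mm = 0,
                       window_s = win$valid_end_s - win$valid_start_s,
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(win))) {
    in_valid <- ev$onset_s >= win$valid_start_s[k] & ev$onset_s <= win$valid_end_s[k]
    early <- ev$onset_s >= win$onset_s[k] & ev$onset_s < win$valid_start_s[k]
    late <- ev$onset_s > win$valid_end_s[k] & ev$onset_s <= win$stim_end_s[k]
    ev$provenance[in_valid] <- "evoked"
    ev$provenance[early] <- "excluded_early"
    ev$provenance[late] <- "excluded_late"
    ev$trial[in_valid | early | late] <- k
    if (any(in_valid)) {
      first <- which(in_valid)[which.min(ev$onset_s[in_valid])]
      trials$responded[k] <- TRUE
      trials$response_time_rel_collision_s[k] <- ev$onset_s[first] - win$collision_s[k]
      trials$peak_amp_mm[k] <- ev$peak_amp_mm[first]
    }
  }
  structure(list(trials = trials, events = ev, mode = mode), class = "response_assignment")
}

#' Stimulus-free intervals of a session
#'
#' The complement of the stimulus-on spans (onset to disappearance) within
#' `[0, session_end_s]`, used to estimate the spontaneous flick rate.
#'
#' @param train a [stimulus_train()].
#' @param session_end_s end of the recording, s.
#' @return Two-column matrix of interval `start`/`end` times.
#' @export
stimulus_free_intervals <- function(train, session_end_s) {
  starts <- c(0, train$end_s)
  ends <- c(train$onsets_s, session_end_s)
  keep <- ends > starts
  cbind(start = starts[keep], end = ends[keep])
}

#' Spontaneous flick rate
#'
#' @param events a `flick_events` data.frame (event times from `onset_s`).
#' @param intervals two-column matrix of stimulus-free intervals (s), e.g.
#'   from [stimulus_free_intervals()].
#' @return Rate in Hz: events inside the intervals divided by total free time.
#' @export
spontaneous_rate <- function(events, intervals) {
  intervals <- as.matrix(intervals)
  total <- sum(intervals[, 2] - intervals[, 1])
  if (total <= 0) stop("total stimulus-free time must be > 0")
  n <- sum(vapply(events$onset_s, function(t)
    any(t >= intervals[, 1] & t < intervals[, 2]), logical(1)))
  n / total
}

#' Poisson correction of an observed response probability
#'
#' Subtracts the probability of observing at least one spontaneous flick in
#' the response window, assuming Poisson-distributed spontaneous events:
#' `p_corr = clip(p_obs - (1 - exp(-rate * window)), 0, 1)`.
#'
#' @param p_obs observed response probability in `[0, 1]`; vectorized.
#' @param rate_hz spontaneous flick rate, Hz (>= 0).
#' @param window_s response-window duration, s (> 0).
#' @return Corrected probability, clipped to `[0, 1]`.
#' @export
corrected_probability <- function(p_obs, rate_hz, window_s) {
  if (any(p_obs < 0 | p_obs > 1)) stop("`p_obs` must lie in [0, 1]")
  if (any(rate_hz < 0)) stop("`rate_hz` must be >= 0")
  if (any(window_s <= 0)) stop("`window_s` must be > 0")
  pmin(pmax(p_obs - (1 - exp(-rate_hz * window_s)), 0), 1)
}

#' Habituation curve across fish with exponential fit
#'
#' Computes the per-trial response probability (fraction of fish that produced
#' a valid tail flick), subtracts the spontaneous Poisson term, and fits
#' \eqn{a \exp(-t/\tau)} to the corrected probabilities with trial time
#' `t = (trial - 1) * isi_s`. A bootstrap over fish gives a 95% band for the
#' per-trial probabilities and the time constant.
#'
#' @param trial_tables list of per-fish trial tables (the `trials` element of
#'   [assign_responses()]), aligned by trial index; at least 2 fish.
#' @param isi_s interstimulus interval used as the trial time step, s.
#' @param rate_hz spontaneous flick rate for the Poisson correction (0 for
#'   none).
#' @param n_boot bootstrap resamples for the confidence band.
#' @param seed RNG seed for the bootstrap.
#' @return List of class `habituation_curve`: `curve` (data.frame `trial`,
#'   `t_s`, `p_obs`, `p_corr`, `ci_lo`, `ci_hi`), `fit` (`a`, `tau_s`,
#'   `inv_tau`, `tau_ci`, `ok`), `n_fish`.
#' @export
habituation_curve <- function(trial_tables, isi_s, rate_hz = 0,
                              n_boot = 1000, seed = 1) {
  n_fish <- length(trial_tables)
  if (n_fish < 2) stop("need trial tables from at least 2 fish")
  n_trials <- min(vapply(trial_tables, nrow, integer(1)))
  if (n_trials < 2) stop("need at least 2 trials to fit a habituation curve")
  resp <- vapply(trial_tables, function(tab) tab$responded[seq_len(n_trials)],
                 logical(n_trials))      # n_trials x n_fish
  resp <- matrix(resp, nrow = n_trials)
  window_s <- trial_tables[[1]]$window_s[seq_len(n_trials)]
  t_s <- (seq_len(n_trials) - 1) * isi_s
  p_of <- function(m) corrected_probability(rowMeans(m), rate_hz, window_s)
  p_corr <- p_of(resp)

  fit_curve <- function(p) {
    if (all(p <= 0)) return(NULL)
    a0 <- max(p[1], 1e-3)
    pos <- p > 1e-6
    r0 <- if (sum(pos) >= 2) {
      sl <- stats::coef(stats::lm(log(p[pos]) ~ t_s[pos]))[2]
      max(1e-6, -sl)
    } else 1 / max(t_s)
    tryCatch(minpack.lm::nlsLM(p ~ a * exp(-r * t_s),
                               start = list(a = a0, r = r0),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             error = function(e) NULL)
  }
  fit <- fit_curve(p_corr)
  fit_info <- list(a = NA_real_, tau_s = NA_real_, inv_tau = NA_real_,
                   tau_ci = c(NA_real_, NA_real_), ok = FALSE,
                   diagnostic = "all-zero probabilities; fit skipped")
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    se <- tryCatch(sqrt(diag(stats::vcov(fit)))["r"], error = function(e) NA_real_)
    r_ci <- cf["r"] + c(-1, 1) * 1.96 * se
    # reject when the decay rate is indistinguishable from zero (tau -> Inf)
    ok <- is.finite(se) && r_ci[1] > 0
    fit_info <- list(a = unname(cf["a"]), tau_s = unname(1 / cf["r"]),
                     inv_tau = unname(-cf["r"]),
                     tau_ci = sort(1 / r_ci), ok = ok,
                     diagnostic = if (ok) NA_character_ else
                       "decay rate CI includes zero (tau unbounded); fit rejected")
  }

  set.seed(seed)
  boot <- replicate(n_boot, {
    idx <- sample.int(n_fish, replace = TRUE)
    p_of(resp[, idx, drop = FALSE])
  })
  ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975), names = FALSE)

  structure(list(curve = data.frame(trial = seq_len(n_trials), t_s = t_s,
                                    p_obs = rowMeans(resp), p_corr = p_corr,
                                    ci_lo = ci[1, ], ci_hi = ci[2, ]),
                 fit = fit_info, n_fish = n_fish, isi_s = isi_s),
            class = "habituation_curve")
}

#' @export
print.habituation_curve <- function(x, ...) {
  cat(sprintf("<habituation_curve> %d fish, %d trials (ISI %g s)\n",
              x$n_fish, nrow(x$curve), x$isi_s))
  if (isTRUE(x$fit$ok))
    cat(sprintf("  fit a*exp(-t/tau): a = %.3f, tau = %.1f s\n", x$fit$a, x$fit$tau_s))
  else cat("  fit:", x$fit$diagnostic, "\n")
  invisible(x)
}

#' K-means classification of escape response types
#'
#' Standardizes the feature columns (z-score) and partitions the events with
#' K-means. Cluster labels are renumbered by descending mean absolute positive
#' peak amplitude so the labeling is reproducible.
#'
#' @param features data.frame or matrix of numeric response features, e.g.
#'   response time, positive peak amplitude, negative peak amplitude and their
#'   ratio.
#' @param k number of clusters (default 5 response categories).
#' @param seed RNG seed (mandatory; K-means initialization is random).
#' @param order_by column used to order clusters (mean absolute value,
#'   descending); defaults to the column named `pos_peak` or else the first
#'   column.
#' @return Integer vector of cluster labels in `1..k`.
#' @export
classify_response_types <- function(features, k = 5, seed, order_by = NULL) {
  x <- as.matrix(features)
  if (k > nrow(x)) stop("`k` cannot exceed the number of events")
  if (missing(seed)) stop("`seed` is required for reproducible clustering")
  z <- scale(x)
  z[, attr(z, "scaled:scale") == 0 | !is.finite(colSums(z))] <- 0
  z[!is.finite(z)] <- 0
  if (all(stats::dist(z) < 1e-12)) return(rep(1L, nrow(x)))
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = 10, iter.max = 100)
  if (is.null(order_by))
    order_by <- if ("pos_peak" %in% colnames(x)) "pos_peak" else colnames(x)[1] %||% 1
  key <- tapply(abs(x[, order_by]), km$cluster, mean)
  relabel <- integer(k)
  relabel[as.integer(names(sort(key, decreasing = TRUE)))] <- seq_len(k)
  relabel[km$cluster]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pectoral fin motion from a video stack
#'
#' Fin motion is quantified as the per-frame standard deviation of the
#' difference between consecutive frames within a small window around each
#' fin; the left and right traces are averaged and smoothed with a moving
#' average. Beats are local maxima of the smoothed trace; the beat frequency
#' is the reciprocal of the median inter-peak interval and the tuck time is
#' the last beat before a reference event (fins stop beating, "tucked in",
#' before large tail flicks).
#'
#' @param stack `height x width x n_frames` grayscale array.
#' @param left_win,right_win windows as `list(rows = r0:r1, cols = c0:c1)`.
#' @param fps frame rate, Hz.
#' @param smooth_s moving-average width, s.
#' @param min_gap_s minimum separation between beat peaks, s.
#' @param ref_event_s optional reference event time for the tuck time.
#' @return List with `trace` (data.frame `time_s`, `motion`), `beat_freq_hz`,
#'   `beat_times_s` and `tuck_time_s` (NA without a reference event).
#' @export
fin_motion <- function(stack, left_win, right_win, fps,
                       smooth_s = 0.2, min_gap_s = 0.15, ref_event_s = NULL) {
  dm <- dim(stack)
  check_win <- function(w) {
    if (!length(w$rows) || !length(w$cols) ||
        min(w$rows) < 1 || max(w$rows) > dm[1] ||
        min(w$cols) < 1 || max(w$cols) > dm[2])
      stop("fin window empty or outside frame bounds")
  }
  check_win(left_win); check_win(right_win)
  n <- dm[3]
  motion_of <- function(w) {
    sub <- stack[w$rows, w$cols, , drop = FALSE]
    vapply(seq_len(n - 1),
           function(i) stats::sd(sub[, , i + 1] - sub[, , i]), numeric(1))
  }
  m <- (motion_of(left_win) + motion_of(right_win)) / 2
  kw <- max(1L, round(smooth_s * fps))
  pad <- c(numeric(kw), m, numeric(kw))
  sm <- as.numeric(stats::filter(pad, rep(1 / kw, kw), sides = 2))[kw + seq_along(m)]
  tt <- (seq_len(n - 1) - 0.5) / fps
  # beat peaks: local maxima above half the trace maximum, refractory-merged
  thr <- max(sm) / 2
  pk <- which(sm[2:(n - 2)] >= sm[1:(n - 3)] & sm[2:(n - 2)] > sm[3:(n - 1)] &
                sm[2:(n - 2)] >= thr) + 1L
  beat_times <- numeric(0)
  for (p in pk) {
    if (!length(beat_times) || tt[p] - beat_times[length(beat_times)] >= min_gap_s)
      beat_times <- c(beat_times, tt[p])
  }
  beat_freq <- if (length(beat_times) >= 2) 1 / stats::median(diff(beat_times)) else NA_real_
  tuck <- if (!is.null(ref_event_s) && any(beat_times < ref_event_s))
    max(beat_times[beat_times < ref_event_s]) else NA_real_
  list(trace = data.frame(time_s = tt, motion = sm),
       beat_freq_hz = beat_freq, beat_times_s = beat_times, tuck_time_s = tuck)
}

#' Fraction of escapes directed away from the stimulated eye
#'
#' By convention negative peak amplitude means the tail bent away from the
#' stimulated eye.
#'
#' @param trials a trial table from [assign_responses()].
#' @return Fraction in `[0, 1]`, or `NA` when no trial was responded.
#' @export
direction_stats <- function(trials) {
  r <- trials$responded
  if (!any(r)) return(NA_real_)
  mean(trials$peak_amp_mm[r] < 0)
}
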