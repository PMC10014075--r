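#' Looming stimulus parameters
#'
#' Describes one visual stimulus presented to one eye. A looming stimulus is a
#' disk expanding as if an object of half-size `l` approached at constant speed
#' `|v|`; its angular size follows \eqn{\theta(t) = 2\,\arctan((l/|v|)/t_{rel})}
#' where \eqn{t_{rel}} is the time remaining to virtual collision. Dimming and
#' brightening stimuli are whole-field luminance ramps matched to the dark
#' loom's dark-pixel fraction; checkerboard looms expand a dark/bright checked
#' disk whose mean luminance stays constant.
#'
#' @param kind one of `"dark_loom"`, `"checker_loom"`, `"dimming"`,
#'   `"brightening"`.
#' @param l_over_v size-to-speed ratio in seconds (> 0). Typical values are
#'   0.240 s (behavioral protocol) and 0.480 s (imaging protocol).
#' @param theta_init,theta_final initial and final angular size in degrees,
#'   `0 < theta_init < theta_final < 180`.
#' @param hold_s time (s) the stimulus is held at its final size before
#'   disappearing.
#' @param refresh_hz display refresh rate in frames per second.
#' @param eye stimulated eye, `"left"` or `"right"`.
#' @return An object of class `looming_params`.
#' @examples
#' p <- looming_params("dark_loom", l_over_v = 0.240,
#'                     theta_init = 4, theta_final = 140)
#' angular_size(p, t_rel = 0.240)  # 90 degrees
#' @export
looming_params <- function(kind = c("dark_loom", "checker_loom", "dimming", "brightening"),
                           l_over_v = 0.240, theta_init = 4, theta_final = 140,
                           hold_s = 2.5, refresh_hz = 20,
                           eye = c("left", "right")) {
  kind <- match.arg(kind)
  eye <- match.arg(eye)
  if (!is.numeric(l_over_v) || length(l_over_v) != 1L || l_over_v <= 0)
    stop("`l_over_v` must be a single positive number (seconds)")
  if (!(theta_init > 0 && theta_init < theta_final && theta_final < 180))
    stop("angular sizes must satisfy 0 < theta_init < theta_final < 180")
  if (hold_s < 0) stop("`hold_s` must be >= 0")
  if (refresh_hz <= 0) stop("`refresh_hz` must be > 0")
  structure(list(kind = kind, l_over_v = l_over_v,
                 theta_init = theta_init, theta_final = theta_final,
                 hold_s = hold_s, refresh_hz = refresh_hz, eye = eye),
            class = "looming_params")
}

#' @export
print.looming_params <- function(x, ...) {
  cat(sprintf("<looming_params> %s, l/|v| = %g s, %g-%g deg, hold %g s, %s eye\n",
              x$kind, x$l_over_v, x$theta_init, x$theta_final, x$hold_s, x$eye))
  invisible(x)
}

#' Angular size of a looming stimulus
#'
#' Evaluates \eqn{\theta(t_{rel}) = 2 \arctan((l/|v|) / t_{rel})} in degrees,
#' clipped to `[theta_init, theta_final]`. At `t_rel = 0` (virtual collision)
#' the unclipped size is 180 degrees.
#'
#' @param params a [looming_params()] object.
#' @param t_rel time remaining to virtual collision, seconds (>= 0);
#'   vectorized.
#' @return Angular size in degrees, same length as `t_rel`. Non-increasing in
#'   `t_rel`.
#' @export
angular_size <- function(params, t_rel) {
  stopifnot(inherits(params, "looming_params"))
  if (any(t_rel < 0)) stop("`t_rel` must be >= 0 (time before virtual collision)")
  theta <- ifelse(t_rel == 0, 180, 2 * atan(params$l_over_v / t_rel) * 180 / pi)
  pmin(pmax(theta, params$theta_init), params$theta_final)
}

#' Expansion window of a looming stimulus
#'
#' Inverts the angular-size law at `theta_init` and `theta_final`:
#' the expansion starts `onset_t_rel = (l/|v|)/tan(theta_init/2)` seconds
#' before collision and ends (disk at final size) `offset_t_rel =
#' (l/|v|)/tan(theta_final/2)` seconds before collision.
#'
#' @inheritParams angular_size
#' @return Named numeric vector `c(onset_t_rel, offset_t_rel)` in seconds,
#'   with `onset_t_rel > offset_t_rel`.
#' @export
expansion_window <- function(params) {
  stopifnot(inherits(params, "looming_params"))
  deg <- pi / 180
  c(onset_t_rel = params$l_over_v / tan(params$theta_init / 2 * deg),
    offset_t_rel = params$l_over_v / tan(params$theta_final / 2 * deg))
}

#' Duration of one stimulus presentation (expansion plus hold), seconds.
#' @inheritParams angular_size
#' @export
stimulus_duration <- function(params) {
  w <- expansion_window(params)
  unname(w[1] - w[2]) + params$hold_s
}

#' A repeated stimulus train
#'
#' @param params a [looming_params()] object.
#' @param n_trials number of presentations.
#' @param isi_s interstimulus interval: the blank time between the
#'   disappearance of one stimulus and the onset of the next, seconds.
#' @param onsets_s optional explicit onset times (s from session start);
#'   defaults to `t0 + (0:(n-1)) * (stimulus_duration + isi_s)`.
#' @param t0 onset of the first trial (s), default 0.
#' @return An object of class `stimulus_train` with fields `params`,
#'   `n_trials`, `isi_s`, `onsets_s`, and derived per-trial times
#'   `collision_s` (virtual collision) and `end_s` (disappearance).
#' @export
stimulus_train <- function(params, n_trials, isi_s, onsets_s = NULL, t0 = 0) {
  stopifnot(inherits(params, "looming_params"), n_trials >= 1, isi_s >= 0)
  dur <- stimulus_duration(params)
  if (is.null(onsets_s))
    onsets_s <- t0 + (seq_len(n_trials) - 1) * (dur + isi_s)
  if (length(onsets_s) != n_trials) stop("`onsets_s` must have length `n_trials`")
  if (n_trials > 1 && any(diff(onsets_s) <= 0))
    stop("trial onsets must be strictly increasing")
  if (n_trials > 1 && any(diff(onsets_s) < dur - 1e-9))
    stop("trial onsets closer than the stimulus duration (overlapping trials)")
  w <- expansion_window(params)
  structure(list(params = params, n_trials = as.integer(n_trials), isi_s = isi_s,
                 onsets_s = onsets_s,
                 collision_s = onsets_s + unname(w[1]),
                 end_s = onsets_s + dur),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("<stimulus_train> %d x %s, ISI %g s, first onset %g s\n",
              x$n_trials, x$params$kind, x$isi_s, x$onsets_s[1]))
  invisible(x)
}

#' Screen geometry for stimulus rendering
#'
#' Maps angular size to an on-screen disk radius. Two projections are
#' supported: `"gnomonic"` (flat screen at distance `distance_mm`, radius
#' `= d_px * tan(theta/2)`) and `"linear"` (fixed pixels per degree,
#' radius `= (theta/2) * px_per_deg`).
#'
#' @param width_px,height_px screen size in pixels.
#' @param px_per_deg pixels per degree at screen center (linear projection).
#' @param width_mm,distance_mm physical screen width and eye-screen distance
#'   (gnomonic projection).
#' @param background_level background luminance, normalized to `[0, 1]`.
#' @param projection `"gnomonic"` or `"linear"`.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 128, height_px = 128,
                            px_per_deg = NULL, width_mm = NULL, distance_mm = NULL,
                            background_level = 1,
                            projection = c("linear", "gnomonic")) {
  projection <- match.arg(projection)
  stopifnot(width_px > 0, height_px > 0,
            background_level >= 0, background_level <= 1)
  if (projection == "linear") {
    if (is.null(px_per_deg)) px_per_deg <- width_px / 180
    stopifnot(px_per_deg > 0)
  } else {
    if (is.null(width_mm) || is.null(distance_mm))
      stop("gnomonic projection needs `width_mm` and `distance_mm`")
    stopifnot(width_mm > 0, distance_mm > 0)
  }
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 px_per_deg = px_per_deg, width_mm = width_mm,
                 distance_mm = distance_mm,
                 background_level = background_level, projection = projection),
            class = "screen_geometry")
}

# disk radius in pixels for an angular size (degrees)
disk_radius_px <- function(theta_deg, geom) {
  if (geom$projection == "linear") {
    (theta_deg / 2) * geom$px_per_deg
  } else {
    d_px <- geom$distance_mm * geom$width_px / geom$width_mm
    d_px * tan(theta_deg / 2 * pi / 180)
  }
}

# logical disk mask on the pixel grid (pixel-center convention, centered disk)
disk_mask <- function(geom, radius_px) {
  cx <- (geom$width_px + 1) / 2
  cy <- (geom$height_px + 1) / 2
  x <- seq_len(geom$width_px) - cx
  y <- seq_len(geom$height_px) - cy
  outer(y^2, x^2, "+") <= radius_px^2
}

# angular size at time t (s) since trial onset (theta = theta_init at t = 0);
# NA outside [0, expansion + hold]
theta_at <- function(params, t) {
  w <- expansion_window(params)
  dur_exp <- unname(w[1] - w[2])
  th <- rep(NA_real_, length(t))
  on <- t >= 0 & t <= dur_exp + params$hold_s
  t_rel <- pmax(unname(w[1]) - t[on], unname(w[2]))
  th[on] <- angular_size(params, t_rel)
  th
}

# Single-frame render at time t since trial onset. All four stimulus kinds go
# through this one code path so that luminance_profile and render_frames are
# exactly consistent. Returns a height x width matrix in [0, 1], or a uniform
# background frame outside the stimulus.
render_frame_at <- function(params, geom, t) {
  bg <- geom$background_level
  blank <- matrix(bg, geom$height_px, geom$width_px)
  th <- theta_at(params, t)
  if (is.na(th)) return(blank)
  dark_params <- params
  dark_params$kind <- "dark_loom"
  r <- disk_radius_px(th, geom)
  mask <- disk_mask(geom, r)
  switch(params$kind,
    dark_loom = {
      f <- blank
      f[mask] <- 0
      f
    },
    checker_loom = {
      f <- matrix(0.5, geom$height_px, geom$width_px)
      cs <- max(4L, round(min(geom$width_px, geom$height_px) / 16))
      checks <- outer(floor((seq_len(geom$height_px) - 1) / cs),
                      floor((seq_len(geom$width_px) - 1) / cs), "+") %% 2
      f[mask] <- checks[mask]
      f
    },
    dimming = {
      dark_frac <- sum(mask) / length(mask)
      matrix(bg * (1 - dark_frac), geom$height_px, geom$width_px)
    },
    brightening = {
      dark_frac <- sum(mask) / length(mask)
      matrix(bg * dark_frac, geom$height_px, geom$width_px)
    })
}

#' Mean screen luminance of a stimulus over time
#'
#' For a dark loom the luminance is one minus the dark-pixel fraction of the
#' rendered disk (times the background level); dimming has the identical time
#' course with no rendered edge; brightening is the polarity-inverted dimming
#' ramp; checkerboard looms stay near the mid-gray background. The profile is
#' computed by pixel counting on the configured screen, so it agrees exactly
#' with the mean of [render_frames()].
#'
#' @inheritParams angular_size
#' @param geom a [screen_geometry()].
#' @param t time since trial onset (s; the disk is at `theta_init` at `t = 0`);
#'   vectorized. Outside the stimulus the background level is returned.
#' @return Normalized luminance values in `[0, 1]`.
#' @export
luminance_profile <- function(params, geom, t) {
  stopifnot(inherits(params, "looming_params"), inherits(geom, "screen_geometry"))
  vapply(t, function(ti) mean(render_frame_at(params, geom, ti)), numeric(1))
}

#' Render a stimulus as a grayscale image stack
#'
#' One frame per display refresh, frame-centered sampling over the stimulus
#' (expansion plus hold). Dark looms render a dark disk on the bright
#' background; checkerboard looms an equal-area dark/bright checked disk on
#' mid-gray; dimming and brightening are uniform fields.
#'
#' @inheritParams luminance_profile
#' @param times optional explicit frame times (s since trial onset).
#' @return A `height x width x n_frames` array in `[0, 1]` with a `times_s`
#'   attribute.
#' @export
render_frames <- function(params, geom, times = NULL) {
  if (is.null(times)) {
    w <- expansion_window(params)
    dur <- unname(w[1] - w[2]) + params$hold_s
    n <- max(1L, floor(dur * params$refresh_hz))
    times <- (seq_len(n) - 0.5) / params$refresh_hz
  }
  frames <- vapply(times, function(ti) render_frame_at(params, geom, ti),
                   matrix(0, geom$height_px, geom$width_px))
  dim(frames) <- c(geom$height_px, geom$width_px, length(times))
  attr(frames, "times_s") <- times
  frames
}

#' Stimulus, ISI and motor regressors for calcium imaging
#'
#' Builds the stimulus drive of a train (angular-size profile above
#' `theta_init` for looming kinds, luminance decrease for dimming, luminance
#' increase for brightening), convolves it with a causal exponential calcium
#' kernel \eqn{\exp(-t/\tau)} and max-normalizes to 1. Also returns an ISI
#' regressor (the complement of stimulus-on, identically filtered) and, when a
#' motor trace is supplied, a motor regressor.
#'
#' @param train a [stimulus_train()].
#' @param geom a [screen_geometry()] (used for the luminance-based drives).
#' @param kernel_tau calcium kernel decay time constant, seconds. The default
#'   3.5 s is appropriate for a slow nuclear-localized indicator.
#' @param fs sampling rate of the regressor, Hz.
#' @param motor optional motor time series on the same clock (length
#'   `ceiling(T * fs)`), convolved with the same kernel.
#' @param t_end end of the session (s); defaults to the last stimulus end plus
#'   one ISI.
#' @return A data.frame with columns `time_s`, `stimulus`, `isi` and (if
#'   `motor` given) `motor`, each regressor max-normalized to 1.
#' @export
build_regressor <- function(train, geom, kernel_tau = 3.5, fs = 1,
                            motor = NULL, t_end = NULL) {
  stopifnot(inherits(train, "stimulus_train"), kernel_tau > 0, fs > 0)
  if (train$n_trials < 1) stop("empty stimulus train")
  if (is.null(t_end)) t_end <- max(train$end_s) + train$isi_s
  tt <- seq(0, t_end, by = 1 / fs)
  drive <- stimulus_drive(train, geom, tt)
  on <- drive > 0
  out <- data.frame(time_s = tt,
                    stimulus = exp_kernel_filter(drive, kernel_tau, fs, normalize = TRUE),
                    isi = exp_kernel_filter(as.numeric(!on), kernel_tau, fs, normalize = TRUE))
  if (!is.null(motor)) {
    if (length(motor) != length(tt))
      stop("`motor` must have length ", length(tt), " (one sample per regressor frame)")
    out$motor <- exp_kernel_filter(motor, kernel_tau, fs, normalize = TRUE)
  }
  out
}

# normalized stimulus drive in [0, 1] for a train, sampled at times tt
stimulus_drive <- function(train, geom, tt) {
  p <- train$params
  drive <- numeric(length(tt))
  for (k in seq_len(train$n_trials)) {
    rel <- tt - train$onsets_s[k]
    idx <- which(rel >= 0 & rel <= (train$end_s[k] - train$onsets_s[k]))
    if (!length(idx)) next
    drive[idx] <- switch(p$kind,
      dark_loom = ,
      checker_loom = {
        th <- theta_at(p, rel[idx])
        (th - p$theta_init) / (p$theta_final - p$theta_init)
      },
      dimming = {
        lum <- luminance_profile(p, geom, rel[idx])
        bg <- geom$background_level
        if (bg > 0) (bg - lum) / bg else 1 - lum
      },
      brightening = {
        lum <- luminance_profile(p, geom, rel[idx])
        bg <- if (geom$background_level > 0) geom$background_level else 1
        lum / bg
      })
  }
  drive
}

# causal exponential kernel as a first-order recursive filter:
# y[t] = x[t] + exp(-1/(tau*fs)) * y[t-1], exactly the discrete convolution
# with the geometric kernel exp(-k/(tau*fs))
exp_kernel_filter <- function(x, tau, fs, normalize = FALSE) {
  a <- exp(-1 / (tau * fs))
  y <- as.numeric(stats::filter(x, a, method = "recursive"))
  if (normalize && max(y) > 0) y <- y / max(y)
  y
}
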