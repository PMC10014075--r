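# shared fixture builders; everything is generated in code at test time

behavior_params <- function() {
  looming_params("dark_loom", 0.240, 4, 140, hold_s = 2.5, refresh_hz = 20)
}

imaging_params <- function(kind = "dark_loom", eye = "left") {
  looming_params(kind, 0.480, 3, 80, hold_s = 10, refresh_hz = 30, eye = eye)
}

# two-eye protocol: every stimulus type presented to each eye in turn
two_eye_trains <- function(n_trials = 10, isi_s = 40,
                           types = c("dm", "dl", "br", "cb")) {
  kinds <- c(dm = "dimming", dl = "dark_loom", br = "brightening",
             cb = "checker_loom")
  trains <- list()
  t0 <- 60
  for (eye in c("right", "left")) {
    for (ty in types) {
      tr <- stimulus_train(imaging_params(kinds[[ty]], eye), n_trials, isi_s,
                           t0 = t0)
      trains[[paste(ty, eye, sep = "_")]] <- tr
      t0 <- max(tr$end_s) + 60
    }
  }
  trains
}

# half-sine bend trace: amplitude amp (signed, mm), duration dur_s,
# centered at center_s, on an otherwise flat trace
bend_trace <- function(amp, center_s = 2, dur_s = 0.4, fps = 200,
                       total_s = 5, noise_sd = 0) {
  n <- round(total_s * fps)
  tt <- (seq_len(n) - 1) / fps
  d <- numeric(n)
  on <- tt >= center_s - dur_s / 2 & tt <= center_s + dur_s / 2
  d[on] <- amp * sin(pi * (tt[on] - center_s + dur_s / 2) / dur_s)
  if (noise_sd > 0) d <- d + stats::rnorm(n, 0, noise_sd)
  tail_trace(d, fps = fps, px_per_mm = 50)
}

# peak series from the exponential model, optionally noisy
peak_series_from <- function(a, inv_tau, c, n_trials = 10, isi_s = 40,
                             noise_sd = 0, responded = TRUE) {
  t <- (seq_len(n_trials) - 1) * isi_s
  y <- a * exp(inv_tau * t) + c
  if (noise_sd > 0) y <- y + stats::rnorm(n_trials, 0, noise_sd)
  structure(data.frame(trial = seq_len(n_trials), peak_time_s = t,
                       peak_amp = y, responded = responded),
            class = c("peak_series", "data.frame"))
}

# match detected events to planted ones within a time tolerance; returns
# c(tp, fp, fn)
match_events <- function(detected_peak_s, true_peak_s, tol_s = 0.3) {
  matched <- rep(FALSE, length(detected_peak_s))
  tp <- 0L; fn <- 0L
  for (t0 in true_peak_s) {
    d <- abs(detected_peak_s - t0)
    j <- which(d < tol_s & !matched)
    if (length(j)) {
      matched[j[which.min(d[j])]] <- TRUE
      tp <- tp + 1L
    } else fn <- fn + 1L
  }
  c(tp = tp, fp = sum(!matched), fn = fn)
}
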