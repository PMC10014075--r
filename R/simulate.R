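#' Configuration for a synthetic behavioral session
#'
#' The defaults reproduce the statistical structure of the behavioral
#' protocol: escape probability ~0.6 on the first trial decaying with a
#' behavioral habituation time constant, escape onsets ~1.3 s (SD 0.5 s)
#' before the projected collision, 76% of flicks directed away from the
#' stimulated eye, and spontaneous flicks as a Poisson process at 0.0266 Hz.
#'
#' @param n_fish number of fish.
#' @param params stimulus parameters ([looming_params()]).
#' @param n_trials,isi_s train layout (see [stimulus_train()]).
#' @param p1 first-trial escape probability.
#' @param tau_h behavioral habituation time constant, s; trial `k` escapes
#'   with probability `p1 * exp(-(k - 1) * isi_s / tau_h)`.
#' @param lambda_spont spontaneous flick rate, Hz.
#' @param away_prob probability that a flick is directed away from the
#'   stimulated eye (away = negative deflection).
#' @param resp_mean_s,resp_sd_s evoked flick onset relative to collision
#'   (mean/SD seconds before collision), truncated to the validity window.
#' @param flick_amp_mean,flick_amp_sd flick peak amplitude distribution, mm;
#'   amplitudes are resampled to stay at or above `flick_amp_min`.
#' @param flick_amp_min minimum planted amplitude, mm (keeps planted flicks
#'   above the detection threshold).
#' @param flick_dur_s duration of the main half-sine bend, s.
#' @param counterbend_ratio counter-bend amplitude as a fraction of the main
#'   bend (0 = none).
#' @param noise_sd additive Gaussian trace noise, mm.
#' @param fps trace sampling rate, Hz.
#' @param pad_s stimulus-free lead-in and tail, s (used to estimate the
#'   spontaneous rate).
#' @return List of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(n_fish = 20,
                                params = looming_params("dark_loom", 0.240, 4, 140,
                                                        hold_s = 2.5, refresh_hz = 20),
                                n_trials = 10, isi_s = 10,
                                p1 = 0.6, tau_h = 60, lambda_spont = 0.0266,
                                away_prob = 0.76,
                                resp_mean_s = 1.3, resp_sd_s = 0.5,
                                flick_amp_mean = 1.0, flick_amp_sd = 0.3,
                                flick_amp_min = 0.5, flick_dur_s = 0.2,
                                counterbend_ratio = 0.5, noise_sd = 0.02,
                                fps = 100, pad_s = 60) {
  stopifnot(p1 >= 0, p1 <= 1, tau_h > 0, lambda_spont >= 0,
            away_prob >= 0, away_prob <= 1, fps > 0)
  if (isi_s < 0) stop("`isi_s` must be >= 0")
  cfg <- list(n_fish = n_fish, params = params, n_trials = n_trials, isi_s = isi_s,
              p1 = p1, tau_h = tau_h, lambda_spont = lambda_spont,
              away_prob = away_prob, resp_mean_s = resp_mean_s, resp_sd_s = resp_sd_s,
              flick_amp_mean = flick_amp_mean, flick_amp_sd = flick_amp_sd,
              flick_amp_min = flick_amp_min, flick_dur_s = flick_dur_s,
              counterbend_ratio = counterbend_ratio, noise_sd = noise_sd,
              fps = fps, pad_s = pad_s)
  class(cfg) <- "behavior_sim_config"
  cfg
}

# half-sine bend of given signed amplitude and duration, stamped into a trace
stamp_bend <- function(trace, fps, onset_s, amp, dur_s) {
  i0 <- round(onset_s * fps) + 1L
  ns <- max(2L, round(dur_s * fps))
  idx <- i0:(i0 + ns - 1L)
  ok <- idx >= 1 & idx <= length(trace)
  trace[idx[ok]] <- trace[idx[ok]] + amp * sin(pi * (seq_len(ns)[ok] - 0.5) / ns)
  trace
}

#' Simulate a behavioral session with known ground truth
#'
#' Generates per-fish tail-deflection traces: trial-locked escape flicks with
#' exponentially decaying probability, spontaneous Poisson flicks, half-sine
#' bend waveforms with optional counter-bends, and additive Gaussian noise.
#' Same seed and config give identical output.
#'
#' @param cfg a [behavior_sim_config()].
#' @param seed RNG seed.
#' @return List of class `behavior_session`: `traces` (list of [tail_trace()]
#'   per fish), `train` (the [stimulus_train()]), `truth` (data.frame `fish`,
#'   `trial` (NA for spontaneous), `time_s` (bend peak), `amp_mm` (signed),
#'   `type`), `session_end_s`, `cfg`.
#' @export
simulate_behavior_session <- function(cfg, seed) {
  stopifnot(inherits(cfg, "behavior_sim_config"))
  set.seed(seed)
  train <- stimulus_train(cfg$params, cfg$n_trials, cfg$isi_s, t0 = cfg$pad_s)
  if (cfg$isi_s < stimulus_duration(cfg$params))
    stop("ISI shorter than the stimulus duration")
  win <- trial_windows(train, "main")
  t_end <- max(train$end_s) + cfg$pad_s
  n_samp <- round(t_end * cfg$fps)
  draw_amp <- function() {
    a <- stats::rnorm(1, cfg$flick_amp_mean, cfg$flick_amp_sd)
    while (a < cfg$flick_amp_min) a <- stats::rnorm(1, cfg$flick_amp_mean, cfg$flick_amp_sd)
    a
  }
  truth <- list()
  traces <- vector("list", cfg$n_fish)
  for (f in seq_len(cfg$n_fish)) {
    d <- numeric(n_samp)
    events <- list()
    for (k in seq_len(cfg$n_trials)) {
      p_k <- cfg$p1 * exp(-(k - 1) * cfg$isi_s / cfg$tau_h)
      if (stats::runif(1) > p_k) next
      # onset before collision, truncated to the validity window
      lo <- win$valid_start_s[k]
      hi <- win$valid_end_s[k] - cfg$flick_dur_s
      onset <- train$collision_s[k] - stats::rnorm(1, cfg$resp_mean_s, cfg$resp_sd_s)
      while (onset < lo || onset > hi)
        onset <- train$collision_s[k] - stats::rnorm(1, cfg$resp_mean_s, cfg$resp_sd_s)
      s <- if (stats::runif(1) < cfg$away_prob) -1 else 1
      amp <- s * draw_amp()
      events[[length(events) + 1]] <-
        data.frame(fish = f, trial = k, time_s = onset + cfg$flick_dur_s / 2,
                   onset_s = onset, amp_mm = amp, type = "evoked")
    }
    # spontaneous Poisson flicks over the whole session
    n_sp <- stats::rpois(1, cfg$lambda_spont * t_end)
    if (n_sp > 0) {
      t_sp <- sort(stats::runif(n_sp, 0, t_end - cfg$flick_dur_s))
      for (ts in t_sp) {
        other <- vapply(events, function(e) e$onset_s, numeric(1))
        if (length(other) && any(abs(ts - other) < 1))
          next  # keep planted events separable for the truth manifest
        s <- if (stats::runif(1) < 0.5) -1 else 1
        events[[length(events) + 1]] <-
          data.frame(fish = f, trial = NA_integer_, time_s = ts + cfg$flick_dur_s / 2,
                     onset_s = ts, amp_mm = s * draw_amp(), type = "spontaneous")
      }
    }
    for (e in events) {
      d <- stamp_bend(d, cfg$fps, e$onset_s, e$amp_mm, cfg$flick_dur_s)
      if (cfg$counterbend_ratio > 0)
        d <- stamp_bend(d, cfg$fps, e$onset_s + cfg$flick_dur_s,
                        -e$amp_mm * cfg$counterbend_ratio, cfg$flick_dur_s * 0.75)
    }
    d <- d + stats::rnorm(n_samp, 0, cfg$noise_sd)
    traces[[f]] <- tail_trace(d, fps = cfg$fps, px_per_mm = 50)
    truth[[f]] <- if (length(events)) do.call(rbind, events) else NULL
  }
  truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  structure(list(traces = traces, train = train, truth = truth,
                 session_end_s = t_end, cfg = cfg),
            class = "behavior_session")
}

#' Run the behavioral pipeline on a simulated (or real) session
#'
#' Detects flicks on every trace, assigns them to trials, estimates the
#' spontaneous rate from the stimulus-free intervals, and builds the
#' corrected habituation curve.
#'
#' @param session a `behavior_session` (or a list with `traces`, `train`,
#'   `session_end_s`).
#' @param mode validity-window mode, see [assign_responses()].
#' @param ... passed to [detect_flicks()].
#' @return List: `assignments` (per fish), `trial_tables`, `rate_hz`, `curve`
#'   (a [habituation_curve()]).
#' @export
analyze_behavior_session <- function(session, mode = "main", ...) {
  free <- stimulus_free_intervals(session$train, session$session_end_s)
  assignments <- lapply(session$traces, function(tr) {
    ev <- detect_flicks(tr, ...)
    assign_responses(ev, session$train, mode = mode)
  })
  rates <- vapply(assignments, function(a) spontaneous_rate(a$events, free), numeric(1))
  rate_hz <- mean(rates)
  tables <- lapply(assignments, `[[`, "trials")
  curve <- habituation_curve(tables, isi_s = session$train$isi_s, rate_hz = rate_hz)
  list(assignments = assignments, trial_tables = tables,
       rate_hz = rate_hz, per_fish_rate_hz = rates, curve = curve)
}

#' Configuration for a synthetic calcium population
#'
#' Each population plants a tuning code, a habituation-dynamics class mixture,
#' a hemispheric placement bias and a GABA-positive fraction. Per-trial
#' response peaks follow `a * exp(t * inv_tau) + c` for the cell's tuned
#' stimulus types; the single-trial response shape is the stimulus drive
#' convolved with a causal exponential calcium kernel, scaled so the planted
#' peak amplitude is realized exactly, plus white Gaussian noise.
#'
#' @param populations list of population specs; each a list with `name`, `n`,
#'   `bits` (named 0/1 vector `dm dl br cb`), `class_probs` (named
#'   depressing/potentiating/stable mixture), `p_contra` (probability of
#'   placement contralateral to the stimulated eye), `gaba_fraction`,
#'   `binocular_fraction` (0 for single-eye protocols). The default plants a
#'   looming-sensitive (code 5) population with a strong contralateral bias
#'   and a dimming-sensitive (code 12) population with none, both with the
#'   55/18/27% depressing/potentiating/stable mixture.
#' @param trains named list of [stimulus_train()]s, names among
#'   `dm dl br cb`; default: 10 trials of each of the four types at ISI 40 s
#'   with the imaging-protocol loom (l/|v| 480 ms, 3-80 degrees, 10 s hold),
#'   presented sequentially to the left eye.
#' @param inv_tau_ranges named list of `c(lo, hi)` rate ranges (1/s) per
#'   dynamics class; stable cells have rate 0. The depressing range brackets
#'   the -0.0075 1/s component typical of strongly habituating cells; the
#'   potentiating range mirrors it.
#' @param class_boundary the planted class boundary (1/s): dynamics slower
#'   than this are "stable" by construction. Used as the override threshold
#'   pair `c(+class_boundary, -class_boundary)` when classifying simulated
#'   populations.
#' @param a_range,c_range uniform ranges for the fit amplitude and offset.
#' @param kernel_tau calcium kernel time constant, s.
#' @param fs imaging rate, Hz.
#' @param noise_sd trace noise SD (SNR = mean a / noise_sd).
#' @param n_fish number of fish the cells are attributed to.
#' @param regions region labels sampled for each cell.
#' @param geom screen geometry for the stimulus drives.
#' @return List of class `calcium_sim_config`.
#' @export
calcium_sim_config <- function(populations = NULL, trains = NULL,
                               inv_tau_ranges = list(depressing = c(-0.009, -0.006),
                                                     potentiating = c(0.006, 0.009),
                                                     stable = c(0, 0)),
                               class_boundary = 0.003,
                               a_range = c(0.8, 1.2), c_range = c(0.05, 0.15),
                               kernel_tau = 3.5, fs = 1, noise_sd = 0.2,
                               n_fish = 7,
                               regions = c("tectum", "tegmentum", "hindbrain",
                                           "pretectum", "thalamus", "pallium"),
                               geom = screen_geometry(64, 64)) {
  if (is.null(populations)) {
    mix <- c(depressing = 0.55, potentiating = 0.18, stable = 0.27)
    populations <- list(
      list(name = "LS", n = 100, bits = c(dm = 0, dl = 1, br = 0, cb = 1),
           class_probs = mix, p_contra = 0.93, gaba_fraction = 0.3,
           binocular_fraction = 0),
      list(name = "DS", n = 100, bits = c(dm = 1, dl = 1, br = 0, cb = 0),
           class_probs = mix, p_contra = 0.49, gaba_fraction = 0.3,
           binocular_fraction = 0))
  }
  if (is.null(trains)) {
    p0 <- looming_params("dark_loom", 0.480, 3, 80, hold_s = 10, refresh_hz = 30,
                         eye = "left")
    types <- c("dm", "dl", "br", "cb")
    kinds <- c(dm = "dimming", dl = "dark_loom", br = "brightening",
               cb = "checker_loom")
    trains <- list()
    t0 <- 60
    for (ty in types) {
      p <- p0; p$kind <- kinds[[ty]]
      trains[[ty]] <- stimulus_train(p, n_trials = 10, isi_s = 40, t0 = t0)
      t0 <- max(trains[[ty]]$end_s) + 60
    }
  }
  for (pop in populations) {
    if (abs(sum(pop$class_probs) - 1) > 1e-9)
      stop("class_probs of population '", pop$name, "' must sum to 1")
  }
  structure(list(populations = populations, trains = trains,
                 inv_tau_ranges = inv_tau_ranges, class_boundary = class_boundary,
                 a_range = a_range,
                 c_range = c_range, kernel_tau = kernel_tau, fs = fs,
                 noise_sd = noise_sd, n_fish = n_fish, regions = regions,
                 geom = geom),
            class = "calcium_sim_config")
}

#' Simulate a calcium population with known ground truth
#'
#' @param cfg a [calcium_sim_config()].
#' @param seed RNG seed.
#' @return List of class `calcium_population`: `traces` (a
#'   [roi_trace_set()]), `trains`, `truth` (one row per cell: population,
#'   planted code/decimal, dynamics class and `(a, inv_tau, c)`, hemisphere,
#'   coordinates, region, fish, GABA flag, binocularity and preferred eye),
#'   `cfg`.
#' @export
simulate_calcium_population <- function(cfg, seed) {
  stopifnot(inherits(cfg, "calcium_sim_config"))
  set.seed(seed)
  trains <- cfg$trains
  types <- names(trains)
  fs <- cfg$fs
  t_end <- max(vapply(trains, function(tr) max(tr$end_s), numeric(1))) + 60
  n_frames <- round(t_end * fs)
  tt <- (seq_len(n_frames) - 1) / fs
  # unit single-trial response per stimulus type: drive convolved with the
  # kernel, normalized to peak 1, so a planted peak amplitude is exact
  unit <- lapply(types, function(ty) {
    tr <- trains[[ty]]
    dur <- stimulus_duration(tr$params) + 5 * cfg$kernel_tau
    ts <- seq(0, dur, by = 1 / fs)
    one <- stimulus_train(tr$params, 1, tr$isi_s, onsets_s = 0)
    u <- exp_kernel_filter(stimulus_drive(one, cfg$geom, ts), cfg$kernel_tau, fs)
    if (max(u) > 0) u / max(u) else u
  })
  names(unit) <- types
  # trains may be named by base type (dm/dl/br/cb) or, for two-eye
  # protocols, as e.g. "dl_right"/"dl_left"; bits are looked up by base type
  base_type <- sub("_(left|right)$", "", types)
  eyes <- vapply(trains, function(tr) tr$params$eye, character(1))
  single_eye <- length(unique(eyes)) == 1
  stim_eye <- eyes[[1]]

  cells <- list()
  F <- list()
  cell_i <- 0L
  for (pop in cfg$populations) {
    # plant exact class counts (largest-remainder rounding) in random order,
    # so the population mixture is the configured one, not a multinomial draw
    target <- pop$class_probs * pop$n
    counts <- floor(target)
    rem <- pop$n - sum(counts)
    if (rem > 0) {
      extra <- order(target - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    cls_seq <- sample(rep(names(pop$class_probs), counts))
    for (j in seq_len(pop$n)) {
      cell_i <- cell_i + 1L
      cls <- cls_seq[j]
      rr <- cfg$inv_tau_ranges[[cls]]
      inv_tau <- stats::runif(1, rr[1], rr[2])
      a <- stats::runif(1, cfg$a_range[1], cfg$a_range[2])
      cc <- stats::runif(1, cfg$c_range[1], cfg$c_range[2])
      binoc <- stats::runif(1) < pop$binocular_fraction
      pref_eye <- if (binoc) NA_character_ else if (single_eye) stim_eye else
        sample(c("left", "right"), 1)
      hemi <- if (binoc) sample(c("left", "right"), 1) else {
        # contralateral bias is defined relative to the eye the cell responds to
        ref <- pref_eye
        contra <- if (ref == "left") "right" else "left"
        if (stats::runif(1) < pop$p_contra) contra else
          if (contra == "left") "right" else "left"
      }
      tr_cell <- numeric(n_frames)
      for (ty in types) {
        bit <- pop$bits[[base_type[match(ty, types)]]]
        if (!bit) next
        tr <- trains[[ty]]
        eye_ok <- binoc || is.na(pref_eye) || tr$params$eye == pref_eye
        if (!eye_ok) next
        u <- unit[[ty]]
        for (k in seq_len(tr$n_trials)) {
          t_k <- tr$onsets_s[k] - tr$onsets_s[1]
          A_k <- a * exp(t_k * inv_tau) + cc
          i0 <- round(tr$onsets_s[k] * fs) + 1L
          idx <- i0:min(n_frames, i0 + length(u) - 1L)
          tr_cell[idx] <- tr_cell[idx] + A_k * u[seq_along(idx)]
        }
      }
      tr_cell <- tr_cell + stats::rnorm(n_frames, 0, cfg$noise_sd)
      F[[cell_i]] <- tr_cell
      x <- (if (hemi == "right") 1 else -1) * stats::runif(1, 5, 200)
      cells[[cell_i]] <- data.frame(
        cell_id = cell_i, population = pop$name,
        decimal = code_decimal(pop$bits[["dm"]], pop$bits[["dl"]],
                               pop$bits[["br"]], pop$bits[["cb"]]),
        dm = pop$bits[["dm"]], dl = pop$bits[["dl"]],
        br = pop$bits[["br"]], cb = pop$bits[["cb"]],
        class = cls, a = a, inv_tau = inv_tau, c = cc,
        hemisphere = hemi, x = x, y = stats::runif(1, 0, 500),
        z = stats::runif(1, 0, 250),
        region = sample(cfg$regions, 1),
        fish_id = ((cell_i - 1L) %% cfg$n_fish) + 1L,
        is_gaba = stats::runif(1) < pop$gaba_fraction,
        binocular = binoc, preferred_eye = pref_eye,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, cells)
  Fm <- do.call(rbind, F)
  structure(list(traces = roi_trace_set(Fm, fs = fs, roi_ids = truth$cell_id,
                                        fish_ids = truth$fish_id),
                 trains = trains, truth = truth, cfg = cfg),
            class = "calcium_population")
}

#' Simulate an ROI label mask and red channel with planted GABA coverage
#'
#' Places non-overlapping elliptical ROIs on a grid and paints red pixels
#' over an exact planted fraction of each ROI (above 0.7 for GABA-true cells,
#' below for the rest). The achieved per-ROI coverage (an exact pixel count)
#' is recorded in the truth table.
#'
#' @param n_rois number of ROIs.
#' @param canvas `c(height, width)` in pixels, at least 128 x 128.
#' @param gaba_fraction fraction of ROIs planted as GABA-positive.
#' @param coverage_gaba,coverage_non uniform ranges for the planted coverage
#'   fraction of GABA-positive and -negative ROIs.
#' @param coverage optional explicit per-ROI coverage fractions (overrides
#'   the random draw; length `n_rois`).
#' @param seed RNG seed.
#' @return List: `mask` (integer label matrix), `red` (numeric matrix in
#'   `[0, 1]`), `truth` (data.frame `roi_id`, `n_px`, `n_red`,
#'   `coverage`, `is_gaba` with `is_gaba = coverage > 0.7`).
#' @export
simulate_roi_images <- function(n_rois = 20, canvas = c(128, 128),
                                gaba_fraction = 0.3,
                                coverage_gaba = c(0.75, 0.95),
                                coverage_non = c(0.1, 0.6),
                                coverage = NULL, seed = 1) {
  if (any(canvas < 128)) stop("canvas must be at least 128 x 128")
  set.seed(seed)
  cell <- 24L
  nr <- canvas[1] %/% cell; nc <- canvas[2] %/% cell
  if (nr * nc < n_rois) stop("canvas too small to place ", n_rois, " ROIs")
  slots <- sample(nr * nc, n_rois)
  mask <- matrix(0L, canvas[1], canvas[2])
  red <- matrix(0, canvas[1], canvas[2])
  if (is.null(coverage)) {
    gaba <- stats::runif(n_rois) < gaba_fraction
    coverage <- ifelse(gaba, stats::runif(n_rois, coverage_gaba[1], coverage_gaba[2]),
                       stats::runif(n_rois, coverage_non[1], coverage_non[2]))
  }
  truth <- list()
  for (i in seq_len(n_rois)) {
    sr <- (slots[i] - 1) %/% nc; sc <- (slots[i] - 1) %% nc
    cy <- sr * cell + cell / 2; cx <- sc * cell + cell / 2
    ry <- stats::runif(1, 5, 9); rx <- stats::runif(1, 5, 9)
    rows <- pmax(1, floor(cy - ry)):pmin(canvas[1], ceiling(cy + ry))
    cols <- pmax(1, floor(cx - rx)):pmin(canvas[2], ceiling(cx + rx))
    sel <- outer(((rows - cy) / ry)^2, ((cols - cx) / rx)^2, "+") <= 1
    px <- which(sel, arr.ind = TRUE)
    px <- cbind(rows[px[, 1]], cols[px[, 2]])
    mask[px] <- i
    n_red <- round(coverage[i] * nrow(px))
    if (n_red > 0) red[px[seq_len(n_red), , drop = FALSE]] <- 1
    truth[[i]] <- data.frame(roi_id = i, n_px = nrow(px), n_red = n_red,
                             coverage = n_red / nrow(px),
                             is_gaba = n_red / nrow(px) > 0.7)
  }
  list(mask = mask, red = red, truth = do.call(rbind, truth))
}

#' Simulate a small tail-tracking video with known deflection
#'
#' Renders a 10-segment tail polyline whose mean lateral deflection follows a
#' supplied (or simulated) deflection trace, with optional flickering fin
#' patches at a fixed beat frequency. Returns the tracked point truth so the
#' deflection pipeline can be validated end to end.
#'
#' @param deflection_px true mean deflection per frame, pixels.
#' @param fps frame rate, Hz.
#' @param canvas `c(height, width)`, at most 256 x 256.
#' @param fin_beat_hz optional fin flash rate; 0 disables the fin patches.
#' @param fin_stop_s time after which fin flicker stops (Inf = never).
#' @param seed RNG seed.
#' @return List: `stack` (`height x width x n_frames` array in `[0, 1]`),
#'   `points` (`n_frames x 20` matrix `x1..x10, y1..y10`), `midline`,
#'   `deflection_px`, `fin_windows`.
#' @export
simulate_tail_video <- function(deflection_px, fps = 50, canvas = c(120, 160),
                                fin_beat_hz = 0, fin_stop_s = Inf, seed = 1) {
  if (any(canvas > 256)) stop("canvas must be at most 256 x 256")
  set.seed(seed)
  n <- length(deflection_px)
  head_xy <- c(canvas[2] * 0.2, canvas[1] / 2)
  axis_dir <- c(1, 0)   # tail extends along +x; deflection is along +y
  seg_len <- canvas[2] * 0.6 / 10
  stack <- array(0.9, dim = c(canvas[1], canvas[2], n))
  points <- matrix(NA_real_, n, 20)
  # quadratic lateral profile: offset_i = s * (i/10)^2, mean deflection =
  # s * mean((1:10/10)^2); scale s so the mean equals the requested deflection
  prof <- (seq_len(10) / 10)^2
  for (f in seq_len(n)) {
    s <- deflection_px[f] / mean(prof)
    xs <- head_xy[1] + seq_len(10) * seg_len * axis_dir[1]
    ys <- head_xy[2] + s * prof
    points[f, ] <- c(xs, ys)
    for (i in seq_len(10)) {
      r <- round(ys[i]); c <- round(xs[i])
      if (r >= 2 && r <= canvas[1] - 1 && c >= 2 && c <= canvas[2] - 1)
        stack[(r - 1):(r + 1), (c - 1):(c + 1), f] <- 0.2
    }
  }
  fin_windows <- list(
    left = list(rows = round(canvas[1] * 0.30) + 0:6,
                cols = round(canvas[2] * 0.12) + 0:6),
    right = list(rows = round(canvas[1] * 0.64) + 0:6,
                 cols = round(canvas[2] * 0.12) + 0:6))
  if (fin_beat_hz > 0) {
    tt <- (seq_len(n) - 1) / fps
    flash <- (tt %% (1 / fin_beat_hz)) < (1 / fps) & tt <= fin_stop_s
    # spatially patterned flash: the motion metric is the SD of the frame
    # difference, which is zero for a spatially uniform intensity step
    for (w in fin_windows) {
      pat <- outer(w$rows, w$cols, "+") %% 2 == 0
      for (f in which(flash)) {
        win <- stack[w$rows, w$cols, f]
        win[pat] <- 0.1
        stack[w$rows, w$cols, f] <- win
      }
    }
  }
  list(stack = stack, points = points,
       midline = list(point = head_xy, direction = axis_dir),
       deflection_px = deflection_px, fin_windows = fin_windows, fps = fps)
}
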