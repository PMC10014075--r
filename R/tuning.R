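#' Fluorescence trace set
#'
#' @param F matrix of fluorescence traces, one ROI per row, one frame per
#'   column (arbitrary units).
#' @param fs imaging rate, Hz (1 Hz in the study's protocol).
#' @param roi_ids,fish_ids per-ROI identifiers (defaults: row index, fish 1).
#' @return Object of class `roi_trace_set`.
#' @export
roi_trace_set <- function(F, fs = 1, roi_ids = NULL, fish_ids = NULL) {
  F <- as.matrix(F)
  stopifnot(fs > 0)
  if (is.null(roi_ids)) roi_ids <- seq_len(nrow(F))
  if (is.null(fish_ids)) fish_ids <- rep(1L, nrow(F))
  stopifnot(length(roi_ids) == nrow(F), length(fish_ids) == nrow(F))
  structure(list(F = F, fs = fs, roi_ids = roi_ids, fish_ids = fish_ids),
            class = "roi_trace_set")
}

#' @export
print.roi_trace_set <- function(x, ...) {
  cat(sprintf("<roi_trace_set> %d ROIs x %d frames at %g Hz\n",
              nrow(x$F), ncol(x$F), x$fs))
  invisible(x)
}

# Pearson r guarded by a variance floor; NA when either input is (near-)constant
pearson_safe <- function(x, y, var_floor = 1e-12) {
  if (stats::var(x) < var_floor || stats::var(y) < var_floor) return(NA_real_)
  stats::cor(x, y)
}

#' Select stimulus/motor-responsive ROIs
#'
#' An ROI is retained if its full-session trace correlates (Pearson,
#' one-sided: positive r only) at or above 0.3 with the stimulus or ISI
#' regressor, or at or above 0.5 with the motor regressor. Tags record which
#' criterion fired.
#'
#' @param traces a [roi_trace_set()] or a plain ROI x frame matrix.
#' @param stim_regressor,isi_regressor,motor_regressor numeric regressors on
#'   the same frame clock as the traces (`isi_regressor` and
#'   `motor_regressor` optional).
#' @param r_stim correlation threshold for the stimulus and ISI regressors.
#' @param r_motor correlation threshold for the motor regressor.
#' @return data.frame with `roi_id`, `r_stim`, `r_isi`, `r_motor`,
#'   `selected`, `reason` (comma-separated tags).
#' @export
select_responsive <- function(traces, stim_regressor, isi_regressor = NULL,
                              motor_regressor = NULL, r_stim = 0.3, r_motor = 0.5) {
  F <- if (inherits(traces, "roi_trace_set")) traces$F else as.matrix(traces)
  ids <- if (inherits(traces, "roi_trace_set")) traces$roi_ids else seq_len(nrow(F))
  check_len <- function(r, nm) {
    if (!is.null(r) && length(r) != ncol(F))
      stop("`", nm, "` length (", length(r), ") does not match frame count (", ncol(F), ")")
  }
  check_len(stim_regressor, "stim_regressor")
  check_len(isi_regressor, "isi_regressor")
  check_len(motor_regressor, "motor_regressor")
  rs <- apply(F, 1, pearson_safe, y = stim_regressor)
  ri <- if (!is.null(isi_regressor)) apply(F, 1, pearson_safe, y = isi_regressor) else NA_real_
  rm_ <- if (!is.null(motor_regressor)) apply(F, 1, pearson_safe, y = motor_regressor) else NA_real_
  hit_s <- !is.na(rs) & rs >= r_stim
  hit_i <- !is.na(ri) & ri >= r_stim
  hit_m <- !is.na(rm_) & rm_ >= r_motor
  reason <- mapply(function(s, i, m)
    paste(c("stimulus"[s], "isi"[i], "motor"[m]), collapse = ","),
    hit_s, hit_i, hit_m)
  data.frame(roi_id = ids, r_stim = rs, r_isi = ri, r_motor = rm_,
             selected = hit_s | hit_i | hit_m, reason = reason,
             stringsAsFactors = FALSE)
}

#' Trial-averaged response of one cell
#'
#' Segments aligned at stimulus onset are baseline-subtracted (mean of the
#' pre-onset span) and averaged across repetitions.
#'
#' @param trace numeric fluorescence trace of one ROI.
#' @param onsets_s stimulus onset times, s.
#' @param window_s averaging window after onset, s.
#' @param baseline_s pre-onset span used for the baseline, s.
#' @param fs sampling rate, Hz.
#' @return Numeric vector of length `round(window_s * fs)` with attributes
#'   `n_reps` and `flagged` (TRUE when fewer than 2 repetitions were inside
#'   the recording).
#' @export
trial_average <- function(trace, onsets_s, window_s, baseline_s = 5, fs = 1) {
  nw <- round(window_s * fs)
  nb <- round(baseline_s * fs)
  n <- length(trace)
  segs <- lapply(onsets_s, function(on) {
    i0 <- round(on * fs) + 1L   # frame at onset
    if (i0 + nw - 1L > n || i0 - nb < 1L) return(NULL)
    base <- mean(trace[(i0 - nb):(i0 - 1L)])
    trace[i0:(i0 + nw - 1L)] - base
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) stop("no stimulus repetition lies fully inside the recording")
  avg <- Reduce(`+`, segs) / length(segs)
  attr(avg, "n_reps") <- length(segs)
  attr(avg, "flagged") <- length(segs) < 2
  avg
}

#' 4-bit stimulus-tuning code of a cell
#'
#' A cell is called responsive to a stimulus type when the Pearson correlation
#' of its average response profile across stimulus types — the concatenation
#' of its per-type trial averages — with that type's regressor exceeds 0.2.
#' The per-type regressor spans the same concatenated profile and is zero
#' outside its own stimulus segment, so the correlation is computed over the
#' full profile (at a 1 Hz imaging rate a single segment is too short for a
#' stable correlation; see the package vignette). The four bits (dimming,
#' dark looming, brightening, checkerboard) carry weights 8/4/2/1, giving a
#' decimal cluster number 0-15: looming-sensitive (LS) cells (dark loom +
#' checkerboard) are cluster 5, dimming-sensitive (DS) cells (dimming + dark
#' loom) are cluster 12.
#'
#' @param trial_averages named list with elements `dm`, `dl`, `br`, `cb`
#'   (trial-averaged responses; `NULL` for a stimulus type not presented).
#' @param regressors named list of regressor segments, same names and lengths
#'   as the trial averages.
#' @param r_code correlation threshold, default 0.2.
#' @param method `"profile"` (default; correlation over the concatenated
#'   across-type profile) or `"segment"` (correlation within each type's own
#'   segment only).
#' @return Object of class `tuning_code`: `bits` (named logical; `NA` when
#'   the type was missing or the correlation undefined), `decimal` (0-15, or
#'   `NA` when any bit is undefined), `correlations`.
#' @export
tuning_code <- function(trial_averages, regressors, r_code = 0.2,
                        method = c("profile", "segment")) {
  method <- match.arg(method)
  types <- c("dm", "dl", "br", "cb")
  weights <- c(dm = 8, dl = 4, br = 2, cb = 1)
  present <- types[!vapply(types, function(ty)
    is.null(trial_averages[[ty]]) || is.null(regressors[[ty]]), logical(1))]
  for (ty in present) {
    if (length(trial_averages[[ty]]) != length(regressors[[ty]]))
      stop("trial average and regressor segment for '", ty, "' differ in length")
  }
  lens <- vapply(present, function(ty) length(trial_averages[[ty]]), integer(1))
  # each segment is mean-centered before concatenation: the per-type baseline
  # offset (shared across a segment's samples) otherwise inflates the null
  # correlation well beyond the 1/sqrt(n) white-noise width
  center <- function(x) as.numeric(x) - mean(x)
  profile <- unlist(lapply(present, function(ty) center(trial_averages[[ty]])),
                    use.names = FALSE)
  r <- sapply(types, function(ty) {
    if (!ty %in% present) return(NA_real_)
    if (method == "segment")
      return(pearson_safe(as.numeric(trial_averages[[ty]]),
                          as.numeric(regressors[[ty]])))
    g <- unlist(lapply(present, function(p)
      if (p == ty) center(regressors[[p]]) else numeric(lens[[p]])),
      use.names = FALSE)
    pearson_safe(profile, g)
  })
  bits <- !is.na(r) & r > r_code          # undefined r (flat trace) -> bit 0
  bits[!types %in% present] <- NA
  decimal <- if (any(is.na(bits))) NA_integer_ else as.integer(sum(weights[bits]))
  structure(list(bits = bits, decimal = decimal, correlations = r),
            class = "tuning_code")
}

#' @export
print.tuning_code <- function(x, ...) {
  b <- ifelse(is.na(x$bits), "?", as.integer(x$bits))
  cat(sprintf("<tuning_code> %s (dm dl br cb) = cluster %s\n",
              paste(b, collapse = " "),
              ifelse(is.na(x$decimal), "NA", x$decimal)))
  invisible(x)
}

#' Decimal cluster number from tuning bits
#' @param dm,dl,br,cb 0/1 bits for dimming, dark looming, brightening,
#'   checkerboard (weights 8/4/2/1); vectorized.
#' @export
code_decimal <- function(dm, dl, br, cb) as.integer(8 * dm + 4 * dl + 2 * br + 1 * cb)

#' Tuning bits from a decimal cluster number
#' @param decimal integer 0-15.
#' @return Named integer vector `(dm, dl, br, cb)`.
#' @export
code_bits <- function(decimal) {
  stopifnot(decimal >= 0, decimal <= 15)
  c(dm = decimal %/% 8 %% 2, dl = decimal %/% 4 %% 2,
    br = decimal %/% 2 %% 2, cb = decimal %% 2)
}

#' Tuning codes for a whole trace set
#'
#' Convenience wrapper: computes per-ROI trial averages for each stimulus
#' type's train and the corresponding regressor segments, then the tuning
#' code of every ROI.
#'
#' @param traces a [roi_trace_set()].
#' @param trains named list of [stimulus_train()] objects (names among `dm`,
#'   `dl`, `br`, `cb`).
#' @param geom a [screen_geometry()] used for the regressor drives.
#' @param kernel_tau calcium kernel time constant, s.
#' @param window_s trial-average window, s; default stimulus duration + 10 s,
#'   truncated at the ISI.
#' @param baseline_s baseline span, s.
#' @param r_code correlation threshold for each bit.
#' @param method correlation mode, see [tuning_code()].
#' @return data.frame with one row per ROI: `roi_id`, bits `dm dl br cb`
#'   (integer 0/1), `decimal`, and correlations `r_dm r_dl r_br r_cb`.
#' @export
tuning_code_table <- function(traces, trains, geom, kernel_tau = 3.5,
                              window_s = NULL, baseline_s = 5, r_code = 0.2,
                              method = "profile") {
  stopifnot(inherits(traces, "roi_trace_set"))
  fs <- traces$fs
  types <- intersect(c("dm", "dl", "br", "cb"), names(trains))
  regs <- list()
  wins <- list()
  for (ty in types) {
    tr <- trains[[ty]]
    w <- if (is.null(window_s))
      min(stimulus_duration(tr$params) + 10, stimulus_duration(tr$params) + tr$isi_s)
    else window_s
    wins[[ty]] <- w
    # regressor segment: single-trial drive convolved with the kernel
    tt <- seq(0, w, by = 1 / fs)[seq_len(round(w * fs))]
    one <- stimulus_train(tr$params, 1, tr$isi_s, onsets_s = 0)
    drive <- stimulus_drive(one, geom, tt)
    regs[[ty]] <- exp_kernel_filter(drive, kernel_tau, fs, normalize = TRUE)
  }
  rows <- lapply(seq_len(nrow(traces$F)), function(i) {
    avgs <- lapply(types, function(ty)
      trial_average(traces$F[i, ], trains[[ty]]$onsets_s, wins[[ty]],
                    baseline_s = baseline_s, fs = fs))
    names(avgs) <- types
    code <- tuning_code(avgs, regs, r_code = r_code, method = method)
    c(as.integer(code$bits), code$decimal, code$correlations)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("dm", "dl", "br", "cb", "decimal", "r_dm", "r_dl", "r_br", "r_cb")
  cbind(data.frame(roi_id = traces$roi_ids), tab)
}

#' Peak latency of a trial-averaged response
#'
#' @param trial_average numeric trial-averaged response aligned at stimulus
#'   onset (first sample = onset).
#' @param fs sampling rate, Hz.
#' @return Latency of the maximum in seconds (earliest maximum on ties), or
#'   `NA` with a warning for a flat average.
#' @export
peak_latency <- function(trial_average, fs = 1) {
  a <- as.numeric(trial_average)
  if (!length(a)) stop("empty trial average")
  if (diff(range(a)) < 1e-12) {
    warning("flat trial average: peak latency undefined")
    return(NA_real_)
  }
  (which.max(a) - 1) / fs
}
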