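#' Per-trial response peak series of one cell
#'
#' For every trial of a train, the response peak is the maximum of the
#' baseline-subtracted trace inside the response window; the cell is counted
#' as having responded on that trial when the peak exceeds
#' `criterion_sd` times the pre-onset standard deviation.
#'
#' @param trace numeric fluorescence trace of one ROI.
#' @param train a [stimulus_train()] on the same clock.
#' @param fs sampling rate, Hz.
#' @param window_s response window after onset, s; default stimulus duration
#'   + 10 s, truncated at the ISI.
#' @param baseline_s pre-onset span for baseline mean and SD, s.
#' @param criterion_sd responded criterion in baseline SDs.
#' @param smooth_s moving-average width applied to the trace before peak
#'   extraction, s (0 disables). Taking a max over tens of unsmoothed frames
#'   is biased upward by noise extremes; a light low-pass at the calcium
#'   indicator's time scale (default 3 s) removes most of that bias while
#'   barely attenuating the response peak.
#' @return data.frame of class `peak_series` with columns `trial`,
#'   `peak_time_s` (trial onset relative to the first onset), `peak_amp`,
#'   `responded`; attribute `n_responded`.
#' @export
extract_peak_series <- function(trace, train, fs = 1, window_s = NULL,
                                baseline_s = 5, criterion_sd = 2, smooth_s = 3) {
  stopifnot(inherits(train, "stimulus_train"))
  kw <- round(smooth_s * fs)
  if (kw > 1) {
    sm <- as.numeric(stats::filter(trace, rep(1 / kw, kw), sides = 2))
    trace <- ifelse(is.na(sm), trace, sm)
  }
  dur <- stimulus_duration(train$params)
  if (is.null(window_s)) window_s <- min(dur + 10, dur + train$isi_s)
  if (train$n_trials > 1 && window_s > min(diff(train$onsets_s)) + 1e-9)
    stop("response windows overlap the next trial; shorten `window_s`")
  nw <- round(window_s * fs)
  nb <- round(baseline_s * fs)
  n <- length(trace)
  rows <- lapply(seq_len(train$n_trials), function(k) {
    i0 <- round(train$onsets_s[k] * fs) + 1L
    if (i0 + nw - 1L > n || i0 - nb < 1L) return(NULL)
    base <- trace[(i0 - nb):(i0 - 1L)]
    pk <- max(trace[i0:(i0 + nw - 1L)] - mean(base))
    c(k, train$onsets_s[k] - train$onsets_s[1], pk, pk > criterion_sd * stats::sd(base))
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- data.frame(trial = as.integer(rows[, 1]), peak_time_s = rows[, 2],
                    peak_amp = rows[, 3], responded = as.logical(rows[, 4]))
  attr(out, "n_responded") <- sum(out$responded)
  class(out) <- c("peak_series", "data.frame")
  out
}

#' Exponential fit to a response peak series
#'
#' Fits \eqn{a \exp(t/\tau) + c} (parameterized by the rate `inv_tau` =
#' 1/tau, in 1/s) to the per-trial peaks by nonlinear least squares.
#' Initialization: `c0` = last peak, `a0` = first minus last peak, `inv_tau0`
#' from a log-linear regression of `peak - c0` on time. The fit requires the
#' cell to have responded on at least three trials; otherwise no fit is
#' returned and the cell is excluded from the dynamics analysis.
#'
#' @param series a `peak_series` from [extract_peak_series()], or any
#'   data.frame with `peak_time_s`, `peak_amp` and `responded`.
#' @return Object of class `exp_fit`: `a`, `inv_tau` (1/s), `c`, `se_inv_tau`,
#'   `ci_inv_tau` (95%, covariance-based), `n_responded`, `fitted` (logical)
#'   and `method` (`"nls"`, or `"linearized"` / `"constant"` for degenerate
#'   series — a flat series leaves the exponential rate unidentified, and the
#'   rate is then taken from the linearized model `slope / intercept`).
#'   Whether the fit is "well fit" is a population-level decision, see
#'   [flag_well_fit()].
#' @export
fit_exponential <- function(series) {
  n_resp <- sum(series$responded)
  out <- structure(list(a = NA_real_, inv_tau = NA_real_, c = NA_real_,
                        se_inv_tau = NA_real_, ci_inv_tau = c(NA_real_, NA_real_),
                        n_responded = n_resp, fitted = FALSE, method = "none"),
                   class = "exp_fit")
  if (n_resp < 3) return(out)
  t <- series$peak_time_s
  y <- series$peak_amp
  # degenerate constant series: a*exp(r t)+c is unidentifiable; the dynamics
  # are exactly flat, report rate 0 with zero-width CI
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    out$a <- 0; out$inv_tau <- 0; out$c <- mean(y)
    out$se_inv_tau <- 0; out$ci_inv_tau <- c(0, 0); out$fitted <- TRUE
    out$method <- "constant"
    return(out)
  }
  # The amplitude is constrained non-negative so the sign of the rate equals
  # the sign of the amplitude trend (without the bound, growing series can be
  # fit equally well by the mirrored decay a < 0, r < 0 saturating at c).
  # Several starts are tried (decay-style c0 at the last peak per the standard
  # initialization, plus growth-style c0 below the smallest peak) and the
  # converged fit with the lowest residual sum of squares is kept.
  trend <- stats::cor(t, y)
  scale_y <- stats::sd(y)          # fit on normalized amplitudes so the
  y <- y / scale_y                 # result is exactly scale-equivariant
  sdy <- 1
  starts <- list()
  add_start <- function(c0) {
    a0 <- max(y[1] - c0, 1e-3 * sdy)
    resid0 <- (y - c0) / a0
    pos <- which(resid0 > 1e-9)
    r0 <- if (length(pos) >= 2)
      unname(stats::coef(stats::lm(log(resid0[pos]) ~ t[pos]))[2])
    else sign(trend + 1e-12) * 1e-3
    if (!is.finite(r0) || r0 == 0) r0 <- sign(trend + 1e-12) * 1e-4
    starts[[length(starts) + 1]] <<- list(a = a0, r = r0, c = c0)
  }
  add_start(y[length(y)])                   # decaying toward the last peak
  add_start(min(y) - 0.5 * sdy)             # growing away from below the data
  add_start(y[1] - 0.5 * (y[length(y)] - y[1]))
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(r * t) + c, start = st,
                        lower = c(a = 0, r = -Inf, c = -Inf),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(f) &&
        (is.null(best) || sum(stats::resid(f)^2) < sum(stats::resid(best)^2)))
      best <- f
  }
  fit <- best
  # Rates faster than the inter-trial spacing cannot be resolved from one
  # peak per trial; beyond that, or when the amplitude collapses to zero
  # (flat series leave the rate unidentified), the nonlinear fit is
  # degenerate and the rate is estimated from the linearized model instead:
  # a*exp(r*t) + c ~ (a + c) + a*r*t, i.e. r ~ slope / intercept.
  r_max <- if (length(t) > 1) 1 / min(diff(t)) else Inf
  degenerate <- is.null(fit)
  if (!degenerate) {
    cf <- stats::coef(fit)
    degenerate <- cf[["a"]] < 0.05 * stats::sd(y) || abs(cf[["r"]]) > r_max
  }
  if (degenerate) {
    lf <- stats::lm(y ~ t)
    b <- stats::coef(lf)
    b0 <- max(b[[1]], stats::sd(y))
    se <- summary(lf)$coefficients[2, 2] / b0
    out$a <- b0 * scale_y; out$inv_tau <- b[[2]] / b0; out$c <- 0
    out$se_inv_tau <- se
    out$ci_inv_tau <- out$inv_tau + c(-1.96, 1.96) * se
    out$fitted <- TRUE
    out$method <- "linearized"
    return(out)
  }
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["r"]], error = function(e) NA_real_)
  out$a <- unname(cf["a"]) * scale_y
  out$inv_tau <- unname(cf["r"])
  out$c <- unname(cf["c"]) * scale_y
  out$se_inv_tau <- unname(se)
  out$ci_inv_tau <- unname(cf["r"]) + c(-1.96, 1.96) * unname(se)
  out$fitted <- TRUE
  out$method <- "nls"
  out
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$fitted)
    cat(sprintf("<exp_fit> not fitted (%d responded trials)\n", x$n_responded))
  else
    cat(sprintf("<exp_fit> a = %.4g, 1/tau = %.4g /s, c = %.4g (95%% CI on 1/tau: %.4g..%.4g)\n",
                x$a, x$inv_tau, x$c, x$ci_inv_tau[1], x$ci_inv_tau[2]))
  invisible(x)
}

#' Collect exponential fits into a table and flag well-fit cells
#'
#' A fit is ill-fit when the 95% confidence interval on its rate (1/tau) is
#' ten times or larger than the largest absolute rate in the population.
#' Ill-fit cells still capture the trend's sign and are later assigned to the
#' depressing/potentiating groups by that sign alone, but their rates are
#' excluded from threshold estimation.
#'
#' @param fits list of `exp_fit` objects (unfitted cells are dropped).
#' @param ids optional cell identifiers, same length as `fits`.
#' @return data.frame `roi_id`, `a`, `inv_tau`, `c`, `ci_lo`, `ci_hi`,
#'   `n_responded`, `well_fit`.
#' @export
flag_well_fit <- function(fits, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(fits)
  keep <- vapply(fits, function(f) isTRUE(f$fitted), logical(1))
  fits <- fits[keep]; ids <- ids[keep]
  tab <- data.frame(roi_id = ids,
                    a = vapply(fits, `[[`, numeric(1), "a"),
                    inv_tau = vapply(fits, `[[`, numeric(1), "inv_tau"),
                    c = vapply(fits, `[[`, numeric(1), "c"),
                    ci_lo = vapply(fits, function(f) f$ci_inv_tau[1], numeric(1)),
                    ci_hi = vapply(fits, function(f) f$ci_inv_tau[2], numeric(1)),
                    n_responded = vapply(fits, `[[`, numeric(1), "n_responded"))
  max_rate <- max(abs(tab$inv_tau), na.rm = TRUE)
  width <- tab$ci_hi - tab$ci_lo
  tab$well_fit <- is.finite(width) & width < 10 * max_rate
  tab
}

#' Population rate thresholds from a double-Gaussian fit
#'
#' The histogram of well-fit rates (1/tau) shows a large peak near zero
#' (stable cells) and a second prominent peak at more negative values
#' (depressing cells). A sum of two Gaussians is least-squares fitted to the
#' bin counts; the full width at half maximum of the near-zero component sets
#' the classification thresholds `mu1 +/- FWHM/2`. An override mode passes
#' externally supplied thresholds through unchanged (e.g. thresholds
#' published for a reference dataset).
#'
#' @param inv_tau rates of well-fit cells, 1/s.
#' @param bins `"fd"` (Freedman-Diaconis, default) or an integer bin count.
#' @param override optional `c(pos_thr, neg_thr)` to bypass estimation.
#' @return Object of class `rate_thresholds`: `pos_thr`, `neg_thr` (1/s),
#'   `near_zero` and `second` component parameters `(mu, sd, A)`,
#'   `bin_width`, `method`.
#' @export
rate_thresholds <- function(inv_tau, bins = "fd", override = NULL) {
  if (!is.null(override)) {
    pos <- max(override); neg <- min(override)
    if (!(neg < pos)) stop("override thresholds must satisfy neg_thr < pos_thr")
    return(structure(list(pos_thr = pos, neg_thr = neg,
                          near_zero = NULL, second = NULL,
                          bin_width = NA_real_, method = "override"),
                     class = "rate_thresholds"))
  }
  x <- inv_tau[is.finite(inv_tau)]
  if (length(x) < 50)
    warning("fewer than 50 well-fit rates; the double-Gaussian fit may be unstable")
  h <- if (identical(bins, "fd")) graphics::hist(x, breaks = "FD", plot = FALSE)
       else graphics::hist(x, breaks = as.integer(bins), plot = FALSE)
  mids <- h$mids; counts <- h$counts
  # initialize the two components from a 1-d 2-means split of the rates
  km <- stats::kmeans(x, centers = sort(c(stats::quantile(x, 0.1), 0)), iter.max = 50)
  mu0 <- as.numeric(km$centers)
  sd0 <- vapply(1:2, function(i) max(stats::sd(x[km$cluster == i]), diff(range(mids)) / 50),
                numeric(1))
  A0 <- vapply(mu0, function(m) max(counts[which.min(abs(mids - m))], 1), numeric(1))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ A1 * exp(-(mids - m1)^2 / (2 * s1^2)) + A2 * exp(-(mids - m2)^2 / (2 * s2^2)),
      start = list(A1 = A0[1], m1 = mu0[1], s1 = sd0[1],
                   A2 = A0[2], m2 = mu0[2], s2 = sd0[2]),
      lower = c(0, -Inf, 0, 0, -Inf, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) stop("double-Gaussian fit failed to converge")
  cf <- stats::coef(fit)
  comp <- list(list(mu = cf[["m1"]], sd = abs(cf[["s1"]]), A = cf[["A1"]]),
               list(mu = cf[["m2"]], sd = abs(cf[["s2"]]), A = cf[["A2"]]))
  near <- which.min(abs(c(comp[[1]]$mu, comp[[2]]$mu)))
  near_zero <- comp[[near]]; second <- comp[[3 - near]]
  if (near_zero$sd < 1e-15 || second$sd < 1e-15 ||
      abs(near_zero$mu - second$mu) < (near_zero$sd + second$sd) / 10)
    stop("degenerate double-Gaussian fit (collapsed or swapped components)")
  fwhm <- 2 * sqrt(2 * log(2)) * near_zero$sd
  structure(list(pos_thr = near_zero$mu + fwhm / 2,
                 neg_thr = near_zero$mu - fwhm / 2,
                 near_zero = near_zero, second = second,
                 bin_width = diff(mids[1:2]), method = "double_gaussian"),
            class = "rate_thresholds")
}

#' @export
print.rate_thresholds <- function(x, ...) {
  cat(sprintf("<rate_thresholds> pos = %.4g /s, neg = %.4g /s (%s)\n",
              x$pos_thr, x$neg_thr, x$method))
  invisible(x)
}

#' Classify habituation dynamics
#'
#' Well-fit cells: rate below the negative threshold are depressing, above
#' the positive threshold potentiating, in between stable. Ill-fit cells are
#' assigned to depressing or potentiating by the sign of their rate alone
#' (never stable).
#'
#' @param inv_tau rates (1/s); vectorized.
#' @param thresholds a [rate_thresholds()] object.
#' @param well_fit logical vector (recycled), from [flag_well_fit()].
#' @return Factor with levels `depressing`, `potentiating`, `stable`.
#' @export
classify_dynamics <- function(inv_tau, thresholds, well_fit = TRUE) {
  stopifnot(inherits(thresholds, "rate_thresholds"))
  well_fit <- rep_len(well_fit, length(inv_tau))
  cls <- ifelse(well_fit,
                ifelse(inv_tau < thresholds$neg_thr, "depressing",
                       ifelse(inv_tau > thresholds$pos_thr, "potentiating", "stable")),
                ifelse(inv_tau < 0, "depressing", "potentiating"))
  factor(cls, levels = c("depressing", "potentiating", "stable"))
}

#' Covert depression contrast between pre-exposure conditions
#'
#' Compares dark-looming response peaks at trials 1, 10 and 11 between two
#' conditions: intervening dimming stimulation versus an equal waiting period.
#' Group medians with standard errors and non-parametric Kruskal-Wallis
#' p-values are reported for the stated contrasts: trial 1 vs 10 within each
#' condition (habituation), trial 1 vs 11 within each condition (recovery),
#' and trial 11 across conditions (the covert-depression effect).
#'
#' @param peaks long data.frame with columns `cell_id`, `condition` (two
#'   levels, e.g. `"dimming"` and `"wait"`), `trial` (must include 1, 10,
#'   11) and `peak`.
#' @return List with `summary` (medians/SE per condition x trial) and
#'   `tests` (data.frame `contrast`, `p_value`).
#' @export
covert_depression_contrast <- function(peaks) {
  need <- c("cell_id", "condition", "trial", "peak")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("`peaks` is missing column(s): ", paste(miss, collapse = ", "))
  conds <- unique(peaks$condition)
  for (cond in conds) {
    have <- unique(peaks$trial[peaks$condition == cond])
    if (!all(c(1, 10, 11) %in% have))
      stop("condition '", cond, "' lacks trials 1, 10 and 11")
  }
  sub <- peaks[peaks$trial %in% c(1, 10, 11), ]
  summary <- do.call(rbind, lapply(split(sub, list(sub$condition, sub$trial), drop = TRUE),
    function(g) data.frame(condition = g$condition[1], trial = g$trial[1],
                           n = nrow(g), median = stats::median(g$peak),
                           se = stats::sd(g$peak) / sqrt(nrow(g)))))
  rownames(summary) <- NULL
  kw <- function(values, groups)
    stats::kruskal.test(values, factor(groups))$p.value
  tests <- list()
  for (cond in conds) {
    g <- sub[sub$condition == cond, ]
    tests[[paste0(cond, ": trial 1 vs 10")]] <-
      kw(g$peak[g$trial %in% c(1, 10)], g$trial[g$trial %in% c(1, 10)])
    tests[[paste0(cond, ": trial 1 vs 11")]] <-
      kw(g$peak[g$trial %in% c(1, 11)], g$trial[g$trial %in% c(1, 11)])
  }
  g11 <- sub[sub$trial == 11, ]
  if (length(conds) >= 2)
    tests[["trial 11 across conditions"]] <- kw(g11$peak, g11$condition)
  list(summary = summary,
       tests = data.frame(contrast = names(tests),
                          p_value = unlist(tests, use.names = FALSE)))
}
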