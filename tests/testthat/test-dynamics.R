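test_that("peak series extraction matches an independent thresholding oracle", {
  p <- imaging_params()
  train <- stimulus_train(p, 5, 40, t0 = 30)
  fs <- 1
  # noiseless: responses every trial with planted amplitudes
  amps <- c(1, 0.8, 0.6, 0.4, 0.3)
  n <- round((max(train$end_s) + 60) * fs)
  trace <- numeric(n)
  for (k in 1:5) {
    i0 <- round(train$onsets_s[k] * fs) + 1
    trace[i0 + 2] <- amps[k]     # single-frame response 2 s after onset
  }
  ps <- extract_peak_series(trace, train, fs = fs, smooth_s = 0)
  expect_equal(ps$peak_amp, amps)
  expect_true(all(ps$responded))
  expect_equal(ps$peak_time_s, (0:4) * unname(diff(train$onsets_s))[1])
  # flat after trial 3 -> responded count 3
  trace2 <- trace
  for (k in 4:5) trace2[round(train$onsets_s[k] * fs) + 3] <- 0
  ps2 <- extract_peak_series(trace2, train, fs = fs, smooth_s = 0)
  expect_equal(attr(ps2, "n_responded"), 3L)
  # noisy responded flags match a direct reimplementation
  set.seed(6)
  trace3 <- trace + stats::rnorm(n, 0, 0.1)
  ps3 <- extract_peak_series(trace3, train, fs = fs, baseline_s = 5,
                             criterion_sd = 2, smooth_s = 0)
  w <- ps3$trial
  oracle <- vapply(w, function(k) {
    i0 <- round(train$onsets_s[k] * fs) + 1
    nw <- round(min(stimulus_duration(p) + 10, stimulus_duration(p) + 40) * fs)
    base <- trace3[(i0 - 5):(i0 - 1)]
    max(trace3[i0:(i0 + nw - 1)] - mean(base)) > 2 * stats::sd(base)
  }, logical(1))
  expect_equal(ps3$responded, oracle)
  expect_error(extract_peak_series(trace, train, fs = fs, window_s = 100),
               "overlap")
})

test_that("exponential fit recovers parameters and handles degeneracies", {
  # noiseless decay recovered to <= 1e-6 relative
  ps <- peak_series_from(a = 1.0, inv_tau = -0.01, c = 0.2)
  f <- fit_exponential(ps)
  expect_equal(f$a, 1.0, tolerance = 1e-6)
  expect_equal(f$inv_tau, -0.01, tolerance = 1e-6)
  expect_equal(f$c, 0.2, tolerance = 1e-6)
  # noiseless growth
  fg <- fit_exponential(peak_series_from(0.5, 0.005, 0.1))
  expect_equal(fg$inv_tau, 0.005, tolerance = 1e-5)
  # constant peaks: rate ~ 0 to 1e-8, stays classified stable downstream
  fc <- fit_exponential(peak_series_from(0, 0, 1))
  expect_lt(abs(fc$inv_tau), 1e-8)
  # fewer than three responded repetitions: no fit
  ps4 <- peak_series_from(1, -0.01, 0.2,
                          responded = c(TRUE, TRUE, rep(FALSE, 8)))
  expect_false(fit_exponential(ps4)$fitted)
})

test_that("exponential fit is scale-equivariant in the amplitude", {
  set.seed(8)
  ps <- peak_series_from(1, -0.008, 0.15, noise_sd = 0.03)
  f1 <- fit_exponential(ps)
  ps2 <- ps; ps2$peak_amp <- 7 * ps$peak_amp
  f2 <- fit_exponential(ps2)
  expect_equal(f2$inv_tau, f1$inv_tau, tolerance = 1e-8)
  expect_equal(f2$a, 7 * f1$a, tolerance = 1e-6)
  expect_equal(f2$c, 7 * f1$c, tolerance = 1e-6)
})

test_that("noisy rate recovery succeeds in at least 90% of replicates", {
  set.seed(12)
  # trial spacing 60 s: at shorter spacings the Fisher information on the
  # rate is too low for 90% within-25% recovery even for an ideal estimator
  ok <- replicate(500, {
    f <- fit_exponential(peak_series_from(1, -0.01, 0.2, isi_s = 60,
                                          noise_sd = 0.05))
    f$fitted && abs(f$inv_tau - (-0.01)) / 0.01 <= 0.25
  })
  expect_gte(mean(ok), 0.9)
})

test_that("well-fit flagging applies the population CI rule", {
  fits <- list(
    structure(list(a = 1, inv_tau = -0.008, c = 0.1, se_inv_tau = 1e-4,
                   ci_inv_tau = c(-0.0082, -0.0078), n_responded = 10,
                   fitted = TRUE, method = "nls"), class = "exp_fit"),
    structure(list(a = 0.5, inv_tau = 1e-4, c = 0.1, se_inv_tau = 0.05,
                   ci_inv_tau = c(-0.098, 0.098), n_responded = 10,
                   fitted = TRUE, method = "nls"), class = "exp_fit"),
    structure(list(a = NA_real_, inv_tau = NA_real_, c = NA_real_,
                   se_inv_tau = NA_real_, ci_inv_tau = c(NA_real_, NA_real_),
                   n_responded = 2, fitted = FALSE, method = "none"),
              class = "exp_fit"))
  tab <- flag_well_fit(fits, ids = 1:3)
  expect_equal(nrow(tab), 2L)          # unfitted cell dropped
  # CI width 0.196 >= 10 * max rate 0.008 -> ill fit
  expect_equal(tab$well_fit, c(TRUE, FALSE))
})

test_that("double-Gaussian thresholds recover a planted rate mixture", {
  set.seed(5)
  x <- c(stats::rnorm(3500, 0, 1e-5), stats::rnorm(1500, -7.5e-3, 1e-3))
  th <- rate_thresholds(x, bins = 2000)
  expect_lt(abs(th$near_zero$mu), 2.5e-6)
  expect_equal(th$near_zero$sd, 1e-5, tolerance = 0.05)
  expect_equal(th$second$mu, -7.5e-3, tolerance = 0.05)
  fwhm2 <- sqrt(2 * log(2)) * 1e-5
  expect_equal(th$pos_thr, fwhm2, tolerance = 0.05)
  expect_equal(th$neg_thr, -fwhm2, tolerance = 0.05)
  expect_lt(th$neg_thr, th$pos_thr)
  # a single symmetric component about zero gives symmetric thresholds
  set.seed(6)
  x1 <- c(stats::rnorm(4000, 0, 1e-3), stats::rnorm(400, -6e-3, 3e-4))
  th1 <- rate_thresholds(x1, bins = 100)
  expect_equal(th1$pos_thr + th1$neg_thr, 2 * th1$near_zero$mu, tolerance = 1e-9)
  # override mode passes published thresholds through unchanged
  tho <- rate_thresholds(NULL, override = c(4.13e-5, -1.17e-5))
  expect_equal(tho$pos_thr, 4.13e-5)
  expect_equal(tho$neg_thr, -1.17e-5)
  expect_equal(tho$method, "override")
})

test_that("threshold estimation is stable under bin-width halving", {
  set.seed(13)
  x <- c(stats::rnorm(3500, 0, 1e-3), stats::rnorm(1500, -7.5e-3, 1e-3))
  t1 <- rate_thresholds(x, bins = 60)
  t2 <- rate_thresholds(x, bins = 120)
  expect_lt(abs(t1$pos_thr - t2$pos_thr) / abs(t1$pos_thr - t1$near_zero$mu), 0.1)
})

test_that("dynamics classification partitions by thresholds and sign rule", {
  thr <- rate_thresholds(NULL, override = c(4.13e-5, -1.17e-5))
  expect_equal(as.character(classify_dynamics(0, thr)), "stable")
  expect_equal(as.character(classify_dynamics(1e-4, thr)), "potentiating")
  expect_equal(as.character(classify_dynamics(-1e-4, thr)), "depressing")
  # ill-fit cells classified by sign only, never stable
  expect_equal(as.character(classify_dynamics(-1e-6, thr, well_fit = FALSE)),
               "depressing")
  expect_equal(as.character(classify_dynamics(1e-8, thr, well_fit = FALSE)),
               "potentiating")
  # every cell gets exactly one label
  x <- stats::rnorm(100, 0, 1e-4)
  cls <- classify_dynamics(x, thr, rep(c(TRUE, FALSE), 50))
  expect_false(any(is.na(cls)))
  expect_equal(sum(prop.table(table(cls))), 1)
})

test_that("covert depression contrast detects suppressed recovery", {
  set.seed(14)
  mk <- function(cond, mu11) {
    n <- 50
    do.call(rbind, lapply(c(1, 10, 11), function(tr) {
      mu <- c("1" = 1, "10" = 0.4, "11" = mu11)[[as.character(tr)]]
      data.frame(cell_id = seq_len(n), condition = cond, trial = tr,
                 peak = stats::rnorm(n, mu, 0.15))
    }))
  }
  peaks <- rbind(mk("wait", 0.9), mk("dimming", 0.4))
  out <- covert_depression_contrast(peaks)
  p <- out$tests$p_value
  names(p) <- out$tests$contrast
  expect_lt(p[["wait: trial 1 vs 10"]], 0.01)        # habituation
  expect_lt(p[["trial 11 across conditions"]], 0.01)  # covert depression
  # the wait condition recovers far more than the dimming condition
  expect_gt(p[["wait: trial 1 vs 11"]], p[["dimming: trial 1 vs 11"]])
  # identical groups give p near 1 (ties handled by kruskal.test)
  same <- rbind(mk("wait", 0.9), mk("wait2", 0.9))
  same$peak <- rep(seq_len(50), 6) / 50
  out_same <- covert_depression_contrast(same)
  p_same <- out_same$tests$p_value[out_same$tests$contrast ==
                                     "trial 11 across conditions"]
  expect_gt(p_same, 0.95)
  expect_error(covert_depression_contrast(peaks[peaks$trial != 11, ]),
               "trials 1, 10 and 11")
  expect_error(covert_depression_contrast(peaks[, -1]), "cell_id")
})

test_that("planted class fractions are recovered end to end", {
  cfg <- calcium_sim_config()
  pop <- simulate_calcium_population(cfg, 3)
  dl <- pop$trains[["dl"]]
  fits <- lapply(seq_len(nrow(pop$traces$F)), function(i)
    fit_exponential(extract_peak_series(pop$traces$F[i, ], dl, fs = cfg$fs)))
  tab <- flag_well_fit(fits, pop$truth$cell_id)
  thr <- rate_thresholds(NULL, override = c(cfg$class_boundary,
                                            -cfg$class_boundary))
  cls <- classify_dynamics(tab$inv_tau, thr, tab$well_fit)
  rec <- prop.table(table(cls))
  truth <- prop.table(table(pop$truth$class[match(tab$roi_id,
                                                  pop$truth$cell_id)]))
  for (g in names(truth))
    expect_lt(abs(rec[[g]] - truth[[g]]), 0.05)
})
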