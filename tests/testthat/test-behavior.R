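test_that("tail deflection is the signed mean distance from the midline", {
  midline <- list(point = c(0, 0), direction = c(1, 0))
  # all points on the midline -> 0
  pts <- cbind(matrix(1:10, 1), matrix(0, 1, 10))
  tr <- tail_deflection(pts, midline, fps = 100, px_per_mm = 10)
  expect_equal(tr$deflection, 0, ignore_attr = TRUE)
  # all points offset by +10 px = +1 mm perpendicular
  pts2 <- cbind(matrix(1:10, 1), matrix(10, 1, 10))
  expect_equal(tail_deflection(pts2, midline, 100, 10)$deflection, 1,
               ignore_attr = TRUE)
  # curved tail: quadratic offset, mean of the sampled offsets
  off <- 20 * (seq_len(10) / 10)^2
  pts3 <- cbind(matrix(1:10, 1), matrix(off, 1))
  expect_equal(tail_deflection(pts3, midline, 100, 10)$deflection,
               mean(off) / 10, ignore_attr = TRUE)
  # sign flips across the midline
  expect_equal(tail_deflection(cbind(matrix(1:10, 1), matrix(-10, 1, 10)),
                               midline, 100, 10)$deflection, -1,
               ignore_attr = TRUE)
})

test_that("missing frames are interpolated up to the configured gap", {
  midline <- list(point = c(0, 0), direction = c(1, 0))
  pts <- cbind(matrix(rep(1:10, each = 7), 7), matrix(10, 7, 10))
  pts[3, 15] <- NA        # single missing frame
  tr <- tail_deflection(pts, midline, 100, 10, max_gap = 3)
  expect_equal(tr$deflection, rep(1, 7), ignore_attr = TRUE)
  expect_true(attr(tr$deflection, "interpolated")[3])
  pts[3:7, 15] <- NA      # gap longer than max_gap, at the end: left missing
  tr2 <- tail_deflection(pts, midline, 100, 10, max_gap = 3)
  expect_true(all(is.na(tr2$deflection[3:7])))
})

test_that("flick detection finds bends above threshold with analytic onsets", {
  # flat trace: nothing
  expect_equal(nrow(detect_flicks(tail_trace(numeric(1000), 200, 50))), 0L)
  # sub-threshold bend (0.3 mm < 0.4 mm): nothing
  expect_equal(nrow(detect_flicks(bend_trace(-0.3), smooth_s = 0)), 0L)
  # single -1 mm half-sine centered at 2 s
  ev <- detect_flicks(bend_trace(-1.0, center_s = 2, dur_s = 0.4), smooth_s = 0)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$peak_s, 2, tolerance = 1 / 200)
  expect_equal(ev$peak_amp_mm, -1, tolerance = 1e-6)
  expect_lt(ev$onset_s, 2)
  # analytic onset: |a sin(pi (t - t0)/D)| crosses 0.2 at
  # t = t0 + D asin(0.2)/pi with t0 = 1.8, D = 0.4
  t_cross <- 1.8 + 0.4 * asin(0.2) / pi
  expect_equal(ev$onset_s, t_cross, tolerance = 1.5 / 200)
})

test_that("flick detection is sign-symmetric and merges within refractory", {
  tr <- bend_trace(0.8, center_s = 1, dur_s = 0.3, total_s = 4)
  tr$deflection <- tr$deflection +
    bend_trace(-0.9, center_s = 3, dur_s = 0.3, total_s = 4)$deflection
  ev <- detect_flicks(tr, smooth_s = 0)
  trm <- tr; trm$deflection <- -tr$deflection
  evm <- detect_flicks(trm, smooth_s = 0)
  expect_equal(ev$peak_s, evm$peak_s)
  expect_equal(ev$peak_amp_mm, -evm$peak_amp_mm)
  expect_equal(nrow(ev), 2L)
  # counter-bend recorded with opposite sign
  tr2 <- bend_trace(-1, center_s = 2, dur_s = 0.2, total_s = 5)
  tr2$deflection <- tr2$deflection +
    bend_trace(0.5, center_s = 2.2, dur_s = 0.2, total_s = 5)$deflection
  ev2 <- detect_flicks(tr2, smooth_s = 0)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$counter_peak_amp_mm, 0.5, tolerance = 0.02)
})

test_that("uncalibrated traces fall back to pixel thresholds with a warning", {
  tr <- bend_trace(-25, center_s = 2)     # 25 px bend
  tr$px_per_mm <- NA_real_
  tr$calibrated <- FALSE
  expect_warning(ev <- detect_flicks(tr, smooth_s = 0), "pixels")
  expect_equal(nrow(ev), 1L)
})

test_that("responses are assigned to validity windows with stated exclusions", {
  p <- behavior_params()
  train <- stimulus_train(p, 3, 30, t0 = 10)
  w <- expansion_window(p)
  coll <- train$collision_s
  # the 5-degree time for this protocol
  t5 <- train$onsets_s + unname(w["onset_t_rel"]) - 0.240 / tan(2.5 * pi / 180)
  ev <- data.frame(
    onset_s = c(coll[1] - 1.3,          # valid (1.3 s before collision)
                train$onsets_s[2] + 0.1,  # before 5 degrees -> excluded_early
                coll[3] + 1.5,          # >1 s after collision -> excluded_late
                5.0),                   # outside all trials -> spontaneous
    peak_s = c(coll[1] - 1.2, train$onsets_s[2] + 0.2, coll[3] + 1.6, 5.1),
    peak_amp_mm = c(-1.1, -0.8, 0.9, 0.5),
    counter_peak_amp_mm = NA_real_, provenance = NA_character_)
  out <- assign_responses(ev, train, mode = "main")
  expect_equal(out$events$provenance,
               c("evoked", "excluded_early", "excluded_late", "spontaneous"))
  expect_equal(out$trials$responded, c(TRUE, FALSE, FALSE))
  expect_equal(out$trials$response_time_rel_collision_s[1], -1.3)
  expect_equal(out$trials$peak_amp_mm, c(-1.1, 0, 0))
  # first-encounter mode keeps events up to 5 s after expansion end
  out2 <- assign_responses(ev, train, mode = "first_encounter")
  expect_equal(out2$events$provenance[3], "evoked")
  # overlapping windows error when the ISI is too short for the mode
  expect_error(assign_responses(ev, stimulus_train(p, 3, 0.2),
                                mode = "first_encounter"), "overlap")
})

test_that("trial table respects the zero-amplitude accounting identity", {
  cfg <- behavior_sim_config(n_fish = 6)
  s <- simulate_behavior_session(cfg, 21)
  out <- analyze_behavior_session(s)
  for (tab in out$trial_tables) {
    if (!any(tab$responded)) next
    expect_equal(mean(tab$peak_amp_mm),
                 mean(tab$responded) * mean(tab$peak_amp_mm[tab$responded]))
  }
})

test_that("spontaneous rate estimation matches direct division and Poisson truth", {
  ev <- data.frame(onset_s = c(10, 50, 90, 120), peak_s = c(10, 50, 90, 120),
                   peak_amp_mm = 1)
  expect_equal(spontaneous_rate(ev, cbind(0, 150)), 4 / 150)
  expect_equal(spontaneous_rate(ev[0, ], cbind(0, 100)), 0)
  expect_error(spontaneous_rate(ev, cbind(10, 10)), "free time")
  # Poisson process at 0.0266 Hz over 10,000 s: within 3 SE of the rate
  set.seed(4)
  lambda <- 0.0266
  n <- stats::rpois(1, lambda * 1e4)
  ev2 <- data.frame(onset_s = sort(stats::runif(n, 0, 1e4)))
  est <- spontaneous_rate(ev2, cbind(0, 1e4))
  expect_lt(abs(est - lambda), 3 * sqrt(lambda / 1e4))
})

test_that("Poisson correction is exact, clipped and monotone", {
  expect_equal(corrected_probability(0.5, 0, 10), 0.5)
  expect_equal(corrected_probability(0.6, 0.0266, 10),
               0.6 - (1 - exp(-0.266)))
  expect_equal(corrected_probability(0.1, 1, 10), 0)
  expect_error(corrected_probability(1.2, 0, 1), "p_obs")
  expect_error(corrected_probability(0.5, -1, 1), "rate")
  # monotone non-increasing in rate and window
  rates <- seq(0, 0.2, by = 0.01)
  expect_true(all(diff(corrected_probability(0.8, rates, 10)) <= 0))
  wins <- seq(1, 30, by = 1)
  expect_true(all(diff(corrected_probability(0.8, 0.05, wins)) <= 0))
})

test_that("habituation curve recovers a planted time constant", {
  cfg <- behavior_sim_config(n_fish = 200, p1 = 1, tau_h = 60, isi_s = 10)
  s <- simulate_behavior_session(cfg, 11)
  out <- analyze_behavior_session(s)
  expect_true(out$curve$fit$ok)
  expect_lt(abs(out$curve$fit$tau_s - 60) / 60, 0.15)
  # constant probability -> fit rejected (tau unbounded)
  tabs <- replicate(10, data.frame(trial = 1:8, responded = TRUE,
                                   window_s = 8, peak_amp_mm = -1),
                    simplify = FALSE)
  hc <- habituation_curve(tabs, isi_s = 10, rate_hz = 0, n_boot = 50)
  expect_false(hc$fit$ok)
  # single trial and single fish are errors
  expect_error(habituation_curve(tabs[1], 10), "2 fish")
  one <- lapply(tabs, function(t) t[1, ])
  expect_error(habituation_curve(one, 10), "2 trials")
})

test_that("K-means response typing recovers planted archetypes", {
  set.seed(9)
  blob <- function(n, mu) sweep(matrix(stats::rnorm(n * 3, sd = 0.1), n), 2, mu, "+")
  x <- rbind(blob(40, c(5, 0, 0)), blob(40, c(0, 5, 0)))
  colnames(x) <- c("pos_peak", "neg_peak", "rt")
  lab <- classify_response_types(x, k = 2, seed = 3)
  expect_equal(length(unique(lab[1:40])), 1L)
  expect_equal(length(unique(lab[41:80])), 1L)
  expect_true(lab[1] != lab[41])
  # labels ordered by descending mean |pos_peak|: first blob must be cluster 1
  expect_equal(lab[1], 1L)
  # identical rows collapse to one label
  same <- matrix(1, 10, 3, dimnames = list(NULL, colnames(x)))
  expect_equal(classify_response_types(same, k = 3, seed = 1), rep(1L, 10))
  expect_error(classify_response_types(x[1:3, ], k = 5, seed = 1), "exceed")
  expect_error(classify_response_types(x, k = 2), "seed")
  # five archetypes at moderate separation: >= 90% recovery
  set.seed(10)
  mus <- list(c(8, -4, 1), c(6, 0, 1), c(2, 0, 4), c(4, -2, 2), c(0.5, -0.5, 8))
  x5 <- do.call(rbind, lapply(mus, function(m)
    sweep(matrix(stats::rnorm(60 * 3, sd = 0.25), 60), 2, m, "+")))
  colnames(x5) <- colnames(x)
  lab5 <- classify_response_types(x5, k = 5, seed = 7)
  truth5 <- rep(1:5, each = 60)
  agree <- sum(vapply(1:5, function(g)
    max(table(lab5[truth5 == g])), numeric(1)))
  expect_gte(agree / 300, 0.9)
})

test_that("fin motion recovers beat frequency and tuck time", {
  v <- simulate_tail_video(rep(0, 300), fps = 50, fin_beat_hz = 2,
                           fin_stop_s = 4, seed = 1)
  fm <- fin_motion(v$stack, v$fin_windows$left, v$fin_windows$right, fps = 50,
                   ref_event_s = 5)
  expect_equal(fm$beat_freq_hz, 2, tolerance = 0.1)
  expect_equal(fm$tuck_time_s, 4, tolerance = 0.2)
  # static video: zero trace, no beats
  v0 <- simulate_tail_video(rep(0, 100), fps = 50, seed = 1)
  fm0 <- fin_motion(v0$stack, v0$fin_windows$left, v0$fin_windows$right, fps = 50)
  expect_equal(max(fm0$trace$motion), 0)
  expect_true(is.na(fm0$beat_freq_hz))
  expect_error(fin_motion(v0$stack, list(rows = 500:510, cols = 1:5),
                          v0$fin_windows$right, 50), "window")
})

test_that("direction statistics count escapes away from the stimulated eye", {
  tab <- data.frame(responded = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    peak_amp_mm = c(-1, -0.8, -1.2, 0.9, 0))
  expect_equal(direction_stats(tab), 0.75)
  tab$peak_amp_mm <- -abs(tab$peak_amp_mm)
  expect_equal(direction_stats(tab), 1)
  expect_true(is.na(direction_stats(data.frame(responded = FALSE,
                                               peak_amp_mm = 0))))
})
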