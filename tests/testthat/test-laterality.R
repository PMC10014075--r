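test_that("hemispheric index equals brute-force counting on random tables", {
  set.seed(15)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    h <- sample(c("left", "right"), n, replace = TRUE)
    eye <- sample(c("left", "right"), 1)
    brute <- (sum(h == eye) - sum(h != eye)) / n
    expect_identical(hi_single_eye(h, eye), brute)
  }
})

test_that("hemispheric index respects sign conventions and edge cases", {
  # all contralateral -> -1
  expect_equal(hi_single_eye(rep("right", 20), "left"), -1)
  expect_equal(hi_single_eye(rep(c("left", "right"), 10), "left"), 0)
  expect_equal(hi_single_eye(c(rep("left", 10), rep("right", 90)), "left"), -0.8)
  # swapping hemisphere labels negates the index
  h <- c(rep("left", 7), rep("right", 3))
  swapped <- ifelse(h == "left", "right", "left")
  expect_equal(hi_single_eye(h, "left"), -hi_single_eye(swapped, "left"))
  # ambiguous midline cells are excluded
  expect_equal(hi_single_eye(c("left", NA, NA), "left"), 1)
  expect_warning(out <- hi_single_eye(rep(NA_character_, 3), "left"), "undefined")
  expect_true(is.na(out))
  expect_true(all(abs(c(hi_single_eye(sample(c("left", "right"), 50, TRUE),
                                      "right"))) <= 1))
})

test_that("monocular and binocular index variants follow the stated formulas", {
  # all right-eye-selective cells in the left hemisphere -> HI_R = -1
  # (the empty left-eye class warns and reports NA)
  hi <- suppressWarnings(hi_monocular(rep("left", 10), rep("right", 10)))
  expect_equal(unname(hi["right"]), -1)
  expect_true(is.na(hi["left"]))
  # 30 right / 70 left hemisphere, right-eye-selective -> -0.4
  hi2 <- suppressWarnings(hi_monocular(c(rep("right", 30), rep("left", 70)),
                                       rep("right", 100)))
  expect_equal(unname(hi2["right"]), -0.4)
  expect_warning(hi_monocular(rep("left", 5), rep("right", 5)), "left eye")
  # binocular index relative to the right eye
  expect_equal(hi_binocular_right(rep("right", 10)), 1)
  expect_equal(hi_binocular_right(rep(c("left", "right"), 10)), 0)
  expect_equal(hi_binocular_right(c(rep("right", 48), rep("left", 52))), -0.04)
})

test_that("midline tolerance flags ambiguous cells", {
  x <- c(-10, -1, 0, 1.5, 10)
  h <- hemisphere_from_x(x, midline_x = 0, tol_um = 2)
  expect_equal(h, c("left", NA, NA, NA, "right"))
})

test_that("planted lateralization bias is recovered through the index", {
  set.seed(16)
  p_contra <- 0.93
  n <- 500
  # left eye stimulated; contralateral = right hemisphere
  h <- ifelse(stats::runif(n) < p_contra, "right", "left")
  hi <- hi_single_eye(h, "left")
  se <- 2 * sqrt(p_contra * (1 - p_contra) / n)   # HI = 1 - 2*p_hat
  expect_lt(abs(hi - (1 - 2 * p_contra)), 3 * se)
})

test_that("binocularity classes follow the two-eye protocol rules", {
  b <- classify_binocularity(c(1, 0, 1, 0), c(0, 1, 1, 0))
  expect_equal(as.character(b),
               c("monocular_right", "monocular_left", "binocular", "none"))
  expect_error(classify_binocularity(c(1, 0), NULL), "both eye")
})

test_that("planted binocular mixture is recovered at population level", {
  trains <- two_eye_trains(n_trials = 8)
  pops <- list(list(name = "DS", n = 240, bits = c(dm = 1, dl = 1, br = 0, cb = 0),
                    class_probs = c(depressing = 0.55, potentiating = 0.18,
                                    stable = 0.27),
                    p_contra = 0.5, gaba_fraction = 0.3,
                    binocular_fraction = 1 / 3))
  cfg <- calcium_sim_config(populations = pops, trains = trains)
  pop <- simulate_calcium_population(cfg, 17)
  sub <- function(eye) {
    nm <- paste(c("dm", "dl", "br", "cb"), eye, sep = "_")
    tr <- trains[nm]
    names(tr) <- c("dm", "dl", "br", "cb")
    tuning_code_table(pop$traces, tr, cfg$geom)
  }
  cr <- sub("right"); cl <- sub("left")
  b <- classify_binocularity(cr$dl, cl$dl)
  rec <- mean(b == "binocular")
  expect_lt(abs(rec - mean(pop$truth$binocular)), 0.03)
  truth_b <- ifelse(pop$truth$binocular, "binocular",
                    paste0("monocular_", pop$truth$preferred_eye))
  expect_gte(mean(as.character(b) == truth_b), 0.95)
})

test_that("GABA calls are pixel-exact at the 70% overlap boundary", {
  # constructed mask: one ROI of 100 pixels
  mask <- matrix(0L, 40, 40)
  mask[1:10, 1:10] <- 1L
  red <- matrix(0, 40, 40)
  red[1:10, 1:7] <- 1          # exactly 70 of 100 pixels
  out <- gaba_assign(mask, red, binarize = 0.5)
  expect_equal(out$overlap_fraction, 0.7)
  expect_false(out$is_gaba)     # strictly greater than 0.7 required
  red[1, 8] <- 1                # 71 pixels
  expect_true(gaba_assign(mask, red, binarize = 0.5)$is_gaba)
  # full and zero coverage
  expect_equal(gaba_assign(mask, matrix(1, 40, 40), binarize = 0.5)$overlap_fraction, 1)
  expect_equal(gaba_assign(mask, matrix(0, 40, 40), binarize = 0.5)$overlap_fraction, 0)
  expect_error(gaba_assign(mask, red[1:10, 1:10]), "pixel grid")
  expect_error(gaba_assign(mask, red, binarize = 0.5, roi_ids = 2), "no pixels")
})

test_that("GABA calls are invariant to ROI relabeling and binarization route", {
  img <- simulate_roi_images(n_rois = 12, seed = 18)
  out1 <- gaba_assign(img$mask, img$red)                 # otsu
  out2 <- gaba_assign(img$mask, img$red, binarize = 0.5) # manual threshold,
  expect_equal(out1$overlap_fraction, out2$overlap_fraction)  # same binary image
  # relabel ids: fractions unchanged per ROI
  relab <- img$mask
  relab[img$mask > 0] <- 100L + img$mask[img$mask > 0]
  out3 <- gaba_assign(relab, img$red)
  expect_equal(out3$overlap_fraction, out1$overlap_fraction)
  expect_equal(out1$is_gaba, img$truth$is_gaba)
})

test_that("region summary applies the 10-cell / 3-fish filter", {
  cells <- rbind(
    data.frame(region = "tectum", fish_id = rep(1:4, each = 4),
               class = rep(c("depressing", "potentiating", "stable", "depressing"), 4)),
    data.frame(region = "thalamus", fish_id = rep(1:2, each = 6),
               class = "depressing"),                     # 12 cells, 2 fish
    data.frame(region = "habenula", fish_id = 1:9,
               class = "stable"))                         # 9 cells
  out <- region_summary(cells)
  expect_equal(out$region, "tectum")
  expect_equal(out$n_cells, 16L)
  expect_equal(out$n_fish, 4L)
  expect_equal(out$depressing, 8L)
  expect_equal(out$potentiating, 4L)
  expect_equal(out$stable, 4L)
  # explicit tally check: 15 cells, 4 fish, classes 9/4/2
  cells2 <- data.frame(region = "pretectum",
                       fish_id = rep(1:4, length.out = 15),
                       class = rep(c("depressing", "potentiating", "stable"),
                                   c(9, 4, 2)))
  out2 <- region_summary(cells2)
  expect_equal(unlist(out2[, c("depressing", "potentiating", "stable")],
                      use.names = FALSE), c(9L, 4L, 2L))
  expect_error(region_summary(cells[, 1:2]), "class")
})
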