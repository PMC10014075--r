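#' Hemisphere assignment from atlas x-coordinates
#'
#' Cells within `tol_um` of the midsagittal plane are flagged ambiguous
#' (`NA`) and are excluded from hemispheric-index counts.
#'
#' @param x atlas x-coordinate, micrometres; vectorized.
#' @param midline_x x-coordinate of the midsagittal plane.
#' @param tol_um ambiguity tolerance around the midline.
#' @return Character vector `"left"`/`"right"`/`NA` (x < midline = left).
#' @export
hemisphere_from_x <- function(x, midline_x = 0, tol_um = 2) {
  out <- ifelse(x < midline_x, "left", "right")
  out[abs(x - midline_x) <= tol_um] <- NA_character_
  out
}

#' Hemispheric index for single-eye stimulation
#'
#' `HI = (n_ipsilateral - n_contralateral) / n_total` relative to the
#' stimulated eye: -1 means all cells sit in the hemisphere contralateral to
#' the stimulus, 0 means a balanced split.
#'
#' @param hemisphere per-cell hemisphere, `"left"`/`"right"` (`NA` excluded).
#' @param stimulated_eye `"left"` or `"right"`.
#' @return Index in `[-1, 1]`, or `NA` (with a warning) for an empty set.
#' @export
hi_single_eye <- function(hemisphere, stimulated_eye = c("left", "right")) {
  stimulated_eye <- match.arg(stimulated_eye)
  h <- hemisphere[!is.na(hemisphere)]
  if (!length(h)) {
    warning("no cells with an unambiguous hemisphere; HI undefined")
    return(NA_real_)
  }
  n_ipsi <- sum(h == stimulated_eye)
  (n_ipsi - (length(h) - n_ipsi)) / length(h)
}

#' Per-eye hemispheric indices for monocular cells
#'
#' For cells selective to one eye, `HI_R` is the difference between the
#' number of right-eye-selective cells in the right versus left hemisphere,
#' divided by the number of right-eye-selective cells (`HI_L` analogously).
#'
#' @param hemisphere per-cell hemisphere (`NA` excluded).
#' @param preferred_eye per-cell selective eye, `"left"`/`"right"`.
#' @return Named vector `c(right = HI_R, left = HI_L)`; `NA` with a warning
#'   for an empty class.
#' @export
hi_monocular <- function(hemisphere, preferred_eye) {
  stopifnot(length(hemisphere) == length(preferred_eye))
  ok <- !is.na(hemisphere) & !is.na(preferred_eye)
  sapply(c(right = "right", left = "left"), function(eye) {
    sel <- ok & preferred_eye == eye
    if (!any(sel)) {
      warning("no cells selective to the ", eye, " eye; HI undefined")
      return(NA_real_)
    }
    (sum(hemisphere[sel] == eye) - sum(hemisphere[sel] != eye)) / sum(sel)
  })
}

#' Hemispheric index of binocular cells, relative to the right eye
#'
#' `HI_R = (n_right_hemisphere - n_left_hemisphere) / n_total` (the right
#' hemisphere being ipsilateral to the right eye).
#'
#' @param hemisphere per-cell hemisphere (`NA` excluded).
#' @return Index in `[-1, 1]`; `NA` with a warning for an empty set.
#' @export
hi_binocular_right <- function(hemisphere) {
  h <- hemisphere[!is.na(hemisphere)]
  if (!length(h)) {
    warning("no binocular cells with an unambiguous hemisphere; HI undefined")
    return(NA_real_)
  }
  (sum(h == "right") - sum(h == "left")) / length(h)
}

#' Classify binocularity from the two-eye protocol
#'
#' In the two-eye protocol the same stimulus type is presented first to one
#' eye, then to the other; a cell responsive (tuning bit set) under exactly
#' one eye is monocular for that eye, under both eyes binocular, under
#' neither none.
#'
#' @param bit_right,bit_left logical (or 0/1): the stimulus-type tuning bit
#'   under right- and left-eye stimulation; vectorized.
#' @return Factor with levels `monocular_right`, `monocular_left`,
#'   `binocular`, `none`.
#' @export
classify_binocularity <- function(bit_right, bit_left) {
  if (is.null(bit_right) || is.null(bit_left))
    stop("both eye protocols are required; use hi_single_eye() for one-eye data")
  stopifnot(length(bit_right) == length(bit_left))
  r <- as.logical(bit_right); l <- as.logical(bit_left)
  cls <- ifelse(r & l, "binocular",
                ifelse(r, "monocular_right",
                       ifelse(l, "monocular_left", "none")))
  factor(cls, levels = c("monocular_right", "monocular_left", "binocular", "none"))
}

#' GABAergic call from red-channel overlap
#'
#' The mean red-channel (gad1b) image is binarized and overlaid on the ROI
#' label mask; a cell is called GABAergic when the binarized red label covers
#' more than 70% of its ROI pixels.
#'
#' @param roi_mask integer label matrix (0 = background, positive integers =
#'   ROI ids), co-registered with `red_image`.
#' @param red_image numeric matrix, same dimensions.
#' @param binarize `"otsu"` (Otsu's threshold on the normalized image) or a
#'   numeric threshold applied to `red_image` directly.
#' @param overlap_thresh overlap fraction above which a cell is GABAergic.
#' @param roi_ids optional explicit ids to report; an id with no pixels is an
#'   error.
#' @return data.frame `roi_id`, `n_px`, `overlap_fraction`, `is_gaba`.
#' @export
gaba_assign <- function(roi_mask, red_image, binarize = "otsu",
                        overlap_thresh = 0.7, roi_ids = NULL) {
  roi_mask <- as.matrix(roi_mask); red_image <- as.matrix(red_image)
  if (!all(dim(roi_mask) == dim(red_image)))
    stop("`roi_mask` and `red_image` must share the same pixel grid")
  red_bin <- if (is.numeric(binarize)) {
    red_image > binarize
  } else if (identical(binarize, "otsu")) {
    rng <- range(red_image)
    norm <- if (diff(rng) > 0) (red_image - rng[1]) / diff(rng) else red_image * 0
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    norm > thr
  } else stop("`binarize` must be \"otsu\" or a numeric threshold")
  if (is.null(roi_ids)) roi_ids <- sort(unique(roi_mask[roi_mask > 0]))
  rows <- lapply(roi_ids, function(id) {
    px <- roi_mask == id
    n <- sum(px)
    if (n == 0) stop("ROI id ", id, " has no pixels")
    frac <- sum(red_bin & px) / n
    data.frame(roi_id = id, n_px = n, overlap_fraction = frac,
               is_gaba = frac > overlap_thresh)
  })
  do.call(rbind, rows)
}

#' Region summary with cell- and fish-count filters
#'
#' Regions are reported only when they contain at least `min_cells` cells
#' contributed by at least `min_fish` distinct fish; within each kept region
#' the cells are tallied by class (e.g. dynamics class) and, if present, by
#' GABA flag.
#'
#' @param cells data.frame with columns `region`, `fish_id`, `class` and
#'   optionally `is_gaba`.
#' @param min_cells,min_fish filter thresholds (defaults 10 cells, 3 fish).
#' @return data.frame with one row per kept region: `region`, `n_cells`,
#'   `n_fish`, one count column per class level and, if available, `n_gaba`.
#' @export
region_summary <- function(cells, min_cells = 10, min_fish = 3) {
  need <- c("region", "fish_id", "class")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("`cells` is missing column(s): ", paste(miss, collapse = ", "))
  lv <- if (is.factor(cells$class)) levels(cells$class) else sort(unique(as.character(cells$class)))
  rows <- lapply(split(cells, cells$region), function(g) {
    if (nrow(g) < min_cells || length(unique(g$fish_id)) < min_fish) return(NULL)
    counts <- table(factor(as.character(g$class), levels = lv))
    row <- data.frame(region = g$region[1], n_cells = nrow(g),
                      n_fish = length(unique(g$fish_id)))
    for (cl in lv) row[[cl]] <- as.integer(counts[[cl]])
    if ("is_gaba" %in% names(g)) row$n_gaba <- sum(g$is_gaba)
    row
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(region = character(0), n_cells = integer(0), n_fish = integer(0))
    for (cl in lv) out[[cl]] <- integer(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
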