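# CSV is the canonical table format: long layout, one row per entity x
# observation, plain numeric columns. Readers validate the header and name
# the offending column on mismatch.

check_schema <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Read / write loomhab tables as CSV
#'
#' Thin, schema-checked wrappers around [utils::read.csv()] and
#' [utils::write.csv()]. Round trips are lossless for numeric values to full
#' double precision (`write.csv` uses 15 significant digits).
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param required character vector of required column names (checked on
#'   read; the error names the missing column).
#' @return `read_table_csv` returns the data.frame; writers return the path
#'   invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(required)) check_schema(df, required, basename(path))
  df
}

#' @rdname write_table_csv
#' @export
read_events_csv <- function(path) {
  df <- read_table_csv(path, c("onset_s", "peak_s", "peak_amp_mm"))
  if (!"counter_peak_amp_mm" %in% names(df)) df$counter_peak_amp_mm <- NA_real_
  if (!"provenance" %in% names(df)) df$provenance <- NA_character_
  class(df) <- c("flick_events", "data.frame")
  df
}

#' @rdname write_table_csv
#' @export
read_trials_csv <- function(path)
  read_table_csv(path, c("trial", "onset_s", "collision_s", "responded",
                         "peak_amp_mm"))

#' Read a fluorescence matrix from CSV
#'
#' Wide layout: one row per ROI, a `roi_id` column (and optionally
#' `fish_id`) followed by one column per frame.
#'
#' @param path CSV path.
#' @param fs imaging rate, Hz.
#' @return A [roi_trace_set()].
#' @export
read_traces_csv <- function(path, fs = 1) {
  df <- read_table_csv(path, "roi_id")
  fish <- if ("fish_id" %in% names(df)) df$fish_id else NULL
  keep <- setdiff(names(df), c("roi_id", "fish_id"))
  roi_trace_set(as.matrix(df[, keep, drop = FALSE]), fs = fs,
                roi_ids = df$roi_id, fish_ids = fish)
}

#' @rdname read_traces_csv
#' @param traces a [roi_trace_set()].
#' @export
write_traces_csv <- function(traces, path) {
  df <- data.frame(roi_id = traces$roi_ids, fish_id = traces$fish_ids)
  fm <- as.data.frame(traces$F)
  names(fm) <- paste0("f", seq_len(ncol(fm)))
  write_table_csv(cbind(df, fm), path)
}

#' Read / write 16-bit TIFF label masks and grayscale images
#'
#' Label masks hold integer ROI ids (stored as 16-bit samples); images are
#' normalized grayscale in `[0, 1]` (stored as 32-bit float). Round trips are
#' pixel-identical.
#'
#' @param mask integer label matrix (ids 0..65535).
#' @param path file path.
#' @export
write_mask_tiff <- function(mask, path) {
  if (any(mask < 0) || any(mask > 65535)) stop("label ids must fit 16 bits")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' @rdname write_mask_tiff
#' @param img numeric matrix in `[0, 1]`.
#' @export
write_image_tiff <- function(img, path) {
  tiff::writeTIFF(img, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.numeric(m), nrow(m), ncol(m))
}

#' Read a pipeline configuration from JSON or YAML
#'
#' The schema is validated: unknown top-level keys are rejected, so typos in
#' stage parameters fail loudly rather than being ignored.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext))
  known <- c("seed", "outdir", "behavior", "calcium", "images",
             "thresholds_override", "mode", "kernel_tau")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a behavioral cohort and a calcium population, runs every
#' analysis stage in dependency order (flick detection, response assignment,
#' Poisson-corrected habituation curve; responsive-cell selection, tuning
#' codes, peak-series exponential fits, rate thresholds and dynamics
#' classification; hemispheric indices, GABA calls from simulated ROI images,
#' region summary) and writes the stage tables plus a JSON run report.
#' Deterministic given `seed`.
#'
#' @param config named list (or path readable by [read_config()]); recognized
#'   keys: `seed`, `outdir`, `behavior` (arguments to
#'   [behavior_sim_config()]), `calcium` (arguments to
#'   [calcium_sim_config()]), `images` (arguments to
#'   [simulate_roi_images()]), `thresholds_override` (`c(pos, neg)`).
#' @param seed overrides `config$seed` when given.
#' @return List of class `run_report`: per-stage record counts, parameter
#'   echo, summary tables (habituation curve, 16-cluster census, dynamics
#'   fractions, HI values, GABA fraction) and the output file list.
#' @export
run_pipeline <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  seed <- seed %||% config$seed %||% 1L
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  files <- character(0)
  emit <- function(df, name) {
    if (!is.null(outdir)) {
      p <- file.path(outdir, paste0(name, ".csv"))
      write_table_csv(df, p)
      files[[length(files) + 1]] <<- p
    }
  }

  # -- behavior ---------------------------------------------------------------
  bcfg <- stage("behavior_sim", do.call(behavior_sim_config, config$behavior %||% list()))
  session <- stage("behavior_sim", simulate_behavior_session(bcfg, seed))
  beh <- stage("behavior_analysis", analyze_behavior_session(session))
  emit(do.call(rbind, Map(cbind, fish = seq_along(beh$trial_tables), beh$trial_tables)),
       "trial_table")
  emit(beh$curve$curve, "habituation_curve")

  # -- calcium ----------------------------------------------------------------
  ccfg <- stage("calcium_sim", do.call(calcium_sim_config, config$calcium %||% list()))
  pop <- stage("calcium_sim", simulate_calcium_population(ccfg, seed + 1L))
  codes <- stage("tuning", tuning_code_table(pop$traces, pop$trains, ccfg$geom,
                                             kernel_tau = ccfg$kernel_tau))
  emit(codes, "tuning_codes")
  census <- as.data.frame(table(decimal = factor(codes$decimal, levels = 0:15)),
                          responseName = "n_cells")
  dl_train <- pop$trains[["dl"]]
  fits <- stage("dynamics", lapply(seq_len(nrow(pop$traces$F)), function(i) {
    fit_exponential(extract_peak_series(pop$traces$F[i, ], dl_train, fs = ccfg$fs))
  }))
  fit_tab <- stage("dynamics", flag_well_fit(fits, ids = pop$traces$roi_ids))
  thr <- stage("dynamics", rate_thresholds(
    fit_tab$inv_tau[fit_tab$well_fit],
    override = config$thresholds_override %||%
      c(ccfg$class_boundary, -ccfg$class_boundary)))
  fit_tab$class <- classify_dynamics(fit_tab$inv_tau, thr, fit_tab$well_fit)
  emit(fit_tab, "dynamics_fits")
  dyn_frac <- prop.table(table(fit_tab$class))

  # -- laterality / GABA ------------------------------------------------------
  truth <- pop$truth
  tcode <- merge(truth, codes[, c("roi_id", "decimal")],
                 by.x = "cell_id", by.y = "roi_id", suffixes = c("_true", ""))
  hi <- list(
    LS = hi_single_eye(tcode$hemisphere[tcode$decimal == 5],
                       stimulated_eye = dl_train$params$eye),
    DS = hi_single_eye(tcode$hemisphere[tcode$decimal == 12],
                       stimulated_eye = dl_train$params$eye))
  imgs <- stage("gaba", do.call(simulate_roi_images,
                                c(config$images %||% list(), list(seed = seed + 2L))))
  gaba <- stage("gaba", gaba_assign(imgs$mask, imgs$red))
  emit(gaba, "gaba_calls")
  cells <- data.frame(region = truth$region, fish_id = truth$fish_id,
                      class = fit_tab$class[match(truth$cell_id, fit_tab$roi_id)],
                      is_gaba = truth$is_gaba)
  regions <- region_summary(cells[!is.na(cells$class), ])
  emit(regions, "region_summary")

  report <- structure(list(
    seed = seed,
    n_fish = bcfg$n_fish, n_cells = nrow(truth),
    counts = list(trials = sum(vapply(beh$trial_tables, nrow, integer(1))),
                  events = sum(vapply(beh$assignments,
                                      function(a) nrow(a$events), integer(1))),
                  cells_fit = nrow(fit_tab), gaba_rois = nrow(gaba)),
    spontaneous_rate_hz = beh$rate_hz,
    habituation = list(tau_s = beh$curve$fit$tau_s, a = beh$curve$fit$a,
                       ok = beh$curve$fit$ok),
    curve = beh$curve$curve,
    cluster_census = census,
    dynamics_fractions = as.list(dyn_frac),
    thresholds = list(pos = thr$pos_thr, neg = thr$neg_thr, method = thr$method),
    hemispheric_index = hi,
    gaba_fraction = mean(gaba$is_gaba),
    region_summary = regions,
    files = unlist(files)),
    class = "run_report")
  if (!is.null(outdir)) {
    jsonlite::write_json(report[setdiff(names(report), c("curve", "cluster_census",
                                                         "region_summary"))],
                         file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "\n")
  cat(sprintf("  behavior: %d fish, %d trials, spontaneous rate %.4f Hz, tau %.1f s\n",
              x$n_fish, x$counts$trials, x$spontaneous_rate_hz,
              x$habituation$tau_s))
  cat(sprintf("  calcium: %d cells; dynamics %s\n", x$n_cells,
              paste(sprintf("%s %.0f%%", names(x$dynamics_fractions),
                            100 * unlist(x$dynamics_fractions)), collapse = ", ")))
  cat(sprintf("  HI: LS %.2f, DS %.2f; GABA fraction %.2f\n",
              x$hemispheric_index$LS, x$hemispheric_index$DS, x$gaba_fraction))
  invisible(x)
}
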