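# End-to-end session orchestration: simulate a cohort to disk in the
# device formats, and analyze a session directory into the validity /
# reliability / cohort reports.

#' Simulate a cohort session to disk
#'
#' Writes, per dog and trial, the paired device files (force-plate CSV and
#' pressure-mat frame blocks), the cohort demographics table, a
#' ground-truth manifest (per-dog targets and per-trial realised measures,
#' with injected-artifact annotations) and a session metadata file. Rerun
#' with the same seed and configuration produces byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param params A [cohort_effect_params()].
#' @param seed Integer seed.
#' @return The session directory path, invisibly; the cohort measures
#'   tibble as attribute `cohort`.
#' @export
run_simulate <- function(out_dir, params = cohort_effect_params(), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  coh <- simulate_cohort(params, seed = seed, keep_recordings = TRUE)
  recs <- attr(coh, "recordings")
  dogs <- dplyr::distinct(coh[, c("dog_id", "sex", "breed_type", "age", "weight",
                                  "height_withers", "body_length", "bcs")])
  write_cohort_table(dogs, file.path(out_dir, "cohort.csv"),
                     meta = list(seed = seed, n_dogs = nrow(dogs)))
  for (rec in recs) {
    stem <- file.path(out_dir, sprintf("%s_%s", rec$dog_id, rec$trial_id))
    write_force_csv(rec$force, paste0(stem, "_plate.csv"),
                    meta = list(dog_id = rec$dog_id, trial_id = rec$trial_id,
                                seed = rec$seed))
    write_pressure_frames(rec$pressure, paste0(stem, "_mat.txt"),
                          meta = list(dog_id = rec$dog_id, trial_id = rec$trial_id,
                                      seed = rec$seed))
  }
  manifest <- dplyr::select(coh, "dog_id", "trial", "device", "artifact",
                            "ap_range", "ml_range", "sway_path",
                            "ellipse_area_95")
  write_results_table(manifest, file.path(out_dir, "manifest.csv"),
                      meta = list(seed = seed,
                                  trials_per_dog = params$trials_per_dog))
  write_results_table(attr(coh, "ground_truth"),
                      file.path(out_dir, "ground_truth.csv"),
                      meta = list(seed = seed))
  jsonlite::write_json(
    list(schema = "pawsway-session-v1", seed = seed,
         n_dogs = params$n_dogs, trials_per_dog = params$trials_per_dog),
    file.path(out_dir, "session.json"), auto_unbox = TRUE, pretty = TRUE)
  attr(out_dir, "cohort") <- coh
  invisible(out_dir)
}

#' Analyze a session directory
#'
#' Reads every trial pair, applies quality control, extracts the CoP
#' trajectories from both devices (at their native rates unless
#' `resample_mat` is given), computes the four stability measures per trial
#' and their per-dog means, and writes the report bundle: a validity table
#' (device means/SDs, Pearson r/p, Bland-Altman bias, limits of agreement,
#' trend), a reliability table (ICC(A,k) with CI and band per measure and
#' device), a cohort report (one-way ANOVAs for sex and breed type;
#' regression-family selection for age and weight), and a run log listing
#' discarded trials with reasons and every threshold used.
#'
#' @param in_dir Session directory produced by [run_simulate()] (or files in
#'   the same formats).
#' @param out_dir Report output directory.
#' @param resample_mat Optional rate (Hz) to resample the mat trajectories
#'   to before computing measures (the default analysis uses each device's
#'   native rate; resampling degrades cross-device correlations for
#'   rate-dependent measures and is off by default).
#' @param thresholds [qc_thresholds()] used for trial QC.
#' @param per_trial_agreement Also compute the validity table on per-trial
#'   values (default FALSE: per-dog means, one point per dog).
#' @param calibration_mass If given, mat streams are calibrated with
#'   [calibrate_pressure()] against this mass (kg) before extraction
#'   (the CoP centroid itself is scale-invariant).
#' @return A `sway_report` list: `measures`, `validity`, `reliability`,
#'   `cohort_anova`, `regressions`, `discards`, `n_dogs_analyzed`.
#' @export
run_analyze <- function(in_dir, out_dir = NULL, resample_mat = NULL,
                        thresholds = qc_thresholds(),
                        per_trial_agreement = FALSE,
                        calibration_mass = NULL) {
  if (!dir.exists(in_dir)) stop(sprintf("session directory %s not found", in_dir),
                                call. = FALSE)
  dogs <- read_cohort_table(file.path(in_dir, "cohort.csv"))
  plate_files <- sort(list.files(in_dir, "_plate\\.csv$", full.names = TRUE))
  log_lines <- c(sprintf("pawsway analyze: %s", in_dir),
                 sprintf("thresholds: %s",
                         paste(sprintf("%s=%g", names(thresholds),
                                       unlist(thresholds)), collapse = ", ")),
                 sprintf("resample_mat: %s",
                         if (is.null(resample_mat)) "native rates" else resample_mat))
  rows <- list(); discards <- list()
  for (pf in plate_files) {
    stem <- sub("_plate\\.csv$", "", pf)
    ids <- regmatches(basename(stem),
                      regexec("^(.*)_(trial-\\d+)$", basename(stem)))[[1]]
    force <- read_force_csv(pf)
    pressure <- read_pressure_frames(paste0(stem, "_mat.txt"))
    if (!is.null(calibration_mass)) {
      pressure <- calibrate_pressure(pressure, calibration_mass)
    }
    rec <- structure(list(trial_id = ids[3], dog_id = ids[2],
                          force = force, pressure = pressure),
                     class = "trial_recording")
    qc <- qc_trial(rec, thresholds)
    if (qc$decision == "reject") {
      discards[[length(discards) + 1L]] <-
        tibble::tibble(dog_id = ids[2], trial = ids[3], reason = qc$reason)
      log_lines <- c(log_lines, sprintf("discard %s %s: %s", ids[2], ids[3], qc$reason))
      next
    }
    traj_p <- cop_from_forceplate(force)
    traj_m <- cop_from_pressure(pressure)
    if (!is.null(resample_mat)) traj_m <- resample_trajectory(traj_m, resample_mat)
    trial_no <- as.integer(sub("trial-", "", ids[3]))
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(
      dplyr::mutate(stability_measures(traj_p), device = "force_plate"),
      dplyr::mutate(stability_measures(traj_m), device = "pressure_mat")) |>
      dplyr::mutate(dog_id = ids[2], trial = trial_no, .before = 1)
  }
  if (length(rows) == 0) stop("analysis aborted: no trial passed QC", call. = FALSE)
  measures <- dplyr::left_join(dplyr::bind_rows(rows), dogs, by = "dog_id")
  n_ok <- dplyr::n_distinct(measures$dog_id)
  if (n_ok < 3) {
    stop(sprintf("analysis aborted: fewer than 3 dogs survive QC (%d)", n_ok),
         call. = FALSE)
  }
  validity <- device_validity(measures, per_dog_means = !per_trial_agreement)
  reliability <- device_reliability(measures)
  per_dog <- dplyr::left_join(trial_means(measures), dogs, by = "dog_id")

  anova_rows <- list()
  for (v in c("ap_range", "ml_range", "sway_path", "ellipse_area_95")) {
    for (fac in c("sex", "breed_type")) {
      for (dev in unique(per_dog$device)) {
        sub <- per_dog[per_dog$device == dev, ]
        res <- tryCatch(one_way_anova(sub, !!rlang::sym(v), !!rlang::sym(fac)),
                        error = function(e) NULL)
        if (!is.null(res)) {
          # group-means layout: one row per group, test statistics repeated
          anova_rows[[length(anova_rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(measure = v, device = dev),
            tidy(res), glance(res))
        }
      }
    }
  }
  cohort_anova <- dplyr::bind_rows(anova_rows)

  reg_rows <- list()
  reg_specs <- list(list(x = "age", y = "ap_range"), list(x = "age", y = "ml_range"),
                    list(x = "age", y = "ellipse_area_95"),
                    list(x = "weight", y = "sway_path"))
  for (rs in reg_specs) {
    for (dev in unique(per_dog$device)) {
      sub <- per_dog[per_dog$device == dev, ]
      fit <- tryCatch(select_family(NULL, sub[[rs$x]], sub[[rs$y]]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      all_fams <- purrr::map(fit$candidates, glance) |> dplyr::bind_rows()
      all_fams$selected <- all_fams$family == fit$family
      all_fams$predictor <- rs$x; all_fams$response <- rs$y
      all_fams$device <- dev
      reg_rows[[length(reg_rows) + 1L]] <- all_fams
    }
  }
  regressions <- dplyr::bind_rows(reg_rows)
  discards <- if (length(discards) > 0) dplyr::bind_rows(discards) else
    tibble::tibble(dog_id = character(), trial = character(), reason = character())

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- list(n_dogs = n_ok, n_trials = nrow(measures) / 2,
                 discarded = nrow(discards))
    write_results_table(measures, file.path(out_dir, "measures.csv"), meta)
    write_results_table(validity, file.path(out_dir, "validity.csv"), meta)
    write_results_table(reliability, file.path(out_dir, "reliability.csv"), meta)
    write_results_table(cohort_anova, file.path(out_dir, "cohort_anova.csv"), meta)
    write_results_table(regressions, file.path(out_dir, "regressions.csv"), meta)
    write_results_table(discards, file.path(out_dir, "discards.csv"), meta)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  structure(list(measures = measures, validity = validity,
                 reliability = reliability, cohort_anova = cohort_anova,
                 regressions = regressions, discards = discards,
                 n_dogs_analyzed = n_ok),
            class = "sway_report")
}

#' @export
print.sway_report <- function(x, ...) {
  cat(sprintf("pawsway session report: %d dogs analysed, %d trials discarded\n",
              x$n_dogs_analyzed, nrow(x$discards)))
  cat("\nValidity (per-dog means):\n")
  print(dplyr::select(x$validity, "measure", "mean_a", "mean_b", "pearson_r",
                      "bias", "loa_low", "loa_high"))
  cat("\nReliability:\n")
  print(dplyr::select(x$reliability, "measure", "device", "icc",
                      "ci_low", "ci_high", "band"))
  invisible(x)
}
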