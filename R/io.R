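#' Write a channel to CSV
#'
#' Two-column CSV, header `time_s,value` (force in N, acceleration in
#' m/s^2), full double precision so a round trip preserves samples.
#'
#' @param series a [timeseries()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel <- function(series, path) {
  stopifnot(inherits(series, "timeseries"))
  utils::write.csv(data.frame(time_s = ts_times(series),
                              value = series$samples),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a channel CSV
#'
#' Expects the `time_s,value` layout of [write_channel()]. The rate is
#' inferred from the median timestamp spacing; spacing that deviates
#' from it by more than 1% anywhere is rejected as nonuniform.
#'
#' @param path CSV path.
#' @param expected_units units to attach (`"N"`, `"m/s^2"`, ...).
#' @return a [timeseries()].
#' @export
read_channel <- function(path, expected_units = "N") {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("channel file must have a 'time_s,value' header: ", path)
  if (nrow(d) < 2L) stop("cannot infer a rate from fewer than 2 samples")
  dt <- diff(d$time_s)
  med <- stats::median(dt)
  if (med <= 0) stop("timestamps must increase")
  if (any(abs(dt - med) > 0.01 * med))
    stop("nonuniform sampling (spacing varies by > 1%): ", path)
  timeseries(d$value, rate = 1 / med, start_time = d$time_s[1L],
             units = expected_units)
}

#' Read a trial manifest
#'
#' One row per condition with columns `subject_id`, `sex`,
#' `body_mass_kg`, `speed_ms`, `force_file`, `accel_file`. Returns
#' metadata stubs; channels are loaded separately with
#' [read_channel()]. Duplicate (subject, speed) pairs, unknown sex
#' labels and nonpositive masses are rejected.
#'
#' @param path manifest CSV path.
#' @return data.frame of trial stubs.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "body_mass_kg", "speed_ms",
            "force_file", "accel_file")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(d$sex %in% c("female", "male")))
    stop("unknown sex label(s): ",
         paste(unique(setdiff(d$sex, c("female", "male"))), collapse = ", "))
  if (any(d$body_mass_kg <= 0)) stop("nonpositive body mass in manifest")
  key <- paste(d$subject_id, d$speed_ms)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, speed) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  d
}

#' Write a simulated cohort to disk
#'
#' One CSV per channel (`time_s,value`), a trial manifest
#' (`subject_id,sex,body_mass_kg,speed_ms,force_file,accel_file`), a
#' per-trial ground-truth step table, a countermovement-jump manifest,
#' and a trial-level truth metadata table.
#'
#' @param cohort a `"gait_cohort"` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); truth_meta <- list(); cmj_rows <- list()
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    stem <- sprintf("%s_%0.1fms", tr$subject_id, tr$speed)
    ff <- file.path(dir, paste0(stem, "_force.csv"))
    af <- file.path(dir, paste0(stem, "_accel.csv"))
    write_channel(tr$force, ff)
    write_channel(tr$acceleration, af)
    rows[[i]] <- data.frame(subject_id = tr$subject_id, sex = tr$sex,
                            body_mass_kg = tr$body_mass, speed_ms = tr$speed,
                            force_file = basename(ff),
                            accel_file = basename(af))
    gt <- tr$ground_truth
    utils::write.csv(gt$steps, file.path(dir, paste0(stem, "_truth.csv")),
                     row.names = FALSE, quote = FALSE)
    truth_meta[[i]] <- data.frame(subject_id = tr$subject_id,
                                  speed_ms = tr$speed,
                                  clock_offset = gt$clock_offset,
                                  step_frequency = gt$step_frequency,
                                  contact_time = gt$contact_time,
                                  impact_amplitude = gt$impact_amplitude)
  }
  for (id in names(cohort$cmj)) {
    for (which in c("pre", "post")) {
      cmj <- cohort$cmj[[id]][[which]]
      ff <- file.path(dir, sprintf("%s_cmj_%s_force.csv", id, which))
      af <- file.path(dir, sprintf("%s_cmj_%s_accel.csv", id, which))
      write_channel(cmj$force, ff)
      write_channel(cmj$acceleration, af)
      cmj_rows[[paste(id, which)]] <-
        data.frame(subject_id = id, which = which,
                   force_file = basename(ff), accel_file = basename(af))
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(do.call(rbind, truth_meta),
                   file.path(dir, "truth_meta.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, cmj_rows),
                   file.path(dir, "cmj_manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding the manifest and channel files.
#' @param config a [default_config()] attached to the result.
#' @return a `"gait_cohort"`-shaped list (without ground truth attached
#'   to trials; truth tables stay on disk).
#' @export
read_cohort <- function(dir, config = default_config()) {
  man <- read_manifest(file.path(dir, "manifest.csv"))
  trials <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    trials[[i]] <- trial_recording(
      man$subject_id[i], man$sex[i], man$body_mass_kg[i], man$speed_ms[i],
      force = read_channel(file.path(dir, man$force_file[i]), "N"),
      acceleration = read_channel(file.path(dir, man$accel_file[i]),
                                  "m/s^2"))
  }
  cmj_man <- utils::read.csv(file.path(dir, "cmj_manifest.csv"))
  cmj <- list()
  for (i in seq_len(nrow(cmj_man))) {
    id <- cmj_man$subject_id[i]
    cmj[[id]][[cmj_man$which[i]]] <- list(
      force = read_channel(file.path(dir, cmj_man$force_file[i]), "N"),
      acceleration = read_channel(file.path(dir, cmj_man$accel_file[i]),
                                  "m/s^2"))
  }
  subjects <- unique(man[c("subject_id", "sex", "body_mass_kg")])
  names(subjects)[3L] <- "body_mass"
  structure(list(subjects = subjects, trials = trials, cmj = cmj,
                 config = config),
            class = "gait_cohort")
}

#' Write an experiment report to disk
#'
#' Emits the accuracy metrics, the per sex x speed observed/predicted
#' summary, the paired model comparisons and a plain-text overview into
#' a directory.
#'
#' @param report an `"experiment_report"` from [run_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  if (nrow(report$metrics) == 0L) stop("empty results")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$condition_summary,
                   file.path(dir, "condition_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$paired, file.path(dir, "paired_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(report$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    "Held-out evaluation of accelerometer-based running kinetics",
    sprintf("train subjects: %s",
            paste(report$split$train_subjects, collapse = ", ")),
    sprintf("test subjects:  %s",
            paste(report$split$test_subjects, collapse = ", ")),
    sprintf("seed: %d", report$split$seed), "",
    utils::capture.output(print(report$metrics, row.names = FALSE,
                                digits = 4)), "",
    utils::capture.output(print(report$paired, row.names = FALSE,
                                digits = 4))), con)
  invisible(dir)
}
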