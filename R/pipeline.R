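#' Simulate a complete dataset on disk
#'
#' Writes a synthetic study to a directory in exactly the layout
#' [run_analyze()] consumes: per-session horse and rider IMU CSV logs
#' (accelerations in g), a YAML session manifest, a functional-test CSV, a
#' ground-truth JSON carrying every generator parameter, and a key=value run
#' log. A simulate -> analyze round trip therefore needs no manual file edits.
#'
#' @param out_dir Output directory (created if needed).
#' @param prog A [progression_config()].
#' @param participants Character vector of participant ids for the IMU
#'   session series.
#' @param functional_participants Mapping for [generate_functional_times()].
#' @param seed Integer master seed; all randomness derives from it.
#' @return Invisibly, a list with the manifest path, functional CSV path,
#'   ground-truth path and the truth table.
#' @export
run_simulate <- function(out_dir, prog = progression_config(),
                         participants = c("P1", "P2", "P3", "P4"),
                         functional_participants = list(
                           TUG = c("P1", "P2", "P3"), "10mWT" = "P4"
                         ),
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  truth_all <- list()
  for (p in participants) {
    series <- generate_session_series(prog, participant_id = p, seed = seed)
    truth_all[[p]] <- series$truth
    for (pair in series$pairs) {
      hpath <- file.path(out_dir, sprintf("%s_s%d_horse.csv", p, pair$session_index))
      rpath <- file.path(out_dir, sprintf("%s_s%d_rider.csv", p, pair$session_index))
      write_imu_csv(pair$horse, hpath, acc_units = "g")
      write_imu_csv(pair$rider, rpath, acc_units = "g")
      manifest[[length(manifest) + 1L]] <- list(
        participant = p, session = pair$session_index,
        horse_log = basename(hpath), rider_log = basename(rpath)
      )
    }
  }
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  func <- generate_functional_times(prog, functional_participants, seed = seed)
  functional_path <- file.path(out_dir, "functional.csv")
  utils::write.csv(as.data.frame(unclass(func)), functional_path, row.names = FALSE)
  truth <- do.call(rbind, truth_all)
  rownames(truth) <- NULL
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(
    list(
      seed = seed,
      horse = unclass(prog$horse),
      schedule = truth,
      functional_schedule = prog$functional
    ),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("mode=simulate"),
    sprintf("seed=%d", seed),
    sprintf("participants=%s", paste(participants, collapse = ",")),
    sprintf("sessions=%s", paste(prog$sessions, collapse = ",")),
    sprintf("cadence_spm=%g", prog$horse$cadence_spm),
    sprintf("duration_s=%g", prog$horse$duration_s),
    sprintf("rate_hz=%g", prog$horse$rate_hz)
  ), log_path)
  invisible(list(
    manifest = manifest_path, functional = functional_path,
    ground_truth = truth_path, truth = truth, out_dir = out_dir
  ))
}

#' Analyze a dataset end to end
#'
#' Loads a session manifest, computes [session_metrics()] for every pair
#' (per-session failures are isolated, reported and listed rather than
#' aborting the run), summarises the functional mobility tests, and writes a
#' percent-change report for sessions 4 and 8 against session 1 — the
#' reporting scheme used for both the functional tests and the interaction
#' metrics. Analysis is fully deterministic: rerunning with the same inputs
#' and configuration reproduces byte-identical outputs.
#'
#' Outputs written to `out_dir`: `metrics.csv` (one row per session pair),
#' `functional_summary.csv`, `functional_percent_change.csv`, `report.csv`
#' (percent changes for max_corr [increase-phrased], lag, harmonic RMSE and
#' pooled functional times), `errors.csv` (when any session failed) and
#' `run_log.txt` (every parameter value applied).
#'
#' @param manifest_path Path to the YAML session manifest.
#' @param functional_path Optional path to the functional-test CSV.
#' @param out_dir Output directory.
#' @param params A [metrics_params()] list.
#' @param acc_units Accelerometer units in the logs (`"g"` or `"ms2"`).
#' @return Invisibly, a list with `metrics` (data frame), `summary`,
#'   `report`, `errors` (character vector, empty on full success) and the
#'   output paths.
#' @export
run_analyze <- function(manifest_path, functional_path = NULL, out_dir,
                        params = metrics_params(), acc_units = "g") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- load_session_manifest(manifest_path)
  metrics_rows <- list()
  errors <- character()
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    res <- tryCatch({
      horse <- read_razor_log(e$horse_log, acc_units = acc_units,
                              placement = "horse_back")
      rider <- read_razor_log(e$rider_log, acc_units = acc_units,
                              placement = "rider_head")
      offset <- if (is.na(e$offset_override)) NULL else e$offset_override
      pair <- align_pair(horse, rider, offset = offset,
                         participant_id = e$participant,
                         session_index = e$session)
      as.data.frame(session_metrics(pair, params))
    }, error = function(err) {
      sprintf("participant %s session %d: %s", e$participant, e$session,
              conditionMessage(err))
    })
    if (is.character(res)) errors <- c(errors, res) else {
      metrics_rows[[length(metrics_rows) + 1L]] <- res
    }
  }
  metrics <- if (length(metrics_rows)) do.call(rbind, metrics_rows) else NULL
  metrics_path <- file.path(out_dir, "metrics.csv")
  if (!is.null(metrics)) utils::write.csv(metrics, metrics_path, row.names = FALSE)

  summary_obj <- NULL
  if (!is.null(functional_path)) {
    func <- read_functional_tests(functional_path)
    summary_obj <- functional_summary(func)
    utils::write.csv(summary_obj$by_group,
                     file.path(out_dir, "functional_summary.csv"), row.names = FALSE)
    utils::write.csv(summary_obj$percent_change,
                     file.path(out_dir, "functional_percent_change.csv"),
                     row.names = FALSE)
  }

  report <- session_change_report(metrics,
                                  if (is.null(functional_path)) NULL else func)
  report_path <- file.path(out_dir, "report.csv")
  utils::write.csv(report, report_path, row.names = FALSE)

  if (length(errors)) {
    utils::write.csv(data.frame(error = errors),
                     file.path(out_dir, "errors.csv"), row.names = FALSE)
    warning(sprintf("%d session(s) failed; see errors.csv", length(errors)))
  }
  log_path <- file.path(out_dir, "run_log.txt")
  plines <- vapply(names(params), function(k) {
    sprintf("%s=%s", k, paste(format(params[[k]]), collapse = ","))
  }, character(1))
  writeLines(c("mode=analyze",
               sprintf("manifest=%s", manifest_path),
               sprintf("acc_units=%s", acc_units),
               plines), log_path)
  invisible(list(
    metrics = metrics, summary = summary_obj, report = report, errors = errors,
    paths = list(metrics = metrics_path, report = report_path, log = log_path)
  ))
}

#' Percent-change report across sessions
#'
#' One row per (metric, target session) giving the percent change of the
#' session mean against session 1, mirroring the convention of reporting
#' sessions 4 and 8 relative to the first session. `max_corr` is
#' increase-phrased (positive = correlation grew); the time shift, the
#' harmonic RMSE and the functional-test times are decrease-phrased
#' (positive = the quantity fell).
#'
#' @param metrics Data frame of flattened [session_metrics()] rows (or NULL).
#' @param functional Optional [functional_records] table (pooled over phases).
#' @param target_sessions Sessions to compare against session 1.
#' @return `data.frame(metric, target_session, direction, pct_change)`.
#' @export
session_change_report <- function(metrics, functional = NULL,
                                  target_sessions = c(4L, 8L)) {
  rows <- list()
  add <- function(df, metric, value, direction) {
    if (is.null(df) || !1L %in% df$session) return()
    for (s in intersect(target_sessions, unique(df$session))) {
      pc <- tryCatch(
        percent_change(df, 1L, s, value = value, direction = direction),
        error = function(e) NA_real_
      )
      rows[[length(rows) + 1L]] <<- data.frame(
        metric = metric, target_session = s, direction = direction,
        pct_change = pc, stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(metrics)) {
    add(metrics, "max_corr", "max_corr", "increase")
    add(metrics, "time_shift", "lag_s", "decrease")
    add(metrics, "harmonic_rmse", "rmse_freq_hz", "decrease")
  }
  if (!is.null(functional)) {
    for (test in unique(functional$test)) {
      sub <- functional[functional$test == test, , drop = FALSE]
      add(sub, test, "time_s", "decrease")
    }
  }
  if (!length(rows)) {
    return(data.frame(metric = character(), target_session = integer(),
                      direction = character(), pct_change = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
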