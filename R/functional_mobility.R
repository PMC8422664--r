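#' Build and validate a functional mobility test table
#'
#' Functional mobility was assessed with the Timed Up and Go (TUG) for
#' ambulatory participants and the 10-Meter Walk Test (10mWT) otherwise, once
#' immediately before and once immediately after the riding sessions on days
#' 1, 4 and 8. Each record is one timing observation.
#'
#' @param df `data.frame` with columns `participant`, `session` (in
#'   `{1, 4, 8}`), `phase` (`"pre"`/`"post"`), `test` (`"TUG"`/`"10mWT"`),
#'   `time_s` (positive seconds).
#' @return The validated `data.frame` with class `functional_records`
#'   prepended.
#' @export
functional_records <- function(df) {
  need <- c("participant", "session", "phase", "test", "time_s")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("functional test table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$session <- as.integer(df$session)
  df$time_s <- as.numeric(df$time_s)
  if (!all(df$session %in% c(1L, 4L, 8L))) {
    stop("functional test sessions must be 1, 4 or 8", call. = FALSE)
  }
  if (!all(df$phase %in% c("pre", "post"))) {
    stop("phase must be 'pre' or 'post'", call. = FALSE)
  }
  if (!all(df$test %in% c("TUG", "10mWT"))) {
    stop("test must be 'TUG' or '10mWT'", call. = FALSE)
  }
  if (any(!is.finite(df$time_s)) || any(df$time_s <= 0)) {
    stop("time_s must be finite and positive", call. = FALSE)
  }
  key <- paste(df$participant, df$session, df$phase, df$test)
  if (anyDuplicated(key)) {
    stop("duplicate record for (participant, session, phase, test): ",
         key[duplicated(key)][1], call. = FALSE)
  }
  class(df) <- c("functional_records", class(df))
  df
}

#' Read functional mobility records from CSV
#'
#' @param path CSV with columns `participant`, `session`, `phase`, `test`,
#'   `time_s`.
#' @return A [functional_records] table.
#' @export
read_functional_tests <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  functional_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Percent change of a session mean relative to a baseline session
#'
#' The trend summaries report each later session against session 1 as a
#' percent change of the session means. For decrease-phrased quantities
#' (test completion times, lag, harmonic RMSE) the value is
#' `100 * (mean_baseline - mean_target) / mean_baseline`, so an improvement
#' (smaller time) is a positive percent decrease. For increase-phrased
#' quantities (maximum correlation) the sign convention flips to
#' `100 * (mean_target - mean_baseline) / mean_baseline`.
#'
#' Means pool every observation of the requested sessions (for functional
#' records: across participants and pre/post phases, unless `phase` is
#' given).
#'
#' @param data A [functional_records] table or any `data.frame` with a
#'   `session` column and the value column named by `value`.
#' @param baseline_session,target_session Session indices to compare.
#' @param value Name of the value column (default `"time_s"`).
#' @param direction `"decrease"` (default) or `"increase"` phrasing.
#' @param phase Optional restriction to `"pre"` or `"post"` records.
#' @return Percent change (single number).
#' @export
percent_change <- function(data, baseline_session, target_session,
                           value = "time_s",
                           direction = c("decrease", "increase"),
                           phase = NULL) {
  direction <- match.arg(direction)
  if (!is.null(phase)) data <- data[data$phase == phase, , drop = FALSE]
  b <- data[[value]][data$session == baseline_session]
  t <- data[[value]][data$session == target_session]
  if (length(b) == 0L || length(t) == 0L) {
    stop("coverage error: both sessions must have observations", call. = FALSE)
  }
  mb <- mean(b); mt <- mean(t)
  if (abs(mb) < .Machine$double.eps) {
    stop("undefined-change error: baseline mean is zero", call. = FALSE)
  }
  if (direction == "decrease") 100 * (mb - mt) / mb else 100 * (mt - mb) / mb
}

#' Standard deviation of a (session, phase) group
#'
#' Sample standard deviation (n - 1 denominator) of the completion times
#' across participants within one session and phase, the variability measure
#' used for the pre/post comparison.
#'
#' @param records A [functional_records] table.
#' @param session Session index.
#' @param phase `"pre"` or `"post"`.
#' @param test Optional restriction to one test.
#' @return Standard deviation in seconds.
#' @export
group_sd <- function(records, session, phase, test = NULL) {
  g <- records[records$session == session & records$phase == phase, , drop = FALSE]
  if (!is.null(test)) g <- g[g$test == test, , drop = FALSE]
  if (nrow(g) < 2L) {
    stop("undefined-sd error: fewer than 2 records in the group", call. = FALSE)
  }
  stats::sd(g$time_s)
}

#' Session-trend summary of functional mobility tests
#'
#' Produces, per (test, phase, session), the participant count, mean time and
#' sample standard deviation — the sd is reported as `NA` for single-record
#' groups, mirroring bar-graph summaries that omit error bars for a single
#' participant — plus per-phase percent changes of each later session against
#' session 1.
#'
#' @param records A [functional_records] table.
#' @return List of class `functional_summary` with `by_group` and
#'   `percent_change` data frames.
#' @export
functional_summary <- function(records) {
  stopifnot(inherits(records, "functional_records"))
  groups <- unique(records[, c("test", "phase", "session")])
  groups <- groups[order(groups$test, groups$phase, groups$session), , drop = FALSE]
  by_group <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    x <- records$time_s[records$test == g$test & records$phase == g$phase &
                          records$session == g$session]
    data.frame(
      test = g$test, phase = g$phase, session = g$session,
      n = length(x), mean_s = mean(x),
      sd_s = if (length(x) >= 2L) stats::sd(x) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(by_group) <- NULL
  pc <- list()
  for (test in unique(records$test)) {
    for (phase in unique(records$phase[records$test == test])) {
      sub <- records[records$test == test & records$phase == phase, , drop = FALSE]
      sessions <- sort(unique(sub$session))
      if (!1L %in% sessions) next
      for (s in setdiff(sessions, 1L)) {
        pc[[length(pc) + 1L]] <- data.frame(
          test = test, phase = phase, target_session = s,
          pct_decrease = percent_change(sub, 1L, s),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  percent_change_df <- if (length(pc)) do.call(rbind, pc) else
    data.frame(test = character(), phase = character(),
               target_session = integer(), pct_decrease = numeric())
  structure(list(by_group = by_group, percent_change = percent_change_df),
            class = "functional_summary")
}

#' @export
print.functional_summary <- function(x, ...) {
  cat("<functional_summary>\nGroup means:\n")
  print(x$by_group, row.names = FALSE)
  if (nrow(x$percent_change)) {
    cat("Percent decrease vs session 1:\n")
    print(x$percent_change, row.names = FALSE)
  }
  invisible(x)
}
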