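# SMBG adherence: checks performed vs checks recommended, capped at 100%,
# plus the pre/during rank-based comparison.

#' Read a glucometer device export
#'
#' CSV with columns `participant_id`, `datetime` (ISO-8601) and
#' `glucose_mgdl`. Exact duplicate rows are dropped and records are sorted
#' by time within participant.
#'
#' @param path CSV file.
#' @return data frame with `participant_id`, `measured_at` (POSIXct, UTC)
#'   and `value`.
#' @export
read_device_export <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "datetime", "glucose_mgdl")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("device export missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- data.frame(participant_id = as.character(df$participant_id),
                    measured_at = parse_ts(df$datetime),
                    value = df$glucose_mgdl, stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$participant_id, out$measured_at), , drop = FALSE]
}

#' Write a device-export data frame back to CSV
#'
#' @param records data frame as returned by [read_device_export()].
#' @param path output file.
#' @export
write_device_export <- function(records, path) {
  utils::write.csv(
    data.frame(participant_id = records$participant_id,
               datetime = fmt_ts(records$measured_at),
               glucose_mgdl = records$value),
    path, row.names = FALSE)
  invisible(path)
}

#' Count distinct glucose checks on one day
#'
#' Readings within `dedup_minutes` of each other (chained: each reading
#' within the gap of the previous one) collapse into a single check event,
#' so an immediate fingerstick retest does not count twice.
#'
#' @param records device-record data frame (`participant_id`,
#'   `measured_at`).
#' @param participant_id whose records to count.
#' @param day local calendar day (`Date` or string).
#' @param dedup_minutes retest collapse window (default 5).
#' @return integer number of distinct check events.
#' @export
count_checks <- function(records, participant_id, day, dedup_minutes = 5) {
  day <- as.Date(day)
  ts <- records$measured_at[records$participant_id == participant_id &
                              local_day(records$measured_at) == day]
  if (length(ts) == 0) return(0L)
  ts <- sort(as.numeric(ts))
  as.integer(1L + sum(diff(ts) > dedup_minutes * 60))
}

#' Per-day check counts over a span of days
#'
#' @param records device-record data frame.
#' @param participant_id whose records to count.
#' @param days vector of `Date`s.
#' @param dedup_minutes see [count_checks()].
#' @return named integer vector, one count per day.
#' @export
checks_by_day <- function(records, participant_id, days,
                          dedup_minutes = 5) {
  days <- as.Date(days)
  out <- vapply(days, function(d)
    count_checks(records, participant_id, d, dedup_minutes), integer(1))
  names(out) <- as.character(days)
  out
}

#' Capped adherence percentage for one participant-period
#'
#' Adherence is checks performed divided by checks recommended; a
#' participant who checks more often than recommended still scores 100%.
#' With `cap = "day"` (default) the cap is applied per day before
#' aggregation, so a binge day cannot mask missed days; `cap = "period"`
#' caps only the period total. The integer `pct` is for reporting; the
#' raw `fraction` is retained for statistics.
#'
#' @param performed_by_day integer vector of daily check counts.
#' @param recommended_per_day clinician-recommended checks per day.
#' @param period `"pre"` or `"during"`.
#' @param participant_id optional identifier carried into the summary.
#' @param cap `"day"` or `"period"`.
#' @return an `adherence_summary` list: `participant_id`, `period`,
#'   `performed`, `recommended`, `fraction`, `pct`.
#' @export
adherence_pct <- function(performed_by_day, recommended_per_day,
                          period = c("during", "pre"),
                          participant_id = NA_character_,
                          cap = c("day", "period")) {
  period <- match.arg(period)
  cap <- match.arg(cap)
  if (length(performed_by_day) == 0) stop("period contains no days")
  if (recommended_per_day < 1) {
    stop("recommended_per_day must be >= 1; adherence undefined otherwise")
  }
  recommended <- length(performed_by_day) * recommended_per_day
  performed <- if (cap == "day") {
    sum(pmin(performed_by_day, recommended_per_day))
  } else {
    min(sum(performed_by_day), recommended)
  }
  fraction <- performed / recommended
  structure(list(participant_id = participant_id, period = period,
                 performed = as.integer(performed),
                 recommended = as.integer(recommended),
                 fraction = fraction,
                 pct = as.integer(round_half_up(100 * fraction))),
            class = "adherence_summary")
}

#' @export
print.adherence_summary <- function(x, ...) {
  cat(sprintf("<adherence_summary> %s [%s]: %d/%d checks = %d%%\n",
              x$participant_id, x$period, x$performed, x$recommended,
              x$pct))
  invisible(x)
}

# day spans for the two analysis periods: the 7 days before the enrollment
# day, and the program days starting the first full day after the 24-h
# start delay
participant_period_days <- function(p, period, pre_days = 7) {
  e_day <- local_day(p$enrolled_at)
  if (period == "pre") {
    seq(e_day - pre_days, e_day - 1, by = "day")
  } else {
    start <- local_day(p$enrolled_at + 24 * 3600)
    seq(start, start + p$program_days - 1, by = "day")
  }
}

#' Adherence summaries for a whole cohort
#'
#' For each participant, counts checks day by day over the requested
#' period (pre: the 7 days before enrollment; during: `program_days` days
#' from the first active day) and applies the capped adherence
#' calculation against the clinician-recommended daily checks from the
#' roster.
#'
#' @param records device-record data frame.
#' @param roster list of [participant()] objects.
#' @param period `"pre"` or `"during"`.
#' @param pre_days length of the pre-enrollment window (default 7).
#' @param cap see [adherence_pct()].
#' @param dedup_minutes see [count_checks()].
#' @return data frame, one row per participant: `participant_id`,
#'   `period`, `performed`, `recommended`, `fraction`, `pct`,
#'   `has_records` (whether any device record fell in the period - used
#'   to exclude participants without pre-period data from comparisons).
#' @export
cohort_adherence <- function(records, roster, period = c("during", "pre"),
                             pre_days = 7, cap = "day",
                             dedup_minutes = 5) {
  period <- match.arg(period)
  rows <- lapply(roster, function(p) {
    days <- participant_period_days(p, period, pre_days)
    counts <- checks_by_day(records, p$participant_id, days, dedup_minutes)
    s <- adherence_pct(counts, p$recommended_checks_per_day, period,
                       p$participant_id, cap)
    data.frame(participant_id = s$participant_id, period = s$period,
               performed = s$performed, recommended = s$recommended,
               fraction = s$fraction, pct = s$pct,
               has_records = any(counts > 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare adherence between two periods with a rank-based test
#'
#' Two-sample Wilcoxon rank-sum test on per-participant adherence
#' fractions: exact enumeration when both groups have at most 10 values
#' and there are no ties, otherwise the normal approximation with tie and
#' continuity correction. Shapiro-Wilk normality probabilities, medians
#' and 25th-75th percentiles are reported per group; differences are
#' called significant below 0.05. A paired signed-rank variant is
#' available via `paired = TRUE` for the (paired by design) pre/during
#' comparison, but the unpaired rank-sum is the default.
#'
#' @param pre_pcts,during_pcts numeric vectors of per-participant
#'   adherence (fractions or percents), at least 2 values each.
#' @param paired use the signed-rank test instead.
#' @param exact_max_n largest per-group size for exact enumeration
#'   (default 10).
#' @param alpha significance threshold (default 0.05).
#' @return a `rank_test_result` list: `statistic`, `p_value`, `method`,
#'   `exact`, `significant`, per-group `n`, `median`, `iqr` (25th and
#'   75th percentiles) and `normality_p`.
#' @export
compare_periods <- function(pre_pcts, during_pcts, paired = FALSE,
                            exact_max_n = 10, alpha = 0.05) {
  pre_pcts <- as.numeric(pre_pcts); during_pcts <- as.numeric(during_pcts)
  if (length(pre_pcts) < 2 || length(during_pcts) < 2) {
    stop("each group needs at least 2 values")
  }
  has_ties <- if (paired) {
    d <- during_pcts - pre_pcts
    anyDuplicated(abs(d[d != 0])) > 0 || any(d == 0)
  } else {
    anyDuplicated(c(pre_pcts, during_pcts)) > 0
  }
  exact <- !has_ties && length(pre_pcts) <= exact_max_n &&
    length(during_pcts) <= exact_max_n
  wt <- suppressWarnings(
    stats::wilcox.test(pre_pcts, during_pcts, paired = paired,
                       exact = exact, correct = TRUE))
  shapiro_p <- function(x) {
    if (length(unique(x)) < 3 || length(x) < 3 || length(x) > 5000) {
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }
  grp <- function(x) list(
    n = length(x), median = stats::median(x),
    iqr = unname(stats::quantile(x, c(0.25, 0.75))),
    normality_p = shapiro_p(x))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = wt$method, exact = exact,
                 significant = wt$p.value < alpha, alpha = alpha,
                 pre = grp(pre_pcts), during = grp(during_pcts)),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  fmt_grp <- function(g, nm) sprintf(
    "  %-7s n=%d median %.3f [25th-75th %.3f-%.3f] (Shapiro-Wilk P=%s)\n",
    nm, g$n, g$median, g$iqr[1], g$iqr[2],
    ifelse(is.na(g$normality_p), "NA", sprintf("%.3f", g$normality_p)))
  cat(sprintf("<rank_test_result> %s\n", x$method))
  cat(fmt_grp(x$pre, "pre"), fmt_grp(x$during, "during"), sep = "")
  cat(sprintf("  W = %g, P = %.4g (%ssignificant at %.2g)\n", x$statistic,
              x$p_value, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Write an adherence report: summary CSV plus test-result JSON
#'
#' @param summaries data frame from [cohort_adherence()] (pre and during
#'   rows may be rbound together).
#' @param test a `rank_test_result`, or `NULL` to omit.
#' @param dir output directory (created if needed).
#' @return paths of the files written, invisibly.
#' @export
write_adherence_report <- function(summaries, test, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "adherence_summary.csv")
  utils::write.csv(summaries, csv, row.names = FALSE)
  paths <- csv
  if (!is.null(test)) {
    js <- file.path(dir, "rank_test.json")
    jsonlite::write_json(unclass(test), js, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, js)
  }
  invisible(paths)
}
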