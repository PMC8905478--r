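#' Create a participant record
#'
#' Holds everything the scheduler and engine need: reported mealtimes (the
#' anchors for the four daily reminders), the weekly-message preference,
#' enrollment time, program length, and the clinician-recommended number of
#' daily glucose checks. Mealtimes must be ordered breakfast < lunch <
#' dinner within the day and are fixed for the program duration.
#'
#' @param participant_id opaque identifier.
#' @param breakfast,lunch,dinner local clock times, `"HH:MM"`.
#' @param enrolled_at enrollment timestamp (POSIXct or ISO-8601 string).
#' @param weekly_message_day day of week for the weekly educational and
#'   motivational messages (1-7, Monday = 1, or `"Mon"`..`"Sun"`).
#' @param weekly_message_time local clock time for weekly messages.
#' @param language `"en"` or `"es"`.
#' @param program_days program length in days (default 14).
#' @param recommended_checks_per_day clinician-recommended daily checks
#'   (default 4).
#' @param status one of `"onboarding"`, `"active"`, `"unsubscribed"`,
#'   `"completed"`.
#' @return a `t4s_participant` list.
#' @export
participant <- function(participant_id, breakfast, lunch, dinner,
                        enrolled_at,
                        weekly_message_day = 1L,
                        weekly_message_time = "19:00",
                        language = "en",
                        program_days = 14L,
                        recommended_checks_per_day = 4L,
                        status = "onboarding") {
  b <- parse_hhmm(breakfast); l <- parse_hhmm(lunch); d <- parse_hhmm(dinner)
  if (anyNA(c(b, l, d))) stop("mealtimes must be HH:MM clock times")
  if (!(b < l && l < d)) {
    stop("mealtimes must satisfy breakfast < lunch < dinner")
  }
  if (program_days < 1) stop("program_days must be >= 1")
  if (recommended_checks_per_day < 1)
    stop("recommended_checks_per_day must be >= 1")
  status <- match.arg(status,
                      c("onboarding", "active", "unsubscribed", "completed"))
  structure(list(
    participant_id = as.character(participant_id),
    language = match.arg(language, c("en", "es")),
    breakfast = b, lunch = l, dinner = d,
    weekly_message_day = day_number(weekly_message_day),
    weekly_message_time = parse_hhmm(weekly_message_time),
    enrolled_at = parse_ts(enrolled_at),
    program_days = as.integer(program_days),
    recommended_checks_per_day = as.integer(recommended_checks_per_day),
    status = status
  ), class = "t4s_participant")
}

#' @export
print.t4s_participant <- function(x, ...) {
  cat(sprintf(
    "<t4s_participant> %s [%s] meals %s/%s/%s, weekly %s %s, enrolled %s, %d days, %d checks/day\n",
    x$participant_id, x$status, fmt_hhmm(x$breakfast), fmt_hhmm(x$lunch),
    fmt_hhmm(x$dinner), .day_names[x$weekly_message_day],
    fmt_hhmm(x$weekly_message_time), fmt_ts(x$enrolled_at), x$program_days,
    x$recommended_checks_per_day))
  invisible(x)
}

#' Read a participant roster from CSV
#'
#' One record per participant: `participant_id`, `breakfast`, `lunch`,
#' `dinner` (HH:MM), `weekly_message_day`, `weekly_message_time`,
#' `enrolled_at` (ISO-8601), `program_days`, `recommended_checks_per_day`,
#' and optionally `language`.
#'
#' @param path CSV file.
#' @return list of `t4s_participant` objects, named by id.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "breakfast", "lunch", "dinner",
                "enrolled_at", "recommended_checks_per_day")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("roster is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$participant_id <- as.character(df$participant_id)
  roster <- lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, ])
    participant(
      participant_id = r$participant_id,
      breakfast = r$breakfast, lunch = r$lunch, dinner = r$dinner,
      enrolled_at = r$enrolled_at,
      weekly_message_day = r$weekly_message_day %||% 1L,
      weekly_message_time = r$weekly_message_time %||% "19:00",
      language = r$language %||% "en",
      program_days = r$program_days %||% 14L,
      recommended_checks_per_day = r$recommended_checks_per_day)
  })
  names(roster) <- vapply(roster, `[[`, "", "participant_id")
  roster
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write a participant roster to CSV
#'
#' @param roster list of `t4s_participant` objects.
#' @param path output file.
#' @export
write_roster <- function(roster, path) {
  df <- do.call(rbind, lapply(roster, function(p) {
    data.frame(participant_id = p$participant_id,
               breakfast = fmt_hhmm(p$breakfast),
               lunch = fmt_hhmm(p$lunch),
               dinner = fmt_hhmm(p$dinner),
               weekly_message_day = p$weekly_message_day,
               weekly_message_time = fmt_hhmm(p$weekly_message_time),
               enrolled_at = fmt_ts(p$enrolled_at),
               program_days = p$program_days,
               recommended_checks_per_day = p$recommended_checks_per_day,
               language = p$language,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.empty_schedule <- function() {
  data.frame(participant_id = character(0),
             fire_at = as.POSIXct(character(0), tz = "UTC"),
             category = character(0), slot = character(0),
             stringsAsFactors = FALSE)
}

#' Build the outbound message timetable for one participant
#'
#' Four reminders per active day, anchored to reported mealtimes: 30
#' minutes before breakfast (the fasting check) and one hour after
#' breakfast, lunch and dinner (the postprandial checks). One educational
#' and one motivational message per 7-day window, at the participant's
#' chosen day and time. No event fires earlier than 24 hours after
#' enrollment; the schedule covers the half-open window
#' `[enrolled_at + 24 h, enrolled_at + 24 h + horizon_days)`, so every
#' horizon of `d` days contributes exactly `4 d` reminders and `d/7`
#' educational and motivational messages each, regardless of how the
#' window aligns with clock slots.
#'
#' @param p a [participant()].
#' @param horizon_days number of active days to schedule (default: the
#'   participant's `program_days`).
#' @return data frame of events (`participant_id`, `fire_at`, `category`,
#'   `slot`) sorted by `fire_at`; `slot` is `"none"` for non-reminder
#'   events. Deterministic: identical inputs give identical schedules.
#' @export
build_schedule <- function(p, horizon_days = p$program_days) {
  stopifnot(inherits(p, "t4s_participant"))
  if (horizon_days < 1) stop("horizon_days must be >= 1")
  start <- p$enrolled_at + 24 * 3600
  end <- start + horizon_days * 86400          # half-open [start, end)
  days <- seq(local_day(start) - 1, local_day(end) + 1, by = "day")

  slot_min <- c(fasting = p$breakfast - 30L,
                post_breakfast = p$breakfast + 60L,
                post_lunch = p$lunch + 60L,
                post_dinner = p$dinner + 60L)
  rem <- do.call(rbind, lapply(names(slot_min), function(s) {
    data.frame(participant_id = p$participant_id,
               fire_at = at_clock(days, slot_min[[s]]),
               category = "reminder", slot = s, stringsAsFactors = FALSE)
  }))

  wk_days <- days[weekday_of(days) == p$weekly_message_day]
  wk <- do.call(rbind, lapply(c("educational", "motivational"), function(cat) {
    data.frame(participant_id = p$participant_id,
               fire_at = at_clock(wk_days, p$weekly_message_time),
               category = cat, slot = "none", stringsAsFactors = FALSE)
  }))

  ev <- rbind(rem, wk)
  ev <- ev[ev$fire_at >= start & ev$fire_at < end, , drop = FALSE]
  ev <- ev[order(ev$fire_at, ev$category, ev$slot), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Drop all pending events for a participant after a cut-off
#'
#' Used when a participant texts STOP: every event with `fire_at > as_of`
#' is removed while past events are untouched. Idempotent.
#'
#' @param schedule event data frame as produced by [build_schedule()].
#' @param participant_id participant whose future events are dropped.
#' @param as_of cut-off timestamp.
#' @return the filtered schedule.
#' @export
cancel_future <- function(schedule, participant_id, as_of) {
  as_of <- parse_ts(as_of)
  keep <- !(schedule$participant_id == participant_id &
              schedule$fire_at > as_of)
  out <- schedule[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
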