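# The two-way conversation engine. It is a pure state machine: time is
# supplied externally through tick(), all randomness lives in the
# simulator, and replaying the same inbound stream against the same roster
# always yields a byte-identical message log.

.clarification_body <-
  "Sorry, we didn't understand that. Please reply with your number only."
.stop_ack_body <- paste0(
  "You have been unsubscribed and will receive no more messages. ",
  "Thank you for participating.")

#' Initialize an empty engine state
#'
#' @param catalog message catalog (default: [default_catalog()]).
#' @param thresholds classification thresholds
#'   (default: [glucose_thresholds()]).
#' @param link_window_hours how far back an unanswered reminder can be and
#'   still claim an incoming glucose value (default 3).
#' @return a `t4s_engine` state object.
#' @export
engine_init <- function(catalog = default_catalog(),
                        thresholds = glucose_thresholds(),
                        link_window_hours = 3) {
  structure(list(
    participants = list(),
    schedule = cbind(.empty_schedule(),
                     data.frame(dispatched = logical(0))),
    pending = data.frame(participant_id = character(0), slot = character(0),
                         seq = integer(0),
                         fire_at = as.POSIXct(character(0), tz = "UTC"),
                         answered = logical(0), clarified = logical(0),
                         stringsAsFactors = FALSE),
    catalog = catalog, thresholds = thresholds,
    link_window_hours = link_window_hours,
    log_rows = list(), seq = 0L
  ), class = "t4s_engine")
}

append_log <- function(state, timestamp, direction, participant_id,
                       category, slot = NA_character_, body = "",
                       in_reply_to = NA_integer_, answers = NA_integer_) {
  state$seq <- state$seq + 1L
  state$log_rows[[state$seq]] <- data.frame(
    seq = state$seq, timestamp = parse_ts(timestamp), direction = direction,
    participant_id = participant_id, category = category,
    slot = ifelse(is.na(slot), "none", slot), body = body,
    in_reply_to = as.integer(in_reply_to), answers = as.integer(answers),
    stringsAsFactors = FALSE)
  state
}

#' Extract the message log from an engine state
#'
#' @param state a `t4s_engine`.
#' @return append-only data frame, one row per inbound or outbound
#'   message, ordered by sequence number (timestamp ties broken by
#'   sequence).
#' @export
message_log <- function(state) {
  if (length(state$log_rows) == 0) {
    return(data.frame(seq = integer(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      direction = character(0), participant_id = character(0),
                      category = character(0), slot = character(0),
                      body = character(0), in_reply_to = integer(0),
                      answers = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, state$log_rows)
  rownames(out) <- NULL
  out
}

send_template <- function(state, p, category, now, slot = NA_character_,
                          in_reply_to = NA_integer_,
                          answers = NA_integer_, rank = NULL) {
  if (is.null(rank)) {
    sel <- next_template(state$catalog, p$participant_id, category,
                         p$language)
    state$catalog <- sel$catalog
    body <- sel$template$body
  } else {
    g <- catalog_group(state$catalog, category, p$language)
    row <- g[g$rotation_rank == rank, , drop = FALSE]
    if (nrow(row) == 0) {
      stop(sprintf("catalog gap: no '%s' rank %d for language '%s'",
                   category, rank, p$language), call. = FALSE)
    }
    body <- row$body[1]
  }
  append_log(state, now, "out", p$participant_id, category, slot, body,
             in_reply_to, answers)
}

#' Enroll a participant
#'
#' Queues the welcome message (with opt-out information), the
#' not-monitored-in-real-time disclaimer, and the first onboarding
#' mealtime question. The participant starts in `onboarding` status;
#' glucose reminders begin only once all three mealtime answers are
#' recorded, and never earlier than 24 hours after enrollment.
#'
#' @param state a `t4s_engine`.
#' @param p a [participant()].
#' @param now enrollment timestamp (default: the participant's
#'   `enrolled_at`).
#' @return the updated state.
#' @export
enroll <- function(state, p, now = p$enrolled_at) {
  stopifnot(inherits(state, "t4s_engine"), inherits(p, "t4s_participant"))
  if (p$participant_id %in% names(state$participants)) {
    stop("participant already enrolled: ", p$participant_id)
  }
  p$status <- "onboarding"
  p$onboarding_idx <- 0L
  p$onboarding_answers <- rep(NA_integer_, 3)
  state$participants[[p$participant_id]] <- p
  state <- send_template(state, p, "welcome", now)
  state <- send_template(state, p, "disclaimer", now)
  send_template(state, p, "onboarding_question", now, rank = 0L)
}

#' Parse an inbound SMS text
#'
#' A trimmed, case-insensitive `"STOP"` unsubscribes. During onboarding an
#' `HH:MM` token is a mealtime answer. Otherwise the first numeric token
#' that lands in the plausible glucose window 20-600 mg/dL (after
#' stripping units such as "mg/dl" and rounding half-up) is a glucose
#' value. Anything else is `unrecognized` - a value, not an error.
#'
#' @param text raw message text.
#' @param onboarding is the sender currently answering onboarding
#'   questions?
#' @return list with `kind` (one of `"stop"`, `"glucose_value"`,
#'   `"onboarding_answer"`, `"unrecognized"`), and `value` (integer mg/dL,
#'   glucose only) or `time` (minutes past midnight, onboarding only).
#' @export
parse_inbound <- function(text, onboarding = FALSE) {
  raw <- trimws(as.character(text))
  if (toupper(raw) == "STOP") return(list(kind = "stop"))
  if (onboarding) {
    tok <- regmatches(raw, regexpr("\\b[0-9]{1,2}[:.][0-9]{2}\\b", raw))
    if (length(tok) == 1) {
      mins <- parse_hhmm(sub("\\.", ":", tok))
      if (!is.na(mins)) return(list(kind = "onboarding_answer", time = mins))
    }
  }
  cleaned <- gsub("(?i)mg\\s*/?\\s*dl", " ", raw, perl = TRUE)
  toks <- regmatches(cleaned,
                     gregexpr("[0-9]+(\\.[0-9]+)?", cleaned))[[1]]
  for (tok in toks) {
    v <- round_half_up(as.numeric(tok))
    if (v >= 20 && v <= 600) {
      return(list(kind = "glucose_value", value = as.integer(v)))
    }
  }
  list(kind = "unrecognized")
}

#' Resolve the measurement context of an incoming glucose value
#'
#' If the participant has an unanswered reminder whose fire time lies
#' within the linkage window (default 3 hours) before `received_at`, the
#' most recent such reminder claims the value and its slot fixes the
#' context (the fasting slot gives `fasting`, the three post-meal slots
#' give `postprandial`). Unsolicited values fall back to time of day:
#' before the participant's reported breakfast time counts as fasting,
#' anything later as postprandial.
#'
#' @param state a `t4s_engine`.
#' @param participant_id participant identifier.
#' @param received_at timestamp of the inbound value.
#' @return list with `context` and `reminder_seq` (the claimed reminder's
#'   log sequence number, or `NA` for unsolicited values).
#' @export
link_context <- function(state, participant_id, received_at) {
  received_at <- parse_ts(received_at)
  pend <- state$pending
  win <- state$link_window_hours * 3600
  cand <- pend[pend$participant_id == participant_id & !pend$answered &
                 pend$fire_at <= received_at &
                 as.numeric(received_at) - as.numeric(pend$fire_at) <= win, ,
               drop = FALSE]
  if (nrow(cand) > 0) {
    best <- cand[which.max(as.numeric(cand$fire_at)), ]
    ctx <- if (best$slot == "fasting") "fasting" else "postprandial"
    return(list(context = ctx, reminder_seq = best$seq))
  }
  p <- state$participants[[participant_id]]
  ctx <- if (clock_minutes(received_at) < p$breakfast) "fasting"
         else "postprandial"
  list(context = ctx, reminder_seq = NA_integer_)
}

activate_participant <- function(state, pid, meals) {
  p <- state$participants[[pid]]
  p$breakfast <- meals[1]; p$lunch <- meals[2]; p$dinner <- meals[3]
  p$status <- "active"
  state$participants[[pid]] <- p
  sched <- build_schedule(p)
  sched$dispatched <- FALSE
  state$schedule <- rbind(state$schedule, sched)
  state$schedule <-
    state$schedule[order(state$schedule$fire_at), , drop = FALSE]
  rownames(state$schedule) <- NULL
  state
}

#' Process one inbound message
#'
#' Logs the message verbatim, then acts on the parsed kind: `STOP` cancels
#' all future events, flips the participant to `unsubscribed`, and sends a
#' single acknowledgment (no outbound message ever follows it); a glucose
#' value is contextualized via [link_context()], classified, answered with
#' the tier's feedback template, and marks its claimed reminder answered;
#' an onboarding answer records the next mealtime and advances (or
#' completes) onboarding; an unrecognized text earns at most one
#' clarification prompt per pending reminder. Messages from unknown
#' senders are logged and dropped with a warning.
#'
#' @param state a `t4s_engine`.
#' @param participant_id sender.
#' @param received_at timestamp.
#' @param text raw message text.
#' @return the updated state.
#' @export
handle_inbound <- function(state, participant_id, received_at, text) {
  received_at <- parse_ts(received_at)
  p <- state$participants[[participant_id]]
  if (is.null(p)) {
    state <- append_log(state, received_at, "in", participant_id,
                        "unknown_sender", body = text)
    warning("inbound message from unknown participant: ", participant_id)
    return(state)
  }
  parsed <- parse_inbound(text, onboarding = p$status == "onboarding")
  state <- append_log(state, received_at, "in", participant_id,
                      parsed$kind, body = text)
  inbound_seq <- state$seq

  if (p$status == "unsubscribed") return(state)

  if (parsed$kind == "stop") {
    state$schedule <- cancel_future(state$schedule, participant_id,
                                    received_at)
    p$status <- "unsubscribed"
    state$participants[[participant_id]] <- p
    return(append_log(state, received_at, "out", participant_id,
                      "stop_ack", body = .stop_ack_body,
                      in_reply_to = inbound_seq))
  }

  if (parsed$kind == "onboarding_answer" && p$status == "onboarding") {
    idx <- p$onboarding_idx + 1L
    p$onboarding_answers[idx] <- parsed$time
    if (idx < 3L) {
      p$onboarding_idx <- idx
      state$participants[[participant_id]] <- p
      return(send_template(state, p, "onboarding_question", received_at,
                           rank = idx, in_reply_to = inbound_seq))
    }
    meals <- p$onboarding_answers
    if (!(meals[1] < meals[2] && meals[2] < meals[3])) {
      # unordered mealtimes: restart the three questions
      p$onboarding_idx <- 0L
      p$onboarding_answers <- rep(NA_integer_, 3)
      state$participants[[participant_id]] <- p
      return(send_template(state, p, "onboarding_question", received_at,
                           rank = 0L, in_reply_to = inbound_seq))
    }
    return(activate_participant(state, participant_id, meals))
  }

  if (parsed$kind == "glucose_value" && p$status == "active") {
    link <- link_context(state, participant_id, received_at)
    cls <- classify_glucose(parsed$value, link$context, state$thresholds)
    sel <- next_feedback(state$catalog, participant_id, cls$tier,
                         p$language)
    state$catalog <- sel$catalog
    slot <- NA_character_
    if (!is.na(link$reminder_seq)) {
      hit <- state$pending$seq == link$reminder_seq
      state$pending$answered[hit] <- TRUE
      slot <- state$pending$slot[hit]
    }
    return(append_log(state, received_at, "out", participant_id,
                      tier_to_category(cls$tier), slot = slot,
                      body = sel$template$body, in_reply_to = inbound_seq,
                      answers = link$reminder_seq))
  }

  # unrecognized (or a stray number during onboarding): at most one
  # clarification prompt per pending reminder
  win <- state$link_window_hours * 3600
  pend <- state$pending
  cand <- which(pend$participant_id == participant_id & !pend$answered &
                  !pend$clarified & pend$fire_at <= received_at &
                  as.numeric(received_at) - as.numeric(pend$fire_at) <= win)
  if (length(cand) > 0) {
    i <- cand[which.max(as.numeric(pend$fire_at[cand]))]
    state$pending$clarified[i] <- TRUE
    state <- append_log(state, received_at, "out", participant_id,
                        "clarification", slot = pend$slot[i],
                        body = .clarification_body,
                        in_reply_to = inbound_seq)
  }
  state
}

#' Advance the engine clock and dispatch due events
#'
#' Every scheduled event with `fire_at <= now` that has not yet been
#' dispatched is rendered from the catalog in the participant's language
#' and appended to the log exactly once; reminders additionally register
#' as pending (awaiting a glucose reply). Events belonging to
#' non-active participants are discarded. Idempotent: ticking twice at the
#' same time sends nothing new.
#'
#' @param state a `t4s_engine`.
#' @param now current time.
#' @return the updated state.
#' @export
tick <- function(state, now) {
  now <- parse_ts(now)
  due <- which(!state$schedule$dispatched & state$schedule$fire_at <= now)
  if (length(due) == 0) return(state)
  due <- due[order(state$schedule$fire_at[due])]
  slot_rank <- c(fasting = 0L, post_breakfast = 1L, post_lunch = 2L,
                 post_dinner = 3L)
  for (i in due) {
    ev <- state$schedule[i, ]
    state$schedule$dispatched[i] <- TRUE
    p <- state$participants[[ev$participant_id]]
    if (is.null(p) || p$status != "active") next
    if (ev$category == "reminder") {
      state <- send_template(state, p, "reminder", ev$fire_at,
                             slot = ev$slot, rank = slot_rank[[ev$slot]])
      state$pending <- rbind(state$pending, data.frame(
        participant_id = ev$participant_id, slot = ev$slot,
        seq = state$seq, fire_at = ev$fire_at, answered = FALSE,
        clarified = FALSE, stringsAsFactors = FALSE))
    } else {
      state <- send_template(state, p, ev$category, ev$fire_at,
                             slot = NA_character_)
    }
  }
  state
}

#' Fraction of reply-requesting messages that received a reply
#'
#' A message counts as answered when a later feedback message claims it
#' via the reminder linkage (the `answers` column of the log). Reported as
#' a percent rounded to one decimal, matching how response rates are
#' conventionally quoted.
#'
#' @param log message log data frame (see [message_log()]).
#' @param categories outbound categories that request a reply (default:
#'   glucose reminders).
#' @return percent in `[0, 100]`, one decimal.
#' @export
response_rate <- function(log, categories = "reminder") {
  sent <- log[log$direction == "out" & log$category %in% categories, ]
  if (nrow(sent) == 0) {
    stop("no reply-requesting messages in the log; response rate undefined")
  }
  answered <- sum(sent$seq %in% log$answers[!is.na(log$answers)])
  round(100 * answered / nrow(sent), 1)
}

#' Run a full program: enroll a roster and replay an inbound stream
#'
#' Merges enrollment events and inbound messages into one time-ordered
#' event queue, ticking the scheduler up to each event before applying
#' it, then ticks past the last scheduled event so every due message is
#' dispatched. With a fixed roster and inbound stream the resulting log is
#' byte-identical across runs.
#'
#' @param roster list of [participant()] objects.
#' @param inbound data frame with columns `participant_id`, `received_at`,
#'   `text`.
#' @param catalog,thresholds,link_window_hours see [engine_init()].
#' @return the final `t4s_engine` state; retrieve the log with
#'   [message_log()].
#' @export
run_program <- function(roster, inbound = NULL,
                        catalog = default_catalog(),
                        thresholds = glucose_thresholds(),
                        link_window_hours = 3) {
  state <- engine_init(catalog, thresholds, link_window_hours)
  enrolls <- data.frame(
    at = as_utc(as.POSIXct(vapply(roster, function(p)
      as.numeric(p$enrolled_at), 0), origin = "1970-01-01", tz = "UTC")),
    pid = vapply(roster, `[[`, "", "participant_id"),
    kind = "enroll", idx = seq_along(roster), stringsAsFactors = FALSE)
  events <- enrolls
  if (!is.null(inbound) && nrow(inbound) > 0) {
    inb <- data.frame(at = parse_ts(inbound$received_at),
                      pid = inbound$participant_id, kind = "inbound",
                      idx = seq_len(nrow(inbound)),
                      stringsAsFactors = FALSE)
    events <- rbind(events, inb)
  }
  # enrollments sort before inbound messages at the same instant
  events <- events[order(events$at, events$kind != "enroll", events$idx), ]
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    state <- tick(state, ev$at)
    if (ev$kind == "enroll") {
      state <- enroll(state, roster[[ev$idx]], now = ev$at)
    } else {
      state <- handle_inbound(state, ev$pid, ev$at,
                              inbound$text[ev$idx])
    }
  }
  if (nrow(state$schedule) > 0) {
    state <- tick(state, max(state$schedule$fire_at))
  }
  # participants still active at the end have completed the program
  for (pid in names(state$participants)) {
    if (state$participants[[pid]]$status == "active") {
      state$participants[[pid]]$status <- "completed"
    }
  }
  state
}

#' @export
print.t4s_engine <- function(x, ...) {
  log <- message_log(x)
  cat(sprintf(
    "<t4s_engine> %d participants, %d scheduled events (%d dispatched), %d log messages\n",
    length(x$participants), nrow(x$schedule), sum(x$schedule$dispatched),
    nrow(log)))
  invisible(x)
}

#' Write a message log as JSON-lines
#'
#' One JSON object per line with keys `seq`, `timestamp` (ISO-8601),
#' `direction`, `participant_id`, `category`, `slot`, `body`,
#' `in_reply_to`, `answers`; absent optional fields are omitted.
#'
#' @param log message log data frame.
#' @param path output file.
#' @export
write_message_log <- function(log, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    rec <- list(seq = log$seq[i], timestamp = fmt_ts(log$timestamp[i]),
                direction = log$direction[i],
                participant_id = log$participant_id[i],
                category = log$category[i], slot = log$slot[i],
                body = log$body[i])
    if (!is.na(log$in_reply_to[i])) rec$in_reply_to <- log$in_reply_to[i]
    if (!is.na(log$answers[i])) rec$answers <- log$answers[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a JSON-lines message log
#'
#' @param path file written by [write_message_log()].
#' @return message log data frame.
#' @export
read_message_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    data.frame(seq = as.integer(rec$seq),
               timestamp = parse_ts(rec$timestamp),
               direction = rec$direction,
               participant_id = rec$participant_id,
               category = rec$category, slot = rec$slot, body = rec$body,
               in_reply_to = as.integer(rec$in_reply_to %||% NA_integer_),
               answers = as.integer(rec$answers %||% NA_integer_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
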