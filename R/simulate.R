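# Synthetic cohort generator. Emulates the study conditions: a cohort of
# 10 women monitored for 14 program days (plus a 7-day pre-enrollment
# baseline), 4 recommended checks per day, per-slot Bernoulli check
# behavior around a 93% adherence level, and a conditional probability of
# texting back a performed value calibrated to the observed 67.9% reply
# rate. Glucose values come from context-dependent distributions with
# small critical-low/high tail mixtures.

#' Simulation configuration
#'
#' @param n_participants cohort size (default 10).
#' @param program_days active program length in days (default 14).
#' @param pre_days baseline days before enrollment (default 7).
#' @param check_prob per-slot probability of performing a check during the
#'   program (default 0.93).
#' @param pre_check_prob per-slot check probability in the baseline week
#'   (default: same as `check_prob`).
#' @param reply_prob probability of texting a performed value back
#'   (conditional on the check having happened; default 0.679).
#' @param fasting_mean,fasting_sd fasting glucose distribution, mg/dL.
#' @param postprandial_mean,postprandial_sd postprandial distribution.
#' @param p_critical_low,p_critical_high tail mixture weights for
#'   critically low / high values.
#' @param jitter_sd_min SD (minutes) of the check-time jitter after the
#'   reminder slot.
#' @param enrolled_at shared enrollment instant; the default midnight
#'   start puts the 24-h program start before the day's first reminder
#'   slot, so every participant accrues complete reminder-days.
#' @param seed integer seed; per-participant substreams are derived from
#'   it so growing the cohort never reshuffles existing participants.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_participants = 10, program_days = 14,
                       pre_days = 7, check_prob = 0.93,
                       pre_check_prob = check_prob, reply_prob = 0.679,
                       fasting_mean = 85, fasting_sd = 8,
                       postprandial_mean = 115, postprandial_sd = 18,
                       p_critical_low = 0.01, p_critical_high = 0.02,
                       jitter_sd_min = 10,
                       enrolled_at = "2023-03-06 00:00:00",
                       seed = 1) {
  cfg <- list(n_participants = as.integer(n_participants),
              program_days = as.integer(program_days),
              pre_days = as.integer(pre_days), check_prob = check_prob,
              pre_check_prob = pre_check_prob, reply_prob = reply_prob,
              fasting_mean = fasting_mean, fasting_sd = fasting_sd,
              postprandial_mean = postprandial_mean,
              postprandial_sd = postprandial_sd,
              p_critical_low = p_critical_low,
              p_critical_high = p_critical_high,
              jitter_sd_min = jitter_sd_min,
              enrolled_at = parse_ts(enrolled_at),
              seed = as.integer(seed))
  probs <- c(check_prob = cfg$check_prob,
             pre_check_prob = cfg$pre_check_prob,
             reply_prob = cfg$reply_prob,
             p_critical_low = cfg$p_critical_low,
             p_critical_high = cfg$p_critical_high)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "))
  }
  if (cfg$p_critical_low + cfg$p_critical_high >= 1) {
    stop("critical tail probabilities must sum to < 1")
  }
  if (cfg$fasting_sd <= 0 || cfg$postprandial_sd <= 0 ||
      cfg$jitter_sd_min <= 0) {
    stop("standard deviations must be > 0")
  }
  if (cfg$n_participants < 1) stop("n_participants must be >= 1")
  if (cfg$program_days < 1 || cfg$pre_days < 0) {
    stop("program_days must be >= 1 and pre_days >= 0")
  }
  structure(cfg, class = "sim_config")
}

# substream seed for participant i; kept well below 2^31
.participant_seed <- function(seed, i) {
  (abs(seed) %% 1000000L) * 1009L + i
}

# context-dependent glucose values with critical tail mixture, vectorized
.draw_values <- function(cfg, context) {
  n <- length(context)
  u <- stats::runif(n)
  mu <- ifelse(context == "fasting", cfg$fasting_mean,
               cfg$postprandial_mean)
  sd <- ifelse(context == "fasting", cfg$fasting_sd, cfg$postprandial_sd)
  v <- stats::rnorm(n, mu, sd)
  low <- u < cfg$p_critical_low
  high <- !low & u < cfg$p_critical_low + cfg$p_critical_high
  v[low] <- stats::runif(sum(low), 30, 59)
  v[high] <- stats::runif(sum(high), 200, 280)
  as.integer(pmax(20, pmin(600, round_half_up(v))))
}

#' Simulate a synthetic cohort
#'
#' Draws, per participant, mealtimes on a 15-minute grid (breakfast
#' 06:30-09:00, lunch 12:00-13:30, dinner 18:00-20:00) and a weekly
#' message preference; then realizes, for every program day and reminder
#' slot, a Bernoulli check, a context-dependent glucose value, a jittered
#' check time shortly after the reminder, and - conditionally on the
#' check - a Bernoulli texted reply. Baseline (pre-enrollment) days
#' produce device records only, since the program is not yet messaging.
#' The inbound stream also carries the three onboarding mealtime answers
#' so a replay exercises the whole conversation. Fully reproducible from
#' the seed; each participant has an independent derived substream.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_cohort` list: `roster` (list of [participant()]),
#'   `inbound` (data frame `participant_id`, `received_at`, `text`),
#'   `device` (data frame `participant_id`, `measured_at`, `value`,
#'   `period`), `truth` (per-slot realization table plus the generating
#'   config), and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  roster <- list()
  inbound <- list()
  device <- list()
  truth <- list()
  for (i in seq_len(cfg$n_participants)) {
    set.seed(.participant_seed(cfg$seed, i))
    pid <- sprintf("P%02d", i)
    b <- sample(seq(390L, 540L, by = 15L), 1)
    l <- sample(seq(720L, 810L, by = 15L), 1)
    d <- sample(seq(1080L, 1200L, by = 15L), 1)
    p <- participant(pid, fmt_hhmm(b), fmt_hhmm(l), fmt_hhmm(d),
                     enrolled_at = cfg$enrolled_at,
                     weekly_message_day = sample(1:7, 1),
                     weekly_message_time = fmt_hhmm(
                       sample(seq(540L, 1260L, by = 30L), 1)),
                     program_days = cfg$program_days,
                     recommended_checks_per_day = 4L)
    roster[[pid]] <- p

    # onboarding answers a few minutes after enrollment
    inbound[[length(inbound) + 1]] <- data.frame(
      participant_id = pid,
      received_at = cfg$enrolled_at + c(2, 4, 6) * 60,
      text = fmt_hhmm(c(b, l, d)), stringsAsFactors = FALSE)

    slot_min <- c(fasting = b - 30L, post_breakfast = b + 60L,
                  post_lunch = l + 60L, post_dinner = d + 60L)
    slot_ctx <- c(fasting = "fasting", post_breakfast = "postprandial",
                  post_lunch = "postprandial", post_dinner = "postprandial")

    sim_days <- function(days, check_prob, in_program) {
      n_days <- length(days)
      day <- rep(days, each = 4)
      slot <- rep(names(slot_min), times = n_days)
      reminder_at <- at_clock(day, slot_min[slot])
      n <- 4L * n_days
      check <- stats::runif(n) < check_prob
      check_at <- reminder_at +
        (10 + abs(stats::rnorm(n, 0, cfg$jitter_sd_min))) * 60
      value <- .draw_values(cfg, slot_ctx[slot])
      replied <- rep(FALSE, n)
      reply_at <- reminder_at + NA
      text <- rep(NA_character_, n)
      if (in_program) {
        replied <- check & stats::runif(n) < cfg$reply_prob
        reply_at[replied] <- check_at[replied] +
          stats::runif(sum(replied), 0.5, 3) * 60
        text <- ifelse(stats::runif(n) < 0.1,
                       paste0(value, " mg/dl"), as.character(value))
      }
      check_at[!check] <- NA
      value[!check] <- NA_integer_
      data.frame(participant_id = pid, day = day, slot = slot,
                 context = unname(slot_ctx[slot]),
                 period = if (in_program) "during" else "pre",
                 reminder_at = reminder_at, check = check,
                 check_at = check_at, value = value, replied = replied,
                 reply_at = reply_at, text = text, stringsAsFactors = FALSE)
    }

    e_day <- local_day(cfg$enrolled_at)
    slots <- list()
    if (cfg$pre_days > 0) {
      slots$pre <- sim_days(seq(e_day - cfg$pre_days, e_day - 1,
                                by = "day"),
                            cfg$pre_check_prob, in_program = FALSE)
    }
    start_day <- local_day(cfg$enrolled_at + 24 * 3600)
    slots$during <- sim_days(
      seq(start_day, start_day + cfg$program_days - 1, by = "day"),
      cfg$check_prob, in_program = TRUE)
    slots <- do.call(rbind, slots)

    done <- slots[slots$check, , drop = FALSE]
    device[[i]] <- data.frame(
      participant_id = done$participant_id, measured_at = done$check_at,
      value = done$value, period = done$period, stringsAsFactors = FALSE)
    rep_rows <- slots[slots$replied, , drop = FALSE]
    inbound[[length(inbound) + 1]] <- data.frame(
      participant_id = rep_rows$participant_id,
      received_at = rep_rows$reply_at,
      text = rep_rows$text, stringsAsFactors = FALSE)
    truth[[i]] <- slots[setdiff(names(slots), "text")]
  }
  inbound <- do.call(rbind, inbound)
  inbound <- inbound[order(inbound$received_at, inbound$participant_id), ,
                     drop = FALSE]
  rownames(inbound) <- NULL
  device <- if (length(device) > 0) do.call(rbind, device) else
    data.frame(participant_id = character(0),
               measured_at = as.POSIXct(character(0), tz = "UTC"),
               value = integer(0), period = character(0))
  device <- device[order(device$participant_id, device$measured_at), ,
                   drop = FALSE]
  rownames(device) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(roster = roster, inbound = inbound, device = device,
                 truth = truth, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d participants, %d device records, %d inbound texts (seed %d)\n",
    length(x$roster), nrow(x$device), nrow(x$inbound), x$config$seed))
  invisible(x)
}

#' Recover the planted behavioral parameters from simulator output
#'
#' Empirical fractions over the realized program slots: the check
#' probability is checks performed / reminder slots, and the reply
#' probability is texted values / checks performed (it is conditional on
#' the check, because a value can only be texted once it exists). Used to
#' confirm that the engine and analytics measure what the generator
#' planted.
#'
#' @param sim a `sim_cohort`.
#' @return list with `check_prob_hat`, `reply_prob_hat`, and the
#'   denominators `n_slots`, `n_checks`.
#' @export
recover_parameters <- function(sim) {
  stopifnot(inherits(sim, "sim_cohort"))
  t <- sim$truth[sim$truth$period == "during", ]
  list(check_prob_hat = mean(t$check),
       reply_prob_hat = sum(t$replied) / sum(t$check),
       n_slots = nrow(t), n_checks = sum(t$check))
}

#' Write simulator artifacts to disk
#'
#' Emits the same formats the engine and analytics consume: a roster CSV,
#' a JSON-lines inbound stream, a device-export CSV, and the slot-level
#' truth table as JSON.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return file paths, invisibly.
#' @export
write_sim_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roster_path <- file.path(dir, "roster.csv")
  write_roster(sim$roster, roster_path)
  inbound_path <- file.path(dir, "inbound.jsonl")
  write_inbound_stream(sim$inbound, inbound_path)
  device_path <- file.path(dir, "device_export.csv")
  write_device_export(sim$device, device_path)
  truth_path <- file.path(dir, "truth.json")
  tr <- sim$truth
  tr$reminder_at <- fmt_ts(tr$reminder_at)
  tr$check_at <- ifelse(is.na(tr$check_at), NA, fmt_ts(tr$check_at))
  tr$reply_at <- ifelse(is.na(tr$reply_at), NA, fmt_ts(tr$reply_at))
  tr$day <- as.character(tr$day)
  jsonlite::write_json(list(config = unclass(sim$config)[
    setdiff(names(sim$config), "enrolled_at")],
    enrolled_at = fmt_ts(sim$config$enrolled_at), slots = tr),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = FALSE, na = "null")
  invisible(c(roster = roster_path, inbound = inbound_path,
              device = device_path, truth = truth_path))
}

#' Write an inbound stream as JSON-lines
#'
#' Same record shape as the message log, with `direction = "in"`.
#'
#' @param inbound data frame with `participant_id`, `received_at`,
#'   `text`.
#' @param path output file.
#' @export
write_inbound_stream <- function(inbound, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(inbound))) {
    writeLines(jsonlite::toJSON(list(
      seq = i, timestamp = fmt_ts(inbound$received_at[i]),
      direction = "in", participant_id = inbound$participant_id[i],
      body = inbound$text[i]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a JSON-lines inbound stream
#'
#' @param path file written by [write_inbound_stream()].
#' @return data frame with `participant_id`, `received_at`, `text`.
#' @export
read_inbound_stream <- function(path) {
  rows <- lapply(readLines(path, encoding = "UTF-8"), function(l) {
    rec <- jsonlite::fromJSON(l)
    data.frame(participant_id = rec$participant_id,
               received_at = parse_ts(rec$timestamp),
               text = rec$body, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
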