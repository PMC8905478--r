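test_that("enrollment sends welcome with opt-out info, then the disclaimer", {
  st <- engine_init()
  p <- make_participant()
  st <- enroll(st, p)
  log <- message_log(st)
  expect_equal(log$category[1:2], c("welcome", "disclaimer"))
  expect_match(log$body[1], "STOP")
  expect_match(log$body[2], "not monitored")
  expect_equal(log$category[3], "onboarding_question")
  expect_error(enroll(st, p), "already enrolled")
})

test_that("no reminder fires before 24 hours after enrollment", {
  st <- activate_one()
  expect_true(all(st$schedule$fire_at >=
                    st$participants$P01$enrolled_at + 24 * 3600))
  st <- tick(st, st$participants$P01$enrolled_at + 23 * 3600)
  log <- message_log(st)
  expect_equal(sum(log$category == "reminder"), 0)
})

test_that("inbound parsing matches the token-extraction oracle on a reply corpus", {
  corpus <- c(
    "95", " 95 ", "95.", "142 mg/dl", "my number is 142 mg/dl",
    "142mg/dl", "142 MG/DL", "it was 108 this morning", "108!",
    "glucose 131", "131 after lunch", "sugar was 99 today", "85?",
    "reading: 77", "96.4", "95.5", "60", "200", "20", "600",
    "9", "19", "601", "700", "0", "hello??", "thanks", "ok", "", "   ",
    "no reading today", "forgot sorry", "will check later", "??",
    "one twenty", "about 150 then 95", "120 and 135", "fasting 88",
    "88 fasting", "yes", "done", "checked!", "low", "high",
    "my glucose was about 104.7", "було 105", "104 :)", "110mgdl",
    "<60", "over 200!")
  for (text in corpus) {
    parsed <- parse_inbound(text)
    expected <- oracle_first_glucose(text)
    if (toupper(trimws(text)) == "STOP") next
    if (is.na(expected)) {
      expect_equal(parsed$kind, "unrecognized", info = text)
    } else {
      expect_equal(parsed$kind, "glucose_value", info = text)
      expect_equal(parsed$value, expected, info = text)
    }
  }
  # STOP in any case or padding unsubscribes
  expect_equal(parse_inbound("stop")$kind, "stop")
  expect_equal(parse_inbound("STOP ")$kind, "stop")
  expect_equal(parse_inbound(" Stop")$kind, "stop")
  # mealtime answers are only recognized during onboarding
  expect_equal(parse_inbound("8:30", onboarding = TRUE)$kind,
               "onboarding_answer")
  expect_equal(parse_inbound("8:30", onboarding = TRUE)$time, 510)
  expect_equal(parse_inbound("around 18.15", onboarding = TRUE)$time, 1095)
})

test_that("onboarding answers set mealtimes and activate the schedule", {
  st <- engine_init()
  p <- make_participant()
  st <- enroll(st, p)
  t0 <- p$enrolled_at
  st <- handle_inbound(st, "P01", t0 + 60, "7:45")
  expect_equal(st$participants$P01$status, "onboarding")
  st <- handle_inbound(st, "P01", t0 + 120, "12:15")
  st <- handle_inbound(st, "P01", t0 + 180, "18:30")
  expect_equal(st$participants$P01$status, "active")
  expect_equal(st$participants$P01$breakfast, parse_hhmm("7:45"))
  expect_equal(nrow(st$schedule), 14 * 4 + 4)
  # three questions were asked in order
  log <- message_log(st)
  q <- log$body[log$category == "onboarding_question"]
  expect_length(q, 3)
  expect_match(q[1], "breakfast")
  expect_match(q[2], "lunch")
  expect_match(q[3], "dinner")
})

test_that("glucose replies link to their reminder and earn tiered feedback", {
  st <- activate_one()
  fasting_at <- st$schedule$fire_at[st$schedule$slot == "fasting"][1]
  st <- tick(st, fasting_at)
  log <- message_log(st)
  expect_equal(sum(log$category == "reminder"), 1)
  reminder_seq <- log$seq[log$category == "reminder"]

  # in-range value 40 minutes later -> rotating in-range feedback
  st1 <- handle_inbound(st, "P01", fasting_at + 40 * 60, "85")
  log1 <- message_log(st1)
  fb <- log1[nrow(log1), ]
  expect_equal(fb$category, "feedback_in_range")
  expect_equal(fb$in_reply_to, log1$seq[log1$category == "glucose_value"])
  expect_equal(fb$answers, reminder_seq)
  expect_equal(fb$slot, "fasting")

  # critically high value after a post-lunch reminder -> the single
  # critical reply directing the care team
  lunch_at <- st1$schedule$fire_at[st1$schedule$slot == "post_lunch"][1]
  st2 <- tick(st1, lunch_at)
  st2 <- handle_inbound(st2, "P01", lunch_at + 30 * 60, "210")
  log2 <- message_log(st2)
  fb2 <- log2[nrow(log2), ]
  expect_equal(fb2$category, "feedback_critical_high")
  expect_match(fb2$body, "care team")
})

test_that("context linkage: recent reminder wins, else time of day decides", {
  st <- activate_one()
  fasting_at <- st$schedule$fire_at[st$schedule$slot == "fasting"][1]
  st <- tick(st, fasting_at)
  link <- link_context(st, "P01", fasting_at + 40 * 60)
  expect_equal(link$context, "fasting")
  expect_false(is.na(link$reminder_seq))
  # beyond the 3-hour window the reminder no longer claims the value
  link_far <- link_context(st, "P01", fasting_at + 4 * 3600)
  expect_true(is.na(link_far$reminder_seq))
  # no pending reminder: before breakfast is fasting, afternoon is not
  st0 <- activate_one()
  day2 <- as.Date(st0$participants$P01$enrolled_at) + 2
  early <- as.POSIXct(paste(day2, "06:10:00"), tz = "UTC")
  late <- as.POSIXct(paste(day2, "15:00:00"), tz = "UTC")
  expect_equal(link_context(st0, "P01", early)$context, "fasting")
  expect_equal(link_context(st0, "P01", late)$context, "postprandial")
})

test_that("every glucose reply gets exactly one feedback message", {
  sim <- simulate_cohort(sim_config(n_participants = 3, program_days = 5,
                                    seed = 7))
  st <- run_program(sim$roster, sim$inbound)
  log <- message_log(st)
  glucose_in <- log$seq[log$direction == "in" &
                          log$category == "glucose_value"]
  feedback <- log[log$direction == "out" &
                    startsWith(log$category, "feedback_"), ]
  expect_equal(sort(feedback$in_reply_to), sort(glucose_in))
  expect_false(anyDuplicated(feedback$in_reply_to) > 0)
})

test_that("after STOP nothing but the acknowledgment is ever sent", {
  st <- activate_one()
  fasting_at <- st$schedule$fire_at[st$schedule$slot == "fasting"][1]
  st <- tick(st, fasting_at)
  st <- handle_inbound(st, "P01", fasting_at + 10 * 60, "STOP")
  log <- message_log(st)
  expect_equal(log$category[nrow(log)], "stop_ack")
  expect_equal(st$participants$P01$status, "unsubscribed")
  n_before <- nrow(log)
  # ticking through the rest of the program and texting again changes
  # nothing outbound
  st <- tick(st, fasting_at + 30 * 86400)
  st <- handle_inbound(st, "P01", fasting_at + 2 * 86400, "95")
  log2 <- message_log(st)
  expect_equal(sum(log2$direction == "out"), sum(log$direction == "out"))
  expect_true(nrow(log2) == n_before + 1)  # the inbound is still logged
})

test_that("unrecognized texts earn at most one clarification per reminder", {
  st <- activate_one()
  fasting_at <- st$schedule$fire_at[st$schedule$slot == "fasting"][1]
  st <- tick(st, fasting_at)
  st <- handle_inbound(st, "P01", fasting_at + 5 * 60, "hello??")
  log <- message_log(st)
  expect_equal(sum(log$category == "clarification"), 1)
  expect_match(log$body[log$category == "clarification"], "number only")
  st <- handle_inbound(st, "P01", fasting_at + 10 * 60, "still confused")
  expect_equal(sum(message_log(st)$category == "clarification"), 1)
  # with no pending reminder there is nothing to clarify
  st2 <- activate_one()
  st2 <- handle_inbound(st2, "P01",
                        st2$participants$P01$enrolled_at + 30 * 3600,
                        "hello??")
  expect_equal(sum(message_log(st2)$category == "clarification"), 0)
})

test_that("messages from unknown senders are logged and dropped with a warning", {
  st <- engine_init()
  expect_warning(st <- handle_inbound(st, "ghost", "2023-03-07 10:00:00",
                                      "95"),
                 "unknown participant")
  log <- message_log(st)
  expect_equal(nrow(log), 1)
  expect_equal(sum(log$direction == "out"), 0)
})

test_that("tick is idempotent and skips non-active participants", {
  st <- activate_one()
  t1 <- st$schedule$fire_at[5]
  st <- tick(st, t1)
  n <- nrow(message_log(st))
  st <- tick(st, t1)
  expect_equal(nrow(message_log(st)), n)
})

test_that("response rate is answered reminders over sent reminders", {
  # constructed log: 5 reminders, 3 answered through the linkage chain
  log <- data.frame(
    seq = 1:13,
    timestamp = as.POSIXct("2023-03-07", tz = "UTC") + (1:13) * 60,
    direction = c(rep("out", 5), rep(c("in", "out"), 3), "in", "in"),
    participant_id = "P01",
    category = c(rep("reminder", 5),
                 rep(c("glucose_value", "feedback_in_range"), 3),
                 "unrecognized", "unrecognized"),
    slot = "none", body = "x",
    in_reply_to = c(rep(NA, 5), NA, 6, NA, 8, NA, 10, NA, NA),
    answers = c(rep(NA, 5), NA, 1, NA, 2, NA, 3, NA, NA),
    stringsAsFactors = FALSE)
  expect_equal(response_rate(log), 60.0)
  expect_error(response_rate(log[log$category != "reminder", ]),
               "undefined")
})

test_that("replaying the same roster and stream gives a byte-identical log", {
  cfg <- sim_config(n_participants = 3, program_days = 4, seed = 11)
  sim <- simulate_cohort(cfg)
  st1 <- run_program(sim$roster, sim$inbound)
  st2 <- run_program(sim$roster, sim$inbound)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_message_log(message_log(st1), f1)
  write_message_log(message_log(st2), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the log round-trips through the JSON-lines format
  back <- read_message_log(f1)
  expect_equal(back, message_log(st1))
})
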