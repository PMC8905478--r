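make_records <- function(pid, times) {
  data.frame(participant_id = pid,
             measured_at = as.POSIXct(times, tz = "UTC"),
             value = 100L, stringsAsFactors = FALSE)
}

test_that("distinct checks count once; 5-minute retests collapse", {
  day <- "2023-03-07"
  rec <- make_records("P01", paste(day, c("07:30:00", "09:05:00",
                                          "13:35:00", "20:10:00")))
  expect_equal(count_checks(rec, "P01", day), 4L)
  retest <- make_records("P01", paste(day, c("07:30:00", "07:32:00")))
  expect_equal(count_checks(retest, "P01", day), 1L)
  expect_equal(count_checks(rec, "P01", "2023-03-08"), 0L)
  expect_equal(count_checks(rec, "P02", day), 0L)
})

test_that("check clustering agrees with the brute-force gap oracle", {
  set.seed(42)
  base <- as.numeric(as.POSIXct("2023-03-07 06:00:00", tz = "UTC"))
  for (i in 1:25) {
    n <- sample(1:12, 1)
    # clustered times: a few anchors with retests sprinkled nearby
    anchors <- sort(runif(sample(1:5, 1), 0, 16 * 3600))
    times <- base + sample(c(anchors,
                             anchors[1] + cumsum(runif(n, 0, 600))))
    rec <- make_records("P01", as.POSIXct(times, origin = "1970-01-01",
                                          tz = "UTC"))
    expect_equal(count_checks(rec, "P01", "2023-03-07"),
                 oracle_dedup_count(times))
  }
})

test_that("adherence is capped: over-checking still counts as 100%", {
  # a 6-check day on a 4-recommended schedule contributes 4, not 6
  counts <- c(6, 4, 4, 4, 4, 4, 4)
  s <- adherence_pct(counts, 4, "pre")
  expect_equal(s$performed, 28L)
  expect_equal(s$pct, 100L)
  # aggregate-level cap instead lets the binge day mask a miss
  counts2 <- c(6, 4, 4, 4, 4, 4, 2)
  expect_equal(adherence_pct(counts2, 4, "pre")$performed, 26L)
  expect_equal(adherence_pct(counts2, 4, "pre", cap = "period")$performed,
               28L)
  expect_equal(adherence_pct(rep(0, 7), 4, "pre")$pct, 0L)
  expect_error(adherence_pct(counts, 0, "pre"), "undefined")
  expect_error(adherence_pct(integer(0), 4, "pre"), "no days")
})

test_that("adherence never exceeds 100% and is monotone in performed checks", {
  set.seed(42)
  for (i in 1:20) {
    counts <- sample(0:8, 14, replace = TRUE)
    s <- adherence_pct(counts, 4, "during")
    expect_lte(s$pct, 100)
    expect_gte(s$pct, 0)
    more <- counts + sample(0:2, 14, replace = TRUE)
    expect_gte(adherence_pct(more, 4, "during")$fraction, s$fraction)
  }
})

test_that("the printed baseline arithmetic holds: 222 of 238 is 93%", {
  # 9 participants with baseline data over 7 days: eight recommended 4
  # checks/day (each missing 2 checks), one recommended 2 checks/day with
  # none missed -> 238 recommended, 222 performed
  summaries <- c(
    lapply(1:8, function(i)
      adherence_pct(c(2, 4, 4, 4, 4, 4, 4), 4, "pre",
                    participant_id = sprintf("P%02d", i))),
    list(adherence_pct(rep(2, 7), 2, "pre", participant_id = "P09")))
  performed <- sum(vapply(summaries, `[[`, 0L, "performed"))
  recommended <- sum(vapply(summaries, `[[`, 0L, "recommended"))
  expect_equal(recommended, 238)
  expect_equal(performed, 222)
  expect_equal(round(100 * performed / recommended), 93)
})

test_that("rank-sum comparison matches the permutation oracle exactly", {
  r <- compare_periods(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p_value, oracle_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(seq_len(50), n1); y <- sample(setdiff(seq_len(50), x), n2)
    r <- compare_periods(x, y)
    expect_true(r$exact)
    expect_equal(r$p_value, oracle_ranksum_p(x, y), tolerance = 1e-12,
                 info = paste(c(x, "|", y), collapse = " "))
  }
})

test_that("identical groups give p = 1 and sensible summaries", {
  r <- compare_periods(c(0.9, 0.93, 0.97, 1), c(0.9, 0.93, 0.97, 1))
  expect_equal(r$p_value, 1.0)
  expect_equal(r$pre$median, r$during$median)
  expect_equal(r$pre$iqr, r$during$iqr)
  expect_false(r$significant)
  expect_error(compare_periods(1, c(1, 2)), "at least 2")
})

test_that("normal approximation stays within 0.05 of the exact p for small n", {
  set.seed(42)
  for (i in 1:20) {
    n1 <- sample(4:10, 1); n2 <- sample(4:10, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    p_exact <- compare_periods(x, y)$p_value
    p_norm <- compare_periods(x, y, exact_max_n = 0)$p_value
    expect_lt(abs(p_exact - p_norm), 0.05)
  }
})

test_that("tied data fall back to the corrected normal approximation", {
  x <- c(0.9, 0.93, 0.93, 1)
  y <- c(0.93, 0.97, 1, 1)
  r <- compare_periods(x, y)
  expect_false(r$exact)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  # paired variant runs and respects pairing
  rp <- compare_periods(c(0.1, 0.2, 0.3, 0.4), c(0.2, 0.3, 0.4, 0.5),
                        paired = TRUE)
  expect_match(rp$method, "signed rank")
})

test_that("cohort adherence uses the right periods and flags missing baselines", {
  p <- make_participant()
  # checks only on the first two program days
  start <- as.Date(p$enrolled_at) + 1
  rec <- make_records("P01", paste(rep(c(start, start + 1), each = 4),
                                   c("07:35:00", "09:10:00", "13:40:00",
                                     "20:05:00")))
  during <- cohort_adherence(rec, list(P01 = p), "during")
  expect_equal(during$performed, 8L)
  expect_equal(during$recommended, 56L)
  pre <- cohort_adherence(rec, list(P01 = p), "pre")
  expect_equal(pre$performed, 0L)
  expect_false(pre$has_records)
})

test_that("device exports round-trip and deduplicate", {
  rec <- make_records("P01", paste("2023-03-07",
                                   c("07:30:00", "07:30:00", "09:05:00")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_device_export(rec, path)
  back <- read_device_export(path)
  expect_equal(nrow(back), 2)  # exact duplicate dropped
  expect_error(read_device_export(withr::local_tempfile(
    lines = "a,b\n1,2", fileext = ".csv")), "missing column")
})
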