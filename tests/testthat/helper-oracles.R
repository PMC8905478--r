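# Independent oracles used by the tests. These deliberately take a
# different route than the implementation: lookup tables built segment by
# segment, brute-force enumeration, and explicit loops.

# table-driven glucose tier oracle built directly from the four printed
# bounds: desired fasting 61-94, desired postprandial 61-139, critical
# at <=60 and >=200
oracle_tier_table <- function(context) {
  hi <- if (context == "fasting") 94 else 139
  tiers <- c(rep("critical_low", length(20:60)),
             rep("in_range", length(61:hi)),
             rep("out_of_range", length((hi + 1):199)),
             rep("critical_high", length(200:600)))
  names(tiers) <- as.character(20:600)
  tiers
}

oracle_classify <- function(value, context) {
  unname(oracle_tier_table(context)[as.character(value)])
}

# exact two-sided rank-sum p-value by brute-force enumeration of all
# C(n1+n2, n1) group assignments of the pooled ranks
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  w_all <- apply(sets, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  p <- if (w_obs > mu) {
    2 * mean(w_all >= w_obs)
  } else if (w_obs < mu) {
    2 * mean(w_all <= w_obs)
  } else {
    1
  }
  min(1, p)
}

# explicit-loop 5-minute gap clustering of reading times (seconds)
oracle_dedup_count <- function(times, gap_sec = 300) {
  times <- sort(times)
  if (length(times) == 0) return(0L)
  n <- 1L
  for (i in seq_along(times)[-1]) {
    if (times[i] - times[i - 1] > gap_sec) n <- n + 1L
  }
  n
}

# independent token extractor: split on everything non-numeric, take the
# first token in [20, 600]
oracle_first_glucose <- function(text) {
  text <- gsub("mg/?dl", " ", tolower(text))
  toks <- strsplit(text, "[^0-9.]+")[[1]]
  toks <- toks[nzchar(toks)]
  for (t in toks) {
    v <- suppressWarnings(floor(as.numeric(t) + 0.5))
    if (!is.na(v) && v >= 20 && v <= 600) return(as.integer(v))
  }
  NA_integer_
}

# a standard participant used across tests
make_participant <- function(id = "P01", enrolled = "2023-03-06 00:00:00",
                             breakfast = "08:00", lunch = "12:30",
                             dinner = "19:00", ...) {
  participant(id, breakfast, lunch, dinner, enrolled_at = enrolled, ...)
}

# shorthand: enroll one participant and answer the onboarding questions so
# the engine reaches active status
activate_one <- function(p = make_participant()) {
  st <- engine_init()
  st <- enroll(st, p)
  t0 <- p$enrolled_at
  meals <- fmt_hhmm(c(p$breakfast, p$lunch, p$dinner))
  for (k in 1:3) {
    st <- handle_inbound(st, p$participant_id, t0 + k * 60, meals[k])
  }
  st
}

# binomial 95% CI half-width around a planted probability
binom_halfwidth <- function(p, n) 1.96 * sqrt(p * (1 - p) / n)
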