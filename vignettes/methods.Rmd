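---
title: "Design and methods of the SMBG texting engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and methods of the SMBG texting engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucotext)
```

## The intervention model

Gestational diabetes management asks for four daily fingerstick glucose
checks: fasting (before the first meal) and one hour after each main
meal. This package implements a two-way SMS program that supports that
routine with three message streams:

1. **Reminders** — the cue to action. Four per day, anchored to each
   participant's reported mealtimes: 30 minutes *before* breakfast for
   the fasting check, and 60 minutes *after* breakfast, lunch, and
   dinner for the postprandial checks. Messaging begins 24 hours after
   enrollment and runs for 14 days by default.
2. **Feedback** — the self-efficacy component. Participants text their
   value back; the engine classifies it and replies immediately (see
   the tier model below).
3. **Weekly messages** — one educational and one motivational text per
   7-day window, at the participant's chosen day and time.

The engine is deliberately a *pure state machine*: time enters only
through `tick()`, parsing and classification are deterministic, and all
randomness lives in the simulator. Replaying the same roster and inbound
stream therefore yields a byte-identical message log, which is what makes
the end-to-end properties testable at all.

## Glucose tier model

The desired ranges are fasting 61–94 mg/dL and postprandial 61–139
mg/dL, inclusive. Critical tiers override context: ≤ 60 mg/dL is
critically low and ≥ 200 mg/dL critically high, each answered by a
single fixed reply telling the participant to contact the care team.
Between the desired range and the critical bounds (95–199 fasting,
140–199 postprandial) lies the non-critical out-of-range tier, whose
reply also advises care-team contact but without the urgency wording.

Three boundary decisions were genuinely open and are resolved here:

* **Exactly 60 mg/dL.** The low cut is quoted as "< 60" while the
  desired ranges start at 61, leaving 60 unassigned; we assign it to
  `critical_low`, the conservative choice for patient safety.
* **Mildly low values (20–60).** No separate "mildly low" tier exists;
  everything at or below 60 is treated uniformly as critical.
* **Plausibility.** Integers outside 20–600 mg/dL are almost certainly
  typos; they raise an `glucotext_implausible_value` condition and the
  conversation layer sends a clarification rather than feedback.

Decimal replies are rounded half-up before classification, since meters
and SMS replies are integer-valued. All bounds are overridable through
`glucose_thresholds()` or a YAML file; the defaults are the program's.

## Conversation rules

* **Onboarding** asks the three mealtime questions in sequence; the
  participant activates (and the schedule is built) once all three
  answers arrive in a valid order.
* **Reply linkage.** An inbound value is attributed to the most recent
  unanswered reminder fired within the past 3 hours; its slot fixes the
  context. Unsolicited values fall back to time of day: before the
  reported breakfast time counts as fasting, later as postprandial. The
  3-hour window is a design choice (configurable via
  `link_window_hours`) that makes classification total without claiming
  stale reminders.
* **In-range rotation** is deterministic round-robin per participant
  over the four encouragement templates, via a persisted cursor. "Varied
  feedback" could also be random; round-robin gives the same variety
  with reproducibility, and guarantees exact fairness (each template
  used k times in any 4k consecutive selections).
* **Unrecognized texts** get at most one clarification prompt per
  pending reminder, preventing clarification loops.
* **STOP** (case-insensitive, trimmed) cancels all future events,
  sends one acknowledgment, and silences the participant's outbound
  stream permanently.
* Whether educational and motivational messages share one weekly time
  preference was unspecified; they share one here for simplicity.

## Adherence analytics

Daily check counts come from glucometer export timestamps, with readings
within 5 minutes collapsed into one event so an immediate retest after a
suspect reading is not double-counted (the window is a parameter of
`count_checks()`). Adherence is performed/recommended, capped at 100%.
The cap is applied **per day** by default: the period-level alternative
(`cap = "period"`) would let one over-checked day mask a missed day,
which misrepresents the behavior the metric is meant to track; both are
available because the aggregate reading of "over-checking still counts
as 100%" is also defensible.

The pre-enrollment week (7 days before the enrollment date) is compared
with the program period (14 days from the first active day) using the
Wilcoxon rank-sum test: exact enumeration when both groups have ≤ 10
values and no ties, otherwise the normal approximation with tie and
continuity correction (both routes delegate to `stats::wilcox.test`; the
test suite checks the exact route against a brute-force permutation
oracle). The rank-sum test treats the two periods as independent
samples even though they are paired by participant; it is the method
conventionally reported for this comparison in the usability literature,
and a paired signed-rank variant is available behind `paired = TRUE`. Participants with no baseline device data are
excluded from the comparison — they have nothing to compare.
Shapiro–Wilk normality probabilities, medians and 25th–75th percentiles
accompany the test; P < .05 is called significant.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the study conditions as defaults: 10
participants, 14 program days plus a 7-day baseline, 4 recommended
checks/day, a per-slot Bernoulli check probability of 0.93 (the observed
baseline adherence level), and a 0.679 probability of texting a
performed value (the observed reply rate). Mealtimes are drawn on a
15-minute grid (breakfast 06:30–09:00, lunch 12:00–13:30, dinner
18:00–20:00 — ranges we consider typical; the ordering invariant holds by
construction). Glucose values are drawn from context-dependent normals —
fasting N(85, 8), postprandial N(115, 18), truncated to 20–600 — with a
1% critically-low and 2% critically-high tail mixture; no empirical
glucose distributions were available for this population, so these are
invented but configurable defaults chosen to put most values in range. Check times jitter around
the reminder slot (10 min offset + half-normal with SD 10 min), keeping
them inside the linkage window.

Each participant draws from an independent substream derived from the
master seed, so enlarging the cohort never reshuffles existing
participants, and the same seed reproduces every artifact byte for byte.

Note one structural consequence: because a value can only be texted
after the check happens, the engine-measured response rate equals
`check_prob × reply_prob` (≈ 0.63 at the defaults), while
`recover_parameters()` estimates the conditional reply probability as
texts/checks. Under full check compliance the two coincide and the
response rate recovers 67.9% directly.

The simulator does **not** model: physiological glucose dynamics or any
effect of messaging on glucose values, weekday/weekend mealtime
variation, continuous glucose monitors (only discrete check events),
message delivery failure, or drop-out other than explicit STOP. Passing
tests therefore demonstrate that the engine and analytics measure what a
Bernoulli-behaving cohort plants — not that real participants behave
this way.

## Numerical choices and problem sizes

* Timestamps are POSIXct (UTC) at minute resolution with a single local
  clock per participant; no time-zone arithmetic, since all rules are
  clock-time rules.
* The schedule covers the half-open window `[enrolled_at + 24 h, +d
  days)`, which yields exactly 4d reminders and d/7 weekly messages of
  each kind for any alignment; the simulator enrolls at midnight so all
  14 program days are complete reminder-days.
* Reporting rounds adherence half-up to an integer percent and response
  rates to one decimal; statistics always use the raw fractions.
* Test problem sizes: the classification partition is checked
  exhaustively over 20–600 × both contexts; the exact rank-sum route is
  enumerated for all tie-free configurations up to 6 per group; type-I
  error uses 1,000 null replicates at n = 9 vs 10; the planted
  adherence-jump power check uses 100 replicates of a 20-participant
  cohort. These sizes give stable binomial bands while keeping the suite
  fast.

## Known limitations

Spanish message bodies are not shipped (the language tag is supported
and the catalog validates per language); second reminders for unanswered
prompts, glucose summary tables/graphs, and meal-taken keywords are
deliberately out of scope; and the rank-sum default ignores pairing, as
discussed above. The published per-participant adherence medians cannot
be recomputed from any shipped data — the individual device exports were
never published — so the comparison machinery is validated on simulated
cohorts instead.
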