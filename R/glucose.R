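#' Glucose classification thresholds
#'
#' The desired ranges used by the feedback algorithm, in mg/dL: fasting
#' 61-94, one-hour postprandial 61-139, with critical tiers at <=60 (low)
#' and >=200 (high) that trigger an immediate care-team contact prompt
#' regardless of context. Values 95-199 fasting and 140-199 postprandial
#' fall in the non-critical out-of-range tier. Readings outside the
#' plausibility window [20, 600] are rejected as likely typos rather than
#' classified.
#'
#' @param fasting_low,fasting_high desired fasting range bounds, inclusive.
#' @param postprandial_low,postprandial_high desired postprandial range
#'   bounds, inclusive.
#' @param critical_low_max highest value treated as critically low.
#' @param critical_high_min lowest value treated as critically high.
#' @param plausible_min,plausible_max plausibility window; values outside
#'   it are errors, not classifications.
#' @return a `glucose_thresholds` list.
#' @export
glucose_thresholds <- function(fasting_low = 61, fasting_high = 94,
                               postprandial_low = 61,
                               postprandial_high = 139,
                               critical_low_max = 60,
                               critical_high_min = 200,
                               plausible_min = 20, plausible_max = 600) {
  th <- list(fasting_low = fasting_low, fasting_high = fasting_high,
             postprandial_low = postprandial_low,
             postprandial_high = postprandial_high,
             critical_low_max = critical_low_max,
             critical_high_min = critical_high_min,
             plausible_min = plausible_min, plausible_max = plausible_max)
  if (!(critical_low_max < fasting_low && critical_low_max < postprandial_low))
    stop("critical_low_max must lie below both desired-range lower bounds")
  if (!(critical_high_min > fasting_high && critical_high_min > postprandial_high))
    stop("critical_high_min must lie above both desired-range upper bounds")
  if (!(plausible_min <= critical_low_max && plausible_max >= critical_high_min))
    stop("desired and critical bounds must lie within the plausibility window")
  if (fasting_low > fasting_high || postprandial_low > postprandial_high)
    stop("desired range bounds must be ordered")
  structure(th, class = "glucose_thresholds")
}

#' Read threshold overrides from a YAML file
#'
#' Keys mirror the arguments of [glucose_thresholds()]; absent keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return a `glucose_thresholds` list.
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(glucose_thresholds))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown threshold key(s): ", paste(extra, collapse = ", "))
  do.call(glucose_thresholds, cfg)
}

#' Classify reported glucose values
#'
#' Assigns each value exactly one feedback tier given its measurement
#' context. The critical tiers are context-independent: `critical_low` for
#' values at or below 60 mg/dL and `critical_high` at or above 200 mg/dL.
#' Between those, a value inside the context's desired range (fasting
#' 61-94, postprandial 61-139) is `in_range`; anything else is the
#' non-critical `out_of_range` tier that advises contacting the care team.
#' Decimal inputs (rare in SMS replies) are rounded half-up before
#' classification.
#'
#' @param value numeric vector of glucose readings in mg/dL.
#' @param context `"fasting"` or `"postprandial"`, recycled to the length
#'   of `value`.
#' @param thresholds a [glucose_thresholds()] object.
#' @return data frame of class `glucose_classification` with columns
#'   `context`, `value` (the rounded integer) and `tier`.
#' @export
classify_glucose <- function(value, context,
                             thresholds = glucose_thresholds()) {
  context <- rep_len(match.arg(context, c("fasting", "postprandial"),
                               several.ok = TRUE), length(value))
  v <- round_half_up(value)
  bad <- v < thresholds$plausible_min | v > thresholds$plausible_max
  if (any(bad)) {
    stop(structure(
      class = c("glucotext_implausible_value", "error", "condition"),
      list(message = sprintf(
        "implausible glucose value(s) outside [%d, %d] mg/dL: %s",
        thresholds$plausible_min, thresholds$plausible_max,
        paste(v[bad], collapse = ", ")),
        call = sys.call(-1))))
  }
  lo <- ifelse(context == "fasting", thresholds$fasting_low,
               thresholds$postprandial_low)
  hi <- ifelse(context == "fasting", thresholds$fasting_high,
               thresholds$postprandial_high)
  tier <- ifelse(v <= thresholds$critical_low_max, "critical_low",
          ifelse(v >= thresholds$critical_high_min, "critical_high",
          ifelse(v >= lo & v <= hi, "in_range", "out_of_range")))
  structure(data.frame(context = context, value = as.integer(v),
                       tier = tier, stringsAsFactors = FALSE),
            class = c("glucose_classification", "data.frame"))
}

#' Map a feedback tier to its message category
#'
#' @param tier character vector of tiers.
#' @return matching `feedback_*` message categories.
#' @export
tier_to_category <- function(tier) {
  map <- c(in_range = "feedback_in_range",
           out_of_range = "feedback_out_of_range",
           critical_low = "feedback_critical_low",
           critical_high = "feedback_critical_high")
  out <- unname(map[tier])
  if (any(is.na(out))) {
    stop("unknown tier(s): ",
         paste(unique(tier[is.na(out)]), collapse = ", "))
  }
  out
}
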