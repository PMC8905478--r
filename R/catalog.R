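#' Message categories used by the program
#'
#' The ten message categories the intervention sends or uses during
#' onboarding. Feedback to a submitted glucose value is tiered: four
#' rotating encouragement messages when the value is in the desired range,
#' a single fixed reply for critically low and critically high values, and
#' a care-team contact prompt for values out of the desired (non-critical)
#' range.
#'
#' @export
message_categories <- c(
  "welcome", "disclaimer", "onboarding_question", "reminder",
  "feedback_in_range", "feedback_out_of_range",
  "feedback_critical_low", "feedback_critical_high",
  "educational", "motivational"
)

# categories whose templates rotate round-robin per participant when the
# group holds more than one template
.rotating_categories <- c("feedback_in_range", "educational", "motivational")

.default_templates <- function() {
  tpl <- function(category, rank, body) {
    data.frame(category = category, language = "en",
               rotation_rank = as.integer(rank), body = body,
               stringsAsFactors = FALSE)
  }
  rbind(
    tpl("welcome", 0L, paste0(
      "Welcome to Text 4 Success! We will text you reminders to check your ",
      "blood glucose and feedback on your numbers. Reply STOP at any time ",
      "to unsubscribe.")),
    tpl("disclaimer", 0L, paste0(
      "Please note: this account is not monitored by a clinician in real ",
      "time. Contact your care team with any clinical questions.")),
    tpl("onboarding_question", 0L,
        "To time your reminders, what time do you usually eat breakfast? Please reply like 08:00."),
    tpl("onboarding_question", 1L,
        "Thanks! What time do you usually eat lunch? Please reply like 12:30."),
    tpl("onboarding_question", 2L,
        "Great. And what time do you usually eat dinner? Please reply like 18:30."),
    tpl("reminder", 0L, paste0(
      "Hello! This is a Text 4 Success reminder to check your number before ",
      "eating your first meal. Please reply with your number only.")),
    tpl("reminder", 1L, paste0(
      "Hello! This is a Text 4 Success reminder to check your number 1 hour ",
      "after breakfast. Please reply with your number only.")),
    tpl("reminder", 2L, paste0(
      "Hello! This is a Text 4 Success reminder to check your number 1 hour ",
      "after lunch. Please reply with your number only.")),
    tpl("reminder", 3L, paste0(
      "Hello! This is a Text 4 Success reminder to check your number 1 hour ",
      "after dinner. Please reply with your number only.")),
    tpl("feedback_in_range", 0L,
        "Keep up the great work checking your numbers and taking charge of your health!"),
    tpl("feedback_in_range", 1L,
        "Great job! That number is in your goal range. Keep it up!"),
    tpl("feedback_in_range", 2L,
        "Nice work checking your number - it is right on target!"),
    tpl("feedback_in_range", 3L,
        "Well done! That reading is in range. Thank you for checking!"),
    tpl("feedback_out_of_range", 0L, paste0(
      "Thank you for checking. This number is outside your goal range. ",
      "Please contact your care team to discuss it.")),
    tpl("feedback_critical_low", 0L, paste0(
      "This number is low. Please treat your low blood sugar now and ",
      "contact your care team right away.")),
    tpl("feedback_critical_high", 0L, paste0(
      "This number is high. Please contact your care team right away.")),
    tpl("educational", 0L, paste0(
      "Eating nutritious foods is a key part of staying healthy. One ",
      "healthy snack is a plain Greek yogurt. Click for a list of more ",
      "snacks: http://tinyurl.com/y2az4zn6")),
    tpl("motivational", 0L,
        "If you feel off track, know that every day is another chance to get back on track!"),
    tpl("motivational", 1L,
        "You've got what it takes to keep checking your numbers!")
  )
}

#' Validate a template table
#'
#' Checks the invariants a catalog must satisfy: non-empty bodies, no
#' duplicate (category, language, rotation_rank), every required category
#' present for at least one language, exactly four rotating in-range
#' feedback templates, and exactly one template each for the critical-low
#' and critical-high tiers.
#'
#' @param templates data frame with columns `category`, `language`,
#'   `rotation_rank`, `body`.
#' @return character vector of problems; empty when the table is valid.
#' @export
catalog_problems <- function(templates) {
  problems <- character(0)
  needed <- c("category", "language", "rotation_rank", "body")
  miss_col <- setdiff(needed, names(templates))
  if (length(miss_col) > 0) {
    return(paste0("missing column(s): ", paste(miss_col, collapse = ", ")))
  }
  missing_cat <- setdiff(message_categories, unique(templates$category))
  if (length(missing_cat) > 0) {
    problems <- c(problems,
                  paste0("missing category: ", missing_cat))
  }
  unknown <- setdiff(unique(templates$category), message_categories)
  if (length(unknown) > 0) {
    problems <- c(problems, paste0("unknown category: ", unknown))
  }
  if (nrow(templates) > 0) {
    if (any(!nzchar(trimws(templates$body)))) {
      problems <- c(problems, "empty message body")
    }
    key <- paste(templates$category, templates$language,
                 templates$rotation_rank)
    if (anyDuplicated(key)) {
      problems <- c(problems, paste0(
        "duplicate (category, language, rotation_rank): ",
        paste(unique(key[duplicated(key)]), collapse = "; ")))
    }
    for (lang in unique(templates$language)) {
      n_in <- sum(templates$category == "feedback_in_range" &
                    templates$language == lang)
      if (n_in != 4) {
        problems <- c(problems, sprintf(
          "feedback_in_range must have exactly 4 templates (%s has %d)",
          lang, n_in))
      }
      for (cat in c("feedback_critical_low", "feedback_critical_high")) {
        n <- sum(templates$category == cat & templates$language == lang)
        if (n != 1) {
          problems <- c(problems, sprintf(
            "%s must have exactly 1 template (%s has %d)", cat, lang, n))
        }
      }
    }
  }
  problems
}

new_catalog <- function(templates) {
  templates <- templates[order(templates$category, templates$language,
                               templates$rotation_rank), , drop = FALSE]
  rownames(templates) <- NULL
  templates$template_id <- paste(templates$category, templates$language,
                                 templates$rotation_rank, sep = ":")
  structure(list(templates = templates, cursors = list()),
            class = "t4s_catalog")
}

#' Build the default message catalog
#'
#' English bodies for all ten categories: the reminder and weekly-message
#' texts the deployed program used, four rotating in-range feedback
#' replies, and single critical-low / critical-high replies. The wording of
#' the out-of-range feedback and onboarding prompts is this package's own.
#'
#' @return a `t4s_catalog` object.
#' @export
default_catalog <- function() {
  cat <- new_catalog(.default_templates())
  stopifnot(length(catalog_problems(cat$templates)) == 0)
  cat
}

#' Read a message catalog from a CSV file
#'
#' One record per template with columns `category`, `language`,
#' `rotation_rank`, `body`. Round-trips losslessly with
#' [write_catalog()]. With `path = NULL` the built-in default catalog is
#' returned.
#'
#' @param path CSV file, or `NULL` for the default catalog.
#' @return a `t4s_catalog` object.
#' @export
read_catalog <- function(path = NULL) {
  if (is.null(path)) return(default_catalog())
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  problems <- catalog_problems(df)
  if (length(problems) > 0) {
    stop("invalid catalog:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  df$rotation_rank <- as.integer(df$rotation_rank)
  new_catalog(df[c("category", "language", "rotation_rank", "body")])
}

#' Write a message catalog to CSV
#'
#' @param catalog a `t4s_catalog`.
#' @param path output file.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "t4s_catalog"))
  utils::write.csv(
    catalog$templates[c("category", "language", "rotation_rank", "body")],
    path, row.names = FALSE)
  invisible(path)
}

# all templates of one (category, language) group, in rotation-rank order
catalog_group <- function(catalog, category, language) {
  t <- catalog$templates
  g <- t[t$category == category & t$language == language, , drop = FALSE]
  g[order(g$rotation_rank), , drop = FALSE]
}

#' Select the next template of a category for a participant
#'
#' Categories with more than one template (the four in-range feedback
#' replies, weekly messages) rotate deterministically round-robin per
#' participant: each selection advances that participant's cursor by one,
#' modulo the group size, so over any 4k consecutive in-range selections
#' each of the four replies is used exactly k times. Single-template
#' categories always return their only template and keep no cursor.
#'
#' @param catalog a `t4s_catalog`.
#' @param participant_id participant identifier.
#' @param category message category.
#' @param language `"en"` or `"es"`.
#' @return list with `template` (one-row list: `template_id`, `category`,
#'   `language`, `rotation_rank`, `body`) and the updated `catalog`.
#' @export
next_template <- function(catalog, participant_id, category,
                          language = "en") {
  stopifnot(inherits(catalog, "t4s_catalog"))
  g <- catalog_group(catalog, category, language)
  if (nrow(g) == 0) {
    stop(sprintf("catalog gap: no '%s' template for language '%s'",
                 category, language), call. = FALSE)
  }
  if (nrow(g) == 1 || !(category %in% .rotating_categories)) {
    return(list(template = as.list(g[1, ]), catalog = catalog))
  }
  key <- paste(participant_id, category, language, sep = "\r")
  cur <- catalog$cursors[[key]]
  if (is.null(cur)) cur <- 0L
  idx <- (cur %% nrow(g)) + 1L
  catalog$cursors[[key]] <- (cur + 1L) %% nrow(g)
  list(template = as.list(g[idx, ]), catalog = catalog)
}

#' Select the feedback reply for a glucose tier
#'
#' Maps the tier to its feedback category and delegates to
#' [next_template()]: in-range feedback rotates through its four replies
#' per participant, while the critical tiers always return their single
#' fixed reply.
#'
#' @param catalog a `t4s_catalog`.
#' @param participant_id participant identifier.
#' @param tier one of `"in_range"`, `"out_of_range"`, `"critical_low"`,
#'   `"critical_high"`.
#' @param language `"en"` or `"es"`.
#' @return list with `template` and the updated `catalog` (see
#'   [next_template()]).
#' @export
next_feedback <- function(catalog, participant_id, tier, language = "en") {
  next_template(catalog, participant_id, tier_to_category(tier), language)
}

#' @export
print.t4s_catalog <- function(x, ...) {
  t <- x$templates
  cat(sprintf("<t4s_catalog> %d templates, %d language(s), %d rotation cursor(s)\n",
              nrow(t), length(unique(t$language)), length(x$cursors)))
  counts <- table(t$category)
  for (nm in names(counts)) cat(sprintf("  %-24s %d\n", nm, counts[[nm]]))
  invisible(x)
}
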