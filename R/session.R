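# Session data model: raw trial-level assessment records and cohort tables.
# The session file format is a versioned JSON schema defined by this package
# (the tablet's native log format is not parsed).

SESSION_SCHEMA_VERSION <- "1.0"

#' Construct a trial event
#'
#' @param trial_index Ordinal of the trial within its subtask (1-based).
#' @param stimulus_id Stimulus identifier string.
#' @param response_value Response as a string (verbal/choice tasks) or `NA`.
#' @param correct Logical: `TRUE`, `FALSE`, or `NA` for unscored events
#'   (e.g. stage markers, free-recall word productions).
#' @param timestamp_ms Milliseconds from session start.
#' @param tap_xy Optional numeric length-2 screen coordinate (pixels, origin
#'   top-left, y increasing downward), or `NULL`.
#' @return A list of class `ocs_event`.
#' @export
trial_event <- function(trial_index, stimulus_id, response_value = NA_character_,
                        correct = NA, timestamp_ms = 0, tap_xy = NULL) {
  ev <- list(
    trial_index = as.integer(trial_index),
    stimulus_id = as.character(stimulus_id),
    response_value = as.character(response_value),
    correct = as.logical(correct),
    timestamp_ms = as.numeric(timestamp_ms)
  )
  if (!is.null(tap_xy)) {
    stopifnot(length(tap_xy) == 2L)
    ev$tap_xy <- as.numeric(tap_xy)
  }
  class(ev) <- "ocs_event"
  ev
}

#' Construct a subtask block
#'
#' @param subtask_id One of [subtask_order()].
#' @param events List of [trial_event()]s, in presentation order.
#' @param skipped Was the subtask skipped? If `TRUE`, `events` must be empty
#'   and `skip_reason` non-empty; downstream measures become not-assessed,
#'   never zero.
#' @param skip_reason Free-text reason recorded when a subtask is skipped.
#' @param condition_flags Character vector of administration confounds
#'   (e.g. `"interruption"`, `"fatigue"`, `"technical"`).
#' @return A list of class `ocs_block`.
#' @export
subtask_block <- function(subtask_id, events = list(), skipped = FALSE,
                          skip_reason = NULL, condition_flags = character()) {
  blk <- list(
    subtask_id = as.character(subtask_id),
    skipped = isTRUE(skipped),
    skip_reason = if (is.null(skip_reason)) NULL else as.character(skip_reason),
    condition_flags = as.character(condition_flags),
    events = events
  )
  class(blk) <- "ocs_block"
  blk
}

#' Construct a session log
#'
#' @param participant_id Participant identifier.
#' @param age Age in years (> 0).
#' @param education_band `"standard"` or `"higher"`.
#' @param sex Free-form sex/gender code as recorded at testing.
#' @param site Collection site label (e.g. `"UK"`, `"DE"`).
#' @param session_datetime ISO-8601 datetime string.
#' @param blocks List of [subtask_block()]s in administration order.
#' @param validate Validate on construction (default `TRUE`).
#' @return A list of class `ocs_session`.
#' @export
session_log <- function(participant_id, age, education_band = "standard",
                        sex = NA_character_, site = NA_character_,
                        session_datetime = NA_character_, blocks = list(),
                        validate = TRUE) {
  log <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    participant_id = as.character(participant_id),
    age = as.numeric(age),
    education_band = as.character(education_band),
    sex = as.character(sex),
    site = as.character(site),
    session_datetime = as.character(session_datetime),
    blocks = blocks
  )
  class(log) <- "ocs_session"
  if (validate) validate_session(log)
  log
}

#' Validate a session log against the schema invariants
#'
#' Checks: known schema version; positive age; known subtask ids; unique trial
#' indices and non-decreasing timestamps within each block; skipped blocks have
#' no events and a non-empty skip reason. Errors name the offending block and
#' field.
#'
#' @param log An `ocs_session`.
#' @return `log`, invisibly, if valid; otherwise an error.
#' @export
validate_session <- function(log) {
  fail <- function(...) stop("session validation: ", ..., call. = FALSE)
  if (!identical(log$schema_version, SESSION_SCHEMA_VERSION))
    fail("unsupported schema_version '", log$schema_version, "'")
  if (!length(log$participant_id) || is.na(log$participant_id) || !nzchar(log$participant_id))
    fail("participant_id missing")
  if (!is.finite(log$age) || log$age <= 0) fail("age must be > 0")
  if (!log$education_band %in% c("standard", "higher", NA_character_))
    fail("education_band must be 'standard' or 'higher'")
  seen <- character()
  for (bi in seq_along(log$blocks)) {
    blk <- log$blocks[[bi]]
    where <- paste0("block ", bi, " ('", blk$subtask_id, "')")
    if (!blk$subtask_id %in% SUBTASK_ORDER)
      fail(where, ": unknown subtask_id")
    if (blk$subtask_id %in% seen) fail(where, ": duplicated subtask")
    seen <- c(seen, blk$subtask_id)
    if (blk$skipped) {
      if (length(blk$events)) fail(where, ": skipped block must have no events")
      if (is.null(blk$skip_reason) || !nzchar(blk$skip_reason))
        fail(where, ": skipped block requires a skip_reason")
      next
    }
    idx <- vapply(blk$events, function(e) e$trial_index, integer(1))
    if (anyDuplicated(idx)) fail(where, ": duplicate trial_index")
    ts <- vapply(blk$events, function(e) e$timestamp_ms, numeric(1))
    if (length(ts) > 1 && any(diff(ts) < 0))
      fail(where, ": timestamps must be non-decreasing")
  }
  # when all ten blocks are present their order must match administration order
  if (length(seen) == length(SUBTASK_ORDER) && !identical(seen, SUBTASK_ORDER))
    fail("all ten blocks present but not in administration order")
  invisible(log)
}

# canonical list representation used for JSON serialisation
session_to_list <- function(log) {
  blocks <- lapply(log$blocks, function(blk) {
    b <- list(subtask_id = blk$subtask_id, skipped = blk$skipped)
    if (!is.null(blk$skip_reason)) b$skip_reason <- blk$skip_reason
    b$condition_flags <- as.list(blk$condition_flags)
    b$events <- lapply(blk$events, function(e) {
      ev <- list(trial_index = e$trial_index, stimulus_id = e$stimulus_id,
                 response_value = e$response_value, correct = e$correct,
                 timestamp_ms = e$timestamp_ms)
      if (!is.null(e$tap_xy)) ev$tap_xy <- e$tap_xy
      ev
    })
    b
  })
  list(schema_version = log$schema_version,
       participant_id = log$participant_id, age = log$age,
       education_band = log$education_band, sex = log$sex, site = log$site,
       session_datetime = log$session_datetime, blocks = blocks)
}

#' Write a session log to a JSON file
#'
#' The on-disk format is a versioned JSON schema; optional fields (`tap_xy`,
#' `skip_reason`) are omitted, never null-filled. Files written here round-trip
#' bit-exactly through [read_session()].
#'
#' @param log A valid `ocs_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(log, path) {
  validate_session(log)
  jsonlite::write_json(session_to_list(log), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read and validate a session log from a JSON file
#'
#' @param path Path to a session JSON file written by [write_session()] (or
#'   conforming to the same schema).
#' @return A validated `ocs_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("schema_version", "participant_id", "age", "blocks")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("session validation: missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  blocks <- lapply(raw$blocks, function(b) {
    events <- lapply(b$events, function(e) {
      trial_event(e$trial_index, e$stimulus_id,
                  response_value = if (is.null(e$response_value)) NA_character_ else e$response_value,
                  correct = if (is.null(e$correct)) NA else e$correct,
                  timestamp_ms = e$timestamp_ms,
                  tap_xy = if (is.null(e$tap_xy)) NULL else unlist(e$tap_xy))
    })
    subtask_block(b$subtask_id, events = events, skipped = isTRUE(b$skipped),
                  skip_reason = b$skip_reason,
                  condition_flags = unlist(b$condition_flags) %||% character())
  })
  session_log(raw$participant_id, raw$age,
              education_band = raw$education_band %||% NA_character_,
              sex = raw$sex %||% NA_character_,
              site = raw$site %||% NA_character_,
              session_datetime = raw$session_datetime %||% NA_character_,
              blocks = blocks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort score table from CSV
#'
#' The CSV header must use canonical measure names from [measure_registry()]
#' alongside the demographic columns `participant_id`, `age` and optionally
#' `education_band`, `sex`, `site`. Empty cells become `NA` (explicit missing,
#' never zero); out-of-range scores raise an error naming row and measure.
#'
#' @param path CSV path (UTF-8, `.` decimal separator).
#' @return A data.frame of class `ocs_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_cohort(df)
}

#' Validate a data.frame as a cohort table
#'
#' @param df Data.frame with demographic columns and canonical measure columns.
#' @return `df` with class `ocs_cohort` prepended.
#' @export
as_cohort <- function(df) {
  reg <- measure_registry()
  demo <- c("participant_id", "age", "education_band", "sex", "site")
  meas <- setdiff(names(df), demo)
  unknown <- setdiff(meas, reg$measure)
  if (length(unknown))
    stop("unregistered measure column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!"participant_id" %in% names(df)) stop("cohort needs participant_id", call. = FALSE)
  for (m in meas) {
    r <- registry_row(m)
    v <- df[[m]]
    bad <- which(!is.na(v) & (v < r$min | (!is.na(r$max) & v > r$max)))
    if (length(bad))
      stop("out-of-range score for '", m, "' in row ", bad[1], ": ", v[bad[1]],
           " (allowed ", r$min, "-", ifelse(is.na(r$max), "Inf", r$max), ")",
           call. = FALSE)
  }
  class(df) <- unique(c("ocs_cohort", class(df)))
  df
}

#' Write a cohort table to CSV
#' @param cohort An `ocs_cohort` (or plain data.frame of scores).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
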