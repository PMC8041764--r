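# Automated per-participant impairment report: the "wheel" summary as
# structured data (JSON) plus a plain-text rendering. Each task segment is
# impaired / spared / not_assessed; "unscored" is reserved for measures with
# no scoring path (e.g. figure drawings without element scores, which the app
# greys out).

REPORT_SCHEMA_VERSION <- "1.0"

#' Generate an impairment report
#'
#' Binds a classified profile, domain scores and session metadata into a
#' deterministic, versioned report structure. Condition flags and skip
#' reasons are echoed; the norms provenance (band used) is recorded. Session
#' duration (first event of the first task to last event of the last) is
#' reported informationally and never used for classification.
#'
#' @param profile An `ocs_profile` from [classify_scores()].
#' @param session Optional `ocs_session` the profile came from (for metadata
#'   and duration). Participant ids must agree.
#' @return List of class `ocs_report`.
#' @export
generate_report <- function(profile, session = NULL) {
  pid <- attr(profile, "participant_id")
  meta <- list(participant_id = pid)
  if (!is.null(session)) {
    if (!is.na(pid) && !identical(session$participant_id, pid))
      stop("participant id mismatch: profile '", pid, "' vs session '",
           session$participant_id, "'", call. = FALSE)
    meta$participant_id <- session$participant_id
    meta$age <- session$age
    meta$session_datetime <- session$session_datetime
    ts <- unlist(lapply(session$blocks, function(b)
      vapply(b$events, `[[`, numeric(1), "timestamp_ms")))
    meta$duration_min <- if (length(ts)) round((max(ts) - min(ts)) / 60000, 2) else NA_real_
  }
  reasons <- attr(profile, "not_assessed") %||% character()
  segments <- lapply(seq_len(nrow(profile)), function(i) {
    m <- profile$measure[i]
    reason <- if (m %in% names(reasons)) unname(reasons[[m]]) else NULL
    status <- switch(profile$classification[i],
                     impaired = "impaired", within_norms = "spared",
                     not_assessed = if (!is.null(reason) &&
                                        grepl("^no element scores|^unscorable", reason))
                       "unscored" else "not_assessed")
    seg <- list(measure = m, status = status, score = profile$score[i],
                cutoff_value = profile$cutoff_value[i],
                cutoff_operator = profile$cutoff_operator[i])
    if (!is.null(reason)) seg$reason <- reason
    seg
  })
  doms <- attr(profile, "domains")
  domains <- if (is.null(doms)) list() else lapply(seq_len(nrow(doms)), function(i)
    list(domain = doms$domain[i], score = doms$score[i],
         classification = doms$classification[i]))
  structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    participant = meta,
    age_band = profile$age_band[1],
    condition_flags = as.character(attr(profile, "condition_flags") %||% character()),
    segments = segments,
    domains = domains
  ), class = "ocs_report")
}

#' Serialize a report to JSON
#'
#' Byte-identical output for identical inputs (stable field order, fixed
#' number formatting).
#'
#' @param report An `ocs_report`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path, useBytes = TRUE); return(invisible(js)) }
  js
}

#' @export
format.ocs_report <- function(x, ...) {
  glyph <- c(impaired = "[X]", spared = "[ok]", not_assessed = "[--]",
             unscored = "[..]")
  lines <- c(
    sprintf("OCS-Plus impairment report (schema %s)", x$schema_version),
    sprintf("participant: %s   age band: %s", x$participant$participant_id,
            x$age_band),
    if (length(x$condition_flags))
      sprintf("condition flags: %s", paste(x$condition_flags, collapse = ", ")),
    "",
    vapply(x$segments, function(s)
      sprintf("  %s %-28s %s", glyph[[s$status]], s$measure,
              if (is.na(s$score)) (s$reason %||% "") else
                sprintf("score %.6g (cut-off %s %s)", s$score,
                        s$cutoff_operator %||% "", format(s$cutoff_value))),
      character(1)),
    "",
    "domains:",
    vapply(x$domains, function(d)
      sprintf("  %-20s %s (%s)", d$domain,
              if (is.na(d$score)) "not assessed" else format(d$score),
              d$classification), character(1))
  )
  paste(lines, collapse = "\n")
}

#' @export
print.ocs_report <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
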