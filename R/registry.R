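# Canonical measure registry: every measure name used anywhere in the package
# resolves against this single table (name, range, direction of impairment,
# cut-off method). Ranges follow the published task score ranges.

#' Canonical OCS-Plus measure registry
#'
#' Returns the registry of all derived measures: score range, direction in
#' which impairment lies, and the normative cut-off method used for each.
#' Wide-range measures (trails, rule finding, figure drawing, cancellation
#' accuracies) use a z-based cut-off at 1.65 SD from the cohort mean;
#' restricted-range measures (the 0-4/0-5 tasks, error counts, rules learned)
#' use empirical 5th/95th centiles. Error counts and rules learned carry a
#' conservative floor: when the relevant centile reaches the degenerate end of
#' the scale the cut-off is raised to one.
#'
#' @return A data.frame with one row per measure: `measure`, `min`, `max`
#'   (`NA` for unbounded counts), `direction` (`"low_bad"` or `"high_bad"`),
#'   `method` (`"z"`, `"centile"` or `"none"` for intermediate measures that
#'   are not normed), `conservative_floor`, `uk_only` (measure normed on the
#'   UK subset when a `site` column is available), and `integer` (scores take
#'   integer values).
#' @export
#' @examples
#' measure_registry()[, c("measure", "min", "max", "method")]
measure_registry <- function() {
  reg <- read.csv(text = "measure,min,max,direction,method,conservative_floor,uk_only,integer
picture_naming,0,4,low_bad,centile,FALSE,FALSE,TRUE
semantics,0,4,low_bad,centile,FALSE,FALSE,TRUE
orientation,0,4,low_bad,centile,FALSE,FALSE,TRUE
encoding1,0,5,low_bad,centile,FALSE,FALSE,TRUE
encoding2,0,5,low_bad,centile,FALSE,FALSE,TRUE
delayed_recall,0,5,low_bad,centile,FALSE,FALSE,TRUE
delayed_recall_recognition,0,5,low_bad,centile,FALSE,FALSE,TRUE
episodic_recognition,0,4,low_bad,centile,FALSE,FALSE,TRUE
trails_circle,0,7,low_bad,none,FALSE,FALSE,TRUE
trails_square,0,7,low_bad,none,FALSE,FALSE,TRUE
trails_switch_correct,0,NA,low_bad,none,FALSE,FALSE,TRUE
executive_score,0,100,low_bad,z,FALSE,FALSE,FALSE
processing_speed,0,NA,high_bad,z,FALSE,FALSE,FALSE
rule_accuracy,0,46,low_bad,z,FALSE,FALSE,TRUE
rules_learned,0,5,low_bad,centile,TRUE,FALSE,TRUE
figure_copy,0,60,low_bad,z,FALSE,TRUE,TRUE
figure_recall,0,60,low_bad,z,FALSE,FALSE,TRUE
cancellation_hits,0,30,low_bad,z,FALSE,FALSE,TRUE
false_positives,0,NA,high_bad,centile,TRUE,FALSE,TRUE
invisible_hits,0,30,low_bad,z,FALSE,FALSE,TRUE
correct_revisits,0,NA,high_bad,centile,TRUE,FALSE,TRUE",
    stringsAsFactors = FALSE)
  reg
}

#' Registry lookup for a single measure
#' @param measure Measure name.
#' @return One-row data.frame from [measure_registry()].
#' @keywords internal
registry_row <- function(measure) {
  reg <- measure_registry()
  i <- match(measure, reg$measure)
  if (is.na(i)) stop("unknown measure: '", measure, "'", call. = FALSE)
  reg[i, , drop = FALSE]
}

#' Cognitive domain definitions
#'
#' Six domain summative scores, each the sum of related measures (false
#' positives enter the executive domain with negative sign).
#'
#' @return Named list; each element has `measures` (character) and `weights`
#'   (numeric, same length), plus the domain's theoretical `min`/`max`.
#' @export
domain_registry <- function() {
  list(
    executive_function = list(
      measures = c("rule_accuracy", "rules_learned", "executive_score", "false_positives"),
      weights  = c(1, 1, 1, -1), min = NA_real_, max = 151),
    praxis = list(
      measures = c("figure_copy", "figure_recall"), weights = c(1, 1),
      min = 0, max = 120),
    delayed_memory = list(
      measures = c("delayed_recall", "delayed_recall_recognition"), weights = c(1, 1),
      min = 0, max = 10),
    attention = list(
      measures = c("cancellation_hits", "invisible_hits"), weights = c(1, 1),
      min = 0, max = 60),
    memory_encoding = list(
      measures = c("encoding1", "encoding2"), weights = c(1, 1),
      min = 0, max = 10),
    naming_semantics = list(
      measures = c("picture_naming", "semantics"), weights = c(1, 1),
      min = 0, max = 8)
  )
}

# Subtask identifiers in administration order (1-10).
SUBTASK_ORDER <- c(
  "picture_naming", "semantics", "orientation", "word_encoding", "trails",
  "verbal_recall", "episodic_recognition", "figure", "rule_finding",
  "cancellation"
)

#' Subtask identifiers in administration order
#' @return Character vector of the ten subtask ids.
#' @export
subtask_order <- function() SUBTASK_ORDER

# The fixed five-word target list for the word memory tasks.
WORD_TARGETS <- c("bicycle", "mist", "wardrobe", "teacher", "rectangle")

#' Target word list for the word memory tasks
#' @return Character vector of the five target words.
#' @export
word_targets <- function() WORD_TARGETS

# Which measures each subtask yields (used when propagating skips).
SUBTASK_MEASURES <- list(
  picture_naming = "picture_naming",
  semantics = "semantics",
  orientation = "orientation",
  word_encoding = c("encoding1", "encoding2"),
  trails = c("trails_circle", "trails_square", "trails_switch_correct",
             "executive_score", "processing_speed"),
  verbal_recall = c("delayed_recall", "delayed_recall_recognition"),
  episodic_recognition = "episodic_recognition",
  figure = c("figure_copy", "figure_recall"),
  rule_finding = c("rule_accuracy", "rules_learned"),
  cancellation = c("cancellation_hits", "false_positives",
                   "invisible_hits", "correct_revisits")
)

# round half away from zero, as printed normative tables do
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
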