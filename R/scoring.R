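# Subtask scoring: converts trial-level session logs into the derived measure
# vector. Scoring rules follow the published task definitions: choice tasks
# count correct responses, word memory counts target intersections, trails
# yield an executive (switching) score and an accuracy-corrected processing
# speed, rule finding yields accuracy out of 46 plus rules detected, figure
# drawings sum 20 element scores out of 3, and the cancellation conditions
# yield hits plus condition-specific error counts.

#' Trails scoring configuration
#'
#' @param circle_max,square_max Number of connections in each baseline trail
#'   (seven each).
#' @param switch_max Number of connections in the switching trail. The
#'   instrument does not publish this length; the default of 13 is a
#'   configuration value, not a normative constant.
#' @return List of class `trails_config`.
#' @export
trails_config <- function(circle_max = 7L, square_max = 7L, switch_max = 13L) {
  stopifnot(circle_max > 0, square_max > 0, switch_max > 0)
  structure(list(circle_max = as.integer(circle_max),
                 square_max = as.integer(square_max),
                 switch_max = as.integer(switch_max)),
            class = "trails_config")
}

#' Rule-finding task configuration
#'
#' Five rules presented in contiguous segments; the trial immediately after
#' each rule change is excluded from the accuracy score, leaving 46 scoreable
#' trials under the default layout (5 segments of 10 trials, first trial of
#' segments 2-5 excluded).
#'
#' @param trials_per_segment Integer vector, trials in each rule segment.
#' @param consecutive_needed Correct anticipations in a row (within a segment,
#'   counted over scoreable trials only) required to credit rule detection.
#' @return List of class `rule_config` with `n_rules`, `scoreable_trials`,
#'   and an `excluded` logical vector over the full trial sequence.
#' @export
rule_config <- function(trials_per_segment = rep(10L, 5L), consecutive_needed = 2L) {
  n_rules <- length(trials_per_segment)
  segment <- rep(seq_len(n_rules), trials_per_segment)
  # first trial after each rule change (i.e. first trial of segments 2..n)
  excluded <- !duplicated(segment) & segment > 1L
  structure(list(n_rules = n_rules,
                 trials_per_segment = as.integer(trials_per_segment),
                 segment = segment, excluded = excluded,
                 scoreable_trials = sum(!excluded),
                 consecutive_needed = as.integer(consecutive_needed)),
            class = "rule_config")
}

# ---- individual scoring operations -----------------------------------------

#' Score a four-item choice subtask
#'
#' Applies to picture naming, semantics, orientation and episodic recognition:
#' the score is the count of correct responses out of `n_items`.
#'
#' @param block A `subtask_block`.
#' @param n_items Number of scoreable items (4).
#' @return Integer count, or `NA` (not assessed) when the block was skipped.
#' @export
score_choice_task <- function(block, n_items = 4L) {
  if (block$skipped) return(NA_integer_)
  scored <- Filter(function(e) !is.na(e$correct), block$events)
  if (length(scored) > n_items)
    stop("block '", block$subtask_id, "': ", length(scored),
         " scored events but only ", n_items, " items", call. = FALSE)
  sum(vapply(scored, function(e) isTRUE(e$correct), logical(1)))
}

normalize_word <- function(w) tolower(trimws(w))

#' Score the two word-memory encoding attempts
#'
#' Each attempt is scored independently as the number of distinct target words
#' produced (case-folded, trimmed; duplicates collapse; non-target words do
#' not count).
#'
#' @param attempt1,attempt2 Character vectors of recalled words.
#' @param targets Target word list (default [word_targets()]).
#' @return Named integer vector `c(encoding1 =, encoding2 =)`.
#' @export
score_word_memory <- function(attempt1, attempt2, targets = word_targets()) {
  tg <- normalize_word(targets)
  n1 <- length(intersect(normalize_word(attempt1), tg))
  n2 <- length(intersect(normalize_word(attempt2), tg))
  c(encoding1 = n1, encoding2 = n2)
}

#' Score delayed verbal recall with recognition fallback
#'
#' Free recall is scored 0-5; forced-choice recognition is offered only for
#' the words missed in free recall, and the combined recall-and-recognition
#' total adds correct recognitions to the free-recall score.
#'
#' @param free Character vector of freely recalled words.
#' @param recognized Named logical vector: one outcome per *missed* target
#'   word (`TRUE` = recognized). Supplying an outcome for a freely recalled
#'   word is an error.
#' @param targets Target word list.
#' @return Named integer vector `c(delayed_recall =, delayed_recall_recognition =)`.
#' @export
score_delayed_recall <- function(free, recognized = logical(), targets = word_targets()) {
  tg <- normalize_word(targets)
  got <- intersect(normalize_word(free), tg)
  rec_names <- normalize_word(names(recognized))
  overlap <- intersect(rec_names, got)
  if (length(overlap))
    stop("recognition outcome supplied for freely recalled word(s): ",
         paste(overlap, collapse = ", "), call. = FALSE)
  unknown <- setdiff(rec_names, tg)
  if (length(unknown))
    stop("recognition outcome for non-target word(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  recall <- length(got)
  total <- recall + sum(recognized)
  c(delayed_recall = recall, delayed_recall_recognition = total)
}

#' Executive (switching) score and accuracy-corrected processing speed
#'
#' The switching effect is expressed as the proportion correct on the
#' switching trail over the summed proportion correct on both baseline trails,
#' scaled to 0-100 and capped at 100. Processing speed is the summed baseline
#' time divided by the baseline accuracy proportion, so fast-but-inaccurate
#' trail drawing is penalised (higher = worse).
#'
#' @param circle_correct,square_correct,switch_correct Correct connections.
#' @param circle_time_s,square_time_s Baseline completion times in seconds.
#' @param cfg A [trails_config()].
#' @param cap Cap the executive ratio at this value (default 100; set `Inf`
#'   to disable).
#' @return List with `executive_score`, `processing_speed`, and `unscorable`
#'   (TRUE when baseline accuracy is zero, in which case both values are `NA`
#'   rather than infinite).
#' @export
compute_trails_metrics <- function(circle_correct, square_correct, switch_correct,
                                   circle_time_s, square_time_s,
                                   cfg = trails_config(), cap = 100) {
  stopifnot(circle_correct >= 0, circle_correct <= cfg$circle_max,
            square_correct >= 0, square_correct <= cfg$square_max,
            switch_correct >= 0, switch_correct <= cfg$switch_max,
            circle_time_s > 0, square_time_s > 0)
  baseline_prop <- (circle_correct + square_correct) / (cfg$circle_max + cfg$square_max)
  if (baseline_prop == 0)
    return(list(executive_score = NA_real_, processing_speed = NA_real_,
                unscorable = TRUE))
  switch_prop <- switch_correct / cfg$switch_max
  list(executive_score = 100 * min(cap / 100, switch_prop / baseline_prop),
       processing_speed = (circle_time_s + square_time_s) / baseline_prop,
       unscorable = FALSE)
}

#' Score the rule-finding task
#'
#' Accuracy is the number of correct anticipations over the scoreable trials
#' (those not immediately after a rule change). A rule counts as detected when
#' at least `consecutive_needed` consecutive correct responses occur within
#' its segment; excluded trials neither break a run nor count toward it.
#'
#' @param correct Logical vector over the full trial sequence.
#' @param cfg A [rule_config()] describing segments and exclusions.
#' @return Named integer vector `c(rule_accuracy =, rules_learned =)`.
#' @export
score_rule_finding <- function(correct, cfg = rule_config()) {
  correct <- as.logical(correct)
  if (length(correct) != length(cfg$segment))
    stop("expected ", length(cfg$segment), " trials, got ", length(correct),
         call. = FALSE)
  scoreable <- !cfg$excluded
  acc <- sum(correct[scoreable], na.rm = TRUE)
  learned <- 0L
  for (g in seq_len(cfg$n_rules)) {
    run <- 0L
    hit <- FALSE
    for (i in which(cfg$segment == g)) {
      if (cfg$excluded[i]) next            # breaks no run, counts for none
      run <- if (isTRUE(correct[i])) run + 1L else 0L
      if (run >= cfg$consecutive_needed) { hit <- TRUE; break }
    }
    learned <- learned + hit
  }
  c(rule_accuracy = acc, rules_learned = learned)
}

#' Score a figure drawing from its 20 element scores
#'
#' Each of the 20 specified elements is scored 0/1 for presence, position and
#' accuracy (a total out of 3); the drawing score is the sum, out of 60. The
#' same rule applies to the copy and the recall drawing.
#'
#' @param elements Data.frame with columns `element_id` (1-20, unique),
#'   `presence`, `position`, `accuracy` (each 0/1).
#' @return Integer total 0-60.
#' @export
score_figure <- function(elements) {
  if (!all(c("element_id", "presence", "position", "accuracy") %in% names(elements)))
    stop("elements needs element_id/presence/position/accuracy", call. = FALSE)
  if (nrow(elements) != 20L || anyDuplicated(elements$element_id) ||
      !setequal(elements$element_id, 1:20))
    stop("exactly 20 elements with unique ids 1-20 required", call. = FALSE)
  sub <- as.matrix(elements[, c("presence", "position", "accuracy")])
  if (any(!sub %in% c(0, 1))) stop("element sub-scores must be 0/1", call. = FALSE)
  as.integer(sum(sub))
}

# ---- cancellation -----------------------------------------------------------

#' Default cancellation display layout
#'
#' A 9x5 grid of 45 axis-aligned item bounding boxes: 30 targets (fruit) and
#' 15 distractors (vegetables), 80x80 px cells with 10 px gutters. Shipped as
#' the reference layout for simulated sessions; real deployments supply their
#' own layout.
#'
#' @return Data.frame with `item_id`, `role` ("target"/"distractor"),
#'   `x0`, `y0`, `x1`, `y1`.
#' @export
default_cancellation_layout <- function() {
  grid <- expand.grid(col = 0:8, row = 0:4)
  n <- nrow(grid)
  role <- rep("target", n)
  role[seq(3, n, by = 3)] <- "distractor"   # every third cell: 15 distractors
  data.frame(
    item_id = sprintf("item_%02d", seq_len(n)),
    role = role,
    x0 = grid$col * 90 + 10, y0 = grid$row * 90 + 10,
    x1 = grid$col * 90 + 90, y1 = grid$row * 90 + 90,
    stringsAsFactors = FALSE
  )
}

# tap -> layout row index; smallest enclosing box wins, ties by layout order;
# taps outside every box return NA
hit_test <- function(xy, layout) {
  inside <- xy[1] >= layout$x0 & xy[1] <= layout$x1 &
            xy[2] >= layout$y0 & xy[2] <= layout$y1
  if (!any(inside)) return(NA_integer_)
  cand <- which(inside)
  area <- (layout$x1 - layout$x0) * (layout$y1 - layout$y0)
  cand[which.min(area[cand])]
}

#' Score one cancellation condition from its tap stream
#'
#' Taps are hit-tested against the layout's bounding boxes (taps outside any
#' box are ignored). Hits are distinct targets selected (max 30). In the
#' feedback condition each selection of a distractor scores one false
#' positive; in the no-feedback (invisible) condition each re-selection of an
#' already-found target scores one correct revisit.
#'
#' @param block A `subtask_block` whose events carry `tap_xy`; only events for
#'   the requested condition are replayed (matched on `stimulus_id` prefix
#'   `"feedback"` / `"no_feedback"`).
#' @param layout Item bounding boxes, as [default_cancellation_layout()].
#' @param condition `"feedback"` or `"no_feedback"`.
#' @return Named integer vector: `c(hits =, false_positives =)` for the
#'   feedback condition, `c(hits =, correct_revisits =)` otherwise.
#' @export
score_cancellation <- function(block, layout = default_cancellation_layout(),
                               condition = c("feedback", "no_feedback")) {
  condition <- match.arg(condition)
  n_targets <- sum(layout$role == "target")
  if (n_targets != 30L)
    stop("layout must contain 30 targets, found ", n_targets, call. = FALSE)
  evs <- Filter(function(e) startsWith(e$stimulus_id, condition) &&
                  !startsWith(e$stimulus_id, paste0("no_", condition)),
                block$events)
  selected <- character()
  errors <- 0L
  for (e in evs) {
    if (is.null(e$tap_xy)) next
    i <- hit_test(e$tap_xy, layout)
    if (is.na(i)) next
    id <- layout$item_id[i]
    if (layout$role[i] == "distractor") {
      if (condition == "feedback") errors <- errors + 1L
      next
    }
    if (id %in% selected) {
      if (condition == "no_feedback") errors <- errors + 1L
    } else {
      selected <- c(selected, id)
    }
  }
  hits <- min(length(selected), 30L)
  if (condition == "feedback") c(hits = hits, false_positives = errors)
  else c(hits = hits, correct_revisits = errors)
}

# ---- session orchestration --------------------------------------------------

block_by_id <- function(log, id) {
  for (blk in log$blocks) if (blk$subtask_id == id) return(blk)
  NULL
}

events_df <- function(block) {
  data.frame(
    trial_index = vapply(block$events, `[[`, integer(1), "trial_index"),
    stimulus_id = vapply(block$events, `[[`, character(1), "stimulus_id"),
    response_value = vapply(block$events, `[[`, character(1), "response_value"),
    correct = vapply(block$events, `[[`, logical(1), "correct"),
    timestamp_ms = vapply(block$events, `[[`, numeric(1), "timestamp_ms"),
    stringsAsFactors = FALSE
  )
}

stage_time_s <- function(df, stage) {
  rows <- df[startsWith(df$stimulus_id, stage), , drop = FALSE]
  if (!nrow(rows)) return(NA_real_)
  (max(rows$timestamp_ms) - min(rows$timestamp_ms)) / 1000
}

#' Score a full session
#'
#' Orchestrates all subtask scoring rules over a validated session log. Every
#' measure is either scored or marked not-assessed (with the block's skip
#' reason); skipped or absent subtasks propagate `NA`, never zero. Condition
#' flags are collected and attached for the downstream report.
#'
#' @param log A validated `ocs_session`.
#' @param trails_cfg A [trails_config()].
#' @param rule_cfg A [rule_config()].
#' @param layout Cancellation layout (see [default_cancellation_layout()]).
#' @return A one-row data.frame of class `ocs_scores` with one column per
#'   registry measure plus `participant_id` and `age`; attributes
#'   `not_assessed` (named character: measure -> reason) and
#'   `condition_flags`.
#' @export
score_session <- function(log, trails_cfg = trails_config(),
                          rule_cfg = rule_config(),
                          layout = default_cancellation_layout()) {
  validate_session(log)
  reg <- measure_registry()
  scores <- stats::setNames(rep(NA_real_, nrow(reg)), reg$measure)
  reasons <- character()
  flags <- character()

  mark_skipped <- function(id, reason) {
    for (m in SUBTASK_MEASURES[[id]]) reasons[[m]] <<- reason
  }

  for (id in SUBTASK_ORDER) {
    blk <- block_by_id(log, id)
    if (is.null(blk)) { mark_skipped(id, "block absent"); next }
    if (length(blk$condition_flags))
      flags <- c(flags, paste0(id, ":", blk$condition_flags))
    if (blk$skipped) { mark_skipped(id, blk$skip_reason); next }

    if (id %in% c("picture_naming", "semantics", "orientation", "episodic_recognition")) {
      scores[[id]] <- score_choice_task(blk)
    } else if (id == "word_encoding") {
      df <- events_df(blk)
      sc <- score_word_memory(df$response_value[df$stimulus_id == "attempt1"],
                              df$response_value[df$stimulus_id == "attempt2"])
      scores[["encoding1"]] <- sc[["encoding1"]]
      scores[["encoding2"]] <- sc[["encoding2"]]
    } else if (id == "verbal_recall") {
      df <- events_df(blk)
      free <- df$response_value[df$stimulus_id == "free"]
      rec <- df[startsWith(df$stimulus_id, "recognition:"), , drop = FALSE]
      recognized <- stats::setNames(rec$correct, sub("^recognition:", "", rec$stimulus_id))
      sc <- score_delayed_recall(free, recognized)
      scores[["delayed_recall"]] <- sc[["delayed_recall"]]
      scores[["delayed_recall_recognition"]] <- sc[["delayed_recall_recognition"]]
    } else if (id == "trails") {
      df <- events_df(blk)
      conn <- function(stage) {
        rows <- df[startsWith(df$stimulus_id, paste0(stage, "_c")), , drop = FALSE]
        sum(rows$correct, na.rm = TRUE)
      }
      cc <- conn("circle"); sc_ <- conn("square"); sw <- conn("switch")
      scores[["trails_circle"]] <- cc
      scores[["trails_square"]] <- sc_
      scores[["trails_switch_correct"]] <- sw
      ct <- stage_time_s(df, "circle"); st <- stage_time_s(df, "square")
      if (is.finite(ct) && is.finite(st) && ct > 0 && st > 0) {
        tm <- compute_trails_metrics(cc, sc_, sw, ct, st, trails_cfg)
        if (tm$unscorable) {
          reasons[["executive_score"]] <- "unscorable: zero baseline accuracy"
          reasons[["processing_speed"]] <- "unscorable: zero baseline accuracy"
        } else {
          scores[["executive_score"]] <- tm$executive_score
          scores[["processing_speed"]] <- tm$processing_speed
        }
      } else {
        reasons[["executive_score"]] <- "missing stage timing"
        reasons[["processing_speed"]] <- "missing stage timing"
      }
    } else if (id == "figure") {
      df <- events_df(blk)
      fig <- function(stage) {
        rows <- df[startsWith(df$stimulus_id, paste0(stage, "_elem_")), , drop = FALSE]
        if (!nrow(rows)) return(NA_integer_)
        parts <- do.call(rbind, lapply(strsplit(rows$response_value, ","), as.numeric))
        score_figure(data.frame(
          element_id = as.integer(sub(paste0("^", stage, "_elem_"), "", rows$stimulus_id)),
          presence = parts[, 1], position = parts[, 2], accuracy = parts[, 3]))
      }
      fc <- fig("copy"); fr <- fig("recall")
      if (is.na(fc)) reasons[["figure_copy"]] <- "no element scores supplied"
      else scores[["figure_copy"]] <- fc
      if (is.na(fr)) reasons[["figure_recall"]] <- "no element scores supplied"
      else scores[["figure_recall"]] <- fr
    } else if (id == "rule_finding") {
      df <- events_df(blk)
      df <- df[order(df$trial_index), , drop = FALSE]
      sc <- score_rule_finding(df$correct, rule_cfg)
      scores[["rule_accuracy"]] <- sc[["rule_accuracy"]]
      scores[["rules_learned"]] <- sc[["rules_learned"]]
    } else if (id == "cancellation") {
      fb <- score_cancellation(blk, layout, "feedback")
      nf <- score_cancellation(blk, layout, "no_feedback")
      scores[["cancellation_hits"]] <- fb[["hits"]]
      scores[["false_positives"]] <- fb[["false_positives"]]
      scores[["invisible_hits"]] <- nf[["hits"]]
      scores[["correct_revisits"]] <- nf[["correct_revisits"]]
    }
  }

  out <- as.data.frame(as.list(scores))
  out <- cbind(data.frame(participant_id = log$participant_id, age = log$age,
                          stringsAsFactors = FALSE), out)
  attr(out, "not_assessed") <- reasons
  attr(out, "condition_flags") <- flags
  class(out) <- c("ocs_scores", class(out))
  out
}
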