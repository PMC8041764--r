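# Synthetic cohorts, trial-level sessions, retest pairs and external-battery
# scores with known ground truth. Default distributional parameters are
# illustrative values loosely calibrated to the shapes of published
# age-banded normative tables (declining means and widening SDs with age,
# ceiling effects on the restricted-range tasks); they are configuration, not
# the instrument's data.

# inverse-CDF truncated normal
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Default synthetic-cohort configuration
#'
#' Per-age-band generating parameters for every measure. Continuous z-normed
#' measures are truncated normals with band means/SDs following the published
#' age-banded patterns (e.g. figure recall means 47.02 / 42.43 / 41.25 across
#' the three bands); restricted-range tasks are binomial hit-count models
#' near ceiling; error counts are Poisson. Band sizes default to 111/101/108
#' of n = 320.
#'
#' @param n_participants Cohort size.
#' @return Nested list of class `ocs_genconfig`.
#' @export
default_generator_config <- function(n_participants = 320) {
  structure(list(
    n_participants = n_participants,
    band_weights = c(111, 101, 108) / 320,
    age_ranges = list(c(23, 59), c(60, 70), c(71, 99)),
    p_uk = 234 / 320,
    p_higher_edu = 0.6,
    continuous = list(
      processing_speed = list(mean = c(31.44, 31.67, 39.54),
                              sd = c(16.78, 15.05, 22.58), lo = 14, hi = 150),
      rule_accuracy    = list(mean = c(29.17, 26.56, 24.41),
                              sd = c(7.82, 7.99, 8.15), lo = 0, hi = 46),
      figure_copy      = list(mean = c(56.85, 55.37, 53.57),
                              sd = c(6.24, 6.09, 7.35), lo = 0, hi = 60),
      figure_recall    = list(mean = c(47.02, 42.43, 41.25),
                              sd = c(9.70, 11.27, 9.88), lo = 0, hi = 60),
      cancellation_hits = list(mean = c(29.82, 29.63, 29.56),
                               sd = c(0.43, 0.62, 0.78), lo = 0, hi = 30),
      invisible_hits   = list(mean = c(28.93, 28.46, 27.94),
                              sd = c(1.43, 1.50, 2.26), lo = 0, hi = 30)
    ),
    hit_rates = list(                    # binomial p per band
      picture_naming = c(0.96, 0.95, 0.94),
      semantics = c(0.95, 0.94, 0.93),
      orientation = c(0.95, 0.94, 0.92),
      encoding1 = c(0.90, 0.87, 0.83),
      encoding2 = c(0.97, 0.95, 0.93),
      delayed_recall = c(0.86, 0.80, 0.74),
      episodic_recognition = c(0.93, 0.93, 0.92),
      trails_baseline = c(0.985, 0.98, 0.975),
      trails_switch = c(0.90, 0.82, 0.85)
    ),
    p_recognition = 0.90,                # recovery of missed words by choice
    error_rates = list(                  # Poisson lambda per band
      false_positives = c(0.05, 0.07, 0.09),
      correct_revisits = c(0.20, 0.30, 0.50)
    ),
    rules_noise_sd = 0.8
  ), class = "ocs_genconfig")
}

# feasible rules_learned range given a rule accuracy under the default layout
rules_feasible_range <- function(acc, cfg = rule_config()) {
  sizes <- sort(tapply(!cfg$excluded, cfg$segment, sum), decreasing = TRUE)
  capacity <- vapply(0:cfg$n_rules, function(k) {
    full <- if (k) sum(sizes[seq_len(k)]) else 0
    rest_sizes <- if (k) sizes[-seq_len(k)] else sizes
    full + sum(ceiling(rest_sizes / 2))
  }, numeric(1))
  kmin <- min(which(capacity >= acc)) - 1L
  kmax <- min(cfg$n_rules, floor(acc / cfg$consecutive_needed))
  if (kmin > kmax) stop("no feasible rules_learned for accuracy ", acc, call. = FALSE)
  c(kmin, kmax)
}

#' Simulate a normative cohort with known ground truth
#'
#' Deterministic under the seed. Returns the cohort score table (one row per
#' participant, canonical measure columns) and the ground truth needed to
#' reconstruct trial-level sessions that score back to exactly these values
#' (trail connection counts and stage times, recognition successes).
#'
#' @param cfg A [default_generator_config()].
#' @param seed Random seed.
#' @return List: `cohort` (`ocs_cohort`), `truth` (data.frame with
#'   per-participant latent/auxiliary values and the intended scores).
#' @export
simulate_cohort <- function(cfg = default_generator_config(), seed = 1) {
  set.seed(seed)
  n <- cfg$n_participants
  band_i <- sample.int(3, n, replace = TRUE, prob = cfg$band_weights)
  age <- vapply(band_i, function(b) {
    r <- cfg$age_ranges[[b]]
    sample(seq(r[1], r[2]), 1)
  }, numeric(1))
  site <- ifelse(stats::runif(n) < cfg$p_uk, "UK", "DE")
  edu <- ifelse(stats::runif(n) < cfg$p_higher_edu, "higher", "standard")
  sex <- sample(c("male", "female"), n, replace = TRUE)

  hb <- function(task, size) {
    p <- cfg$hit_rates[[task]][band_i]
    stats::rbinom(n, size, p)
  }
  tc <- function(m) {
    par <- cfg$continuous[[m]]
    rtruncnorm(n, par$mean[band_i], par$sd[band_i], par$lo, par$hi)
  }

  picture_naming <- hb("picture_naming", 4)
  semantics <- hb("semantics", 4)
  orientation <- hb("orientation", 4)
  encoding1 <- hb("encoding1", 5)
  encoding2 <- hb("encoding2", 5)
  delayed_recall <- hb("delayed_recall", 5)
  recognized <- stats::rbinom(n, 5 - delayed_recall, cfg$p_recognition)
  delayed_recall_recognition <- delayed_recall + recognized
  episodic_recognition <- hb("episodic_recognition", 4)

  trails_circle <- pmax(hb("trails_baseline", 7), 1)   # healthy norms: never zero baseline
  trails_square <- pmax(hb("trails_baseline", 7), 1)
  trails_switch <- hb("trails_switch", 13)
  bp <- (trails_circle + trails_square) / 14
  ps_target <- tc("processing_speed")
  total_ms <- round(ps_target * bp * 1000)
  circle_ms <- round(total_ms * stats::runif(n, 0.45, 0.55))
  square_ms <- total_ms - circle_ms
  # same floating-point op order as compute_trails_metrics, so sessions
  # reconstructed from this truth score back to bit-identical values
  processing_speed <- (circle_ms / 1000 + square_ms / 1000) / bp
  executive_score <- 100 * pmin(1, (trails_switch / 13) / bp)

  rule_accuracy <- pmin(46, pmax(0, round(tc("rule_accuracy"))))
  rules_learned <- vapply(seq_len(n), function(i) {
    fr <- rules_feasible_range(rule_accuracy[i])
    cand <- round(rule_accuracy[i] / 46 * 5 + stats::rnorm(1, 0, cfg$rules_noise_sd))
    min(max(cand, fr[1]), fr[2])
  }, numeric(1))

  figure_copy <- pmin(60, pmax(0, round(tc("figure_copy"))))
  figure_recall <- pmin(60, pmax(0, round(tc("figure_recall"))))
  cancellation_hits <- pmin(30, pmax(0, round(tc("cancellation_hits"))))
  invisible_hits <- pmax(pmin(30, pmax(0, round(tc("invisible_hits")))), 1)
  false_positives <- stats::rpois(n, cfg$error_rates$false_positives[band_i])
  correct_revisits <- stats::rpois(n, cfg$error_rates$correct_revisits[band_i])

  cohort <- data.frame(
    participant_id = sprintf("sim_%04d", seq_len(n)),
    age = age, education_band = edu, sex = sex, site = site,
    picture_naming = picture_naming, semantics = semantics,
    orientation = orientation, encoding1 = encoding1, encoding2 = encoding2,
    delayed_recall = delayed_recall,
    delayed_recall_recognition = delayed_recall_recognition,
    episodic_recognition = episodic_recognition,
    trails_circle = trails_circle, trails_square = trails_square,
    trails_switch_correct = trails_switch,
    executive_score = executive_score, processing_speed = processing_speed,
    rule_accuracy = rule_accuracy, rules_learned = rules_learned,
    figure_copy = figure_copy, figure_recall = figure_recall,
    cancellation_hits = cancellation_hits, false_positives = false_positives,
    invisible_hits = invisible_hits, correct_revisits = correct_revisits,
    stringsAsFactors = FALSE
  )
  truth <- cbind(cohort,
                 data.frame(band = AGE_BANDS[band_i], recognized = recognized,
                            circle_ms = circle_ms, square_ms = square_ms,
                            stringsAsFactors = FALSE))
  list(cohort = as_cohort(cohort), truth = truth)
}

# constructive correct/incorrect sequence achieving (acc, k) exactly
make_rule_sequence <- function(acc, k, cfg = rule_config()) {
  fr <- rules_feasible_range(acc, cfg)
  if (k < fr[1] || k > fr[2])
    stop("infeasible intended rule scores: accuracy ", acc, ", rules ", k,
         " (feasible rules ", fr[1], "-", fr[2], ")", call. = FALSE)
  correct <- rep(FALSE, length(cfg$segment))
  seg_slots <- lapply(seq_len(cfg$n_rules), function(g)
    which(cfg$segment == g & !cfg$excluded))
  sizes <- lengths(seg_slots)
  learned <- order(sizes, decreasing = TRUE)[seq_len(k)]
  alloc <- integer(cfg$n_rules)
  rem <- acc
  for (g in learned) { alloc[g] <- cfg$consecutive_needed; rem <- rem - cfg$consecutive_needed }
  for (g in learned) {                 # top up learned segments to full
    extra <- min(sizes[g] - alloc[g], rem)
    alloc[g] <- alloc[g] + extra; rem <- rem - extra
  }
  for (g in setdiff(seq_len(cfg$n_rules), learned)) {  # non-adjacent fills
    extra <- min(ceiling(sizes[g] / 2), rem)
    alloc[g] <- extra; rem <- rem - extra
  }
  stopifnot(rem == 0)
  for (g in seq_len(cfg$n_rules)) {
    slots <- seg_slots[[g]]
    if (g %in% learned) {
      correct[slots[seq_len(alloc[g])]] <- TRUE      # one consecutive run
    } else if (alloc[g] > 0) {
      correct[slots[seq(1, by = 2, length.out = alloc[g])]] <- TRUE  # no run of 2
    }
  }
  correct
}

#' Simulate a trial-level session from intended scores
#'
#' Emits a full ten-block session log (choice responses, word lists, trail
#' connections with stage timings, the rule-finding anticipation sequence
#' with post-change exclusions, 20 figure elements per drawing, and
#' cancellation tap streams with layout coordinates) constructed so that
#' [score_session()] recovers the intended scores exactly.
#'
#' @param truth One row of the `truth` data.frame from [simulate_cohort()].
#' @param seed Random seed (reserved for event timing jitter).
#' @param layout Cancellation layout used for tap coordinates.
#' @return An `ocs_session`.
#' @export
simulate_session <- function(truth, seed = 1, layout = default_cancellation_layout()) {
  set.seed(seed)
  tr <- as.list(truth[1, , drop = FALSE])
  clock <- 0
  tick <- function(ms = 1500) { clock <<- clock + ms; clock }
  targets <- word_targets()

  choice_block <- function(id, score, n_items = 4) {
    evs <- lapply(seq_len(n_items), function(i)
      trial_event(i, paste0(id, "_item_", i), correct = i <= score,
                  timestamp_ms = tick()))
    subtask_block(id, evs)
  }
  word_events <- function(words, stim, offset = 0) {
    lapply(seq_along(words), function(i)
      trial_event(offset + i, stim, response_value = words[i],
                  timestamp_ms = tick(800)))
  }

  blocks <- list()
  blocks[[1]] <- choice_block("picture_naming", tr$picture_naming)
  blocks[[2]] <- choice_block("semantics", tr$semantics)
  blocks[[3]] <- choice_block("orientation", tr$orientation)

  evs <- c(word_events(targets[seq_len2(tr$encoding1)], "attempt1"),
           word_events(targets[seq_len2(tr$encoding2)], "attempt2",
                       offset = tr$encoding1))
  blocks[[4]] <- subtask_block("word_encoding", evs)

  stage_events <- function(stage, n_max, n_correct, dur_ms, idx0) {
    start <- trial_event(idx0, paste0(stage, "_start"), timestamp_ms = tick(500))
    t0 <- start$timestamp_ms
    step <- dur_ms / n_max
    evs <- lapply(seq_len(n_max), function(i)
      trial_event(idx0 + i, sprintf("%s_c%d", stage, i), correct = i <= n_correct,
                  timestamp_ms = t0 + round(i * step)))
    clock <<- t0 + dur_ms
    # pin the last event exactly at t0 + dur_ms so the stage time is exact
    evs[[n_max]]$timestamp_ms <- t0 + dur_ms
    c(list(start), evs)
  }
  evs <- c(stage_events("circle", 7, tr$trails_circle, tr$circle_ms, 0),
           stage_events("square", 7, tr$trails_square, tr$square_ms, 10),
           stage_events("switch", 13, tr$trails_switch_correct, 20000, 20))
  blocks[[5]] <- subtask_block("trails", evs)

  free <- targets[seq_len2(tr$delayed_recall)]
  missed <- setdiff(targets, free)
  rec_ok <- seq_along(missed) <= tr$recognized
  evs <- c(word_events(free, "free"),
           lapply(seq_along(missed), function(i)
             trial_event(length(free) + i, paste0("recognition:", missed[i]),
                         correct = rec_ok[i], timestamp_ms = tick())))
  blocks[[6]] <- subtask_block("verbal_recall", evs)

  blocks[[7]] <- choice_block("episodic_recognition", tr$episodic_recognition)

  elem_scores <- function(total) {
    per <- integer(20)
    full <- total %/% 3
    per[seq_len2(full)] <- 3
    if (full < 20) per[full + 1] <- total %% 3
    vapply(per, function(s) paste(c(rep(1, s), rep(0, 3 - s)), collapse = ","),
           character(1))
  }
  fig_events <- function(stage, total, offset) {
    sc <- elem_scores(total)
    lapply(1:20, function(i)
      trial_event(offset + i, sprintf("%s_elem_%d", stage, i),
                  response_value = sc[i], timestamp_ms = tick(900)))
  }
  blocks[[8]] <- subtask_block("figure", c(fig_events("copy", tr$figure_copy, 0),
                                           fig_events("recall", tr$figure_recall, 20)))

  rcfg <- rule_config()
  seqc <- make_rule_sequence(tr$rule_accuracy, tr$rules_learned, rcfg)
  evs <- lapply(seq_along(seqc), function(i)
    trial_event(i, sprintf("rule_s%d_t%d", rcfg$segment[i], i),
                response_value = if (rcfg$excluded[i]) "post_change" else "scoreable",
                correct = seqc[i], timestamp_ms = tick(700)))
  blocks[[9]] <- subtask_block("rule_finding", evs)

  tgt <- layout[layout$role == "target", , drop = FALSE]
  dis <- layout[layout$role == "distractor", , drop = FALSE]
  centre <- function(row) c((row$x0 + row$x1) / 2, (row$y0 + row$y1) / 2)
  if (tr$correct_revisits > 0 && tr$invisible_hits < 1)
    stop("infeasible: correct_revisits > 0 with no invisible hits", call. = FALSE)
  evs <- list(); idx <- 0
  tap <- function(stim, xy) {
    idx <<- idx + 1
    evs[[idx]] <<- trial_event(idx, stim, timestamp_ms = tick(600), tap_xy = xy)
  }
  for (i in seq_len2(tr$cancellation_hits)) tap("feedback_tap", centre(tgt[i, ]))
  for (i in seq_len2(tr$false_positives)) tap("feedback_tap", centre(dis[1, ]))
  for (i in seq_len2(tr$invisible_hits)) tap("no_feedback_tap", centre(tgt[i, ]))
  for (i in seq_len2(tr$correct_revisits)) tap("no_feedback_tap", centre(tgt[1, ]))
  blocks[[10]] <- subtask_block("cancellation", evs)

  session_log(tr$participant_id, tr$age, education_band = tr$education_band,
              sex = tr$sex, site = tr$site,
              session_datetime = "2026-01-01T09:00:00", blocks = blocks)
}

# seq_len that tolerates numeric input
seq_len2 <- function(n) seq_len(as.integer(n))

#' Simulate a retest cohort with target reliability
#'
#' Second-session scores are drawn from a Gaussian model around each
#' measure's observed distribution so that the expected test-retest
#' correlation approximates the target and the expected mean shift equals the
#' configured practice effect (default zero). Bounded measures are clamped to
#' their registry range and integer measures rounded, which slightly
#' attenuates the realized correlation near ceilings.
#'
#' @param cohort An `ocs_cohort` (session 1 scores).
#' @param reliability Target test-retest correlation in [0, 1): single value
#'   or named per-measure vector.
#' @param practice_shift Expected score change at session 2 (single value or
#'   named per measure). Default 0.
#' @param interval_mean,interval_sd,interval_range Between-session interval
#'   model in days (defaults: mean 320, SD 266, range 30-1182).
#' @param seed Random seed.
#' @return List: `t1` (the input cohort), `t2` (second-session cohort),
#'   `interval_days`.
#' @export
simulate_retest <- function(cohort, reliability = 0.7, practice_shift = 0,
                            interval_mean = 320, interval_sd = 266,
                            interval_range = c(30, 1182), seed = 1) {
  set.seed(seed)
  n <- nrow(cohort)
  reg <- measure_registry()
  meas <- intersect(reg$measure, names(cohort))
  t2 <- cohort
  for (m in meas) {
    rho <- if (length(reliability) > 1) reliability[[m]] else reliability
    shift <- if (length(practice_shift) > 1) practice_shift[[m]] else practice_shift
    stopifnot(rho >= 0, rho < 1)
    x <- cohort[[m]]
    mu <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) { t2[[m]] <- x + shift; next }
    z <- (x - mu) / s
    y <- mu + s * (rho * z + sqrt(1 - rho^2) * stats::rnorm(n)) + shift
    r <- registry_row(m)
    y <- pmax(y, r$min)
    if (!is.na(r$max)) y <- pmin(y, r$max)
    if (r$integer) y <- round(y)
    t2[[m]] <- y
  }
  interval <- pmin(pmax(round(rtruncnorm(n, interval_mean, interval_sd,
                                         interval_range[1], interval_range[2])),
                        interval_range[1]), interval_range[2])
  list(t1 = cohort, t2 = t2, interval_days = interval)
}

#' Simulate external-battery scores with known latent correlations
#'
#' Each external measure shares a specified latent correlation with the
#' construct underlying its mapped instrument measure (divergent mappings
#' typically 0), on an arbitrary mean-50/SD-10 scale. When the mapping
#' carries `ocs_reliability` / `external_reliability` columns, the observed
#' correlation is attenuated to `latent_r * sqrt(rel_x * rel_y)`, so
#' [attenuation_correct()] on the observed coefficient recovers `latent_r`.
#'
#' @param cohort An `ocs_cohort` providing the instrument scores.
#' @param mapping Data.frame: `ocs_measure`, `external_measure`, `family`,
#'   `latent_r`, and optionally `ocs_reliability`, `external_reliability`
#'   (default 1 = no attenuation).
#' @param seed Random seed.
#' @return Data.frame of external scores, one column per `external_measure`.
#' @export
simulate_external_battery <- function(cohort, mapping, seed = 1) {
  set.seed(seed)
  n <- nrow(cohort)
  out <- data.frame(participant_id = cohort$participant_id,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mapping))) {
    rho <- mapping$latent_r[i]
    stopifnot(abs(rho) <= 1)
    rel_x <- if ("ocs_reliability" %in% names(mapping)) mapping$ocs_reliability[i] else 1
    rel_y <- if ("external_reliability" %in% names(mapping)) mapping$external_reliability[i] else 1
    obs <- rho * sqrt(rel_x * rel_y)
    x <- cohort[[mapping$ocs_measure[i]]]
    s <- stats::sd(x, na.rm = TRUE)
    z <- if (is.finite(s) && s > 0) (x - mean(x, na.rm = TRUE)) / s else rep(0, n)
    y <- obs * z + sqrt(1 - obs^2) * stats::rnorm(n)
    out[[mapping$external_measure[i]]] <- 50 + 10 * y
  }
  out
}
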