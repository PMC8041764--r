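test_that("choice tasks count correct responses and honour skips", {
  blk <- subtask_block("semantics", lapply(1:4, function(i)
    trial_event(i, paste0("s", i), correct = c(TRUE, FALSE, TRUE, TRUE)[i],
                timestamp_ms = i)))
  expect_equal(score_choice_task(blk), 3)
  full <- subtask_block("orientation", lapply(1:4, function(i)
    trial_event(i, paste0("s", i), correct = TRUE, timestamp_ms = i)))
  expect_equal(score_choice_task(full), 4)
  skipped <- subtask_block("picture_naming", skipped = TRUE, skip_reason = "refused")
  expect_true(is.na(score_choice_task(skipped)))
  five <- subtask_block("orientation", lapply(1:5, function(i)
    trial_event(i, paste0("s", i), correct = TRUE, timestamp_ms = i)))
  expect_error(score_choice_task(five), "scored events")
})

test_that("word memory scores each attempt as a normalized target intersection", {
  expect_equal(unname(score_word_memory(word_targets(), word_targets())), c(5, 5))
  sc <- score_word_memory(c("bicycle", "mist"), word_targets())
  expect_equal(unname(sc), c(2, 5))
  # duplicates collapse; case and whitespace are normalized; intrusions ignored
  expect_equal(unname(score_word_memory(c("Bicycle ", "bicycle", "sofa"),
                                        character(0))), c(1, 0))
})

test_that("delayed recall adds recognitions only for missed words", {
  expect_equal(unname(score_delayed_recall(word_targets())), c(5, 5))
  free <- c("bicycle", "mist", "teacher")
  rec <- c(wardrobe = TRUE, rectangle = TRUE)
  expect_equal(unname(score_delayed_recall(free, rec)), c(3, 5))
  rec2 <- c(wardrobe = TRUE, rectangle = FALSE)
  expect_equal(unname(score_delayed_recall(free, rec2)), c(3, 4))
  expect_error(score_delayed_recall(free, c(bicycle = TRUE)), "freely recalled")
  expect_error(score_delayed_recall(free, c(sofa = TRUE)), "non-target")
})

test_that("trails metrics implement the switching ratio and accuracy-corrected speed", {
  perfect <- compute_trails_metrics(7, 7, 13, 15, 15)
  expect_equal(perfect$executive_score, 100)
  expect_equal(perfect$processing_speed, 30)
  # baseline 7/14 = 0.5 halves accuracy: 20 s of drawing becomes 40 s
  half <- compute_trails_metrics(4, 3, 6, 10, 10)
  expect_equal(half$processing_speed, 40)
  # zero baseline accuracy is unscorable, never infinite
  zero <- compute_trails_metrics(0, 0, 5, 10, 10)
  expect_true(zero$unscorable)
  expect_true(is.na(zero$processing_speed) && is.na(zero$executive_score))
})

test_that("processing speed is monotone in time and in (inverse) accuracy", {
  base <- compute_trails_metrics(6, 6, 10, 12, 12)$processing_speed
  slower <- compute_trails_metrics(6, 6, 10, 14, 12)$processing_speed
  sloppier <- compute_trails_metrics(5, 6, 10, 12, 12)$processing_speed
  expect_gt(slower, base)
  expect_gt(sloppier, base)
})

test_that("executive score is invariant under exchanging the baseline counts", {
  a <- compute_trails_metrics(6, 4, 9, 10, 12)$executive_score
  b <- compute_trails_metrics(4, 6, 9, 10, 12)$executive_score
  expect_equal(a, b)
})

test_that("rule finding scores accuracy out of 46 and detects consecutive-correct rules", {
  cfg <- rule_config()
  expect_equal(cfg$scoreable_trials, 46)
  all_right <- rep(TRUE, 50)
  expect_equal(unname(score_rule_finding(all_right, cfg)), c(46, 5))
  # two adjacent corrects in one segment only
  one_rule <- rep(FALSE, 50)
  one_rule[14:15] <- TRUE   # segment 2, scoreable positions
  expect_equal(unname(score_rule_finding(one_rule, cfg)), c(2, 1))
  # corrects only on post-change trials score nothing
  post_only <- rep(FALSE, 50)
  post_only[which(cfg$excluded)] <- TRUE
  expect_equal(unname(score_rule_finding(post_only, cfg)), c(0, 0))
  # a run spanning an excluded trial still counts: the exclusion breaks no run
  span <- rep(FALSE, 50)
  span[12] <- TRUE          # second scoreable trial of segment 2 is trial 12
  span[11] <- TRUE          # trial 11 is the excluded post-change trial
  span[13] <- TRUE
  expect_equal(unname(score_rule_finding(span, cfg)), c(2, 1))
  expect_error(score_rule_finding(rep(TRUE, 49), cfg), "expected 50")
})

test_that("rule detection matches the brute-force run-enumeration oracle", {
  cfg <- rule_config()
  set.seed(42)
  for (i in 1:1000) {
    correct <- runif(50) < runif(1, 0.1, 0.9)
    got <- score_rule_finding(correct, cfg)
    expect_identical(unname(got["rules_learned"]),
                     as.integer(oracle_rules_learned(correct, cfg)))
    expect_identical(unname(got["rule_accuracy"]),
                     as.integer(sum(correct[!cfg$excluded])))
  }
})

test_that("figure scoring sums 20 three-point elements", {
  el <- data.frame(element_id = 1:20, presence = 1, position = 1, accuracy = 1)
  expect_equal(score_figure(el), 60)
  el2 <- transform(el, accuracy = 0)
  expect_equal(score_figure(el2), 40)
  el3 <- transform(el, presence = 0, position = 0, accuracy = 0)
  expect_equal(score_figure(el3), 0)
  expect_error(score_figure(el[-1, ]), "20 elements")
  dup <- el; dup$element_id[2] <- 1
  expect_error(score_figure(dup), "20 elements")
})

test_that("cancellation replays tap streams against the layout", {
  layout <- default_cancellation_layout()
  tgt <- layout[layout$role == "target", ]
  dis <- layout[layout$role == "distractor", ]
  ctr <- function(r) c((r$x0 + r$x1) / 2, (r$y0 + r$y1) / 2)
  mk <- function(taps, stim) {
    subtask_block("cancellation", lapply(seq_along(taps), function(i)
      trial_event(i, stim, timestamp_ms = i, tap_xy = taps[[i]])))
  }
  # all 30 targets once: full hits, no errors
  taps <- lapply(seq_len(30), function(i) ctr(tgt[i, ]))
  blk <- mk(taps, "feedback_tap")
  expect_equal(unname(score_cancellation(blk, layout, "feedback")), c(30, 0))
  # one distractor tap in the feedback condition = one false positive
  blk2 <- mk(c(taps[1:3], list(ctr(dis[1, ]))), "feedback_tap")
  expect_equal(unname(score_cancellation(blk2, layout, "feedback")), c(3, 1))
  # same target three times in the no-feedback condition: one hit, two revisits
  blk3 <- mk(rep(list(ctr(tgt[5, ])), 3), "no_feedback_tap")
  expect_equal(unname(score_cancellation(blk3, layout, "no_feedback")), c(1, 2))
  # taps outside every box are ignored
  blk4 <- mk(list(c(-50, -50), ctr(tgt[1, ])), "no_feedback_tap")
  expect_equal(unname(score_cancellation(blk4, layout, "no_feedback")), c(1, 0))
  # distractor reselection in no-feedback condition scores nothing
  blk5 <- mk(rep(list(ctr(dis[2, ])), 2), "no_feedback_tap")
  expect_equal(unname(score_cancellation(blk5, layout, "no_feedback")), c(0, 0))
})

test_that("scored measures stay within registry ranges on arbitrary simulated sessions", {
  sim <- simulate_cohort(default_generator_config(40), seed = 99)
  reg <- measure_registry()
  for (i in seq_len(10)) {
    sc <- score_session(simulate_session(sim$truth[i, ], seed = 100 + i))
    for (k in seq_len(nrow(reg))) {
      v <- sc[[reg$measure[k]]]
      if (is.na(v)) next
      expect_gte(v, reg$min[k])
      if (!is.na(reg$max[k])) expect_lte(v, reg$max[k])
    }
    # recognition total never below free recall, surplus bounded by misses
    expect_gte(sc$delayed_recall_recognition, sc$delayed_recall)
    expect_lte(sc$delayed_recall_recognition - sc$delayed_recall,
               5 - sc$delayed_recall)
  }
})

test_that("a session missing the figure block scores everything else", {
  sim <- simulate_cohort(default_generator_config(2), seed = 3)
  log <- simulate_session(sim$truth[1, ], seed = 5)
  log$blocks[[8]] <- subtask_block("figure", skipped = TRUE,
                                  skip_reason = "drawing not administered")
  sc <- score_session(log)
  expect_true(is.na(sc$figure_copy) && is.na(sc$figure_recall))
  expect_false(anyNA(sc[c("picture_naming", "rule_accuracy", "processing_speed",
                          "cancellation_hits")]))
  expect_match(attr(sc, "not_assessed")[["figure_copy"]], "not administered")
})
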