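test_that("split-half reliability hits the fixed points: parallel halves and noise", {
  set.seed(5)
  # fully duplicated items: the two half-scores are equal under every split
  col <- rbinom(50, 1, 0.6)
  dup <- matrix(rep(col, 8), 50, 8)
  r <- split_half_reliability(dup, n_iter = 200, seed = 1)
  expect_equal(r$estimate, 1)
  expect_true(r$interpretable)
  # independent coin flips: no internal consistency
  noise <- matrix(rbinom(500 * 20, 1, 0.5), 500, 20)
  r0 <- split_half_reliability(noise, n_iter = 500, seed = 2)
  expect_lt(abs(r0$estimate), 0.1)
  # ceiling responses on a 4-item task: splits are degenerate, flagged
  ceiling <- matrix(1, 12, 4); ceiling[1, 1] <- 0
  rc <- split_half_reliability(ceiling, n_iter = 100, seed = 3)
  expect_false(rc$interpretable)
  expect_match(rc$reason, "degenerate")
})

test_that("split-half estimates are seed-reproducible and item-order invariant", {
  set.seed(8)
  m <- matrix(rbinom(80 * 10, 1, 0.5) + rep(rbinom(80, 1, 0.5), 10), 80, 10)
  a <- split_half_reliability(m, n_iter = 300, seed = 42)
  b <- split_half_reliability(m, n_iter = 300, seed = 42)
  expect_identical(a$estimate, b$estimate)
  perm <- split_half_reliability(m[, sample(10)], n_iter = 300, seed = 43)
  expect_lt(abs(perm$estimate - a$estimate), diff(a$ci))
  expect_true(a$ci[1] <= a$estimate && a$estimate <= a$ci[2])
})

test_that("attenuation correction rescales by the reliability geometric mean", {
  expect_equal(attenuation_correct(0.5, 1, 1)$corrected, 0.5)
  ac <- attenuation_correct(0.3, 0.36, 0.25)
  expect_equal(ac$corrected, 1.0)
  expect_false(ac$exceeds_unity)
  ac2 <- attenuation_correct(0.5, 0.1, 0.1)
  expect_equal(ac2$corrected, 5.0)
  expect_true(ac2$exceeds_unity)   # never clamped
  expect_error(attenuation_correct(0.5, 0, 1), "> 0")
  # corrected magnitude never below the raw magnitude for reliabilities <= 1
  set.seed(9)
  for (i in 1:50) {
    cc <- runif(1, -1, 1); rx <- runif(1, 0.2, 1); ry <- runif(1, 0.2, 1)
    expect_gte(abs(attenuation_correct(cc, rx, ry)$corrected), abs(cc))
  }
})

test_that("reliable change index is zero at no change and antisymmetric", {
  expect_equal(reliable_change_index(8, 8, 2, 0.5), 0)
  expect_equal(reliable_change_index(8, 10, 2, 0.5), 1.0)
  set.seed(10)
  for (i in 1:20) {
    x1 <- rnorm(1, 50, 10); x2 <- rnorm(1, 50, 10)
    s <- runif(1, 1, 5); r <- runif(1, 0, 0.95)
    expect_equal(reliable_change_index(x1, x2, s, r),
                 -reliable_change_index(x2, x1, s, r))
  }
  expect_error(reliable_change_index(1, 2, 2, 1), "r_xx")
  expect_error(reliable_change_index(1, 2, 0, 0.5), "sd_baseline")
})

test_that("signed-rank p-values match exhaustive sign-permutation enumeration", {
  set.seed(11)
  for (i in 1:15) {
    n <- sample(6:10, 1)
    t1 <- rnorm(n, 50, 8)
    t2 <- t1 + rnorm(n, 0.5, 2)
    res <- paired_retest(t1, t2)
    expect_equal(res$p, oracle_signed_rank_p(t2 - t1), tolerance = 1e-12)
  }
})

test_that("paired retest handles ties, families and reports RCIs", {
  x <- c(10, 12, 9, 14, 11, 13, 10, 12)
  same <- paired_retest(x, x)
  expect_equal(same$effect_size, 0)
  expect_false(same$significant_raw)
  expect_match(same$note, "no change")
  expect_true(all(same$rci == 0))
  # Bonferroni threshold for a 15-measure family
  fam <- paired_retest(x, x + c(1, -1, 2, 0, 1, -2, 1, 0), family_size = 15)
  expect_equal(fam$alpha_corrected, 0.05 / 15)
  expect_equal(round(fam$alpha_corrected, 4), 0.0033)
  expect_equal(length(fam$rci), 8)
  # a genuine shift is detected
  set.seed(12)
  t1 <- rnorm(100, 50, 5)
  shifted <- paired_retest(t1, t1 + rnorm(100, 3, 1), family_size = 15)
  expect_lt(shifted$p, shifted$alpha_corrected)
  expect_gt(shifted$effect_size, 0.5)
})

test_that("Mann-Whitney agrees with brute-force pair counting and enumeration", {
  set.seed(13)
  for (i in 1:10) {
    a <- sample(1:30, 6, replace = TRUE)
    b <- sample(1:30, 6, replace = TRUE)
    res <- compare_cohorts(data.frame(rule_accuracy = a),
                           data.frame(rule_accuracy = b))
    expect_equal(res$U, oracle_mann_whitney_u(a, b))
  }
  # exact p for untied small samples via complete group-relabelling
  a <- c(12, 15, 18, 21, 30, 7)
  b <- c(11, 13, 25, 26, 28, 5)
  res <- compare_cohorts(data.frame(rule_accuracy = a),
                         data.frame(rule_accuracy = b))
  pool <- c(a, b)
  combos <- combn(12, 6)
  udist <- apply(combos, 2, function(ix) oracle_mann_whitney_u(pool[ix], pool[-ix]))
  u <- oracle_mann_whitney_u(a, b)
  p_exact <- mean(abs(udist - 18) >= abs(u - 18))  # 18 = nA*nB/2
  expect_equal(res$p, p_exact, tolerance = 1e-12)
  # identical groups: U at its null centre, not significant
  res2 <- compare_cohorts(data.frame(x = c(1, 2, 3, 4)),
                          data.frame(x = c(1, 2, 3, 4)), measures = "x")
  expect_equal(res2$U, 8)
  expect_false(res2$significant_corrected)
})

test_that("cohort comparison detects a 1-SD location shift after correction", {
  set.seed(14)
  hits <- 0
  for (i in 1:40) {
    a <- data.frame(figure_recall = pmin(60, rnorm(80, 44, 10)))
    b <- data.frame(figure_recall = pmin(60, rnorm(80, 34, 10)))
    res <- compare_cohorts(a, b, family_size = 18)
    hits <- hits + res$significant_corrected
  }
  expect_gte(hits / 40, 0.95)
})

test_that("Kendall tau matches the O(n^2) concordance oracle and its invariances", {
  set.seed(15)
  for (i in 1:30) {
    n <- 10
    x <- sample(1:6, n, replace = TRUE)   # ties on purpose
    y <- sample(1:6, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    tau <- suppressWarnings(cor.test(x, y, method = "kendall"))$estimate
    expect_equal(unname(tau), oracle_tau_b(x, y), tolerance = 1e-12)
    expect_lte(abs(tau), 1)
    rev_tau <- suppressWarnings(cor(x, -y, method = "kendall"))
    expect_equal(unname(rev_tau), -oracle_tau_b(x, y), tolerance = 1e-12)
  }
})

test_that("validity tables carry family-wise thresholds and attenuation metadata", {
  set.seed(16)
  n <- 120
  ocs <- data.frame(rule_accuracy = round(rnorm(n, 27, 8)),
                    processing_speed = rnorm(n, 34, 15))
  ext <- data.frame(tmt_a = 0.6 * scale(ocs$processing_speed)[, 1] + 0.8 * rnorm(n),
                    mood = rnorm(n))
  mapping <- data.frame(
    ocs_measure = c("processing_speed", rep("rule_accuracy", 2)),
    external_measure = c("tmt_a", "mood", "tmt_a"),
    family = c("convergent", "divergent", "divergent"),
    external_reliability = c(1, 0.86, 1), stringsAsFactors = FALSE)
  rel <- c(processing_speed = 1, rule_accuracy = 1)
  vt <- validity_table(ocs, ext, mapping, rel)
  expect_equal(vt$alpha_threshold[vt$family == "convergent"], 0.05 / 1)
  expect_equal(unique(vt$alpha_threshold[vt$family == "divergent"]), 0.05 / 2)
  expect_true(vt$acceptable[vt$external_measure == "tmt_a" &
                            vt$family == "convergent"])
  expect_equal(vt$corrected_r, vt$tau / sqrt(rel[vt$ocs_measure] *
                                             mapping$external_reliability),
               ignore_attr = TRUE)
  # perfectly monotone pair
  mono <- validity_table(data.frame(rule_accuracy = 1:10),
                         data.frame(ext = (1:10)^2),
                         data.frame(ocs_measure = "rule_accuracy",
                                    external_measure = "ext",
                                    family = "convergent",
                                    external_reliability = 1),
                         c(rule_accuracy = 1))
  expect_equal(mono$tau, 1)
  # fewer than 3 complete pairs: row reported with missing statistics
  tiny <- validity_table(data.frame(rule_accuracy = c(1, 2, NA)),
                         data.frame(ext = c(1, NA, 3)),
                         data.frame(ocs_measure = "rule_accuracy",
                                    external_measure = "ext",
                                    family = "convergent",
                                    external_reliability = 1),
                         c(rule_accuracy = 1))
  expect_true(is.na(tiny$tau))
  expect_equal(tiny$n, 1)
})
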