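# Fixture builders used across the suite. Everything is generated in code;
# no data files.

# a ground-truth row at the ceiling of every measure
ceiling_truth <- function() {
  data.frame(
    participant_id = "ceiling", age = 50, education_band = "higher",
    sex = "female", site = "UK",
    picture_naming = 4, semantics = 4, orientation = 4,
    encoding1 = 5, encoding2 = 5,
    delayed_recall = 5, delayed_recall_recognition = 5, recognized = 0,
    episodic_recognition = 4,
    trails_circle = 7, trails_square = 7, trails_switch_correct = 13,
    circle_ms = 15000, square_ms = 15000,
    executive_score = 100, processing_speed = 30,
    rule_accuracy = 46, rules_learned = 5,
    figure_copy = 60, figure_recall = 60,
    cancellation_hits = 30, false_positives = 0,
    invisible_hits = 30, correct_revisits = 0,
    stringsAsFactors = FALSE
  )
}

# small valid session, trivially constructed (not via the simulator)
tiny_session <- function(pid = "p1", age = 64) {
  blocks <- list(
    subtask_block("picture_naming", lapply(1:4, function(i)
      trial_event(i, paste0("item", i), correct = i <= 3, timestamp_ms = i * 1000)))
  )
  session_log(pid, age, blocks = blocks)
}

# brute-force oracle: rules learned by enumerating runs per segment over the
# scoreable (non-excluded) trials only
oracle_rules_learned <- function(correct, cfg = rule_config()) {
  learned <- 0L
  for (g in seq_len(cfg$n_rules)) {
    keep <- cfg$segment == g & !cfg$excluded
    v <- correct[keep]
    if (!length(v)) next
    r <- rle(v)
    if (any(r$values & r$lengths >= cfg$consecutive_needed)) learned <- learned + 1L
  }
  learned
}

# O(n^2) Kendall tau-b oracle with tie handling
oracle_tau_b <- function(x, y) {
  n <- length(x)
  nc <- nd <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) nc <- nc + 1
    else nd <- nd + 1
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

# exhaustive signed-rank two-sided p-value for untied differences
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  wdist <- as.matrix(signs) %*% r
  p <- 2 * min(mean(wdist <= w_obs), mean(wdist >= w_obs))
  min(1, p)
}

# brute-force Mann-Whitney U (count of concordant pairs + half ties)
oracle_mann_whitney_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# independent type-7 empirical quantile (sort-and-interpolate)
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}
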