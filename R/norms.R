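# Normative cut-offs, age stratification, impairment classification and
# domain summative scores.
#
# Wide-range measures use a z-based rule: impaired beyond 1.65 SD from the
# control mean in the direction of impairment (a one-tailed 5% design under
# normality). Restricted-range measures use the empirical 5th centile (95th
# for error counts), with a conservative floor of one for error counts and
# rules learned when the centile reaches the degenerate end of the scale.

AGE_BANDS <- c("<60", "60-70", ">70")

#' Assign an age band
#'
#' Normative strata are below 60, 60-70, and above 70 years. The published
#' band headers leave ages exactly 60 and 70 ambiguous; this package assigns
#' the closed interval [60, 70] to the middle band (configurable via
#' `boundaries`).
#'
#' @param age Age(s) in years, > 0.
#' @param boundaries Length-2 numeric, default `c(60, 70)`.
#' @return Character vector over `"<60"`, `"60-70"`, `">70"`.
#' @export
#' @examples
#' assign_age_band(c(45, 60, 70, 75))
assign_age_band <- function(age, boundaries = c(60, 70)) {
  stopifnot(all(age > 0))
  ifelse(age < boundaries[1], AGE_BANDS[1],
         ifelse(age <= boundaries[2], AGE_BANDS[2], AGE_BANDS[3]))
}

#' Derive an impairment cut-off from a normative sample
#'
#' @param values Numeric sample (non-missing values of one measure in one
#'   stratum).
#' @param method `"z"` (mean +/- 1.65 SD, rounded half-up to 2 dp) or
#'   `"centile"` (empirical 5th/95th percentile, type-7 linear interpolation).
#' @param direction `"low_bad"` (impairment = low scores; z uses mean - 1.65
#'   SD, centile uses the 5th) or `"high_bad"` (processing speed, error
#'   counts; mean + 1.65 SD or the 95th centile).
#' @param conservative_floor For count measures: when the centile cut-off
#'   reaches the degenerate end of the scale (<= 0 errors, or <= 0 for a
#'   low-bad count), raise it to one with an inclusive comparison, so that a
#'   single error (or a score of at most one) is flagged.
#' @param multiplier z multiplier, default 1.65.
#' @param round_centile Round centile cut-offs to the nearest whole number
#'   (as the published per-age-band tables do). Default `TRUE`.
#' @return List of class `ocs_cutoff`: `value`, `operator` (one of `"<"`,
#'   `">"`, `"<="`, `">="`; a score satisfying `score <operator> value` is
#'   impaired), `method`, `n`.
#' @export
#' @examples
#' # z rule on a published mean/SD pair
#' derive_cutoff_zstats(26.74, 8.20, "low_bad")   # 13.21
derive_cutoff <- function(values, method = c("z", "centile"),
                          direction = c("low_bad", "high_bad"),
                          conservative_floor = FALSE, multiplier = 1.65,
                          round_centile = TRUE) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty sample", call. = FALSE)
  if (method == "z") {
    s <- stats::sd(values)
    if (!is.finite(s) || s == 0)
      stop("zero variance: z-based cut-off undefined; use the centile method",
           call. = FALSE)
    return(cutoff_from_zstats(mean(values), s, direction, multiplier,
                              n = length(values)))
  }
  p <- if (direction == "low_bad") 0.05 else 0.95
  q <- unname(stats::quantile(values, p, type = 7))
  if (round_centile) q <- round_half_up(q, 0)
  op <- if (direction == "low_bad") "<" else ">"
  if (conservative_floor) {
    if (direction == "high_bad" && q <= 0) { q <- 1; op <- ">=" }
    if (direction == "low_bad" && q <= 0) { q <- 1; op <- "<=" }
  }
  structure(list(value = q, operator = op, method = "centile",
                 n = length(values)), class = "ocs_cutoff")
}

cutoff_from_zstats <- function(mean, sd, direction, multiplier = 1.65, n = NA_integer_) {
  if (direction == "low_bad") {
    structure(list(value = round_half_up(mean - multiplier * sd, 2),
                   operator = "<", method = "z", n = n), class = "ocs_cutoff")
  } else {
    structure(list(value = round_half_up(mean + multiplier * sd, 2),
                   operator = ">", method = "z", n = n), class = "ocs_cutoff")
  }
}

#' z cut-off directly from summary statistics
#'
#' Convenience wrapper reproducing published cut-offs from printed means and
#' SDs: `mean - 1.65*sd` (low_bad) or `mean + 1.65*sd` (high_bad), rounded
#' half-up to two decimals.
#'
#' @param mean,sd Summary statistics of the normative sample.
#' @param direction `"low_bad"` or `"high_bad"`.
#' @param multiplier z multiplier, default 1.65.
#' @return Numeric cut-off value.
#' @export
derive_cutoff_zstats <- function(mean, sd, direction = c("low_bad", "high_bad"),
                                 multiplier = 1.65) {
  direction <- match.arg(direction)
  cutoff_from_zstats(mean, sd, direction, multiplier)$value
}

#' Build an age-stratified normative table from a cohort
#'
#' One row per (measure, age band) plus a pooled `"all"` stratum: N of
#' non-missing scores, mean, SD, median, min, max, and the derived cut-off.
#' The cut-off method comes from the measure registry (z for the wide-range
#' trails/rule-finding/figure/cancellation accuracies, centile for
#' restricted-range measures and error counts). Measures flagged `uk_only`
#' in the registry are normed on the UK subset when the cohort has a `site`
#' column (mirroring the published decision to norm figure copy on the larger
#' UK sample after a cohort difference); this is a per-measure stratification
#' filter, not nationality logic.
#'
#' @param cohort An `ocs_cohort` (see [read_cohort()] / [as_cohort()]).
#' @param by_band Also stratify by age band (requires an `age` column).
#' @param min_n Warn when a stratum has fewer observations than this.
#' @param uk_only Apply the registry's `uk_only` filters (default `TRUE`).
#' @param domains Also norm the six domain summative scores (centile method),
#'   computed row-wise from the cohort's measures. Default `FALSE`.
#' @return Data.frame of class `ocs_normtable` with columns `measure`,
#'   `age_band`, `n`, `mean`, `sd`, `median`, `min`, `max`, `method`,
#'   `cutoff_value`, `cutoff_operator`.
#' @export
build_normative_table <- function(cohort, by_band = TRUE, min_n = 20,
                                  uk_only = TRUE, domains = FALSE) {
  reg <- measure_registry()
  meas <- intersect(reg$measure, names(cohort))
  meas <- meas[vapply(meas, function(m) registry_row(m)$method != "none", logical(1))]
  bands <- "all"
  if (by_band) {
    if (!"age" %in% names(cohort)) stop("cohort needs an age column", call. = FALSE)
    bands <- c(AGE_BANDS, "all")
    band_of <- assign_age_band(cohort$age)
  }
  rows <- list()
  add_rows <- function(name, v_all, band_all, method, direction, floor_) {
    for (b in bands) {
      v <- if (b == "all") v_all else v_all[band_all == b]
      v <- v[!is.na(v)]
      if (!length(v)) {
        warning("measure '", name, "', band '", b, "': no data; stratum omitted")
        next
      }
      if (length(v) < min_n)
        warning("measure '", name, "', band '", b, "': n = ", length(v),
                " below min_n = ", min_n)
      co <- tryCatch(
        derive_cutoff(v, method = method, direction = direction,
                      conservative_floor = floor_),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <<- data.frame(
        measure = name, age_band = b, n = length(v),
        mean = mean(v), sd = stats::sd(v), median = stats::median(v),
        min = min(v), max = max(v),
        method = if (is.null(co)) NA_character_ else co$method,
        cutoff_value = if (is.null(co)) NA_real_ else co$value,
        cutoff_operator = if (is.null(co)) NA_character_ else co$operator,
        stringsAsFactors = FALSE)
    }
  }
  for (m in meas) {
    r <- registry_row(m)
    keep <- rep(TRUE, nrow(cohort))
    if (uk_only && r$uk_only && "site" %in% names(cohort))
      keep <- !is.na(cohort$site) & cohort$site == "UK"
    v_all <- ifelse(keep, cohort[[m]], NA)
    add_rows(m, v_all, if (by_band) band_of else NULL, r$method, r$direction, r$conservative_floor)
  }
  if (domains) {
    dom <- cohort_domain_scores(cohort)
    for (d in names(domain_registry()))
      add_rows(d, dom[[d]], if (by_band) band_of else NULL, "centile", "low_bad", FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ocs_normtable", class(out))
  out
}

#' Serialize / read a normative table
#'
#' CSV mirrors the published normative-table column layout; JSON keeps full
#' metadata.
#' @param table An `ocs_normtable`.
#' @param path Output path (`.csv` or `.json` chosen by extension).
#' @return `path`, invisibly.
#' @export
write_normtable <- function(table, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(schema_version = "1.0", rows = table), path,
                         auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  } else {
    utils::write.csv(table, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_normtable
#' @export
read_normtable <- function(path) {
  tb <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::fromJSON(path)$rows, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  class(tb) <- c("ocs_normtable", class(tb))
  tb
}

apply_cutoff <- function(score, value, operator) {
  impaired <- switch(operator,
    "<" = score < value, "<=" = score <= value,
    ">" = score > value, ">=" = score >= value,
    stop("unknown cut-off operator '", operator, "'", call. = FALSE))
  if (impaired) "impaired" else "within_norms"
}

#' Classify a score vector against a normative table
#'
#' Every registered measure receives exactly one classification: `impaired`,
#' `within_norms`, or `not_assessed`. Impairment is `score < cutoff` for
#' low-bad measures and `score > cutoff` (or `>= 1` under the conservative
#' floor) for high-bad measures, using the rounded stored cut-off. Measures
#' absent from the table are classified `not_assessed` with a warning, never
#' silently.
#'
#' @param scores An `ocs_scores` row (from [score_session()]) or a named
#'   one-row data.frame / named numeric vector of measures.
#' @param age Participant age in years (used to pick the band).
#' @param table An `ocs_normtable`.
#' @param band Override the age band (e.g. `"all"` to use pooled norms).
#' @return Data.frame of class `ocs_profile`: `measure`, `score`, `age_band`,
#'   `cutoff_value`, `cutoff_operator`, `classification`; attributes
#'   `not_assessed` reasons and `condition_flags` carried over from scoring,
#'   and `domains` (see [compute_domain_scores()]).
#' @export
classify_scores <- function(scores, age, table, band = NULL) {
  reg <- measure_registry()
  normed <- reg$measure[reg$method != "none"]
  if (is.null(band)) band <- assign_age_band(age)
  sc <- if (is.data.frame(scores)) as.list(scores[1, , drop = FALSE]) else as.list(scores)
  reasons <- attr(scores, "not_assessed") %||% character()
  rows <- lapply(normed, function(m) {
    val <- if (!is.null(sc[[m]])) as.numeric(sc[[m]]) else NA_real_
    row <- table[table$measure == m & table$age_band == band, , drop = FALSE]
    if (!nrow(row)) row <- table[table$measure == m & table$age_band == "all", , drop = FALSE]
    if (is.na(val)) {
      cls <- "not_assessed"
      cv <- NA_real_; op <- NA_character_
    } else if (!nrow(row) || is.na(row$cutoff_value[1])) {
      warning("measure '", m, "': no normative row for band '", band,
              "'; classified not_assessed")
      cls <- "not_assessed"; cv <- NA_real_; op <- NA_character_
    } else {
      cv <- row$cutoff_value[1]; op <- row$cutoff_operator[1]
      cls <- apply_cutoff(val, cv, op)
    }
    data.frame(measure = m, score = val, age_band = band,
               cutoff_value = cv, cutoff_operator = op,
               classification = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  doms <- compute_domain_scores(scores)
  # classify domains where the table carries domain norms
  doms$classification <- vapply(seq_len(nrow(doms)), function(i) {
    if (is.na(doms$score[i])) return("not_assessed")
    row <- table[table$measure == doms$domain[i] & table$age_band == band, , drop = FALSE]
    if (!nrow(row)) row <- table[table$measure == doms$domain[i] & table$age_band == "all", , drop = FALSE]
    if (!nrow(row) || is.na(row$cutoff_value[1])) return("no_norms")
    apply_cutoff(doms$score[i], row$cutoff_value[1], row$cutoff_operator[1])
  }, character(1))
  attr(out, "domains") <- doms
  attr(out, "not_assessed") <- reasons
  attr(out, "condition_flags") <- attr(scores, "condition_flags") %||% character()
  attr(out, "participant_id") <- sc$participant_id %||% NA_character_
  class(out) <- c("ocs_profile", class(out))
  out
}

#' Cognitive domain summative scores
#'
#' Six theory-driven domain sums: delayed memory = delayed recall + recall-
#' and-recognition; attention = visible + invisible cancellation hits; memory
#' encoding = encoding 1 + 2; naming/semantics = picture naming + semantics;
#' praxis = figure copy + recall; executive function = rule accuracy + rules
#' learned + executive score - false positives (a declared default; the
#' weights are configurable). A domain is `NA` (not assessed) unless all its
#' constituents are assessed.
#'
#' @param scores Named measures (as in [classify_scores()]).
#' @param weights Optional named list overriding per-domain weights, e.g.
#'   `list(executive_function = c(1, 1, 1, -1))`.
#' @return Data.frame: `domain`, `score`.
#' @export
compute_domain_scores <- function(scores, weights = NULL) {
  sc <- if (is.data.frame(scores)) as.list(scores[1, , drop = FALSE]) else as.list(scores)
  dreg <- domain_registry()
  rows <- lapply(names(dreg), function(d) {
    def <- dreg[[d]]
    w <- if (!is.null(weights[[d]])) weights[[d]] else def$weights
    vals <- vapply(def$measures, function(m)
      if (!is.null(sc[[m]])) as.numeric(sc[[m]]) else NA_real_, numeric(1))
    data.frame(domain = d,
               score = if (anyNA(vals)) NA_real_ else sum(w * vals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# row-wise domain scores for a whole cohort table
cohort_domain_scores <- function(cohort) {
  dreg <- domain_registry()
  out <- data.frame(row.names = seq_len(nrow(cohort)))
  for (d in names(dreg)) {
    def <- dreg[[d]]
    if (!all(def$measures %in% names(cohort))) { out[[d]] <- NA_real_; next }
    mat <- as.matrix(cohort[, def$measures, drop = FALSE])
    out[[d]] <- as.numeric(mat %*% def$weights)
    out[[d]][apply(mat, 1, anyNA)] <- NA_real_
  }
  out
}
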