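# Discrimination and threshold statistics for comparing early warning
# scores: rank-based AUROC, a one-observation-per-encounter bootstrap,
# DeLong's paired test, NEWS-anchored threshold matching, observation-level
# test-characteristic tables, precision-recall and encounter-level
# efficiency curves, and trigger-to-event lead times.

risk_direction <- function(values, polarity) {
  if (identical(polarity, "low_is_risk")) -as.numeric(values) else as.numeric(values)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, ties counting one half.
#' Low-is-risk scores are rank-reversed before computation so the result is
#' always the probability that the riskier-looking observation is the one
#' that deteriorates.
#'
#' @param labels Binary 0/1 vector.
#' @param values Numeric score values.
#' @param polarity `"high_is_risk"` or `"low_is_risk"`.
#' @return AUROC in \[0, 1\].
#' @export
roc_auc <- function(labels, values, polarity = "high_is_risk") {
  keep <- !is.na(values) & !is.na(labels)
  labels <- labels[keep]; values <- risk_direction(values[keep], polarity)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("roc_auc undefined: need at least one positive and one negative label")
  }
  r <- rank(values, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# One labeled grid row per encounter, drawn uniformly. Rows must be sorted
# so each encounter's rows are contiguous (grid_to_wide guarantees this).
make_row_groups <- function(encounter_ids) {
  r <- rle(as.character(encounter_ids))
  lens <- r$lengths
  list(starts = cumsum(c(1L, lens[-length(lens)])), lens = lens)
}

sample_one_per_encounter <- function(groups) {
  off <- pmin(floor(runif(length(groups$lens)) * groups$lens),
              groups$lens - 1L)
  groups$starts + as.integer(off)
}

#' Bootstrapped AUROC, one observation per encounter
#'
#' Each iteration draws exactly one aligned grid row per encounter
#' (uniformly over that encounter's rows) and computes every score's AUROC
#' on the identical draw, so cross-score comparisons are paired. The point
#' estimate is the mean over iterations and the CI the 2.5/97.5 percentiles
#' of the per-iteration values. Iterations whose draw contains a single
#' outcome class are redrawn (at most 10 attempts each).
#'
#' @param labeled Labeled long tibble from [label_grid()] (all scores share
#'   the same `(encounter_id, time)` grid).
#' @param config [evaluation_config()]; uses `n_bootstrap` and
#'   `random_seed`.
#' @param polarity Named polarity vector.
#' @return Tibble: one row per score with `auc`, `ci_low`, `ci_high`,
#'   `n_iterations`, plus attribute `per_iteration` (matrix B x scores).
#' @export
bootstrap_auc <- function(labeled, config = evaluation_config(),
                          polarity = default_polarity()) {
  wide <- grid_to_wide(labeled)
  scores <- setdiff(names(wide), c("encounter_id", "time", "label"))
  groups <- make_row_groups(wide$encounter_id)
  B <- config$n_bootstrap
  per_iter <- matrix(NA_real_, nrow = B, ncol = length(scores),
                     dimnames = list(NULL, scores))
  set.seed(config$random_seed)
  redraws <- 0L
  for (b in seq_len(B)) {
    for (attempt in seq_len(10L)) {
      ix <- sample_one_per_encounter(groups)
      lab <- wide$label[ix]
      if (length(unique(lab)) > 1L) break
      redraws <- redraws + 1L
      if (attempt == 10L) stop("bootstrap aborted: 10 single-class draws in a row")
    }
    for (s in scores) {
      v <- wide[[s]][ix]
      ok <- !is.na(v)
      if (sum(lab[ok] == 1) > 0 && sum(lab[ok] == 0) > 0) {
        per_iter[b, s] <- roc_auc(lab[ok], v[ok], polarity[[s]])
      }
    }
  }
  res <- tibble::tibble(
    score_name = scores,
    auc = unname(colMeans(per_iter, na.rm = TRUE)),
    ci_low = unname(apply(per_iter, 2, quantile, probs = 0.025, na.rm = TRUE)),
    ci_high = unname(apply(per_iter, 2, quantile, probs = 0.975, na.rm = TRUE)),
    n_iterations = B
  )
  structure(res, per_iteration = per_iter, n_redraws = redraws)
}

grid_to_wide <- function(labeled) {
  dt <- data.table::as.data.table(
    labeled[, c("encounter_id", "time", "score_name", "value", "label")])
  wide <- data.table::dcast(dt, encounter_id + time + label ~ score_name,
                            value.var = "value")
  tibble::as_tibble(wide)
}

#' DeLong test for two correlated AUROCs
#'
#' Structural-components estimate of the covariance of the two empirical
#' AUCs computed on the same rows, z statistic and two-sided normal p.
#'
#' @param labels Binary outcome labels.
#' @param values_a,values_b Paired score values on identical rows.
#' @param polarity_a,polarity_b Polarities of the two scores.
#' @return List: `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_compare <- function(labels, values_a, values_b,
                           polarity_a = "high_is_risk",
                           polarity_b = "high_is_risk") {
  keep <- !is.na(values_a) & !is.na(values_b) & !is.na(labels)
  labels <- labels[keep]
  va <- risk_direction(values_a[keep], polarity_a)
  vb <- risk_direction(values_b[keep], polarity_b)
  pos <- labels == 1
  m <- sum(pos); n <- sum(!pos)
  if (m < 2 || n < 2) {
    stop("delong_compare: need at least two observations in each outcome class")
  }
  comp <- function(v) {
    x <- v[pos]; y <- v[!pos]
    rx <- rank(c(x, y), ties.method = "average")
    r_x <- rx[seq_len(m)]; r_y <- rx[m + seq_len(n)]
    # V10_i = P(Y < x_i) + .5 P(Y = x_i); from joint ranks minus within-group ranks
    v10 <- (r_x - rank(x, ties.method = "average")) / n
    v01 <- 1 - (r_y - rank(y, ties.method = "average")) / m
    list(theta = mean(v10), v10 = v10, v01 = v01)
  }
  ca <- comp(va); cb <- comp(vb)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$theta - cb$theta
  z <- if (var_diff <= .Machine$double.eps) 0 else d / sqrt(var_diff)
  list(auc_a = ca$theta, auc_b = cb$theta, z = z,
       p = if (z == 0 && d == 0) 1 else 2 * pnorm(-abs(z)))
}

#' Paired DeLong comparison inside the bootstrap
#'
#' Runs [delong_compare()] within each one-per-encounter bootstrap draw
#' (scores share the draw) and summarises the p value as the median across
#' iterations; `mode = "single_sample"` instead draws once.
#'
#' @inheritParams bootstrap_auc
#' @param score_a,score_b Score names present in `labeled`.
#' @param mode `"bootstrap_median"` or `"single_sample"`.
#' @return List: `auc_a`, `auc_b` (means across iterations), `z` (median),
#'   `p` (median).
#' @export
bootstrap_delong <- function(labeled, score_a, score_b,
                             config = evaluation_config(),
                             polarity = default_polarity(),
                             mode = c("bootstrap_median", "single_sample")) {
  mode <- match.arg(mode)
  wide <- grid_to_wide(labeled)
  groups <- make_row_groups(wide$encounter_id)
  B <- if (mode == "single_sample") 1L else config$n_bootstrap
  set.seed(config$random_seed)
  out <- matrix(NA_real_, nrow = B, ncol = 4,
                dimnames = list(NULL, c("auc_a", "auc_b", "z", "p")))
  for (b in seq_len(B)) {
    for (attempt in seq_len(10L)) {
      ix <- sample_one_per_encounter(groups)
      lab <- wide$label[ix]
      ok <- !is.na(wide[[score_a]][ix]) & !is.na(wide[[score_b]][ix])
      if (sum(lab[ok] == 1) >= 2 && sum(lab[ok] == 0) >= 2) break
      if (attempt == 10L) stop("bootstrap aborted: 10 single-class draws in a row")
    }
    d <- delong_compare(lab[ok], wide[[score_a]][ix][ok], wide[[score_b]][ix][ok],
                        polarity[[score_a]], polarity[[score_b]])
    out[b, ] <- c(d$auc_a, d$auc_b, d$z, d$p)
  }
  list(auc_a = mean(out[, "auc_a"]), auc_b = mean(out[, "auc_b"]),
       z = median(out[, "z"]), p = median(out[, "p"]))
}

classify_positive <- function(values, threshold, polarity = "high_is_risk") {
  if (identical(polarity, "low_is_risk")) values <= threshold else values >= threshold
}

#' Test characteristics at one threshold (point estimates)
#'
#' Positivity rate, sensitivity, specificity, PPV and NPV of the trigger
#' condition (>= threshold for high-is-risk scores, <= for low-is-risk).
#'
#' @param labels Binary labels.
#' @param values Score values (rows with `NA` are dropped).
#' @param threshold Threshold on the score's native scale.
#' @param polarity Score polarity.
#' @return One-row tibble of the five characteristics (fractions in
#'   \[0, 1\]; PPV/NPV `NA` when undefined).
#' @export
threshold_stats <- function(labels, values, threshold,
                            polarity = "high_is_risk") {
  keep <- !is.na(values) & !is.na(labels)
  labels <- labels[keep]; values <- values[keep]
  pred <- classify_positive(values, threshold, polarity)
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  tibble::tibble(
    threshold = threshold,
    positivity_rate = (tp + fp) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' Test characteristics at every observed threshold
#'
#' Vectorised sweep over all observed unique values of a score taken as
#' thresholds, via cumulative counts: the full test-characteristics table
#' underlying threshold matching, precision-recall and efficiency curves.
#'
#' @inheritParams threshold_stats
#' @return Tibble with one row per unique threshold (native scale,
#'   ascending): `threshold`, `positivity_rate`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @export
threshold_sweep <- function(labels, values, polarity = "high_is_risk") {
  keep <- !is.na(values) & !is.na(labels)
  labels <- labels[keep]; values <- values[keep]
  if (!length(values)) stop("threshold_sweep: no values")
  v <- risk_direction(values, polarity)
  P <- sum(labels == 1); N <- sum(labels == 0); n <- P + N
  u <- sort(unique(v))
  fv <- factor(v, levels = u)
  pos_at <- unname(vapply(split(labels, fv), sum, numeric(1)))
  cnt_at <- unname(vapply(split(labels, fv), length, numeric(1)))
  # counts at values >= u[k]
  tp <- rev(cumsum(rev(pos_at)))
  np <- rev(cumsum(rev(cnt_at)))
  fp <- np - tp
  fn <- P - tp
  tn <- N - fp
  native <- if (identical(polarity, "low_is_risk")) -u else u
  out <- tibble::tibble(
    threshold = native,
    positivity_rate = np / n,
    sensitivity = if (P > 0) tp / P else NA_real_,
    specificity = if (N > 0) tn / N else NA_real_,
    ppv = ifelse(np > 0, tp / np, NA_real_),
    npv = ifelse(n - np > 0, tn / (n - np), NA_real_)
  )
  dplyr::arrange(out, .data$threshold)
}

#' NEWS-anchored threshold matching
#'
#' Scans every observed unique value of the candidate score as a threshold
#' and returns the one whose sensitivity (moderate risk) or specificity
#' (high risk) is closest to the reference metric; ties break toward the
#' more specific, higher-risk threshold.
#'
#' @param labels Binary labels.
#' @param values Candidate score values.
#' @param reference_metric Metric value of the reference score at its
#'   anchor threshold.
#' @param mode `"sensitivity"` or `"specificity"`.
#' @param polarity Candidate polarity.
#' @return The matched threshold (native scale).
#' @export
match_threshold <- function(labels, values, reference_metric,
                            mode = c("sensitivity", "specificity"),
                            polarity = "high_is_risk") {
  mode <- match.arg(mode)
  keep <- !is.na(values) & !is.na(labels)
  if (!sum(keep)) stop("match_threshold: no candidate values")
  sweep <- threshold_sweep(labels[keep], values[keep], polarity)
  dist <- abs(sweep[[mode]] - reference_metric)
  best <- which(dist <= min(dist) + 1e-12)
  if (length(best) > 1L) {
    ord <- order(-sweep$specificity[best],
                 if (identical(polarity, "low_is_risk")) sweep$threshold[best]
                 else -sweep$threshold[best])
    best <- best[ord][1L]
  }
  sweep$threshold[best]
}

#' Test characteristics with bootstrap CIs
#'
#' Point estimates are means over the same one-observation-per-encounter
#' bootstrap used for AUROC; CIs are 2.5/97.5 percentiles across
#' iterations.
#'
#' @inheritParams bootstrap_auc
#' @param score Score name.
#' @param threshold Threshold on the native scale.
#' @return One-row tibble: `score_name`, `threshold`, and each of the five
#'   characteristics with `_low`/`_high` CI columns.
#' @export
threshold_characteristics <- function(labeled, score, threshold,
                                      config = evaluation_config(),
                                      polarity = default_polarity()) {
  wide <- grid_to_wide(labeled)
  if (!score %in% names(wide)) stop("unknown score '", score, "'")
  groups <- make_row_groups(wide$encounter_id)
  B <- config$n_bootstrap
  stats_names <- c("positivity_rate", "sensitivity", "specificity", "ppv", "npv")
  per_iter <- matrix(NA_real_, nrow = B, ncol = 5,
                     dimnames = list(NULL, stats_names))
  set.seed(config$random_seed)
  for (b in seq_len(B)) {
    for (attempt in seq_len(10L)) {
      ix <- sample_one_per_encounter(groups)
      lab <- wide$label[ix]
      if (length(unique(lab)) > 1L) break
      if (attempt == 10L) stop("bootstrap aborted: 10 single-class draws in a row")
    }
    s <- threshold_stats(lab, wide[[score]][ix], threshold, polarity[[score]])
    per_iter[b, ] <- unlist(s[stats_names])
  }
  est <- colMeans(per_iter, na.rm = TRUE)
  lo <- apply(per_iter, 2, quantile, probs = 0.025, na.rm = TRUE)
  hi <- apply(per_iter, 2, quantile, probs = 0.975, na.rm = TRUE)
  out <- tibble::tibble(score_name = score, threshold = threshold)
  for (nm in stats_names) {
    out[[nm]] <- est[[nm]]
    out[[paste0(nm, "_low")]] <- lo[[nm]]
    out[[paste0(nm, "_high")]] <- hi[[nm]]
  }
  out
}

#' Observation-level precision-recall curve
#'
#' One `(sensitivity, ppv)` point per observed unique threshold, ordered by
#' sensitivity.
#'
#' @param labels Binary labels.
#' @param values Score values.
#' @param polarity Score polarity.
#' @return Tibble `(threshold, sensitivity, ppv)` ordered by sensitivity.
#' @export
precision_recall_curve <- function(labels, values, polarity = "high_is_risk") {
  sweep <- threshold_sweep(labels, values, polarity)
  out <- sweep[, c("threshold", "sensitivity", "ppv")]
  dplyr::arrange(out, .data$sensitivity, .data$threshold)
}

#' Encounter-level efficiency curve
#'
#' Per threshold: x = fraction of all encounters whose pre-event extreme
#' value crosses it, y = fraction of event encounters doing so (encounter
#' sensitivity), using the highest (polarity-respecting) score before the
#' first event or before discharge.
#'
#' @param summary_scores `scores` tibble from [summarize_encounter()],
#'   filtered or not; rows for one score are selected via `score`.
#' @param score Score name.
#' @param polarity Named polarity vector.
#' @return Tibble `(threshold, frac_triggered, sensitivity)` ordered from
#'   permissive to strict thresholds.
#' @export
efficiency_curve <- function(summary_scores, score,
                             polarity = default_polarity()) {
  s <- summary_scores[summary_scores$score_name == score, , drop = FALSE]
  pol <- polarity[[score]]
  vals <- s$extreme_pre_event
  cand <- sort(unique(vals[!is.na(vals)]))
  n_all <- nrow(s)
  n_event <- sum(s$had_event)
  rows <- lapply(cand, function(th) {
    crossed <- !is.na(vals) & classify_positive(vals, th, pol)
    tibble::tibble(
      threshold = th,
      frac_triggered = sum(crossed) / n_all,
      sensitivity = if (n_event > 0) sum(crossed & s$had_event) / n_event else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$frac_triggered))
}

#' Trigger-to-event lead-time analysis
#'
#' For each event encounter, lead time = first event time minus the first
#' pre-event threshold crossing, in hours; encounters whose score never
#' crossed the threshold before the event contribute 0 hours. Compared with
#' a reference score's lead-time sample by a two-sided Wilcoxon rank sum.
#'
#' @param summary Result of [summarize_encounter()] (needs `scores` and
#'   `triggers`).
#' @param score Score name.
#' @param threshold Threshold (must be present in `summary$triggers`).
#' @param reference_leads Optional numeric vector of reference lead times.
#' @return List: `score_name`, `threshold`, `leads` (per event encounter),
#'   `median_lead_hours`, `iqr_low`, `iqr_high`, `n_events`,
#'   `n_never_triggered`, `p_vs_reference` (`NA` without a reference).
#' @export
lead_time_analysis <- function(summary, score, threshold,
                               reference_leads = NULL) {
  ev <- summary$scores[summary$scores$had_event &
                         summary$scores$score_name == score, , drop = FALSE]
  ev <- ev[!duplicated(ev$encounter_id), , drop = FALSE]
  if (!nrow(ev)) {
    return(list(score_name = score, threshold = threshold, leads = numeric(),
                median_lead_hours = NA_real_, iqr_low = NA_real_,
                iqr_high = NA_real_, n_events = 0L, n_never_triggered = 0L,
                p_vs_reference = NA_real_))
  }
  trig <- summary$triggers[summary$triggers$score_name == score &
                             summary$triggers$threshold == threshold, ]
  m <- match(ev$encounter_id, trig$encounter_id)
  lead <- hours_between(trig$first_trigger_time[m], ev$first_event_time)
  never <- is.na(lead)
  lead[never] <- 0
  lead <- pmax(lead, 0)
  p <- if (!is.null(reference_leads)) {
    if (identical(sort(lead), sort(as.numeric(reference_leads)))) 1 else
      suppressWarnings(wilcox.test(lead, reference_leads, exact = FALSE)$p.value)
  } else NA_real_
  list(score_name = score, threshold = threshold, leads = lead,
       median_lead_hours = median(lead),
       iqr_low = unname(quantile(lead, 0.25)),
       iqr_high = unname(quantile(lead, 0.75)),
       n_events = nrow(ev), n_never_triggered = sum(never),
       p_vs_reference = p)
}
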