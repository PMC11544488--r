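# AUROC, bootstrap, DeLong, threshold matching, characteristic tables,
# curves and lead times, each against an independent oracle where one
# exists.

test_that("roc_auc matches hand cases and rejects single-class input", {
  expect_equal(roc_auc(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(2, 4)), 0.5)      # pure ties
  expect_equal(roc_auc(c(1, 1, 0, 0), c(4, 2, 3, 1)), 0.75) # 3 of 4 pairs
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "positive and one negative")
  # low-is-risk values are rank-reversed
  expect_equal(roc_auc(c(1, 0), c(10, 90), "low_is_risk"), 1)
})

test_that("roc_auc equals brute-force pair counting on random tied instances", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))     # both classes guaranteed
    values <- sample(0:8, n, replace = TRUE)     # heavy ties
    expect_equal(roc_auc(labels, values), auc_pair_count(labels, values))
  }
})

test_that("AUROC is invariant to monotone transforms and flips under negation", {
  set.seed(8)
  for (i in 1:50) {
    labels <- c(0, 1, rbinom(18, 1, 0.5))
    values <- rnorm(20)                          # tie-free
    a <- roc_auc(labels, values)
    expect_equal(roc_auc(labels, exp(values)), a)
    expect_equal(roc_auc(labels, rank(values)), a)
    expect_equal(roc_auc(labels, -values), 1 - a)
  }
})

test_that("degenerate bootstrap (B=1, one row per encounter) equals plain AUROC", {
  set.seed(3)
  n <- 40
  lab_df <- tibble::tibble(
    encounter_id = sprintf("e%02d", 1:n),
    time = at_hours(1), score_name = "NEWS",
    value = sample(0:10, n, replace = TRUE),
    label = c(0, 1, rbinom(n - 2, 1, 0.3))
  )
  cfg <- evaluation_config(n_bootstrap = 1, random_seed = 5)
  res <- bootstrap_auc(lab_df, cfg)
  expect_equal(res$auc, roc_auc(lab_df$label, lab_df$value))
  # same seed twice -> identical result including CIs
  res2 <- bootstrap_auc(lab_df, cfg)
  expect_identical(res, res2)
})

test_that("bootstrap pairs scores on shared draws and orders signal above noise", {
  set.seed(10)
  n_enc <- 150
  rows <- lapply(seq_len(n_enc), function(i) {
    k <- sample(2:5, 1)
    risk <- runif(1)
    tibble::tibble(encounter_id = sprintf("e%03d", i), time = at_hours(1:k),
                   label = rep(rbinom(1, 1, 0.2 + 0.6 * risk), k),
                   ORACLE = risk + rnorm(k, 0, 0.05),
                   NOISY = risk + rnorm(k, 0, 0.8))
  })
  lab <- tidyr::pivot_longer(dplyr::bind_rows(rows), c("ORACLE", "NOISY"),
                             names_to = "score_name", values_to = "value")
  cfg <- evaluation_config(n_bootstrap = 100, random_seed = 17)
  res <- bootstrap_auc(lab, cfg, polarity = c(ORACLE = "high_is_risk",
                                              NOISY = "high_is_risk"))
  expect_true(res$auc[res$score_name == "ORACLE"] >
                res$auc[res$score_name == "NOISY"])
  expect_true(all(res$ci_low <= res$auc & res$auc <= res$ci_high))
})

test_that("DeLong self-comparison gives p = 1 and swapping arguments negates z", {
  set.seed(11)
  labels <- c(rep(1, 15), rep(0, 30))
  va <- rnorm(45) + labels
  vb <- rnorm(45) + 0.5 * labels
  self <- delong_compare(labels, va, va)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  ab <- delong_compare(labels, va, vb)
  ba <- delong_compare(labels, vb, va)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$auc_a, roc_auc(labels, va))
})

test_that("DeLong agrees with the reference implementation in pROC", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:20) {
    labels <- c(rep(1, 20), rep(0, 40))
    va <- rnorm(60) + 0.8 * labels
    vb <- rnorm(60) + 0.8 * labels
    mine <- delong_compare(labels, va, vb)
    ref <- pROC::roc.test(
      pROC::roc(labels, va, quiet = TRUE, direction = "<"),
      pROC::roc(labels, vb, quiet = TRUE, direction = "<"),
      method = "delong", paired = TRUE)
    expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-8)
  }
})

test_that("threshold matching equals an exhaustive scan with the documented tie-break", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(30:80, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.3))
    values <- sample(0:12, n, replace = TRUE)
    ref_metric <- runif(1)
    mode <- sample(c("sensitivity", "specificity"), 1)
    got <- match_threshold(labels, values, ref_metric, mode)
    # oracle: scan all unique thresholds, argmin distance, break ties toward
    # the higher (more specific) threshold
    cand <- sort(unique(values))
    metr <- vapply(cand, function(th) {
      s <- threshold_stats(labels, values, th)
      s[[mode]]
    }, numeric(1))
    d <- abs(metr - ref_metric)
    best <- cand[d <= min(d) + 1e-12]
    expect_equal(got, max(best))
  }
})

test_that("equidistant candidates break toward the more specific threshold", {
  # sens(1)=1, sens(2)=0.5, sens(3)=0; anchor 0.75 is equidistant from 1 and .5
  labels <- c(1, 1, 0, 0)
  values <- c(1, 2, 0, 0)
  expect_equal(match_threshold(labels, values, 0.75, "sensitivity"), 2)
  # exact match returns that threshold
  expect_equal(match_threshold(labels, values, 0.5, "sensitivity"), 2)
})

test_that("threshold stats reproduce a constructed confusion table", {
  labels <- c(rep(1, 9), rep(0, 91), rep(1, 1), rep(0, 899))
  values <- c(rep(5, 100), rep(1, 900))  # first 100 trigger at >= 5
  s <- threshold_stats(labels, values, 5)
  expect_equal(s$sensitivity, 0.9)
  expect_equal(s$specificity, 899 / 990)          # ~0.908
  expect_equal(s$ppv, 0.09)
  expect_equal(s$npv, 899 / 900)                  # ~0.9989
  expect_equal(s$positivity_rate, 0.1)
  # low-is-risk: positives are values <= threshold
  s2 <- threshold_stats(c(1, 0), c(30, 80), 41, polarity = "low_is_risk")
  expect_equal(s2$sensitivity, 1)
  expect_equal(s2$specificity, 1)
  # zero predicted positives -> PPV undefined
  expect_true(is.na(threshold_stats(c(1, 0), c(1, 2), 99)$ppv))
})

test_that("count conservation holds at every threshold of a sweep", {
  set.seed(14)
  labels <- c(0, 1, rbinom(198, 1, 0.1))
  values <- sample(0:15, 200, replace = TRUE)
  P <- sum(labels); N <- sum(1 - labels)
  sw <- threshold_sweep(labels, values)
  positives <- sw$sensitivity * P + (1 - sw$specificity) * N
  expect_equal(positives, sw$positivity_rate * 200)
  expect_true(all(diff(sw$positivity_rate) <= 0))  # nonincreasing in threshold
})

test_that("precision-recall curve matches pointwise recomputation", {
  set.seed(15)
  labels <- c(0, 1, rbinom(300, 1, 0.15))
  values <- sample(0:10, 302, replace = TRUE)
  pr <- precision_recall_curve(labels, values)
  for (k in seq_len(nrow(pr))) {
    s <- threshold_stats(labels, values, pr$threshold[k])
    expect_equal(pr$sensitivity[k], s$sensitivity)
    expect_equal(pr$ppv[k], s$ppv)
  }
  # perfect score: the achievable PPV is 1 at every sensitivity (points at
  # thresholds below the separating gap are dominated, same recall less
  # precision)
  perf <- precision_recall_curve(c(1, 1, 0, 0), c(9, 8, 2, 1))
  best <- tapply(perf$ppv, perf$sensitivity, max)
  expect_true(all(best[names(best) != "0"] == 1))
  # uninformative score: PPV ~ prevalence at every recall
  set.seed(16)
  lab_u <- rbinom(20000, 1, 0.1)
  val_u <- runif(20000)
  pr_u <- precision_recall_curve(lab_u, val_u)
  mid <- pr_u[pr_u$sensitivity > 0.2 & pr_u$sensitivity < 0.95, ]
  expect_lt(max(abs(mid$ppv - mean(lab_u))), 0.05)
})

test_that("bootstrapped threshold characteristics are deterministic and bounded", {
  set.seed(17)
  n <- 60
  lab_df <- tibble::tibble(
    encounter_id = rep(sprintf("e%02d", 1:n), each = 2),
    time = rep(at_hours(c(1, 2)), n), score_name = "NEWS",
    value = sample(0:10, 2 * n, replace = TRUE),
    label = rep(c(0, 1, rbinom(n - 2, 1, 0.3)), each = 2)
  )
  cfg <- evaluation_config(n_bootstrap = 25, random_seed = 9)
  a <- threshold_characteristics(lab_df, "NEWS", 5, cfg)
  b <- threshold_characteristics(lab_df, "NEWS", 5, cfg)
  expect_identical(a, b)
  for (nm in c("positivity_rate", "sensitivity", "specificity", "ppv", "npv")) {
    expect_gte(a[[paste0(nm, "_low")]], 0)
    expect_lte(a[[paste0(nm, "_high")]], 1)
    expect_true(a[[paste0(nm, "_low")]] <= a[[nm]] &&
                  a[[nm]] <= a[[paste0(nm, "_high")]])
  }
})

test_that("efficiency curve matches a hand-counted 4-encounter fixture", {
  summ_scores <- tibble::tibble(
    encounter_id = c("e1", "e2", "e3", "e4"),
    score_name = "NEWS",
    extreme_pre_event = c(2, 5, 3, 7),
    first_event_time = at_hours(c(NA, 30, NA, 40)),
    had_event = c(FALSE, TRUE, FALSE, TRUE)
  )
  cv <- efficiency_curve(summ_scores, "NEWS")
  expect_equal(cv$threshold, c(2, 3, 5, 7))
  expect_equal(cv$frac_triggered, c(1, 0.75, 0.5, 0.25))
  expect_equal(cv$sensitivity, c(1, 1, 1, 0.5))
  # threshold below every max -> (1,1); above every max -> absent by design
  expect_equal(cv$frac_triggered[1], 1)
})

test_that("lead times subtract first trigger from event, imputing 0 when never triggered", {
  summ <- list(
    scores = tibble::tibble(
      encounter_id = c("e1", "e2"), score_name = "NEWS",
      extreme_pre_event = c(6, 2),
      first_event_time = at_hours(c(30, 50)), had_event = TRUE),
    triggers = tibble::tibble(
      encounter_id = "e1", first_trigger_time = at_hours(10),
      score_name = "NEWS", threshold = 5)
  )
  lt <- lead_time_analysis(summ, "NEWS", 5)
  expect_equal(sort(lt$leads), c(0, 20))     # e2 never triggered -> 0
  expect_equal(lt$n_never_triggered, 1L)
  expect_equal(lt$median_lead_hours, 10)
  # identical samples versus reference -> p = 1
  lt2 <- lead_time_analysis(summ, "NEWS", 5, reference_leads = c(0, 20))
  expect_equal(lt2$p_vs_reference, 1)
  lt3 <- lead_time_analysis(summ, "NEWS", 5, reference_leads = c(100, 120, 90))
  expect_lt(lt3$p_vs_reference, 0.2)
})

test_that("stratified runs preserve row counts between pooled and strata", {
  cohort <- tiny_cohort()
  # both campuses need both outcome classes for a per-stratum evaluation
  cohort$encounters$campus[cohort$encounters$encounter_id == "e3"] <- "B"
  lab <- tibble::tibble(
    encounter_id = rep(c("e1", "e2", "e3", "e4"), each = 3),
    time = rep(at_hours(1:3), 4), score_name = "NEWS",
    value = sample(0:8, 12, replace = TRUE),
    label = rep(c(0L, 1L, 1L, 0L), each = 3)
  )
  counts <- stratified_run(lab, cohort$encounters, function(sub, stratum) {
    tibble::tibble(stratum = stratum, n = nrow(sub))
  })
  expect_equal(counts$n[counts$stratum == "All"],
               sum(counts$n[counts$stratum != "All"]))
  # single-campus input: pooled equals the stratum
  one <- cohort$encounters[cohort$encounters$campus == "A", ]
  lab1 <- lab[lab$encounter_id %in% one$encounter_id, ]
  c1 <- stratified_run(lab1, one, function(sub, stratum) {
    tibble::tibble(stratum = stratum, n = nrow(sub))
  })
  expect_equal(unique(c1$n), c1$n[c1$stratum == "All"])
})
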