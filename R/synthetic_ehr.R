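# Synthetic multi-campus ward cohort with known ground-truth risk.
#
# Encounters draw a log-normal length of stay (median 96 h, IQR ~59-171 h)
# and a Bernoulli deterioration event at a campus-adjusted base rate of
# 4.6%; roughly 46% of events are ward deaths (7600 of 16693) and the rest
# direct ward-to-ICU transfers. Event times fall uniformly in the second
# half of the ward stay so pre-event observations always exist. Vitals are
# sampled on an exponentially jittered grid (mean gap 4 h) from adult norms
# and displaced toward abnormal in proportion to the latent risk r(t),
# which ramps linearly from baseline to 1 over the pre-event window.
# A dense reference stream (1 h grid) emulates the densest score stream for
# alignment; sparse PaCO2/FiO2 blood gases exercise the NEWS2 scale rule.

#' Generator configuration for synthetic ward cohorts
#'
#' @param n_encounters Number of encounters.
#' @param campuses Tibble `(label, weight, event_multiplier)`; encounters
#'   are assigned to campuses by weight and the event rate scaled by the
#'   multiplier.
#' @param base_event_rate Composite deterioration probability per encounter
#'   before campus adjustment.
#' @param death_share Fraction of events that are ward deaths (rest are
#'   ward-to-ICU transfers).
#' @param los_median_hours,los_log_sd Log-normal length-of-stay parameters
#'   (median 96 h with `sdlog` 0.79 gives an IQR of roughly 59-171 h).
#' @param vitals_interval_hours Mean gap between vital-sign observations
#'   (exponential jitter).
#' @param reference_interval_hours Gap of the dense reference score grid.
#' @param pre_event_ramp_hours Duration of pre-event physiological drift.
#' @param drift_magnitude Scale of the displacement toward abnormal vitals
#'   (1 = full displacement at r = 1; 0 = uninformative vitals).
#' @param lab_rate Expected number of blood gases per encounter.
#' @param random_seed Seed controlling the entire cohort.
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(n_encounters = 2000L,
                             campuses = tibble::tibble(
                               label = c("A", "B", "C"),
                               weight = c(0.4, 0.35, 0.25),
                               event_multiplier = c(1, 0.7, 1.3)),
                             base_event_rate = 0.046,
                             death_share = 7600 / 16693,
                             los_median_hours = 96,
                             los_log_sd = 0.79,
                             vitals_interval_hours = 4,
                             reference_interval_hours = 1,
                             pre_event_ramp_hours = 24,
                             drift_magnitude = 1,
                             lab_rate = 0.1,
                             random_seed = 1L) {
  stopifnot(n_encounters >= 1, base_event_rate >= 0, base_event_rate <= 1,
            death_share >= 0, death_share <= 1, los_median_hours > 0,
            vitals_interval_hours > 0, reference_interval_hours > 0,
            pre_event_ramp_hours > 0, lab_rate >= 0)
  if (!all(c("label", "weight", "event_multiplier") %in% names(campuses))) {
    stop("campuses needs columns label, weight, event_multiplier")
  }
  structure(list(n_encounters = as.integer(n_encounters), campuses = campuses,
                 base_event_rate = base_event_rate, death_share = death_share,
                 los_median_hours = los_median_hours, los_log_sd = los_log_sd,
                 vitals_interval_hours = vitals_interval_hours,
                 reference_interval_hours = reference_interval_hours,
                 pre_event_ramp_hours = pre_event_ramp_hours,
                 drift_magnitude = drift_magnitude, lab_rate = lab_rate,
                 random_seed = as.integer(random_seed)),
            class = "generator_config")
}

# adult baseline norms; drift displaces each vital toward its scored bands
VITAL_NORMS <- list(
  heart_rate = list(mean = 75, sd = 10, drift = 55),
  respiratory_rate = list(mean = 14, sd = 2, drift = 16),
  systolic_bp = list(mean = 120, sd = 15, drift = -45),
  temperature = list(mean = 36.8, sd = 0.3, drift = 2.0),
  spo2 = list(mean = 97, sd = 1.5, drift = -12)
)

risk_at <- function(hours_to_event, ramp, baseline = 0.03) {
  r <- ifelse(is.na(hours_to_event), baseline,
              pmax(baseline, 1 - pmax(hours_to_event, 0) / ramp))
  pmin(r, 1)
}

#' Simulate a synthetic multi-campus ward cohort
#'
#' @param config [generator_config()].
#' @return List: `encounters`, `locations`, `observations` (valid inputs to
#'   the evaluation pipeline), `reference` (a dense external-style score
#'   series, `score_name = "SEDI"`, a noisy monotone readout of risk on the
#'   reference grid), and `ground_truth` (list with `events` and the latent
#'   `trajectory` of r(t); never consumed by the evaluation path).
#' @export
simulate_cohort <- function(config = generator_config()) {
  set.seed(config$random_seed)
  n <- config$n_encounters
  epoch <- as.POSIXct("2023-01-01 00:00", tz = "UTC")

  camp <- config$campuses
  campus <- sample(camp$label, n, replace = TRUE,
                   prob = camp$weight / sum(camp$weight))
  mult <- camp$event_multiplier[match(campus, camp$label)]
  p_event <- pmin(1, config$base_event_rate * mult)
  had_event <- rbinom(n, 1, p_event) == 1
  event_type <- ifelse(had_event,
                       ifelse(runif(n) < config$death_share,
                              "ward_death", "ward_to_icu"),
                       NA_character_)
  los <- rlnorm(n, log(config$los_median_hours), config$los_log_sd)
  los <- pmin(pmax(los, 12), 24 * 28)
  admit <- epoch + round(runif(n, 0, 365 * 24 * 60)) * 60
  event_h <- ifelse(had_event, los * runif(n, 0.5, 1), NA_real_)

  id <- sprintf("E%05d", seq_len(n))
  # ward stay ends at the event for event encounters; ICU tail for transfers
  ward_end_h <- ifelse(had_event, event_h, los)
  icu_tail_h <- ifelse(had_event & event_type == "ward_to_icu",
                       pmin(rlnorm(n, log(72), 0.6), 24 * 14), 0)
  discharge_h <- ifelse(had_event,
                        ifelse(event_type == "ward_death", event_h,
                               event_h + icu_tail_h),
                        los)
  icu_death <- had_event & event_type == "ward_to_icu" & runif(n) < 0.3
  disposition <- ifelse(had_event & event_type == "ward_death", "dead",
                        ifelse(icu_death, "dead", "alive"))
  to_min <- function(h) round(h * 60) / 60
  encounters <- tibble::tibble(
    encounter_id = id, campus = campus,
    age_years = round(runif(n, 18, 95)),
    admit_time = admit,
    discharge_time = admit + to_min(discharge_h) * 3600,
    disposition = disposition
  )
  loc1 <- tibble::tibble(encounter_id = id, start_time = admit,
                         end_time = admit + to_min(ward_end_h) * 3600,
                         location = "ward")
  icu_ix <- which(had_event & event_type == "ward_to_icu")
  loc2 <- tibble::tibble(
    encounter_id = id[icu_ix],
    start_time = loc1$end_time[icu_ix],
    end_time = encounters$discharge_time[icu_ix],
    location = "icu"
  )
  locations <- dplyr::arrange(dplyr::bind_rows(loc1, loc2),
                              .data$encounter_id, .data$start_time)

  # observation times: admission plus exponential gaps through the ward stay
  obs_times <- lapply(seq_len(n), function(i) {
    end <- ward_end_h[i]
    t <- 0
    gaps <- stats::rexp(ceiling(end / config$vitals_interval_hours * 2.5) + 5,
                        rate = 1 / config$vitals_interval_hours)
    tt <- cumsum(c(0, gaps))
    tt <- tt[tt <= end]
    # guarantee a final pre-event vital close to the event
    if (had_event[i] && (length(tt) == 0 || end - max(tt) > 1)) {
      tt <- c(tt, end - runif(1, 0, 0.5))
    }
    sort(unique(round(tt * 60) / 60))
  })
  n_obs <- lengths(obs_times)
  oi <- rep(seq_len(n), n_obs)
  t_h <- unlist(obs_times)
  tte <- event_h[oi] - t_h
  r <- risk_at(ifelse(had_event[oi], tte, NA_real_),
               config$pre_event_ramp_hours)

  d <- config$drift_magnitude
  draw_vital <- function(nm) {
    v <- VITAL_NORMS[[nm]]
    v$mean + rnorm(length(oi), 0, v$sd) + d * v$drift * (r - 0.03) / 0.97
  }
  spo2 <- pmin(pmax(draw_vital("spo2"), 50), 100)
  on_o2 <- runif(length(oi)) < pmin(0.9, 0.05 + 0.5 * d * r)
  consciousness <- ifelse(runif(length(oi)) < pmin(0.8, 0.35 * d * pmax(r - 0.4, 0)),
                          sample(c("V", "P", "C"), length(oi), replace = TRUE,
                                 prob = c(0.5, 0.3, 0.2)),
                          "A")
  observations <- tibble::tibble(
    encounter_id = id[oi],
    time = admit[oi] + round(t_h * 60) * 60,
    respiratory_rate = round(pmax(draw_vital("respiratory_rate"), 4)),
    spo2 = round(spo2),
    supplemental_o2 = on_o2,
    fio2 = ifelse(on_o2,
                  round(pmin(pmax(21 + 10 + 40 * r + rnorm(length(oi), 0, 5), 22), 100)),
                  NA_real_),
    temperature = round(draw_vital("temperature"), 1),
    systolic_bp = round(pmax(draw_vital("systolic_bp"), 40)),
    heart_rate = round(pmax(draw_vital("heart_rate"), 20)),
    consciousness = consciousness,
    paco2 = NA_real_,
    location = "ward"
  )
  # sparse blood gases: a Poisson number of observation rows carry a PaCO2
  n_labs <- rpois(n, config$lab_rate)
  lab_rows <- unlist(lapply(seq_len(n), function(i) {
    rows <- which(oi == i)
    if (!n_labs[i] || !length(rows)) return(integer())
    sample(rows, min(n_labs[i], length(rows)))
  }))
  if (length(lab_rows)) {
    rlab <- r[lab_rows]
    observations$paco2[lab_rows] <- round(rnorm(length(lab_rows), 40, 5) + 14 * rlab, 1)
    need_fio2 <- lab_rows[is.na(observations$fio2[lab_rows])]
    observations$fio2[need_fio2] <- 21
  }
  observations$time <- as.POSIXct(round(observations$time, units = "mins"), tz = "UTC")
  observations <- observations[!duplicated(observations[, c("encounter_id", "time")]), ]
  observations <- dplyr::arrange(observations, .data$encounter_id, .data$time)

  # dense reference grid and latent trajectory
  ref_times <- lapply(seq_len(n), function(i) {
    seq(0, ward_end_h[i], by = config$reference_interval_hours)
  })
  ri <- rep(seq_len(n), lengths(ref_times))
  rt <- unlist(ref_times)
  r_ref <- risk_at(ifelse(had_event[ri], event_h[ri] - rt, NA_real_),
                   config$pre_event_ramp_hours)
  trajectory <- tibble::tibble(
    encounter_id = id[ri],
    time = admit[ri] + round(rt * 60) * 60,
    risk = r_ref
  )
  reference <- tibble::tibble(
    encounter_id = trajectory$encounter_id,
    score_name = "SEDI",
    time = trajectory$time,
    value = round(pmin(pmax(100 * (r_ref + rnorm(length(r_ref), 0, 0.18)), 0), 100), 1)
  )
  events <- tibble::tibble(
    encounter_id = id[had_event],
    event_time = admit[had_event] + round(event_h[had_event] * 60) * 60,
    event_type = event_type[had_event]
  )
  gt_enc <- tibble::tibble(
    encounter_id = id, had_event = had_event,
    event_time = admit + round(event_h * 60) * 60,  # NA for non-events
    event_type = event_type
  )
  list(encounters = encounters, locations = locations,
       observations = observations, reference = reference,
       ground_truth = list(events = gt_enc, trajectory = trajectory),
       config = config)
}

#' Ground-truth oracle score
#'
#' Emits the latent risk trajectory r(t) on the reference grid as a
#' high-is-risk score series: the best-achievable ranking signal for the
#' generated cohort.
#'
#' @param ground_truth `ground_truth` element of [simulate_cohort()].
#' @param encounter_id Optional single encounter to extract.
#' @return Score-series tibble (`score_name = "ORACLE"`).
#' @export
oracle_score <- function(ground_truth, encounter_id = NULL) {
  tr <- ground_truth$trajectory
  if (!is.null(encounter_id)) tr <- tr[tr$encounter_id == encounter_id, ]
  tibble::tibble(encounter_id = tr$encounter_id, score_name = "ORACLE",
                 time = tr$time, value = tr$risk)
}

#' Degrade a score series with seeded Gaussian noise
#'
#' Builds score families with a known discrimination ordering: more noise,
#' no better AUROC.
#'
#' @param series Score-series tibble.
#' @param noise_sd Noise standard deviation on the score's native scale.
#' @param seed Seed for the noise draw.
#' @param suffix Appended to the score name (default `"_deg"`).
#' @return Score-series tibble of the same length.
#' @export
degrade <- function(series, noise_sd, seed = 1L, suffix = "_deg") {
  out <- series
  if (noise_sd > 0) {
    set.seed(seed)
    out$value <- out$value + rnorm(nrow(out), 0, noise_sd)
  }
  out$score_name <- paste0(series$score_name, if (noise_sd > 0) suffix else "")
  if (noise_sd == 0) out$score_name <- series$score_name
  out
}
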