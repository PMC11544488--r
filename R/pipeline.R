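# Config-driven pipeline stages: simulate -> score -> evaluate. Each stage
# reads plain CSV, writes plain CSV plus a JSON manifest (seed, config
# hash, file checksums) sufficient to reproduce its outputs bit-identically.
# The numbered scripts under analysis/ are thin drivers over these.

read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

config_from_yaml <- function(y) {
  gen_args <- y$generator %||% list()
  if (!is.null(gen_args$campuses)) {
    gen_args$campuses <- dplyr::bind_rows(lapply(gen_args$campuses, tibble::as_tibble))
  }
  eval_args <- y$evaluation %||% list()
  list(generator = do.call(generator_config, gen_args),
       evaluation = do.call(evaluation_config, eval_args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_manifest <- function(out_dir, stage, seed, config, files) {
  checksums <- vapply(files, function(f) {
    unname(tools::md5sum(file.path(out_dir, f)))
  }, character(1))
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("ewsbench")),
    seed = seed,
    config_hash = digest_config(config),
    files = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

digest_config <- function(config) {
  # stable hash without extra deps: md5 of the deparsed config
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate a cohort and write it to disk
#'
#' Writes `encounters.csv`, `locations.csv`, `observations.csv`,
#' `external_scores.csv` (the dense reference stream), the ground-truth
#' files (`ground_truth_events.csv`, `ground_truth_trajectory.csv`; for
#' audit only, never consumed by the evaluation stages) and a JSON
#' manifest.
#'
#' @param config [generator_config()], or a YAML path with a `generator`
#'   section.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(config = generator_config(), out_dir) {
  if (is.character(config)) config <- config_from_yaml(read_run_config(config))$generator
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)
  write_table(sim$encounters, file.path(out_dir, "encounters.csv"))
  write_table(sim$locations, file.path(out_dir, "locations.csv"))
  write_table(sim$observations, file.path(out_dir, "observations.csv"))
  write_table(sim$reference, file.path(out_dir, "external_scores.csv"))
  write_table(sim$ground_truth$events, file.path(out_dir, "ground_truth_events.csv"))
  write_table(sim$ground_truth$trajectory,
              file.path(out_dir, "ground_truth_trajectory.csv"))
  invisible(write_manifest(out_dir, "simulate", config$random_seed, config,
                           c("encounters.csv", "locations.csv", "observations.csv",
                             "external_scores.csv", "ground_truth_events.csv",
                             "ground_truth_trajectory.csv")))
}

load_cohort <- function(dir) {
  enc <- read_encounters(file.path(dir, "encounters.csv"),
                         file.path(dir, "locations.csv"))
  obs <- read_observations(file.path(dir, "observations.csv"))
  list(encounters = enc$encounters, locations = enc$locations,
       observations = obs)
}

#' Compute engine score streams for a cohort on disk
#'
#' Writes one CSV per requested engine (`scores_MEWS.csv`, ...) plus a
#' manifest.
#'
#' @param cohort_dir Directory written by [run_simulate()] (or containing
#'   equivalently shaped CSVs).
#' @param engines Engines to run.
#' @param out_dir Output directory; defaults to `cohort_dir`.
#' @return Invisibly, the manifest.
#' @export
run_score <- function(cohort_dir, engines = c("MEWS", "NEWS", "NEWS2"),
                      out_dir = cohort_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- load_cohort(cohort_dir)
  files <- character()
  for (eng in engines) {
    s <- score_streams(cohort$observations, eng)
    f <- paste0("scores_", eng, ".csv")
    write_table(s, file.path(out_dir, f))
    files <- c(files, f)
    message(sprintf("%s: %d points over %d encounters", eng, nrow(s),
                    length(unique(s$encounter_id))))
  }
  invisible(write_manifest(out_dir, "score", NA_integer_,
                           list(engines = engines), files))
}

#' Full evaluation of a scored cohort
#'
#' The complete comparison protocol on in-memory inputs: alignment of all
#' streams to the reference grid restricted to ward-located times, outcome
#' labeling, bootstrapped AUROC per campus and pooled, paired DeLong
#' comparison against the reference score, NEWS-anchored threshold matching
#' and test-characteristic tables, precision-recall curves, encounter-level
#' efficiency curves and alert counts, and lead-time analysis.
#'
#' @param encounters,locations,observations Cohort tibbles.
#' @param external Named list of score-series tibbles for externally
#'   supplied scores (each may carry a `polarity` attribute).
#' @param engines Engines to compute from the observations.
#' @param config [evaluation_config()].
#' @param reference_stream Name of the stream providing the alignment grid
#'   (the densest stream).
#' @param polarity Named polarity vector covering every score evaluated.
#' @return List of result tables (`auroc_by_campus`,
#'   `threshold_characteristics`, `encounter_comparison`, `pr_curves`,
#'   `efficiency_curves`, `lead_times`) plus `matched_thresholds`,
#'   `labeled`, and `n_encounters`.
#' @export
evaluate_cohort <- function(encounters, locations, observations,
                            external = list(),
                            engines = c("MEWS", "NEWS", "NEWS2"),
                            config = evaluation_config(),
                            reference_stream = names(external)[1],
                            polarity = default_polarity()) {
  elig <- eligibility_filter(encounters, locations)
  obs <- observations[observations$encounter_id %in% elig$encounter_id, ]
  streams <- list()
  for (eng in engines) streams[[eng]] <- score_streams(obs, eng)
  for (nm in names(external)) {
    s <- external[[nm]]
    streams[[nm]] <- s[s$encounter_id %in% elig$encounter_id, , drop = FALSE]
    p <- attr(s, "polarity")
    if (!is.null(p)) polarity[nm] <- p
  }
  unknown <- setdiff(names(streams), names(polarity))
  if (length(unknown)) {
    stop("no polarity known for score(s): ", paste(unknown, collapse = ", "),
         "; known scores: ", paste(names(polarity), collapse = ", "))
  }
  if (is.null(reference_stream) || !reference_stream %in% names(streams)) {
    stop("reference stream '", reference_stream, "' not among streams: ",
         paste(names(streams), collapse = ", "))
  }
  events <- extract_events_cohort(elig, locations, obs)
  reference <- streams[[reference_stream]]
  others <- streams[setdiff(names(streams), reference_stream)]
  grid <- align_scores(reference, others)
  grid <- restrict_to_ward(grid, locations)
  labeled <- label_grid(grid, events, config)

  score_names <- names(streams)
  # Table 2: AUROC per campus and pooled, paired DeLong vs reference score
  auroc_tbl <- stratified_run(labeled, elig, function(sub, stratum) {
    res <- bootstrap_auc(sub, config, polarity)
    res$campus <- stratum
    res$n_encounters <- length(unique(sub$encounter_id))
    res
  })
  delong_rows <- lapply(setdiff(score_names, config$reference_score), function(s) {
    d <- bootstrap_delong(labeled, s, config$reference_score, config, polarity)
    tibble::tibble(score_name = s, reference = config$reference_score,
                   auc = d$auc_a, auc_reference = d$auc_b, z = d$z, p = d$p)
  })
  delong_tbl <- dplyr::bind_rows(delong_rows)

  # NEWS-anchored thresholds (observation level, full labeled set)
  ref_lab <- labeled[labeled$score_name == config$reference_score, ]
  anchor_sens <- threshold_stats(ref_lab$label, ref_lab$value,
                                 config$moderate_anchor,
                                 polarity[[config$reference_score]])$sensitivity
  anchor_spec <- threshold_stats(ref_lab$label, ref_lab$value,
                                 config$high_anchor,
                                 polarity[[config$reference_score]])$specificity
  matched <- list()
  for (s in score_names) {
    sl <- labeled[labeled$score_name == s, ]
    if (s == config$reference_score) {
      matched[[s]] <- c(moderate = config$moderate_anchor,
                        high = config$high_anchor)
    } else {
      matched[[s]] <- c(
        moderate = match_threshold(sl$label, sl$value, anchor_sens,
                                   "sensitivity", polarity[[s]]),
        high = match_threshold(sl$label, sl$value, anchor_spec,
                               "specificity", polarity[[s]]))
    }
  }

  # Table 3: observation-level test characteristics at matched thresholds
  char_rows <- list()
  for (risk in c("moderate", "high")) {
    for (s in score_names) {
      row <- threshold_characteristics(labeled, s, matched[[s]][[risk]],
                                       config, polarity)
      row <- tibble::add_column(row, risk_level = risk, .before = 1)
      char_rows[[length(char_rows) + 1L]] <- row
    }
  }
  char_tbl <- dplyr::bind_rows(char_rows)

  # curves
  pr_rows <- lapply(score_names, function(s) {
    sl <- labeled[labeled$score_name == s, ]
    cv <- precision_recall_curve(sl$label, sl$value, polarity[[s]])
    tibble::add_column(cv, score_name = s, .before = 1)
  })
  pr_tbl <- dplyr::bind_rows(pr_rows)

  thresholds <- lapply(matched, unname)
  summ <- summarize_encounter(grid, events, thresholds, polarity,
                              config$outcome_type)
  eff_rows <- lapply(score_names, function(s) {
    cv <- efficiency_curve(summ$scores, s, polarity)
    tibble::add_column(cv, score_name = s, .before = 1)
  })
  eff_tbl <- dplyr::bind_rows(eff_rows)

  # Table 4: encounter-level alert counts and lead times vs reference
  n_enc <- nrow(elig)
  event_enc <- unique(events$encounter_id[
    if (config$outcome_type == "death") events$event_type == "ward_death"
    else rep(TRUE, nrow(events))])
  n_event_enc <- length(event_enc)
  enc_rows <- list(); lead_rows <- list()
  ref_leads <- list()
  for (risk in c("moderate", "high")) {
    lt_ref <- lead_time_analysis(summ, config$reference_score,
                                 matched[[config$reference_score]][[risk]])
    ref_leads[[risk]] <- lt_ref$leads
  }
  for (risk in c("moderate", "high")) {
    for (s in score_names) {
      th <- matched[[s]][[risk]]
      trig <- summ$triggers[summ$triggers$score_name == s &
                              summ$triggers$threshold == th, ]
      alerts <- length(unique(trig$encounter_id))
      caught <- length(intersect(trig$encounter_id, event_enc))
      lt <- lead_time_analysis(summ, s, th,
                               reference_leads =
                                 if (s == config$reference_score) NULL
                                 else ref_leads[[risk]])
      enc_rows[[length(enc_rows) + 1L]] <- tibble::tibble(
        risk_level = risk, score_name = s, threshold = th,
        n_encounters_alerted = alerts,
        pct_encounters_alerted = 100 * alerts / n_enc,
        n_events_caught = caught,
        pct_events_caught = if (n_event_enc) 100 * caught / n_event_enc else NA_real_,
        median_lead_hours = lt$median_lead_hours,
        lead_iqr_low = lt$iqr_low, lead_iqr_high = lt$iqr_high,
        lead_p_vs_reference = lt$p_vs_reference
      )
      lead_rows[[length(lead_rows) + 1L]] <- tibble::tibble(
        risk_level = risk, score_name = s, threshold = th,
        n_events = lt$n_events, n_never_triggered = lt$n_never_triggered,
        median_lead_hours = lt$median_lead_hours,
        iqr_low = lt$iqr_low, iqr_high = lt$iqr_high,
        p_vs_reference = lt$p_vs_reference
      )
    }
  }
  list(
    auroc_by_campus = auroc_tbl,
    delong_vs_reference = delong_tbl,
    threshold_characteristics = char_tbl,
    encounter_comparison = dplyr::bind_rows(enc_rows),
    pr_curves = pr_tbl,
    efficiency_curves = eff_tbl,
    lead_times = dplyr::bind_rows(lead_rows),
    matched_thresholds = matched,
    labeled = labeled,
    n_encounters = n_enc,
    n_event_encounters = n_event_enc
  )
}

restrict_to_ward <- function(grid, locations) {
  if (!nrow(grid)) return(grid)
  ward <- locations[locations$location == "ward", , drop = FALSE]
  g <- data.table::data.table(encounter_id = grid$encounter_id,
                              time = grid$time, row = seq_len(nrow(grid)))
  w <- data.table::data.table(encounter_id = ward$encounter_id,
                              time = ward$start_time,
                              int_end = ward$end_time)
  data.table::setkey(w, encounter_id, time)
  hit <- w[g, on = c("encounter_id", "time"), roll = TRUE]
  ok <- !is.na(hit$int_end) & hit$time <= hit$int_end
  grid[sort(hit$row[ok]), , drop = FALSE]
}

#' Repeat an evaluation per campus and pooled
#'
#' Applies `fn(labeled_subset, stratum_label)` to the pooled labeled grid
#' (`"All"`) and to each campus's encounters, binding the results.
#'
#' @param labeled Labeled grid tibble.
#' @param encounters Encounter tibble with a `campus` column.
#' @param fn Function of (labeled subset, stratum label) returning a tibble.
#' @return Row-bound tibble over `"All"` plus each campus.
#' @export
stratified_run <- function(labeled, encounters, fn) {
  out <- list(fn(labeled, "All"))
  for (cp in sort(unique(encounters$campus))) {
    ids <- encounters$encounter_id[encounters$campus == cp]
    sub <- labeled[labeled$encounter_id %in% ids, , drop = FALSE]
    if (nrow(sub) && length(unique(sub$label)) > 1L) {
      out[[length(out) + 1L]] <- fn(sub, cp)
    }
  }
  dplyr::bind_rows(out)
}

#' Evaluate a cohort on disk and write report tables
#'
#' Reads the cohort and score streams written by [run_simulate()] and
#' [run_score()], runs [evaluate_cohort()], and writes
#' `auroc_by_campus.csv`, `delong_vs_reference.csv`,
#' `threshold_characteristics.csv`, `encounter_comparison.csv`,
#' `pr_curves.csv`, `efficiency_curves.csv`, `lead_times.csv` and a
#' manifest.
#'
#' @param cohort_dir Directory with the cohort and score CSVs.
#' @param out_dir Output directory for report tables.
#' @param config [evaluation_config()], or a YAML path with an `evaluation`
#'   section.
#' @param engines Engine score names to include.
#' @param external_scores Named list: score name -> polarity, for streams
#'   stored as `external_scores.csv` (reference) — the first is used as the
#'   alignment reference.
#' @return Invisibly, the full result list from [evaluate_cohort()].
#' @export
run_evaluate <- function(cohort_dir, out_dir,
                         config = evaluation_config(),
                         engines = c("MEWS", "NEWS", "NEWS2"),
                         external_scores = list(SEDI = "high_is_risk")) {
  if (is.character(config)) config <- config_from_yaml(read_run_config(config))$evaluation
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- load_cohort(cohort_dir)
  ext <- list()
  ext_path <- file.path(cohort_dir, "external_scores.csv")
  if (file.exists(ext_path) && length(external_scores)) {
    all_ext <- readr::read_csv(ext_path, col_types = readr::cols(.default = "c"),
                               progress = FALSE)
    for (nm in names(external_scores)) {
      sub <- all_ext[all_ext$score_name == nm | !"score_name" %in% names(all_ext), ]
      tmp <- tempfile(fileext = ".csv")
      readr::write_csv(sub, tmp, progress = FALSE)
      ext[[nm]] <- external_score_adapter(tmp, nm, external_scores[[nm]],
                                          known_encounters = cohort$encounters$encounter_id)
      unlink(tmp)
    }
  }
  res <- evaluate_cohort(cohort$encounters, cohort$locations,
                         cohort$observations, external = ext,
                         engines = engines, config = config,
                         reference_stream = names(ext)[1])
  tables <- c("auroc_by_campus", "delong_vs_reference",
              "threshold_characteristics", "encounter_comparison",
              "pr_curves", "efficiency_curves", "lead_times")
  for (tb in tables) write_table(res[[tb]], file.path(out_dir, paste0(tb, ".csv")))
  write_manifest(out_dir, "evaluate", config$random_seed, config,
                 paste0(tables, ".csv"))
  invisible(res)
}
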