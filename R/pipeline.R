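# End-to-end driver: simulate (or load) -> preprocess -> per-session
# clustering -> hierarchical aggregation -> backfit -> temporal parameters
# -> statistics. Streaming: EEG is rendered and preprocessed one session at
# a time from deterministic per-session seeds, so memory stays flat and a
# rerun with the same configuration reproduces identical outputs.

prep_session <- function(cohort, subject, session, pcfg) {
  rec <- render_cohort_recording(cohort, subject, session)
  if (isTRUE(pcfg$enabled)) {
    rec <- preprocess_recording(
      rec, low_hz = pcfg$low_hz, high_hz = pcfg$high_hz,
      transition_hz = pcfg$transition_hz, epoch_s = pcfg$epoch_s,
      faster_z = pcfg$faster_z, amp_uv = pcfg$amp_uv, prob_sd = pcfg$prob_sd,
      target_hz = pcfg$target_hz,
      bandpass = isTRUE(pcfg$bandpass),
      detect_bads = isTRUE(pcfg$detect_bads),
      use_neighbors = isTRUE(pcfg$use_neighbors))$recording
  } else {
    rec <- average_reference(rec)
  }
  rec
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> session-level modified k-means ->
#' hierarchical aggregation (session to subject-stage to stage to global)
#' -> canonical letter assignment -> backfit -> temporal parameters ->
#' repeated-measures ANOVA, paired t-tests and Spearman brain-behavior
#' correlation, writing every artifact plus a run manifest under `out_dir`.
#'
#' @param config nested configuration list (see
#'   [default_pipeline_config()]) or the path of a YAML file.
#' @param out_dir output directory (created if missing).
#' @return the run manifest, invisibly. Artifacts written: global and
#'   per-stage microstate maps (JSON/CSV), the tidy parameter table and its
#'   subject-by-stage summary, per-stage mean GEV, ANOVA tables for the
#'   three parameters and the evaluations, stage paired t-tests, the
#'   Spearman correlation heatmap table, the evaluation table, a config
#'   echo and `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  t0 <- Sys.time()
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tick <- function(name, t_start) {
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  }

  # --- simulate ------------------------------------------------------------
  ts <- Sys.time()
  ccfg <- config$cohort
  ccfg$sessions_per_stage <- unlist(ccfg$sessions_per_stage)
  if (!is.null(ccfg$stage_names)) ccfg$stage_names <- unlist(ccfg$stage_names)
  if (!is.null(ccfg$planted_effects) && !is.data.frame(ccfg$planted_effects))
    ccfg$planted_effects <- do.call(rbind, lapply(ccfg$planted_effects, as.data.frame))
  ccfg$seed <- config$seed
  cohort <- simulate_cohort(do.call(cohort_config, ccfg))
  plan <- cohort$plan
  n_sub <- cohort$config$n_subjects
  tick("simulate", ts)

  # --- pass 1: session-level clustering ------------------------------------
  ts <- Sys.time()
  mcfg <- config$microstates
  K <- mcfg$k
  session_sets <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    session_sets[[s]] <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      rec <- prep_session(cohort, s, i, config$preprocess)
      g <- gfp(rec)
      pk <- find_gfp_peaks(g, mcfg$min_peak_distance)
      if (length(pk) <= K)
        stopf("stage fit: subject %d session %d has too few GFP peaks", s, i)
      session_sets[[s]][[i]] <- modified_kmeans(
        rec$data[, pk, drop = FALSE], K, n_init = mcfg$n_init,
        seed = derive_seed(config$seed, "fit", s * 1000L + i))
    }
  }
  tick("session_fit", ts)

  # --- hierarchical aggregation --------------------------------------------
  ts <- Sys.time()
  stages <- cohort$config$stage_names
  subject_stage_sets <- list()
  for (s in seq_len(n_sub)) {
    for (st in stages) {
      idx <- which(plan$stage == st)
      subject_stage_sets[[paste(s, st)]] <- aggregate_maps(
        session_sets[[s]][idx], K, n_iter = mcfg$aggregate_n_iter,
        seed = derive_seed(config$seed, "agg_subject", s * 131L + match(st, stages)),
        provenance = "subject")
    }
  }
  stage_sets <- lapply(stages, function(st) {
    aggregate_maps(subject_stage_sets[paste(seq_len(n_sub), st)], K,
                   n_iter = mcfg$aggregate_n_iter,
                   seed = derive_seed(config$seed, "agg_stage", match(st, stages)),
                   provenance = "condition")
  })
  names(stage_sets) <- stages
  global_set <- aggregate_maps(stage_sets, K, n_iter = mcfg$aggregate_n_iter,
                               seed = derive_seed(config$seed, "agg_global"),
                               provenance = "global")
  canon <- canonical_templates(cohort$montage)
  global_set <- assign_letters(global_set, canon)
  tick("aggregate", ts)

  # --- pass 2: backfit + parameters + per-stage GEV ------------------------
  ts <- Sys.time()
  rows <- list()
  gev_rows <- list()
  for (s in seq_len(n_sub)) {
    for (i in seq_len(nrow(plan))) {
      rec <- prep_session(cohort, s, i, config$preprocess)
      lab <- backfit(rec, global_set)
      p <- microstate_parameters(lab$labels, lab$fs, K)
      p$subject <- s; p$stage <- plan$stage[i]; p$session <- plan$session[i]
      rows[[length(rows) + 1L]] <- p
      g <- gfp(rec)
      pk <- find_gfp_peaks(g, mcfg$min_peak_distance)
      peak_rec <- recording(rec$data[, pk, drop = FALSE], rec$fs, rec$montage,
                            reference = "average")
      gev_rows[[length(gev_rows) + 1L]] <- data.frame(
        subject = s, stage = plan$stage[i], session = plan$session[i],
        gev_peaks = gev(peak_rec, backfit(peak_rec, global_set), global_set))
    }
  }
  parameter_table <- do.call(rbind, rows)
  parameter_table <- parameter_table[, c("subject", "stage", "session", "class",
                                         "coverage", "duration_ms", "occurrence")]
  summary_table <- summarize_parameters(parameter_table)
  gev_table <- do.call(rbind, gev_rows)
  stage_gev <- stats::aggregate(list(mean_gev = gev_table$gev_peaks),
                                by = list(stage = gev_table$stage), FUN = mean)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  stage_gev$se_gev <- stats::aggregate(list(se = gev_table$gev_peaks),
                                       by = list(stage = gev_table$stage),
                                       FUN = se)$se
  tick("backfit_parameters", ts)

  # --- statistics ----------------------------------------------------------
  ts <- Sys.time()
  anovas <- list()
  for (par in c("coverage", "duration_ms", "occurrence")) {
    dfp <- summary_table
    dfp$value <- dfp[[par]]
    anovas[[par]] <- rm_anova_2way(dfp, "value", "subject", "class", "stage")
  }
  ev <- cohort$evaluations
  anova_ev <- rm_anova_2way(ev, "score", "subject", "dimension", "stage")
  tt_ev <- do.call(rbind, lapply(sort(unique(ev$dimension)), function(dim) {
    sub <- ev[ev$dimension == dim, ]
    res <- paired_t_bonferroni(sub, "score", "subject", "stage",
                               family_size = 3)
    res$dimension <- dim
    res
  }))
  spear <- spearman_matrix(summary_table, ev, alpha = config$stats$alpha,
                           unit = config$stats$unit)
  tick("stats", ts)

  # --- write artifacts -----------------------------------------------------
  ts <- Sys.time()
  wcsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(x), p, row.names = FALSE)
    p
  }
  paths <- c(
    wcsv(data.frame(letter = global_set$letters, t(global_set$maps)),
         "global_maps.csv"),
    wcsv(parameter_table, "parameters.csv"),
    wcsv(summary_table, "parameter_summary.csv"),
    wcsv(stage_gev, "stage_gev.csv"),
    wcsv(anovas$coverage, "anova_coverage.csv"),
    wcsv(anovas$duration_ms, "anova_duration.csv"),
    wcsv(anovas$occurrence, "anova_occurrence.csv"),
    wcsv(anova_ev, "anova_evaluations.csv"),
    wcsv(tt_ev, "ttest_evaluations_stage.csv"),
    wcsv(spear, "spearman_heatmap.csv"),
    wcsv(ev, "evaluations.csv"))
  write_microstate_set(global_set, file.path(out_dir, "global_set.json"))
  paths <- c(paths, file.path(out_dir, "global_set.json"))
  yaml::write_yaml(config, file.path(out_dir, "config_echo.yaml"))
  paths <- c(paths, file.path(out_dir, "config_echo.yaml"))
  tick("write", ts)

  manifest <- list(
    package_version = as.character(utils::packageVersion("microflight")),
    r_version = R.version.string,
    seed = config$seed,
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    timings_s = timings,
    global_cv = global_set$cv,
    global_gev = global_set$gev,
    letters = global_set$letters,
    outputs = as.list(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
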