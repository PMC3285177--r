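# End-to-end orchestration: synthesize or read trials, preprocess, detect
# events, compute interception geometry, decompose submovements, classify,
# and fit the mixed models.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the task's standard
#' values as defaults: 0.05 m/s movement threshold, 100 ms minimal
#' submovement duration, R-squared threshold 0.99 with at most 6 components
#' and 20 restarts, arrival-height selection within 0.30 limb lengths of the
#' references (-0.11 low, 0.58 high), 25 Hz zero-phase FIR filtering of
#' 100 Hz data.
#'
#' @param ... Named overrides of the defaults.
#' @param yaml_file Optional YAML file of overrides (applied before `...`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(..., yaml_file = NULL) {
  cfg <- list(
    # preprocessing
    rate = 100, cutoff = 25, fir_order = 30,
    # events
    latency_threshold = 0.05, debounce = 0.05, prominence = 0.05,
    refine_impact = TRUE, extrapolate = 0.15,
    # geometry / selection
    references = c(low = -0.11, high = 0.58), selection_tolerance = 0.30,
    # submovements
    min_duration = 0.1, r2_threshold = 0.99, n_max = 6, restarts = 20,
    # models
    include_trial_glmm = TRUE, include_trial_lmm = FALSE,
    lmm_responses = c("tau_margin", "v_peak1", "interception_index",
                      "tC_minus_tB", "n_submovements"),
    # synthetic input
    n_subjects = 6, trials_per_condition = 10, noise_sd = 0.001,
    # run
    seed = 1L, input_dir = NULL, output_dir = NULL, decompose = TRUE)
  if (!is.null(yaml_file)) {
    over_yaml <- yaml::read_yaml(yaml_file)
    if (length(over_yaml)) cfg <- modifyList(cfg, over_yaml)
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) ck_stop(paste("unknown config fields:", paste(bad, collapse = ", ")),
                             "catchkin_invalid_parameter")
    cfg <- modifyList(cfg, over)
  }
  structure(cfg, class = "run_config")
}

#' Analyze one trial
#'
#' Runs the full per-trial chain: low-pass filtering, wrist velocity and
#' tangential speed, latency and impact detection, speed extrema and timing
#' parameters, anthropometry, normalized arrival height, interception-point
#' geometry, posture angles, trunk displacement, hand-ball coupling, and
#' (optionally) submovement decomposition with movement-type
#' classification.
#'
#' @param trial A `catch_trial`.
#' @param config A [run_config()].
#' @param seed Seed for the decomposition restarts.
#' @return A list with `summary` (one-row data frame), `events`, and
#'   `submovements` (a `submovement_set` or `NULL`).
#' @export
analyze_trial <- function(trial, config = run_config(), seed = config$seed) {
  filt <- lapply(trial$markers, lowpass_filter,
                 cutoff = config$cutoff, rate = trial$rate,
                 order = config$fir_order)
  rw <- (filt$RWRU + filt$RWRR) / 2
  vel <- differentiate(rw, rate = trial$rate)
  speed <- tangential_speed(vel, trial$times)
  launch <- trial$launch_time

  in_flight <- !is.na(trial$ball[, 1])
  if (sum(in_flight) < 4) ck_stop("too few ball samples", "catchkin_missing_data")
  bfilt <- lowpass_filter(trial$ball[in_flight, , drop = FALSE],
                          cutoff = config$cutoff, rate = trial$rate,
                          order = config$fir_order)
  ball <- ball_trajectory(trial$times[in_flight], bfilt)

  LT <- detect_latency(speed, launch, config$latency_threshold, config$debounce)
  IT <- detect_impact_time(ball, filt$RWRU, filt$RWRR, filt$RFRA, trial$times,
                           refine = config$refine_impact, search_from = launch)
  ext <- find_speed_extrema(speed, LT, IT, config$prominence)
  anthro <- compute_anthropometry(
    structure(list(times = trial$times, markers = filt), class = "catch_trial"),
    launch)
  events <- timing_parameters(c(list(LT = LT, IT = IT), ext), launch, ball,
                              plane3(anthro$shoulder, c(1, 0, 0)),
                              config$extrapolate)

  Zn <- normalized_arrival_height(ball, anthro$shoulder, anthro, config$extrapolate)
  geom <- tryCatch({
    reach <- first_reachable_point(ball, anthro$shoulder, anthro$limb_length)
    I <- interception_index(ball, events$t_C, events$t_B, reach$time)
    list(t_A = reach$time, I = as.numeric(I), clamped = attr(I, "clamped"))
  }, catchkin_error = function(e) list(t_A = NA_real_, I = NA_real_, clamped = NA))

  at_IT <- function(m) vapply(1:3, function(j) approx(trial$times, m[, j], IT)$y, 0)
  RSHO_it <- at_IT(filt$RSHO); RELB_it <- at_IT(filt$RELB)
  RWRU_it <- at_IT(filt$RWRU); RWRR_it <- at_IT(filt$RWRR)
  RW_it <- (RWRU_it + RWRR_it) / 2
  prono <- tryCatch(pronosupination_angle(RSHO_it, RELB_it, RW_it, RWRU_it, RWRR_it),
                    catchkin_error = function(e) NA_real_)
  elev <- tryCatch(elevation_angle(RELB_it, RW_it),
                   catchkin_error = function(e) NA_real_)
  i_launch <- which.min(abs(trial$times - launch))
  dsh <- shoulder_displacement(filt$RSHO[i_launch, ], RSHO_it)
  wrist_v_it <- vapply(1:3, function(j) approx(trial$times, vel[, j], IT)$y, 0)
  coupling <- hand_ball_coupling(wrist_v_it, ball_velocity_at(ball, IT))
  vel_at <- function(t) vapply(1:3, function(j) approx(trial$times, vel[, j], t)$y, 0)
  v_peak_xyz <- vel_at(events$t_peak1)
  v_trough_xyz <- if (!is.na(events$t_trough1)) vel_at(events$t_trough1) else rep(NA_real_, 3)

  sub <- NULL; n_sub <- NA_integer_; mtype <- NA_integer_; r2 <- NA_real_
  if (isTRUE(config$decompose)) {
    sub <- decompose(speed, LT, IT, seed = seed,
                     r2_threshold = config$r2_threshold, n_max = config$n_max,
                     restarts = config$restarts,
                     threshold = config$latency_threshold,
                     min_duration = config$min_duration)
    n_sub <- sub$N
    mtype <- as.integer(classify_movement(sub, events$t_trough1))
    r2 <- sub$r_squared
  }

  cond <- trial$condition
  summary <- data.frame(
    trial_id = trial$trial_id %||% NA_character_,
    subject = trial$subject %||% NA_character_,
    T = cond$T %||% NA_real_, Z = cond$Z %||% NA_real_,
    height = cond$height %||% NA_character_,
    label = cond$label %||% NA_character_,
    outcome = trial$outcome %||% NA_character_,
    LT = events$LT, IT = events$IT, MT = events$MT,
    flight_duration = events$flight_duration,
    t_peak1 = events$t_peak1, v_peak1 = events$v_peak1,
    t_trough1 = events$t_trough1, v_trough1 = events$v_trough1,
    tau_margin = events$tau_margin,
    t_C = events$t_C, tC_minus_tB = events$tC_minus_tB,
    Zn = Zn, t_A = geom$t_A, interception_index = geom$I,
    pronosupination = prono, elevation = elev,
    dSh_x = dsh[1], dSh_z = dsh[3],
    vx_peak = v_peak_xyz[1], vz_peak = v_peak_xyz[3],
    vx_trough = v_trough_xyz[1], vz_trough = v_trough_xyz[3],
    vx_IT = wrist_v_it[1], vz_IT = wrist_v_it[3],
    v_hand_z = coupling$v_hand_z, v_ball_z = coupling$v_ball_z,
    v_coupling_diff = coupling$difference,
    arm_length = anthro$arm_length, forearm_length = anthro$forearm_length,
    limb_length = anthro$limb_length,
    n_submovements = n_sub, movement_type = mtype, r_squared = r2)
  list(summary = summary, events = events, submovements = sub,
       anthropometry = anthro)
}

#' Trial table for the mixed models
#'
#' Adds the binary success indicator and keeps kinematic columns only for
#' selected trials (caught, arrival height within tolerance).
#'
#' @param summary The kinematic summary data frame from [run_pipeline()].
#' @param references,tolerance Selection rule, see [select_trials()].
#' @return A data frame with `Y`, `selected`, and masked kinematic columns.
#' @export
cohort_to_table <- function(summary, references = c(low = -0.11, high = 0.58),
                            tolerance = 0.30) {
  tab <- select_trials(summary, references, tolerance)
  tab$Y <- as.integer(tab$outcome == "caught")
  if (!"trial" %in% names(tab)) {
    tab$trial <- stats::ave(seq_len(nrow(tab)),
                            paste(tab$subject, tab$label), FUN = seq_along)
  }
  kin_cols <- setdiff(names(tab),
                      c("trial_id", "subject", "T", "Z", "height", "label",
                        "outcome", "Y", "trial", "selected", "exclusion_reason", "Zn"))
  for (cl in kin_cols) tab[[cl]][!tab$selected] <- NA
  tab
}

#' Submovement-count and movement-type frequencies
#'
#' @param summary The kinematic summary data frame.
#' @return A data frame per subject x condition with mean and sd of the
#'   number of submovements and the relative frequency of each movement
#'   type.
#' @export
type_frequency_table <- function(summary) {
  sel <- summary[!is.na(summary$n_submovements), , drop = FALSE]
  if (!nrow(sel)) return(data.frame())
  groups <- split(sel, list(sel$subject, sel$label), drop = TRUE)
  rows <- lapply(groups, function(g) {
    data.frame(subject = g$subject[1], label = g$label[1], n_trials = nrow(g),
               mean_n = mean(g$n_submovements), sd_n = sd(g$n_submovements),
               f_type1 = mean(g$movement_type == 1),
               f_type2 = mean(g$movement_type == 2),
               f_type3 = mean(g$movement_type == 3))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$subject, res$label), ]
}

#' Run the full pipeline
#'
#' Generates (or reads) trials, analyzes each one, selects trials, fits the
#' success GLMM and the kinematic LMMs, and writes all artifacts to the
#' output directory: `kinematic_summary.tsv`, `submovements.json`,
#' `type_frequency.tsv`, `model_comparisons.json`, `manifest.tsv` (+
#' `ledger.json` for synthetic cohorts), and `run_log.txt`. Per-trial errors
#' are recorded and do not stop the run; reruns with the same configuration
#' and seed reproduce the outputs exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `summary`, `table`, `models`,
#'   `type_frequencies`, `submovements`, `errors`, and `output_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  out_dir <- config$output_dir %||% tempfile("catchkin_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$input_dir)) {
    paths <- list.files(config$input_dir, pattern = "\\.(trc|csv)$",
                        ignore.case = TRUE, full.names = TRUE)
    trials <- list(); read_errors <- list()
    for (p in paths) {
      tr <- tryCatch(read_trial(p), error = function(e) e)
      if (inherits(tr, "error")) read_errors[[p]] <- conditionMessage(tr)
      else trials[[length(trials) + 1L]] <- tr
    }
    cohort <- NULL
  } else {
    cohort <- generate_cohort(config$n_subjects, config$trials_per_condition,
                              seed = config$seed, noise_sd = config$noise_sd)
    trials <- cohort$trials
    read_errors <- list()
  }

  summaries <- list(); subsets <- list(); errors <- read_errors
  for (i in seq_along(trials)) {
    res <- tryCatch(analyze_trial(trials[[i]], config, seed = config$seed + i),
                    error = function(e) e)
    id <- trials[[i]]$trial_id %||% sprintf("trial_%03d", i)
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
    } else {
      summaries[[length(summaries) + 1L]] <- res$summary
      if (!is.null(res$submovements)) {
        s <- res$submovements
        subsets[[length(subsets) + 1L]] <- list(
          trial_id = id, N = s$N, params = s$params, window = s$window,
          r_squared = s$r_squared, type = res$summary$movement_type,
          seed = s$seed)
      }
    }
  }
  if (!length(summaries)) ck_stop("no trial could be analyzed", "catchkin_fit_failure")
  summary <- do.call(rbind, summaries)

  table <- cohort_to_table(summary, config$references, config$selection_tolerance)
  models <- list()
  models$success <- tryCatch(
    fit_success_glmm(table, include_trial = config$include_trial_glmm),
    error = function(e) conditionMessage(e))
  for (resp in intersect(config$lmm_responses, names(table))) {
    models[[resp]] <- tryCatch(
      fit_kinematic_lmm(table[table$selected, , drop = FALSE], resp,
                        include_trial = config$include_trial_lmm),
      error = function(e) conditionMessage(e))
  }
  freq <- type_frequency_table(summary)

  write.table(format(summary, digits = 10, trim = TRUE, scientific = FALSE),
              file.path(out_dir, "kinematic_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(subsets, file.path(out_dir, "submovements.json"),
                       digits = NA, dataframe = "rows", auto_unbox = TRUE)
  if (nrow(freq)) {
    write.table(format(freq, digits = 8, trim = TRUE),
                file.path(out_dir, "type_frequency.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  comp <- lapply(models, function(m) {
    if (inherits(m, "model_comparison")) unclass(m) else list(error = m)
  })
  jsonlite::write_json(comp, file.path(out_dir, "model_comparisons.json"),
                       digits = NA, dataframe = "rows", auto_unbox = TRUE,
                       null = "null")
  if (!is.null(cohort)) write_cohort_manifest(cohort, out_dir)
  log_lines <- c(
    sprintf("catchkin run, seed %d", config$seed),
    sprintf("trials analyzed: %d / %d", nrow(summary), length(trials)),
    sprintf("trials selected: %d", sum(table$selected)),
    if (length(errors)) paste0("error [", names(errors), "]: ", unlist(errors)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(summary = summary, table = table, models = models,
                 type_frequencies = freq, submovements = subsets,
                 errors = errors, output_dir = out_dir, cohort = cohort))
}
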