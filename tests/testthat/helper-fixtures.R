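# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Calibrated launcher mapping under the default drag model.
cached_mapping <- function() memo("mapping", calibrate_launcher())

# Noiseless cohort: 6 subjects (two per archetype) x 1 trial x 6 conditions.
cached_cohort_noiseless <- function() {
  memo("cohort0", generate_cohort(6, 1, seed = 42, mapping = cached_mapping(),
                                  noise_sd = 0))
}

# Noisy cohort at the nominal 1 mm marker residual.
cached_cohort_noisy <- function() {
  memo("cohort1", generate_cohort(3, 2, seed = 7, mapping = cached_mapping(),
                                  noise_sd = 0.001))
}

analyze_all <- function(cohort, config) {
  out <- lapply(cohort$trials, function(tr) {
    tryCatch(analyze_trial(tr, config)$summary, error = function(e) NULL)
  })
  do.call(rbind, Filter(Negate(is.null), out))
}

cached_summary_noiseless <- function() {
  memo("summary0", analyze_all(cached_cohort_noiseless(),
                               run_config(decompose = FALSE, debounce = 0)))
}

# A sampled composite speed series from explicit submovement parameters.
speed_series_from <- function(params, t_end, rate = 100, pad = 0.2) {
  tt <- seq(0, t_end + pad, by = 1 / rate)
  structure(data.frame(time = tt, speed = composite_speed(params, tt)),
            class = c("speed_series", "data.frame"))
}

# Draw n noiseless archetype profiles (cycling type1/2/3) and decompose each;
# returns truth and recovered parameters for fidelity / recovery checks.
recovery_experiment <- function(n = 100, seed = 2024) {
  memo(paste0("recovery", n, "_", seed), {
    archetypes <- rep(c("type1", "type2", "type3"), length.out = n)
    rows <- vector("list", n)
    withr::with_seed(seed, {
      draws <- data.frame(IT = runif(n, 0.5, 0.68), LT = runif(n, 0.08, 0.16),
                          L = runif(n, 0.75, 0.95))
      seeds <- sample.int(2^30, n)
    })
    for (i in seq_len(n)) {
      s <- withr::with_seed(seeds[i],
        catchkin:::sample_submovement_set(archetypes[i], draws$LT[i],
                                          draws$IT[i], draws$L[i]))
      sp <- speed_series_from(s$params, s$t_end)
      LTd <- detect_latency(sp, 0, debounce = 0)
      dec <- decompose(sp, LTd, draws$IT[i], seed = seeds[i] %% 100000)
      k <- min(nrow(s$params), nrow(dec$params))
      rows[[i]] <- list(
        arch = archetypes[i], n_true = s$n, n_hat = dec$N,
        r2 = dec$r_squared,
        true = s$params, fitted = dec$params,
        rel_A = if (dec$N == s$n) abs(dec$params$A - s$params$A) / s$params$A,
        rel_D = if (dec$N == s$n) abs(dec$params$D - s$params$D) / s$params$D,
        abs_t0 = if (dec$N == s$n) abs(dec$params$t0 - s$params$t0))
    }
    rows
  })
}

# Simulated trial table with a planted subject random intercept, for the
# mixed-model verdict checks.
simulate_lmm_table <- function(sd_subject, sd_resid = 1, n_subjects = 6,
                               trials_per_subject = 60, seed = 1) {
  withr::with_seed(seed, {
    cond <- flight_conditions()
    d <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      k <- sample(nrow(cond), trials_per_subject, replace = TRUE)
      data.frame(subject = paste0("S", s), T = cond$T[k], Z = cond$Z[k],
                 trial = seq_len(trials_per_subject),
                 u = rnorm(1, 0, sd_subject))
    }))
    d$y <- 0.5 + 0.7 * d$T - 0.3 * d$Z + d$u + rnorm(nrow(d), 0, sd_resid)
    d$Y <- 1L
    d
  })
}

simulate_glmm_table <- function(sd_subject, beta_T = 7.51, beta_Z = -1.4,
                                n_subjects = 6, trials_per_subject = 60,
                                seed = 1) {
  withr::with_seed(seed, {
    cond <- flight_conditions()
    d <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      k <- sample(nrow(cond), trials_per_subject, replace = TRUE)
      data.frame(subject = paste0("S", s), T = cond$T[k], Z = cond$Z[k],
                 trial = seq_len(trials_per_subject),
                 u = rnorm(1, 0, sd_subject))
    }))
    d$Y <- rbinom(nrow(d), 1,
                  stats::plogis(1 + beta_T * (d$T - 0.65) +
                                  beta_Z * (d$Z - 1.6) + d$u))
    d
  })
}

# Rotation matrix about the vertical (z) axis.
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
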