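# Synthetic subjects: idiosyncratic wrist movements built from minimum-jerk
# submovements, embedded in a full upper-limb marker set at 100 Hz.
#
# Movement archetypes mirror the strategies seen across real catchers:
#   type1 - a direct reach, single-peaked speed (1 component) or a gently
#           decelerated approach (2 strongly overlapping components);
#   type2 - a transport submovement followed by a distinct corrective
#           submovement whose peak is timed onto the ball (the hand does not
#           stop at impact);
#   type3 - hook-like movements built from 3-4 components.

MARKER_NAMES <- c("C7", "CL", "SRN", "RSHO", "RELB", "RFRA", "RWRU", "RWRR")
STICK_LENGTH <- 0.21  # wrist stick with markers at both ends (m)

#' A synthetic subject profile
#'
#' Encodes the anthropometry and the idiosyncratic movement style of one
#' synthetic catcher: which submovement archetype the wrist speed follows,
#' where along the ball path the subject prefers to catch (the target
#' interception index), whether the trunk contributes, and the latency
#' distribution.
#'
#' @param id Subject identifier.
#' @param archetype Movement archetype, `"type1"`, `"type2"` or `"type3"`.
#' @param shoulder_height,arm_length,forearm_length Anthropometry (m).
#' @param catch_pref Preferred interception index in `[0, 1]`.
#' @param trunk_use Whether the shoulder translates during the catch.
#' @param latency_mean,latency_sd Latency distribution after launch (s).
#' @param pronosupination Habitual wrist pronosupination at impact (deg).
#' @param success_offset Subject offset on the logit scale of catch success.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(id = "S1",
                            archetype = c("type1", "type2", "type3"),
                            shoulder_height = 1.38, arm_length = 0.30,
                            forearm_length = 0.26, catch_pref = 0.55,
                            trunk_use = FALSE, latency_mean = 0.12,
                            latency_sd = 0.04, pronosupination = 75,
                            success_offset = 0) {
  archetype <- match.arg(archetype)
  if (catch_pref < 0 || catch_pref > 1) {
    ck_stop("'catch_pref' must be in [0, 1]", "catchkin_invalid_parameter")
  }
  structure(list(id = id, archetype = archetype,
                 shoulder_height = shoulder_height, arm_length = arm_length,
                 forearm_length = forearm_length, catch_pref = catch_pref,
                 trunk_use = trunk_use, latency_mean = latency_mean,
                 latency_sd = latency_sd, pronosupination = pronosupination,
                 success_offset = success_offset),
            class = "subject_profile")
}

# Archetype templates: onsets and durations as fractions of the movement
# span, amplitude weights summing to 1; max(onset + duration) = 1 so that
# the span maps the composite support exactly.
submovement_template <- function(archetype, n) {
  switch(paste0(archetype, "_", n),
    type1_1 = list(on = 0, D = 1, w = 1),
    type1_2 = list(on = c(0, 0.42), D = c(0.60, 0.58), w = c(0.68, 0.32)),
    type2_2 = list(on = c(0, 0.48), D = c(0.55, 0.52), w = c(0.55, 0.45)),
    type3_3 = list(on = c(0, 0.25, 0.62), D = c(0.40, 0.48, 0.38),
                   w = c(0.24, 0.42, 0.34)),
    type3_4 = list(on = c(0, 0.22, 0.50, 0.72), D = c(0.34, 0.44, 0.34, 0.28),
                   w = c(0.20, 0.32, 0.26, 0.22)),
    ck_stop(sprintf("no template for %s with %d components", archetype, n),
            "catchkin_invalid_parameter"))
}

# Draw a concrete submovement set for one trial. For stopping archetypes the
# composite support is [LT, IT]; for type2 the second component peaks at
# impact so the support extends past IT. Amplitudes are scaled so that the
# displacement accumulated by impact equals the wrist path length.
sample_submovement_set <- function(archetype, LT, IT, L_path, n = NULL,
                                   jitter = 0.025) {
  span_avail <- IT - LT
  if (is.null(n)) {
    n <- switch(archetype,
                type1 = if (runif(1) < 0.6) 1L else 2L,
                type2 = 2L,
                type3 = if (runif(1) < 0.7 || span_avail < 0.45 || L_path < 0.85) 3L else 4L)
  }
  if (archetype == "type3" && n == 4L && (span_avail < 0.45 || L_path < 0.85)) n <- 3L
  tpl <- submovement_template(archetype, n)
  S <- if (archetype == "type2") span_avail / 0.74 else span_avail
  on <- tpl$on + c(0, rnorm(n - 1, 0, jitter))
  D <- tpl$D * exp(rnorm(n, 0, 2 * jitter))
  w <- tpl$w * exp(rnorm(n, 0, 3 * jitter))
  w <- w / sum(w)
  t0 <- LT + sort(on) * S
  D_abs <- pmax(D * S, 0.105)
  t0 <- pmin(t0, IT - 0.105)
  params <- data.frame(A = w, D = D_abs, t0 = t0)
  # scale amplitudes: displacement accumulated by impact = path length
  tf <- seq(LT, IT, by = 1e-3)
  F_it <- pracma::trapz(tf, composite_speed(params, tf))
  params$A <- params$A * L_path / F_it
  low <- params$A < 0.11
  if (any(low) && !all(low)) {
    deficit <- sum(0.11 - params$A[low])
    params$A[low] <- 0.11
    params$A[!low] <- params$A[!low] * (1 - deficit / sum(params$A[!low]))
  }
  params$t_off <- params$t0 + params$D
  list(params = params, n = n, t_end = max(params$t_off),
       stops = archetype != "type2")
}

# Sampled composite speed profile on [0, t_end + pad] at the capture rate.
submovement_speed_series <- function(params, t_end, rate = 100, pad = 0.2) {
  tt <- seq(0, t_end + pad, by = 1 / rate)
  structure(data.frame(time = tt, speed = composite_speed(params, tt)),
            class = c("speed_series", "data.frame"))
}

# Cubic Bezier sampled at m points.
bezier_path <- function(P0, P1, P2, P3, m = 400) {
  u <- seq(0, 1, length.out = m)
  b <- cbind((1 - u)^3, 3 * u * (1 - u)^2, 3 * u^2 * (1 - u), u^3)
  b %*% rbind(P0, P1, P2, P3)
}

# Archetype-specific wrist path from rest posture to the impact point.
wrist_path <- function(archetype, W0, B, min_length = 0.72) {
  dvec <- B - W0
  dlen <- vnorm(dvec)
  b <- switch(archetype, type1 = 0.12, type2 = 0.18, type3 = 0.35) * max(dlen, 0.5)
  for (iter in 1:5) {
    ctrl <- switch(archetype,
      type1 = list(W0 + 0.33 * dvec + c(0, 0, b), W0 + 0.67 * dvec + c(0, 0, b)),
      type2 = list(W0 + 0.33 * dvec + c(0, 0, 0.3 * b), W0 + 0.70 * dvec - c(0, 0, b)),
      type3 = list(W0 + c(0.10 * dlen, 0, b), B + c(-0.10 * dlen, 0, 0.6 * b)))
    pts <- bezier_path(W0, ctrl[[1]], ctrl[[2]], B)
    seg <- sqrt(rowSums(diff(pts)^2))
    arc <- c(0, cumsum(seg))
    if (arc[length(arc)] >= min_length) break
    b <- b * 1.4
  }
  list(points = pts, arc = arc, length = arc[length(arc)],
       tangent = unitv(pts[nrow(pts), ] - pts[nrow(pts) - 1, ]))
}

# Position along a path at arc-length s; extends along the final tangent.
path_at_arc <- function(path, s) {
  s_in <- clamp(s, 0, path$length)
  p <- vapply(1:3, function(j) approx(path$arc, path$points[, j], xout = s_in)$y,
              numeric(length(s)))
  p <- matrix(p, ncol = 3)
  over <- s > path$length
  if (any(over)) {
    p[over, ] <- p[over, , drop = FALSE] +
      (s[over] - path$length) %o% path$tangent
  }
  p
}

# Minimum-jerk displacement shape (0 -> 1) between two times.
mj_shape <- function(t, t_from, t_to) {
  tau <- clamp((t - t_from) / (t_to - t_from), 0, 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Generate one synthetic catching trial
#'
#' Builds a full marker-set trial for one subject and one ball flight. The
#' wrist follows an archetype-specific curved path whose progression is
#' driven by a composite minimum-jerk speed profile; the impact point is the
#' ball position at the time where the subject's preferred interception
#' index falls along the reachable stretch of the ball path. Elbow position
#' comes from two-link inverse kinematics, the wrist-stick markers encode
#' the pronosupination angle, and trunk use translates the shoulder cluster.
#' Gaussian noise (default sd 1 mm, the typical motion-capture
#' reconstruction residual) is added per sample and axis.
#'
#' An unreachable ball yields a trial with `outcome = "missed"` (a generic
#' reach toward the closest approach point), never an error.
#'
#' @param profile A [subject_profile()].
#' @param ball A [ball_trajectory()] starting at launch (t = 0).
#' @param seed Integer seed; identical seeds give identical trials.
#' @param condition Optional row of [flight_conditions()] recorded as trial
#'   metadata.
#' @param outcome_target `"caught"`, `"touched"` or `"missed"`: the intended
#'   outcome (touched/missed displace the hand target off the ball).
#' @param noise_sd Marker noise sd (m); 0 for noiseless trials.
#' @param rate Capture rate (Hz).
#' @return An object of class `catch_trial`; the generation ground truth
#'   (events, submovement parameters, geometry) is stored in `$truth`.
#' @export
generate_wrist_movement <- function(profile, ball, seed = 1L,
                                    condition = NULL,
                                    outcome_target = "caught",
                                    noise_sd = 0.001, rate = 100) {
  withr::with_seed(seed, {
    a <- profile$arm_length; f <- profile$forearm_length
    S0 <- c(0, 0, profile$shoulder_height)
    L <- 1.2 * (a + f)
    geom <- tryCatch({
      cross <- evaluate_ball_at_plane(ball, plane3(S0, c(1, 0, 0)), 0.15)
      reach <- first_reachable_point(ball, S0, L)
      list(t_C = cross$time, t_A = reach$time)
    }, catchkin_error = function(e) NULL)

    reachable <- !is.null(geom)
    trunk <- c(0, 0, 0)
    if (profile$trunk_use) trunk <- c(0.05, 0, 0.03 * sample(c(-1, 1), 1))
    p_target <- clamp(profile$catch_pref + rnorm(1, 0, 0.03), 0.05, 0.9)

    if (reachable) {
      tt_arc <- seq(geom$t_A, geom$t_C, by = 1e-3)
      bp <- predict(ball, tt_arc, "position")
      cum <- c(0, cumsum(sqrt(diff(bp[, 1])^2 + diff(bp[, 3])^2)))
      total <- cum[length(cum)]
      pick_tB <- function(p) approx(cum, tt_arc, xout = (1 - p) * total)$y
      p_eff <- p_target
      t_B <- pick_tB(p_eff)
      B_ball <- ball_position_at(ball, t_B)
      # extend trunk forward, then retreat along the path, until reachable
      while (vnorm(B_ball - (S0 + trunk)) > 0.98 * (a + f) && trunk[1] < 0.15) {
        trunk[1] <- trunk[1] + 0.02
      }
      while (vnorm(B_ball - (S0 + trunk)) > 0.98 * (a + f) && p_eff > 0.08) {
        p_eff <- p_eff - 0.05
        t_B <- pick_tB(p_eff)
        B_ball <- ball_position_at(ball, t_B)
      }
      reachable <- vnorm(B_ball - (S0 + trunk)) <= 0.98 * (a + f)
    }
    if (!reachable) {
      # generic reach toward the closest approach of the ball path
      dmin <- which.min(sqrt(rowSums((ball$position -
        matrix(S0, nrow(ball$position), 3, byrow = TRUE))^2)))
      t_B <- ball$times[dmin]
      B_ball <- ball_position_at(ball, t_B)
      B_tgt <- S0 + 0.9 * (a + f) * unitv(B_ball - S0)
      p_eff <- NA_real_
    } else {
      B_tgt <- B_ball
      if (outcome_target == "touched") {
        B_tgt <- B_ball + runif(1, 0.08, 0.11) * random_offset_dir()
      } else if (outcome_target == "missed") {
        B_tgt <- B_ball + runif(1, 0.15, 0.25) * random_offset_dir()
      }
    }

    LT_nom <- clamp(rnorm(1, profile$latency_mean, profile$latency_sd), 0.06, 0.22)
    LT_nom <- min(LT_nom, t_B - 0.25)
    LT_nom <- max(LT_nom, 0.04)

    W0 <- S0 + c(0.10, 0.02, -0.95 * (a + f))
    path <- wrist_path(profile$archetype, W0, B_tgt)
    sub <- sample_submovement_set(profile$archetype, LT_nom, t_B, path$length)

    # displacement along the path driven by the composite speed profile
    t_fine <- seq(0, sub$t_end + 0.05, by = 1e-3)
    v_fine <- composite_speed(sub$params, t_fine)
    s_fine <- pracma::cumtrapz(t_fine, v_fine)[, 1]
    lt_true_i <- which(v_fine >= 0.05)
    LT_true <- if (length(lt_true_i)) t_fine[lt_true_i[1]] else NA_real_

    tt <- seq(-0.2, t_B + 0.2, by = 1 / rate)
    nfr <- length(tt)
    s_t <- approx(t_fine, s_fine, xout = tt, rule = 2)$y
    s_t[tt < 0] <- 0
    W <- path_at_arc(path, s_t)

    shoulder <- matrix(S0, nfr, 3, byrow = TRUE) +
      mj_shape(tt, LT_nom, t_B) %o% trunk
    theta <- deg2rad(clamp(profile$pronosupination + rnorm(1, 0, 5), 5, 175))

    markers <- setNames(vector("list", length(MARKER_NAMES)), MARKER_NAMES)
    for (nm in MARKER_NAMES) markers[[nm]] <- matrix(NA_real_, nfr, 3)
    markers$RSHO <- shoulder
    markers$C7 <- shoulder + matrix(c(-0.06, 0.12, 0.06), nfr, 3, byrow = TRUE)
    markers$CL <- shoulder + matrix(c(0.02, 0.12, 0.00), nfr, 3, byrow = TRUE)
    markers$SRN <- shoulder + matrix(c(0.03, 0.14, -0.06), nfr, 3, byrow = TRUE)
    for (i in seq_len(nfr)) {
      S <- shoulder[i, ]; Wp <- W[i, ]
      d <- clamp(vnorm(Wp - S), 0.25 * (a + f), 0.995 * (a + f))
      u <- unitv(Wp - S)
      e_ref <- c(0, 0, -1) - u * (-u[3])
      if (vnorm(e_ref) < 1e-6) e_ref <- c(1, 0, 0) - u * u[1]
      e <- unitv(e_ref)
      ca <- (a^2 + d^2 - f^2) / (2 * a * d)
      sa <- sqrt(max(0, 1 - ca^2))
      E <- S + a * (ca * u + sa * e)
      uf <- unitv(Wp - E)
      n_arm <- unitv(cross3(S - E, Wp - E))
      m <- cross3(n_arm, uf)
      stick <- cos(theta) * n_arm + sin(theta) * m
      markers$RELB[i, ] <- E
      markers$RFRA[i, ] <- E + 0.55 * (Wp - E) + 0.025 * n_arm
      markers$RWRU[i, ] <- Wp - STICK_LENGTH / 2 * stick
      markers$RWRR[i, ] <- Wp + STICK_LENGTH / 2 * stick
    }

    ball_xyz <- matrix(NA_real_, nfr, 3)
    in_flight <- tt >= 0 & tt <= max(ball$times)
    ball_xyz[in_flight, ] <- predict(ball, tt[in_flight], "position")

    if (noise_sd > 0) {
      for (nm in MARKER_NAMES) {
        markers[[nm]] <- markers[[nm]] + matrix(rnorm(3 * nfr, 0, noise_sd), nfr, 3)
      }
      ball_xyz[in_flight, ] <- ball_xyz[in_flight, ] +
        matrix(rnorm(3 * sum(in_flight), 0, noise_sd), sum(in_flight), 3)
    }

    miss_dist <- vnorm(B_tgt - B_ball)
    outcome <- if (!reachable) "missed"
      else if (miss_dist < 0.065) "caught"
      else if (miss_dist < 0.125) "touched"
      else "missed"

    structure(list(
      times = tt, rate = rate, markers = markers, ball = ball_xyz,
      launch_time = 0, condition = condition, outcome = outcome,
      subject = profile$id, trial_id = NA_character_,
      truth = list(LT = LT_true, onset = LT_nom, IT = t_B,
                   submovements = sub$params, N = sub$n, stops = sub$stops,
                   t_end = sub$t_end, path_length = path$length,
                   p_target = p_target, p_effective = p_eff,
                   t_A = if (reachable) geom$t_A else NA_real_,
                   t_C = if (reachable) geom$t_C else NA_real_,
                   trunk = trunk, pronosupination = rad2deg(theta),
                   impact_point = B_tgt, miss_distance = miss_dist,
                   outcome = outcome, seed = seed)),
      class = "catch_trial")
  })
}

random_offset_dir <- function() {
  v <- rnorm(3)
  v[1] <- 0.3 * v[1]  # displace mostly off the flight axis
  unitv(v)
}

#' @export
print.catch_trial <- function(x, ...) {
  cat(sprintf("<catch_trial> subject %s, %s, %d frames at %g Hz, outcome %s\n",
              x$subject,
              if (!is.null(x$condition)) x$condition$label else "no condition",
              length(x$times), x$rate, x$outcome))
  invisible(x)
}

#' Generate a synthetic cohort of catching trials
#'
#' Subjects cycle through the three movement archetypes with individual
#' anthropometry, catch-zone preference, latency and posture draws. Each
#' trial simulates a drag-affected launch for its condition (with small
#' launch-to-launch jitter), samples the intended outcome from a logistic
#' success model with condition fixed effects and a per-subject random
#' intercept, and generates the full marker trial. A ground-truth ledger
#' (events, submovement parameters, outcomes) accompanies the trials for
#' recovery testing.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param trials_per_condition Trials per subject and condition (>= 1).
#' @param conditions A data frame of flight conditions, see
#'   [flight_conditions()].
#' @param seed Integer seed for the whole cohort.
#' @param mapping Optional pre-computed [calibrate_launcher()] mapping.
#' @param drag A [drag_params()] object.
#' @param noise_sd Marker noise sd (m).
#' @param success Logistic success model: `intercept`, `beta_T` (per s),
#'   `beta_Z` (per m), `sd_subject` (random-intercept sd, logit scale).
#'   Defaults encode that success increases with flight time and decreases
#'   with arrival height.
#' @return An object of class `catch_cohort`: `trials` (list of
#'   `catch_trial`), `ledger` (`$trials` data frame and `$submovements`
#'   long data frame), `subjects`, and the launcher `mapping`.
#' @export
generate_cohort <- function(n_subjects, trials_per_condition,
                            conditions = flight_conditions(), seed = 1L,
                            mapping = NULL, drag = drag_params(),
                            noise_sd = 0.001,
                            success = list(intercept = 1.6, beta_T = 7.51,
                                           beta_Z = -1.4, sd_subject = 0.7)) {
  if (n_subjects < 1 || trials_per_condition < 1) {
    ck_stop("'n_subjects' and 'trials_per_condition' must be >= 1", "catchkin_invalid_parameter")
  }
  if (is.null(conditions) || nrow(conditions) == 0) {
    ck_stop("'conditions' must contain at least one (T, Z) condition", "catchkin_invalid_parameter")
  }
  if (is.null(conditions$height)) {
    conditions$height <- c("low", "high")[1 + (conditions$Z > stats::median(conditions$Z))]
  }
  if (is.null(conditions$label)) {
    conditions$label <- paste0("T", conditions$T, "Z", conditions$Z)
  }
  withr::with_seed(seed, {
    if (is.null(mapping)) mapping <- calibrate_launcher(drag)
    archetypes <- rep(c("type1", "type2", "type3"), length.out = n_subjects)
    subjects <- lapply(seq_len(n_subjects), function(s) {
      subject_profile(
        id = sprintf("S%d", s),
        archetype = archetypes[s],
        shoulder_height = rnorm(1, 1.38, 0.04),
        arm_length = rnorm(1, 0.30, 0.015),
        forearm_length = rnorm(1, 0.26, 0.012),
        catch_pref = runif(1, 0.45, 0.70),
        trunk_use = if (archetypes[s] == "type3") TRUE else runif(1) < 0.3,
        latency_mean = clamp(rnorm(1, 0.12, 0.02), 0.08, 0.18),
        latency_sd = 0.03,
        pronosupination = runif(1, 40, 110),
        success_offset = rnorm(1, 0, success$sd_subject))
    })
    launches <- lapply(seq_len(nrow(conditions)), function(i) {
      launch_for_condition(mapping, conditions$T[i], conditions$Z[i])
    })
    trials <- list()
    rows <- list()
    subrows <- list()
    k <- 0L
    for (s in seq_len(n_subjects)) {
      prof <- subjects[[s]]
      for (ci in seq_len(nrow(conditions))) {
        lc <- launches[[ci]]
        cond <- as.list(conditions[ci, ])
        for (tr in seq_len(trials_per_condition)) {
          k <- k + 1L
          sp <- lc$speed + rnorm(1, 0, 0.05)
          an <- lc$angle + rnorm(1, 0, 0.2)
          fl <- launch_flight(sp, an, drag, mapping$d, lc$height)
          p_succ <- stats::plogis(success$intercept +
                                    success$beta_T * (cond$T - 0.65) +
                                    success$beta_Z * (cond$Z - 1.6) +
                                    prof$success_offset)
          tgt <- if (runif(1) < p_succ) "caught" else
            sample(c("touched", "missed"), 1)
          trial_seed <- sample.int(2^30, 1)
          trial <- generate_wrist_movement(prof, fl, seed = trial_seed,
                                           condition = cond,
                                           outcome_target = tgt,
                                           noise_sd = noise_sd)
          trial$trial_id <- sprintf("%s_%s_t%02d", prof$id, cond$label, tr)
          trials[[k]] <- trial
          tru <- trial$truth
          rows[[k]] <- data.frame(
            trial_id = trial$trial_id, subject = prof$id,
            archetype = prof$archetype, T = cond$T, Z = cond$Z,
            height = cond$height, label = cond$label, trial = tr,
            outcome = trial$outcome, LT = tru$LT, onset = tru$onset,
            IT = tru$IT, N = tru$N, p_target = tru$p_target,
            p_effective = tru$p_effective, path_length = tru$path_length,
            trunk_use = prof$trunk_use, speed = sp, angle = an,
            seed = trial_seed)
          subrows[[k]] <- data.frame(
            trial_id = trial$trial_id, k = seq_len(nrow(tru$submovements)),
            A = tru$submovements$A, D = tru$submovements$D,
            t0 = tru$submovements$t0)
        }
      }
    }
    structure(list(trials = trials,
                   ledger = list(trials = do.call(rbind, rows),
                                 submovements = do.call(rbind, subrows)),
                   subjects = subjects, conditions = conditions,
                   mapping = mapping, seed = seed),
              class = "catch_cohort")
  })
}

#' @export
print.catch_cohort <- function(x, ...) {
  cat(sprintf("<catch_cohort> %d subjects x %d trials (%d caught)\n",
              length(x$subjects), length(x$trials),
              sum(x$ledger$trials$outcome == "caught")))
  invisible(x)
}
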