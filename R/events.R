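# Temporal landmarks of a trial: latency, impact, speed extrema, timing.

#' Movement latency time
#'
#' First time at or after launch at which the wrist tangential speed reaches
#' the movement threshold and stays at or above it for the debounce interval
#' (rejecting isolated noise spikes).
#'
#' @param speed A `speed_series`.
#' @param launch Launch time (s).
#' @param threshold Movement threshold (m/s).
#' @param debounce Minimum dwell above threshold (s); 0 disables debouncing.
#' @param relative If `TRUE`, report the latency relative to launch.
#' @return Latency time (s).
#' @export
detect_latency <- function(speed, launch = 0, threshold = 0.05,
                           debounce = 0.05, relative = FALSE) {
  if (min(speed$time) > launch + 1e-9) {
    ck_stop("speed series must start at or before launch", "catchkin_invalid_parameter")
  }
  idx <- which(speed$time >= launch - 1e-9 & speed$speed >= threshold)
  for (i in idx) {
    dwell <- speed$speed[speed$time >= speed$time[i] &
                           speed$time <= speed$time[i] + debounce + 1e-9]
    if (all(dwell >= threshold)) {
      lt <- speed$time[i]
      return(if (relative) lt - launch else lt)
    }
  }
  ck_stop("wrist speed never crosses the movement threshold", "catchkin_no_movement")
}

# Hand plane from the two wrist-stick markers and the forearm marker, per
# frame; returns |signed distance| of the synchronous ball position.
hand_plane_distance <- function(ball_pos, RWRU, RWRR, RFRA) {
  n <- nrow(ball_pos)
  d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (anyNA(ball_pos[i, ])) next
    nrm <- cross3(RWRR[i, ] - RWRU[i, ], RFRA[i, ] - RWRU[i, ])
    len <- vnorm(nrm)
    if (len < 1e-9) {
      ck_stop("wrist/forearm markers are collinear at a candidate frame",
              "catchkin_degenerate_plane")
    }
    d[i] <- abs(sum((ball_pos[i, ] - RWRU[i, ]) * nrm / len))
  }
  d
}

#' Impact time
#'
#' Time at which the distance between the ball and the plane through the two
#' wrist-stick markers and the forearm marker is minimal. The discrete
#' minimum is optionally refined by quadratic interpolation of the distance
#' over the three samples around it; ties break to the earliest frame.
#'
#' Because the hand plane is unbounded, its distance to the ball can have
#' incidental minima while the ball is still far away; candidate frames are
#' therefore gated to those where the ball lies within `max_wrist_distance`
#' of the wrist midpoint (set to `Inf` to disable the gate).
#'
#' @param ball A [ball_trajectory()].
#' @param RWRU,RWRR,RFRA n x 3 marker position matrices on the trial time base.
#' @param times Marker sample times (s).
#' @param refine Apply quadratic sub-sample refinement.
#' @param search_from Ignore frames before this time (s).
#' @param max_wrist_distance Proximity gate around the wrist midpoint (m).
#' @return Impact time (s).
#' @export
detect_impact_time <- function(ball, RWRU, RWRR, RFRA, times,
                               refine = TRUE, search_from = -Inf,
                               max_wrist_distance = 0.5) {
  keep <- times >= search_from & times >= min(ball$times) - 1e-9 &
    times <= max(ball$times) + 1e-9
  if (!any(keep)) ck_stop("no frames overlap the ball flight", "catchkin_length")
  tt <- times[keep]
  bp <- predict(ball, tt, "position")
  d <- hand_plane_distance(bp, RWRU[keep, , drop = FALSE],
                           RWRR[keep, , drop = FALSE],
                           RFRA[keep, , drop = FALSE])
  rw <- (RWRU[keep, , drop = FALSE] + RWRR[keep, , drop = FALSE]) / 2
  wrist_dist <- sqrt(rowSums((bp - rw)^2))
  cand <- seq_along(d)
  for (gate in c(max_wrist_distance / 2.5, max_wrist_distance)) {
    near <- which(wrist_dist <= gate & !is.na(d))
    if (length(near)) { cand <- near; break }
  }
  dmin <- min(d[cand], na.rm = TRUE)
  i <- cand[which(d[cand] <= dmin + 1e-6)[1]]  # flat minima: earliest frame
  it <- tt[i]
  if (refine && i > 1 && i < length(d) && !anyNA(d[(i - 1):(i + 1)])) {
    y <- d[(i - 1):(i + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom > 1e-12) {
      delta <- 0.5 * (y[1] - y[3]) / denom
      if (abs(delta) <= 1) it <- it + delta * (tt[i + 1] - tt[i])
    }
  }
  it
}

# Prominence of a local maximum at index i: height above the higher of the
# two minima separating it from higher terrain (or the window edge).
peak_prominence <- function(s, i) {
  left <- s[seq_len(i - 1)]
  right <- s[seq(i + 1, length(s))]
  higher_l <- which(left > s[i])
  ml <- min(if (length(higher_l)) left[(max(higher_l) + 1):(i - 1)] else left)
  higher_r <- which(right > s[i])
  mr <- min(if (length(higher_r)) right[seq_len(min(higher_r) - 1)] else right)
  s[i] - max(ml, mr)
}

#' First speed peak and trough within the movement
#'
#' Finds the first local maximum of the wrist tangential speed after movement
#' onset with prominence at least `prominence`, and the first local minimum
#' after that peak and before impact. The trough may be absent (single-peak
#' profiles). If no interior local maximum exists, the global maximum over
#' the window is returned and flagged.
#'
#' @param speed A `speed_series`.
#' @param LT Movement onset (s).
#' @param IT Impact time (s).
#' @param prominence Minimum peak prominence (m/s).
#' @return A list with `t_peak1`, `v_peak1`, `t_trough1`, `v_trough1`
#'   (trough entries `NA` when absent) and `peak_flagged`.
#' @export
find_speed_extrema <- function(speed, LT, IT, prominence = 0.05) {
  if (LT >= IT) ck_stop("'LT' must precede 'IT'", "catchkin_invalid_parameter")
  sel <- which(speed$time >= LT - 1e-9 & speed$time <= IT + 1e-9)
  if (length(sel) < 5) ck_stop("need at least 5 samples in [LT, IT]", "catchkin_length")
  tt <- speed$time[sel]; s <- speed$speed[sel]
  n <- length(s)
  interior <- 2:(n - 1)
  is_max <- s[interior] > s[interior - 1] & s[interior] >= s[interior + 1]
  peaks <- interior[is_max]
  peaks <- peaks[vapply(peaks, function(i) peak_prominence(s, i), numeric(1)) >= prominence]
  flagged <- length(peaks) == 0
  if (flagged) {
    ip <- which.max(s)
  } else {
    ip <- peaks[1]
  }
  out <- list(t_peak1 = tt[ip], v_peak1 = s[ip],
              t_trough1 = NA_real_, v_trough1 = NA_real_,
              peak_flagged = flagged)
  if (ip < n - 1) {
    after <- (ip + 1):(n - 1)
    is_min <- s[after] < s[after - 1] & s[after] <= s[after + 1]
    troughs <- after[is_min]
    troughs <- troughs[vapply(troughs, function(i) peak_prominence(-s, i), numeric(1)) >= prominence]
    if (length(troughs)) {
      out$t_trough1 <- tt[troughs[1]]
      out$v_trough1 <- s[troughs[1]]
    }
  }
  out
}

#' Derived timing parameters of a trial
#'
#' Fills the tau-margin (interval between the first speed peak and impact),
#' the movement time `MT = IT - LT`, the flight duration `IT - launch`, and
#' the extrapolated arrival time of the ball at the frontal plane through the
#' shoulder at launch (`t_C`), reported against the impact time `t_B = IT`.
#'
#' @param events A list with at least `LT`, `IT`, `t_peak1` (s).
#' @param launch Launch time (s).
#' @param ball A [ball_trajectory()].
#' @param frontal_plane A [plane3()] through the shoulder at launch.
#' @param extrapolate Extrapolation limit for the frontal-plane crossing (s).
#' @return The events list completed with `MT`, `tau_margin`,
#'   `flight_duration`, `t_B`, `t_C`, and `tC_minus_tB`.
#' @export
timing_parameters <- function(events, launch, ball, frontal_plane,
                              extrapolate = 0.15) {
  for (nm in c("LT", "IT", "t_peak1")) {
    if (is.null(events[[nm]])) ck_stop(sprintf("'%s' missing from events", nm), "catchkin_invalid_parameter")
  }
  events$MT <- events$IT - events$LT
  events$tau_margin <- events$IT - events$t_peak1
  events$flight_duration <- events$IT - launch
  events$t_B <- events$IT
  crossing <- evaluate_ball_at_plane(ball, frontal_plane, extrapolate)
  events$t_C <- crossing$time
  events$tC_minus_tB <- events$t_C - events$t_B
  events
}
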