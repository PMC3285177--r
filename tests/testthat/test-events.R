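mk_speed <- function(tt, sp) {
  structure(data.frame(time = tt, speed = sp),
            class = c("speed_series", "data.frame"))
}

test_that("latency is the first sustained crossing of the movement threshold", {
  tt <- seq(0, 1, by = 0.01)
  # speed(t) = t crosses 0.05 m/s at t = 0.05 and stays above
  expect_equal(detect_latency(mk_speed(tt, tt), launch = 0), 0.05)
  # never crosses -> no-movement error
  expect_error(detect_latency(mk_speed(tt, rep(0.01, length(tt)))),
               class = "catchkin_no_movement")
  # a 10 ms spike above threshold before true onset is rejected by debouncing
  sp <- rep(0.01, length(tt))
  sp[21] <- 0.2                 # isolated spike at t = 0.20
  sp[tt >= 0.5] <- 1            # true onset at t = 0.50
  expect_equal(detect_latency(mk_speed(tt, sp)), 0.5)
  expect_equal(detect_latency(mk_speed(tt, sp), debounce = 0), 0.2)
  # launch-relative reporting
  expect_equal(detect_latency(mk_speed(tt, tt), launch = 0.02, relative = TRUE),
               0.05 - 0.02)
})

static_hand <- function(tt, origin = c(0.4, 0, 1.3)) {
  n <- length(tt)
  ones <- function(v) matrix(v, n, 3, byrow = TRUE)
  list(RWRU = ones(origin + c(0, -0.105, 0)),
       RWRR = ones(origin + c(0, 0.105, 0)),
       RFRA = ones(origin + c(0.15, 0, 0)))  # hand plane horizontal at z = origin[3]
}

test_that("impact is the minimum ball distance to the wrist/forearm plane", {
  tt <- seq(0, 1, by = 0.01)
  h <- static_hand(tt)
  # ball passes exactly through the hand plane (and the wrist) at t = 0.4
  pos <- cbind(0.4 + 0 * tt, 0 * tt, 1.3 + 2 * (tt - 0.4))
  ball <- ball_trajectory(tt, pos)
  it <- detect_impact_time(ball, h$RWRU, h$RWRR, h$RFRA, tt)
  expect_equal(it, 0.4, tolerance = 1e-6)
  # path parallel to the plane at a constant offset: flat minimum, earliest
  pos2 <- cbind(0.4 + 0.2 * tt, 0 * tt, 1.35 + 0 * tt)  # constant 5 cm above the plane
  ball2 <- ball_trajectory(tt, pos2)
  it2 <- detect_impact_time(ball2, h$RWRU, h$RWRR, h$RFRA, tt, refine = FALSE)
  expect_equal(it2, 0)
  # collinear markers make the plane degenerate
  bad <- h
  bad$RFRA <- (bad$RWRU + bad$RWRR) / 2
  expect_error(detect_impact_time(ball, bad$RWRU, bad$RWRR, bad$RFRA, tt),
               class = "catchkin_degenerate_plane")
})

test_that("impact recovery on synthetic trials is within 10 ms of the ledger", {
  coh <- cached_cohort_noiseless()
  led <- coh$ledger$trials
  sm <- cached_summary_noiseless()
  m <- merge(sm, led[, c("trial_id", "IT", "LT")], by = "trial_id",
             suffixes = c("", ".true"))
  caught <- m[m$outcome == "caught", ]
  expect_gt(nrow(caught), 10)
  expect_true(all(abs(caught$IT - caught$IT.true) < 0.010))
  # latency within one sample of the ledger onset-crossing
  expect_true(all(abs(caught$LT - caught$LT.true) <= 0.010 + 1e-9))
})

test_that("speed extrema: first prominent peak, then first trough before impact", {
  tt <- seq(0, 0.8, by = 0.01)
  # single minimum-jerk bump peaks at mid-duration with no trough
  one <- mk_speed(tt, minimum_jerk_speed(1, 0.6, 0, tt))
  ex <- find_speed_extrema(one, LT = 0.02, IT = 0.6)
  expect_equal(ex$t_peak1, 0.3)
  expect_equal(ex$v_peak1, 1.875 / 0.6, tolerance = 1e-3)
  expect_true(is.na(ex$t_trough1))
  expect_false(ex$peak_flagged)
  # two separated bumps: trough at the numeric inter-bump minimum
  pars <- data.frame(A = c(0.5, 0.4), D = c(0.3, 0.3), t0 = c(0.05, 0.45))
  two <- mk_speed(tt, composite_speed(pars, tt))
  ex2 <- find_speed_extrema(two, LT = 0.05, IT = 0.75)
  opt <- optimize(function(t) composite_speed(pars, t), c(0.2, 0.45))
  expect_lt(abs(ex2$t_trough1 - opt$minimum), 0.011)
  expect_equal(ex2$t_peak1, 0.2, tolerance = 0.011)
  # monotone ramp: no interior extremum, flagged global maximum at window end
  ramp <- mk_speed(tt, tt)
  ex3 <- find_speed_extrema(ramp, LT = 0.05, IT = 0.6)
  expect_true(ex3$peak_flagged)
  expect_equal(ex3$t_peak1, 0.6)
})

test_that("timing parameters compose correctly", {
  tt <- seq(0, 1, by = 0.01)
  pos <- cbind(2 - 4 * tt, 0 * tt, 1.4 + 0 * tt)
  ball <- ball_trajectory(tt, pos)
  frontal <- plane3(c(0, 0, 1.4), c(1, 0, 0))
  ev <- timing_parameters(list(LT = 0.10, IT = 0.52, t_peak1 = 0.30),
                          launch = 0, ball = ball, frontal_plane = frontal)
  expect_equal(ev$tau_margin, 0.22)
  expect_equal(ev$MT, 0.42)
  expect_equal(ev$flight_duration, 0.52)
  expect_equal(ev$t_C, 0.5, tolerance = 1e-9)
  expect_equal(ev$tC_minus_tB, 0.5 - 0.52)
  # intercepting exactly on the frontal plane gives t_C - t_B = 0
  ev0 <- timing_parameters(list(LT = 0.10, IT = 0.5, t_peak1 = 0.30),
                           launch = 0, ball = ball, frontal_plane = frontal)
  expect_equal(ev0$tC_minus_tB, 0, tolerance = 1e-9)
  # identity tau_margin + (t_peak1 - LT) = MT holds by construction
  expect_equal(ev$tau_margin + (ev$t_peak1 - ev$LT), ev$MT)
  # no crossing propagates
  expect_error(
    timing_parameters(list(LT = 0.1, IT = 0.5, t_peak1 = 0.3), 0, ball,
                      plane3(c(0, 0, 5), c(0, 0, 1))),
    class = "catchkin_no_crossing")
})
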