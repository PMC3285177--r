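# A minimal static trial: all markers constant, ball flying past.
toy_trial <- function(RSHO = c(0, 0, 1.4), RELB = c(0.1, 0, 1.15),
                      RW = c(0.2, 0, 0.95), n = 50) {
  ones <- function(v) matrix(v, n, 3, byrow = TRUE)
  structure(list(
    times = seq(0, by = 0.01, length.out = n),
    markers = list(RSHO = ones(RSHO), RELB = ones(RELB),
                   RWRU = ones(RW + c(0, -0.105, 0)),
                   RWRR = ones(RW + c(0, 0.105, 0)))),
    class = "catch_trial")
}

test_that("anthropometry comes from launch-frame marker distances", {
  tr <- toy_trial()
  an <- compute_anthropometry(tr, launch = 0)
  arm <- sqrt(0.1^2 + 0.25^2)
  fore <- sqrt(0.1^2 + 0.2^2)
  expect_equal(an$arm_length, arm)
  expect_equal(an$forearm_length, fore)
  expect_equal(an$limb_length, 1.2 * (arm + fore))
  expect_equal(an$shoulder_height, 1.4)
  # 0.30 + 0.25 arm/forearm gives the textbook 0.66 limb length
  tr2 <- toy_trial(RSHO = c(0, 0, 1.4), RELB = c(0, 0, 1.10), RW = c(0, 0, 0.85))
  expect_equal(compute_anthropometry(tr2)$limb_length, 1.2 * 0.55)
  # wrist is the exact stick midpoint
  i <- 1
  rw <- (tr$markers$RWRU[i, ] + tr$markers$RWRR[i, ]) / 2
  expect_equal(rw, c(0.2, 0, 0.95))
  tr$markers$RSHO[1, ] <- NA
  expect_error(compute_anthropometry(tr), class = "catchkin_missing_data")
})

test_that("anthropometry recovery from noisy synthetic trials is millimetric", {
  coh <- cached_cohort_noisy()
  for (i in seq_len(3)) {
    tr <- coh$trials[[i]]
    prof <- coh$subjects[[match(tr$subject, vapply(coh$subjects, `[[`, "", "id"))]]
    an <- compute_anthropometry(tr, launch = 0)
    expect_lt(abs(an$arm_length - prof$arm_length), 0.005)
    expect_lt(abs(an$forearm_length - prof$forearm_length), 0.005)
  }
})

straight_ball <- function(z = 1.4, v = -5, x0 = 5, n = 150) {
  tt <- seq(0, by = 0.01, length.out = n)
  ball_trajectory(tt, cbind(x0 + v * tt, 0 * tt, z + 0 * tt))
}

test_that("normalized arrival height is shoulder-referenced in limb units", {
  an <- structure(list(limb_length = 0.66, shoulder_height = 1.4,
                       shoulder = c(0, 0, 1.4)), class = "anthropometry")
  # arrival exactly at shoulder height
  expect_equal(normalized_arrival_height(straight_ball(z = 1.4), c(0, 0, 1.4), an), 0)
  # arrival 0.33 m above the shoulder with limb 0.66 -> Zn = 0.5
  expect_equal(normalized_arrival_height(straight_ball(z = 1.73), c(0, 0, 1.4), an),
               0.33 / 0.66, tolerance = 1e-9)
})

test_that("low-condition synthetic cohorts center near the printed reference height", {
  sm <- cached_summary_noiseless()
  low <- sm$Zn[sm$height == "low"]
  expect_gt(length(low), 5)
  expect_lt(abs(mean(low) - (-0.11)), 0.10)
})

test_that("trial selection keeps caught trials near the reference heights", {
  trials <- data.frame(
    Zn = c(-0.11, 0.25, -0.11, 0.58, 0.30, NA),
    outcome = c("caught", "caught", "touched", "caught", "caught", "caught"),
    height = c("low", "low", "low", "high", "high", "low"))
  sel <- suppressWarnings(select_trials(trials))
  expect_identical(sel$selected, c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_identical(sel$exclusion_reason[2], "height_outside_range")
  expect_identical(sel$exclusion_reason[3], "not_caught")
})

test_that("first reachable point is the earliest circle intersection", {
  # horizontal path at shoulder height: A at limb length from the shoulder
  ball <- straight_ball(z = 1.4, v = -5, x0 = 5)
  A <- first_reachable_point(ball, c(0, 0, 1.4), 0.7)
  expect_equal(unname(A$point["x"]), 0.7, tolerance = 1e-6)
  expect_equal(A$time, (5 - 0.7) / 5, tolerance = 1e-6)
  # tangent path: single tangency point
  ballt <- straight_ball(z = 1.4 + 0.7, v = -5, x0 = 5)
  At <- first_reachable_point(ballt, c(0, 0, 1.4), 0.7)
  expect_equal(unname(At$point["x"]), 0, tolerance = 1e-3)
  # unreachable path
  expect_error(first_reachable_point(straight_ball(z = 3), c(0, 0, 1.4), 0.7),
               class = "catchkin_unreachable")
  # drag-free parabola: compare against the closed-form circle intersection
  fl <- simulate_ball_flight(c(6, 0, 1.66), c(-9, 0, 2.5),
                             drag_params(drag_coefficient = 0))
  sho <- c(0, 0, 1.3)
  Ap <- first_reachable_point(fl, sho, 0.7)
  froot <- function(t) {
    p <- c(6 - 9 * t, 1.66 + 2.5 * t - 0.5 * 9.81 * t^2)
    sqrt((p[1] - sho[1])^2 + (p[2] - sho[3])^2) - 0.7
  }
  t_cf <- uniroot(froot, c(0.3, max(fl$times)))$root
  expect_equal(Ap$time, t_cf, tolerance = 1e-4)
})

test_that("interception index endpoints, midpoint and brute-force arc lengths agree", {
  # straight-line path at shoulder height through the shoulder
  ball <- straight_ball(z = 1.4, v = -5, x0 = 5)
  sho <- c(0, 0, 1.4)
  A <- first_reachable_point(ball, sho, 0.7)
  tC <- evaluate_ball_at_plane(ball, plane3(sho, c(1, 0, 0)))$time
  expect_equal(as.numeric(interception_index(ball, tC, tC, A$time)), 0)
  expect_equal(as.numeric(interception_index(ball, tC, A$time, A$time)), 1)
  # impact 0.35 m beyond the frontal plane, limb 0.7 -> I = 0.5
  tB <- (5 - 0.35) / 5
  expect_equal(as.numeric(interception_index(ball, tC, tB, A$time)), 0.5,
               tolerance = 1e-4)
  # curved path: 1 ms piecewise-linear arc length vs dense brute force
  tt <- seq(0, 1.2, by = 0.01)
  pos <- cbind(4 - 4 * tt, 0 * tt, 1.2 + 1.5 * tt - 0.5 * 9.81 * tt^2 / 2)
  ballc <- ball_trajectory(tt, pos)
  i_pkg <- as.numeric(interception_index(ballc, 1.0, 0.7, 0.3))
  arc <- function(a, b) {
    ts <- seq(a, b, length.out = 20000)
    p <- predict(ballc, ts, "position")
    sum(sqrt(diff(p[, 1])^2 + diff(p[, 3])^2))
  }
  i_oracle <- arc(0.7, 1.0) / arc(0.3, 1.0)
  expect_equal(i_pkg, i_oracle, tolerance = 1e-3)
  # clamped when B lies outside [A, C]
  i_cl <- interception_index(ballc, 1.0, 1.1, 0.3)
  expect_true(attr(i_cl, "clamped"))
  expect_equal(as.numeric(i_cl), 0)
})

test_that("interception index is invariant to uniform scaling of the scene", {
  ball <- straight_ball(z = 1.4, v = -5, x0 = 5)
  sho <- c(0, 0, 1.4)
  A <- first_reachable_point(ball, sho, 0.7)
  tC <- evaluate_ball_at_plane(ball, plane3(sho, c(1, 0, 0)))$time
  tB <- 0.88
  i1 <- as.numeric(interception_index(ball, tC, tB, A$time))
  k <- 2.5
  ball2 <- ball_trajectory(ball$times, ball$position * k)
  A2 <- first_reachable_point(ball2, sho * k, 0.7 * k)
  tC2 <- evaluate_ball_at_plane(ball2, plane3(sho * k, c(1, 0, 0)))$time
  i2 <- as.numeric(interception_index(ball2, tC2, tB, A2$time))
  expect_equal(i1, i2, tolerance = 1e-6)
})

test_that("posture angles follow their stated conventions", {
  RSHO <- c(0, 0, 1.4); RELB <- c(0.2, 0, 1.2); RW <- c(0.4, 0, 1.35)
  nrm <- catchkin:::unitv(catchkin:::cross3(RSHO - RELB, RW - RELB))
  # stick parallel / anti-parallel / orthogonal to the arm-plane normal
  expect_equal(pronosupination_angle(RSHO, RELB, RW, RW - 0.1 * nrm, RW + 0.1 * nrm), 0)
  expect_equal(pronosupination_angle(RSHO, RELB, RW, RW + 0.1 * nrm, RW - 0.1 * nrm), 180)
  inplane <- catchkin:::unitv(RW - RELB)
  expect_equal(pronosupination_angle(RSHO, RELB, RW, RW - 0.1 * inplane, RW + 0.1 * inplane), 90)
  expect_error(pronosupination_angle(RSHO, RELB, 2 * RELB - RSHO,
                                     RW - 0.1 * nrm, RW + 0.1 * nrm),
               class = "catchkin_degenerate")
  # elevation: horizontal 0, vertical 90, diagonal 45
  expect_equal(elevation_angle(c(0, 0, 1), c(1, 0, 1)), 0)
  expect_equal(elevation_angle(c(0, 0, 1), c(0, 0, 2)), 90)
  expect_equal(elevation_angle(c(0, 0, 1), c(0, 0, 1) + c(1, 0, 1) / sqrt(2)), 45)
  expect_error(elevation_angle(c(0, 0, 1), c(0, 0, 1)), class = "catchkin_degenerate")
})

test_that("posture angles are invariant to translation and rotation about z", {
  RSHO <- c(0.1, 0.05, 1.42); RELB <- c(0.3, -0.02, 1.18); RW <- c(0.45, 0.03, 1.3)
  RWRU <- RW + c(0.02, -0.1, 0.03); RWRR <- RW + c(-0.02, 0.1, -0.03)
  p0 <- pronosupination_angle(RSHO, RELB, RW, RWRU, RWRR)
  e0 <- elevation_angle(RELB, RW)
  R <- rot_z(63); shift <- c(0.5, -0.3, 0.2)
  tx <- function(v) drop(R %*% v) + shift
  expect_equal(pronosupination_angle(tx(RSHO), tx(RELB), tx(RW), tx(RWRU), tx(RWRR)),
               p0, tolerance = 1e-9)
  expect_equal(elevation_angle(tx(RELB), tx(RW)), e0, tolerance = 1e-9)
})

test_that("shoulder displacement and hand-ball coupling are simple differences", {
  expect_equal(shoulder_displacement(c(0, 0, 1.4), c(0, 0, 1.4)), c(0, 0, 0))
  d <- shoulder_displacement(c(0, 0, 1.4), c(0.05, 0, 1.37))
  expect_equal(d[1], 0.05)
  expect_equal(d[3], -0.03)
  expect_error(shoulder_displacement(c(NA, 0, 1.4), c(0, 0, 1.4)),
               class = "catchkin_missing_data")
  cp <- hand_ball_coupling(c(0.5, 0, -1), c(-6, 0, -3))
  expect_equal(cp$difference, 2)
  expect_equal(hand_ball_coupling(c(1, 1, -2), c(0, 0, -2))$difference, 0)
})

test_that("trunk users displace the shoulder more and catch-zone preference is recovered", {
  coh <- cached_cohort_noiseless()
  sm <- cached_summary_noiseless()
  led <- coh$ledger$trials
  m <- merge(sm, led[, c("trial_id", "trunk_use", "p_effective")], by = "trial_id")
  caught <- m[m$outcome == "caught" & !is.na(m$interception_index), ]
  # measured interception index tracks the generated catch-zone target
  expect_lt(median(abs(caught$interception_index - caught$p_effective), na.rm = TRUE),
            0.05)
  if (any(m$trunk_use) && any(!m$trunk_use)) {
    dsh <- sqrt(m$dSh_x^2 + m$dSh_z^2)
    expect_gt(median(dsh[m$trunk_use]), median(dsh[!m$trunk_use]))
  }
  # type2 subjects approach from below: positive hand vertical velocity at impact
  t2 <- merge(sm, led[, c("trial_id", "archetype")], by = "trial_id")
  t2 <- t2[t2$archetype == "type2" & t2$outcome == "caught", ]
  expect_true(all(t2$v_hand_z > 0))
})
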