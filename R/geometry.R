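# Anthropometry, arrival-height normalization and trial selection,
# interception-point geometry, posture angles, trunk displacement, coupling.

#' Anthropometry from the launch-frame marker positions
#'
#' Arm length is the acromion-to-elbow distance and forearm length the
#' elbow-to-wrist distance, measured at the launch frame; the wrist position
#' is the midpoint of the two wrist-stick markers. Limb length (the functional
#' reach including the palm) is 1.2 times the arm plus forearm lengths.
#'
#' @param trial A `catch_trial`, see [generate_wrist_movement()].
#' @param launch Launch time (s).
#' @return An object of class `anthropometry`: `arm_length`,
#'   `forearm_length`, `limb_length`, `shoulder_height`, `shoulder` (3D, m).
#' @export
compute_anthropometry <- function(trial, launch = 0) {
  i <- which.min(abs(trial$times - launch))
  need <- c("RSHO", "RELB", "RWRU", "RWRR")
  for (nm in need) {
    if (is.null(trial$markers[[nm]]) || anyNA(trial$markers[[nm]][i, ])) {
      ck_stop(sprintf("marker '%s' missing at launch frame", nm), "catchkin_missing_data")
    }
  }
  sho <- trial$markers$RSHO[i, ]
  elb <- trial$markers$RELB[i, ]
  rw <- (trial$markers$RWRU[i, ] + trial$markers$RWRR[i, ]) / 2
  arm <- vnorm(sho - elb)
  fore <- vnorm(elb - rw)
  structure(list(arm_length = arm, forearm_length = fore,
                 limb_length = 1.2 * (arm + fore),
                 shoulder_height = sho[3], shoulder = sho),
            class = "anthropometry")
}

#' Normalized ball arrival height
#'
#' Height of the (possibly extrapolated) ball crossing of the frontal plane
#' through the shoulder at launch, expressed relative to shoulder height in
#' units of limb length: `Zn = (z_arrival - shoulder_height) / limb_length`.
#'
#' @param ball A [ball_trajectory()].
#' @param shoulder Shoulder position at launch (length-3, m).
#' @param anthro An [compute_anthropometry()] result.
#' @param extrapolate Extrapolation limit (s).
#' @return Normalized arrival height (dimensionless).
#' @export
normalized_arrival_height <- function(ball, shoulder, anthro, extrapolate = 0.15) {
  crossing <- evaluate_ball_at_plane(ball, plane3(shoulder, c(1, 0, 0)), extrapolate)
  (crossing$position[3] - anthro$shoulder_height) / anthro$limb_length
}

#' Select trials by outcome and normalized arrival height
#'
#' Keeps caught trials whose normalized arrival height lies within the
#' tolerance of the reference height for the trial's arrival-height
#' condition; all other trials are excluded with a reason.
#'
#' @param trials A data frame with columns `Zn`, `outcome`, and `height`
#'   (`"low"` or `"high"` condition label).
#' @param references Named reference heights for the two conditions.
#' @param tolerance Selection tolerance in limb-length units.
#' @return The input with logical `selected` and character `exclusion_reason`
#'   columns appended.
#' @export
select_trials <- function(trials, references = c(low = -0.11, high = 0.58),
                          tolerance = 0.30) {
  ref <- references[trials$height]
  dev <- abs(trials$Zn - ref)
  caught <- trials$outcome == "caught"
  trials$selected <- caught & !is.na(dev) & dev <= tolerance
  trials$exclusion_reason <- ifelse(trials$selected, NA_character_,
                                    ifelse(!caught, "not_caught",
                                           ifelse(is.na(dev), "no_Zn", "height_outside_range")))
  if (!any(trials$selected)) warning("no trials selected")
  trials
}

#' First reachable point on the ball path
#'
#' Earliest intersection of the ball path, projected on the sagittal (x-z)
#' plane, with the circle of limb-length radius centered on the shoulder.
#' The crossing is root-refined between samples; a path tangent to the
#' circle returns the tangency point.
#'
#' @param ball A [ball_trajectory()].
#' @param shoulder Shoulder position at launch; only x and z are used.
#' @param limb_length Circle radius (m).
#' @return A list with `time`, `point` (x, z), and `position` (3D).
#' @export
first_reachable_point <- function(ball, shoulder, limb_length) {
  sx <- shoulder[1]; sz <- if (length(shoulder) == 3) shoulder[3] else shoulder[2]
  fd <- function(t) {
    p <- predict(ball, t, "position")
    sqrt((p[, 1] - sx)^2 + (p[, 3] - sz)^2) - limb_length
  }
  d <- fd(ball$times)
  n <- length(d)
  if (d[1] <= 0) {
    tc <- ball$times[1]
  } else {
    i <- which(d[-n] > 0 & d[-1] <= 0)
    if (length(i)) {
      tc <- uniroot(function(t) fd(t), lower = ball$times[i[1]],
                    upper = ball$times[i[1] + 1], tol = 1e-10)$root
    } else {
      opt <- optimize(fd, range(ball$times))
      if (opt$objective < 1e-6) {
        tc <- opt$minimum
      } else {
        ck_stop("ball path never enters the reachable circle", "catchkin_unreachable")
      }
    }
  }
  p <- unname(ball_position_at(ball, tc))
  list(time = tc, point = c(x = p[1], z = p[3]), position = p)
}

#' Interception index
#'
#' Ratio of arc lengths along the sagittal-projected ball path: the arc from
#' the impact point B to the frontal-plane crossing C, over the arc from the
#' first reachable point A to C. `I = 0` is a catch at the frontal plane
#' through the shoulder; `I = 1` a catch at the earliest reachable point.
#' Arc lengths are computed by piecewise-linear integration of the projected
#' path resampled at 1 ms.
#'
#' @param ball A [ball_trajectory()].
#' @param t_C,t_B,t_A Times of the frontal-plane crossing, the impact, and
#'   the first reachable point (s); the ball reaches A first and C last.
#' @param resolution Resampling step (s).
#' @return Interception index in `[0, 1]`; attribute `clamped` is `TRUE`
#'   when B fell outside the segment between A and C.
#' @export
interception_index <- function(ball, t_C, t_B, t_A, resolution = 1e-3) {
  if (t_A >= t_C) ck_stop("degenerate geometry: A and C coincide", "catchkin_degenerate")
  tt <- seq(t_A, t_C, by = resolution)
  if (tt[length(tt)] < t_C) tt <- c(tt, t_C)
  p <- predict(ball, tt, "position")
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 3])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total < 1e-9) ck_stop("degenerate geometry: zero arc length", "catchkin_degenerate")
  clamped <- t_B < t_A || t_B > t_C
  tb <- clamp(t_B, t_A, t_C)
  arc_AB <- approx(tt, cum, xout = tb)$y
  i_val <- clamp((total - arc_AB) / total, 0, 1)
  structure(i_val, clamped = clamped)
}

#' Forearm pronosupination angle at impact
#'
#' Angle between the normal of the plane through the shoulder, elbow and
#' wrist markers and the wrist-stick direction (ulnar to radial marker):
#' 0 deg is a pronated wrist, 180 deg supinated. The arm-plane normal is
#' `(elbow -> shoulder) x (elbow -> wrist)`.
#'
#' @param RSHO,RELB,RW,RWRU,RWRR Marker positions at impact (length-3, m).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
pronosupination_angle <- function(RSHO, RELB, RW, RWRU, RWRR) {
  nrm <- cross3(RSHO - RELB, RW - RELB)
  if (vnorm(nrm) < 1e-9) ck_stop("shoulder, elbow and wrist are collinear", "catchkin_degenerate")
  stick <- RWRR - RWRU
  if (vnorm(stick) < 1e-9) ck_stop("wrist-stick markers coincide", "catchkin_degenerate")
  rad2deg(acos(clamp(sum(unitv(nrm) * unitv(stick)), -1, 1)))
}

#' Forearm elevation angle at impact
#'
#' Angle between the forearm axis (elbow to wrist) and the horizontal plane:
#' 0 deg horizontal, 90 deg vertical.
#'
#' @param RELB,RW Marker positions at impact (length-3, m).
#' @return Angle in degrees, in `[-90, 90]`.
#' @export
elevation_angle <- function(RELB, RW) {
  if (vnorm(RW - RELB) < 1e-9) ck_stop("elbow and wrist markers coincide", "catchkin_degenerate")
  rad2deg(asin(unitv(RW - RELB)[3]))
}

#' Shoulder displacement between launch and impact
#'
#' @param RSHO_launch,RSHO_impact Shoulder positions (length-3, m).
#' @return Length-3 displacement vector (m).
#' @export
shoulder_displacement <- function(RSHO_launch, RSHO_impact) {
  if (anyNA(RSHO_launch) || anyNA(RSHO_impact)) {
    ck_stop("shoulder marker missing at launch or impact frame", "catchkin_missing_data")
  }
  as.numeric(RSHO_impact) - as.numeric(RSHO_launch)
}

#' Hand-ball vertical velocity coupling at impact
#'
#' @param wrist_velocity,ball_velocity Velocities at impact (length-3, m/s).
#' @return A list with `v_hand_z`, `v_ball_z`, and their `difference`
#'   (hand minus ball).
#' @export
hand_ball_coupling <- function(wrist_velocity, ball_velocity) {
  list(v_hand_z = wrist_velocity[3], v_ball_z = ball_velocity[3],
       difference = wrist_velocity[3] - ball_velocity[3])
}
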