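# Ball flight under gravity and quadratic air drag.

#' Physical parameters of the ball and air
#'
#' Defaults describe the lightweight expanded-polyurethane ball used in the
#' catching task (20 g, 7 cm diameter) flying in air at sea level. Drag is
#' quadratic with a sphere drag coefficient of 0.5, which is the standard
#' choice for this Reynolds regime.
#'
#' @param mass Ball mass in kg.
#' @param diameter Ball diameter in m.
#' @param drag_coefficient Dimensionless drag coefficient (0 turns drag off).
#' @param air_density Air density in kg m^-3.
#' @param gravity Gravitational acceleration in m s^-2.
#' @return An object of class `drag_params`.
#' @export
#' @examples
#' drag_params()
drag_params <- function(mass = 0.020, diameter = 0.07, drag_coefficient = 0.5,
                        air_density = 1.2, gravity = 9.81) {
  for (nm in c("mass", "diameter", "air_density", "gravity")) {
    v <- get(nm)
    if (!is_scalar_num(v) || v <= 0) {
      ck_stop(sprintf("'%s' must be a positive number", nm), "catchkin_invalid_parameter")
    }
  }
  if (!is_scalar_num(drag_coefficient) || drag_coefficient < 0) {
    ck_stop("'drag_coefficient' must be a non-negative number", "catchkin_invalid_parameter")
  }
  structure(list(mass = mass, diameter = diameter,
                 drag_coefficient = drag_coefficient,
                 air_density = air_density, gravity = gravity),
            class = "drag_params")
}

#' Construct a ball trajectory from time-stamped samples
#'
#' Wraps sampled 3D positions (and optionally velocities) with per-coordinate
#' cubic spline evaluators, supporting interpolation and short extrapolation
#' queries (plane crossings, state at impact time, ...).
#'
#' @param times Numeric vector of sample times (s), strictly increasing.
#' @param position n x 3 matrix of positions (m), columns x, y, z.
#' @param velocity Optional n x 3 matrix of velocities (m/s); if omitted,
#'   velocities are obtained by differentiating the position splines.
#' @return An object of class `ball_trajectory`.
#' @export
ball_trajectory <- function(times, position, velocity = NULL) {
  position <- as.matrix(position)
  if (length(times) < 4L) ck_stop("need at least 4 samples", "catchkin_length")
  if (ncol(position) != 3L || nrow(position) != length(times)) {
    ck_stop("'position' must be an n x 3 matrix matching 'times'", "catchkin_invalid_parameter")
  }
  if (any(diff(times) <= 0)) ck_stop("'times' must be strictly increasing", "catchkin_invalid_parameter")
  fx <- lapply(1:3, function(j) splinefun(times, position[, j], method = "fmm"))
  fv <- if (!is.null(velocity)) {
    velocity <- as.matrix(velocity)
    lapply(1:3, function(j) splinefun(times, velocity[, j], method = "fmm"))
  } else NULL
  structure(list(times = times, position = position, velocity = velocity,
                 .fx = fx, .fv = fv),
            class = "ball_trajectory")
}

#' @export
print.ball_trajectory <- function(x, ...) {
  cat(sprintf("<ball_trajectory> %d samples, t in [%.3f, %.3f] s\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Evaluate a ball trajectory at arbitrary times
#'
#' @param object A `ball_trajectory`.
#' @param t Times (s) at which to evaluate.
#' @param what `"position"` or `"velocity"`.
#' @param ... Unused.
#' @return A length(t) x 3 matrix.
#' @export
predict.ball_trajectory <- function(object, t, what = c("position", "velocity"), ...) {
  what <- match.arg(what)
  out <- if (what == "position") {
    vapply(object$.fx, function(f) f(t), numeric(length(t)))
  } else if (!is.null(object$.fv)) {
    vapply(object$.fv, function(f) f(t), numeric(length(t)))
  } else {
    vapply(object$.fx, function(f) f(t, deriv = 1), numeric(length(t)))
  }
  matrix(out, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
}

ball_position_at <- function(ball, t) drop(predict(ball, t, "position"))
ball_velocity_at <- function(ball, t) drop(predict(ball, t, "velocity"))

#' Simulate a ball flight with quadratic air drag
#'
#' Integrates `a = g - (k/m) |v| v`, with `k = 1/2 rho C_d pi (diameter/2)^2`,
#' using fixed-step 4th-order Runge-Kutta at 1 ms, resampled to the requested
#' output step. Integration stops when the ball passes the arrival plane
#' (x <= 0), hits the ground (z <= 0), or `max_time` elapses; the first sample
#' beyond the stopping condition is retained so that crossings stay bracketed.
#'
#' The frame has x horizontal pointing from the catcher's hand toward the
#' launcher and z vertical up; a launch toward the catcher therefore has a
#' negative x velocity.
#'
#' @param initial_position,initial_velocity Length-3 numeric vectors (m, m/s).
#' @param drag A [drag_params()] object.
#' @param dt Output sampling step in s, in (0, 0.02].
#' @param max_time Maximum flight time in s.
#' @return A [ball_trajectory()].
#' @export
#' @examples
#' fl <- simulate_ball_flight(c(6, 0, 1.66), c(-10, 0, 1))
#' fl
simulate_ball_flight <- function(initial_position, initial_velocity,
                                 drag = drag_params(), dt = 0.01,
                                 max_time = 2) {
  if (!inherits(drag, "drag_params")) drag <- do.call(drag_params, as.list(drag))
  if (!is_scalar_num(dt) || dt <= 0 || dt > 0.02) {
    ck_stop("'dt' must be in (0, 0.02]", "catchkin_invalid_parameter")
  }
  if (vnorm(initial_velocity) <= 0) {
    ck_stop("initial speed must be positive", "catchkin_invalid_parameter")
  }
  h <- 0.001
  kom <- 0.5 * drag$air_density * drag$drag_coefficient *
    pi * (drag$diameter / 2)^2 / drag$mass
  gvec <- c(0, 0, -drag$gravity)
  accel <- function(v) gvec - kom * sqrt(sum(v^2)) * v

  nmax <- ceiling(max_time / h) + 1L
  pos <- matrix(NA_real_, nmax, 3)
  vel <- matrix(NA_real_, nmax, 3)
  pos[1, ] <- as.numeric(initial_position)
  vel[1, ] <- as.numeric(initial_velocity)
  n <- 1L
  t <- 0
  while (t < max_time - 1e-12 && n < nmax) {
    p <- pos[n, ]; v <- vel[n, ]
    k1v <- accel(v);                 k1p <- v
    k2v <- accel(v + h / 2 * k1v);   k2p <- v + h / 2 * k1v
    k3v <- accel(v + h / 2 * k2v);   k3p <- v + h / 2 * k2v
    k4v <- accel(v + h * k3v);       k4p <- v + h * k3v
    n <- n + 1L
    pos[n, ] <- p + h / 6 * (k1p + 2 * k2p + 2 * k3p + k4p)
    vel[n, ] <- v + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    t <- t + h
    if (pos[n, 1] <= 0 || pos[n, 3] <= 0) break
  }
  times <- seq(0, by = h, length.out = n)
  keep <- unique(c(seq(1L, n, by = max(1L, round(dt / h))), n))
  ball_trajectory(times[keep], pos[keep, , drop = FALSE], vel[keep, , drop = FALSE])
}

#' Total mechanical energy along a flight
#'
#' Kinetic plus gravitational potential energy per sample; with drag on this
#' is non-increasing along the flight.
#'
#' @param ball A `ball_trajectory` with stored velocities.
#' @param drag A [drag_params()] object (for mass and gravity).
#' @return Numeric vector of energies (J), one per sample.
#' @export
flight_energy <- function(ball, drag = drag_params()) {
  if (is.null(ball$velocity)) ck_stop("trajectory has no stored velocities", "catchkin_invalid_parameter")
  0.5 * drag$mass * rowSums(ball$velocity^2) + drag$mass * drag$gravity * ball$position[, 3]
}
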