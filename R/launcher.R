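# Launcher calibration: polynomial mapping from launch parameters to flight
# characteristics at the arrival plane, and its quantization-aware inverse.

MPH <- 0.44704  # 1 mph in m/s; launch speed is adjustable in 1 mph steps

#' Calibrate the ball launcher by simulation
#'
#' Simulates a grid of drag-affected launches and fits least-squares
#' polynomial surfaces `T(speed, angle, height)` and `Z(speed, angle,
#' height)` for the flight time and arrival height at the plane a distance
#' `d` from the launcher. The three launch parameters mirror the actuated
#' machine: projection speed (adjustable only in 1 mph steps), elevation
#' angle, and vertical translation of the exit point. The fitted mapping is
#' then inverted for requested (T, Z) conditions while honoring the speed
#' quantization.
#'
#' @param drag A [drag_params()] object.
#' @param speeds Launch speed grid (m/s).
#' @param angles Elevation angle grid (deg, positive upward).
#' @param heights Launch height grid (m); the machine translates vertically
#'   around the nominal exit height of 1.66 m.
#' @param d Distance from launcher to the arrival plane (m).
#' @param degree Total polynomial degree of the fitted surfaces.
#' @param speed_step Speed quantization step (m/s); defaults to 1 mph.
#' @return An object of class `launcher_mapping`.
#' @export
calibrate_launcher <- function(drag = drag_params(),
                               speeds = seq(8, 18, length.out = 20),
                               angles = seq(0, 30, length.out = 20),
                               heights = seq(1.36, 1.96, length.out = 5),
                               d = 6, degree = 3, speed_step = MPH) {
  grid <- expand.grid(speed = speeds, angle = angles, height = heights)
  arrival <- plane3(c(0, 0, 0), c(1, 0, 0))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    fl <- launch_flight(grid$speed[i], grid$angle[i], drag, d, grid$height[i])
    st <- tryCatch(evaluate_ball_at_plane(fl, arrival, extrapolate = 0),
                   catchkin_no_crossing = function(e) NULL)
    if (is.null(st) || st$position[3] <= 0) return(c(NA_real_, NA_real_))
    c(st$time, st$position[3])
  })
  grid$T <- vapply(res, `[`, numeric(1), 1)
  grid$Z <- vapply(res, `[`, numeric(1), 2)
  ok <- stats::complete.cases(grid)
  if (sum(ok) < 2 * choose(degree + 3, 3)) {
    ck_stop("too few valid launches to fit the mapping", "catchkin_invalid_parameter")
  }
  fit <- grid[ok, ]
  X <- poly_design(fit$speed, fit$angle, fit$height, degree)
  model_T <- lm.fit(X, fit$T)$coefficients
  model_Z <- lm.fit(X, fit$Z)$coefficients
  # aliased columns (e.g. degenerate height grids) drop out of the fit
  model_T[is.na(model_T)] <- 0
  model_Z[is.na(model_Z)] <- 0
  structure(list(model_T = model_T, model_Z = model_Z, grid = fit,
                 speeds = range(speeds), angles = range(angles),
                 heights = range(heights), d = d, drag = drag,
                 degree = degree, speed_step = speed_step),
            class = "launcher_mapping")
}

#' @export
print.launcher_mapping <- function(x, ...) {
  cat(sprintf(paste0("<launcher_mapping> degree-%d surfaces fitted on %d launches\n",
                     "  speeds %.1f-%.1f m/s, angles %.1f-%.1f deg, ",
                     "heights %.2f-%.2f m, d = %.1f m\n"),
              x$degree, nrow(x$grid), x$speeds[1], x$speeds[2],
              x$angles[1], x$angles[2], x$heights[1], x$heights[2], x$d))
  invisible(x)
}

#' Simulate one launch from the exit point toward the catcher
#'
#' The ball leaves from `(d, 0, launch_height)` with the given speed and
#' elevation angle, moving in the -x direction (toward the catcher).
#'
#' @param speed Launch speed (m/s).
#' @param angle Elevation angle (deg).
#' @param drag A [drag_params()] object.
#' @param d Distance from launcher to the arrival plane (m).
#' @param launch_height Exit height (m).
#' @param dt Output sampling step (s).
#' @return A [ball_trajectory()].
#' @export
launch_flight <- function(speed, angle, drag = drag_params(), d = 6,
                          launch_height = 1.66, dt = 0.01) {
  a <- deg2rad(angle)
  simulate_ball_flight(c(d, 0, launch_height),
                       c(-speed * cos(a), 0, speed * sin(a)),
                       drag = drag, dt = dt, max_time = 2)
}

# Trivariate raw polynomial design matrix up to total degree `degree`.
poly_design <- function(speed, angle, height, degree) {
  cols <- list(rep(1, length(speed)))
  for (d in 1:degree) {
    for (i in 0:d) {
      for (j in 0:(d - i)) {
        cols[[length(cols) + 1L]] <- speed^(d - i - j) * angle^i * height^j
      }
    }
  }
  do.call(cbind, cols)
}

predict_arrival <- function(mapping, speed, angle, height) {
  X <- poly_design(speed, angle, height, mapping$degree)
  c(T = drop(X %*% mapping$model_T), Z = drop(X %*% mapping$model_Z))
}

#' Launch parameters for a requested flight condition
#'
#' Inverts the calibrated polynomial mapping for a requested flight time and
#' arrival height. Candidate speeds are restricted to multiples of the
#' quantization step; for each candidate speed, elevation angle and launch
#' height are optimized against the polynomial surfaces, and the candidate
#' minimizing the combined relative error (each term normalized by the
#' apparatus accuracy bound: 2% on T, 4% on Z) is kept.
#'
#' @param mapping A [calibrate_launcher()] result.
#' @param T_target Requested flight time (s).
#' @param Z_target Requested arrival height (m).
#' @return A list with `speed` (m/s, quantized), `angle` (deg), `height`
#'   (m), and the polynomial-predicted `T` and `Z`.
#' @export
launch_for_condition <- function(mapping, T_target, Z_target) {
  g <- mapping$grid
  if (T_target < min(g$T) || T_target > max(g$T) ||
      Z_target < min(g$Z) || Z_target > max(g$Z)) {
    ck_stop(sprintf("requested condition (T = %.3g s, Z = %.3g m) lies outside the calibrated range",
                    T_target, Z_target), "catchkin_out_of_range")
  }
  q <- mapping$speed_step
  cand <- seq(ceiling(mapping$speeds[1] / q), floor(mapping$speeds[2] / q)) * q
  obj_at <- function(speed, angle, height) {
    tz <- predict_arrival(mapping, speed, angle, height)
    ((tz["T"] - T_target) / (0.02 * T_target))^2 +
      ((tz["Z"] - Z_target) / (0.04 * Z_target))^2
  }
  best <- NULL
  a0 <- mean(mapping$angles); h0 <- mean(mapping$heights)
  for (s in cand) {
    opt <- optim(c(a0, h0), function(p) obj_at(s, p[1], p[2]),
                 method = "L-BFGS-B",
                 lower = c(mapping$angles[1], mapping$heights[1]),
                 upper = c(mapping$angles[2], mapping$heights[2]))
    if (is.null(best) || opt$value < best$value) {
      best <- list(speed = s, angle = opt$par[1], height = opt$par[2],
                   value = opt$value)
    }
  }
  if (best$value > 25) {  # > 5x the accuracy bounds even at the optimum
    ck_stop("requested condition is not reachable by the calibrated launcher",
            "catchkin_out_of_range")
  }
  tz <- predict_arrival(mapping, best$speed, best$angle, best$height)
  list(speed = best$speed, angle = best$angle, height = best$height,
       T = unname(tz["T"]), Z = unname(tz["Z"]),
       T_target = T_target, Z_target = Z_target)
}

#' The six experimental flight conditions
#'
#' Three mean flight times crossed with two arrival heights at the 6 m plane.
#'
#' @param T_values Flight times (s).
#' @param Z_values Arrival heights (m), low and high.
#' @return A data frame with columns `T`, `Z`, `T_label`, `Z_label`,
#'   `height`, `label`.
#' @export
flight_conditions <- function(T_values = c(0.55, 0.65, 0.75),
                              Z_values = c(low = 1.3, high = 1.9)) {
  cond <- expand.grid(T = T_values, Z = unname(Z_values))
  cond$T_label <- paste0("T", match(cond$T, sort(unique(cond$T))))
  cond$Z_label <- paste0("Z", match(cond$Z, sort(unique(cond$Z))))
  cond$height <- c("low", "high")[match(cond$Z, sort(unique(cond$Z)))]
  cond$label <- paste0(cond$T_label, cond$Z_label)
  cond
}

#' Achieved accuracy of the calibrated launcher
#'
#' For each requested condition, inverts the mapping, simulates the selected
#' launch, measures the achieved flight time and arrival height at the
#' arrival plane, and reports relative accuracies
#' `100 * (1 - |achieved - requested| / requested)` in percent.
#'
#' @param mapping A [calibrate_launcher()] result.
#' @param conditions A data frame with columns `T` and `Z`; defaults to the
#'   six experimental conditions.
#' @return A data frame with requested and achieved values plus accuracy
#'   columns `acc_T` and `acc_Z` (percent).
#' @export
launcher_accuracy <- function(mapping, conditions = flight_conditions()) {
  arrival <- plane3(c(0, 0, 0), c(1, 0, 0))
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    lc <- launch_for_condition(mapping, conditions$T[i], conditions$Z[i])
    fl <- launch_flight(lc$speed, lc$angle, mapping$drag, mapping$d, lc$height)
    st <- evaluate_ball_at_plane(fl, arrival, extrapolate = 0.05)
    data.frame(T_requested = conditions$T[i], Z_requested = conditions$Z[i],
               speed = lc$speed, angle = lc$angle, height = lc$height,
               T_achieved = st$time, Z_achieved = st$position[3],
               acc_T = 100 * (1 - abs(st$time - conditions$T[i]) / conditions$T[i]),
               acc_Z = 100 * (1 - abs(st$position[3] - conditions$Z[i]) / conditions$Z[i]))
  })
  do.call(rbind, rows)
}
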