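# Filtering, differentiation, and spline-based trajectory queries.

#' A plane in 3D
#'
#' @param point A point on the plane (length-3, m).
#' @param normal Plane normal (length-3); normalized internally.
#' @return An object of class `catchkin_plane`.
#' @export
#' @examples
#' frontal <- plane3(c(0, 0, 1.45), c(1, 0, 0))
plane3 <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = unitv(as.numeric(normal))),
            class = "catchkin_plane")
}

signed_distance <- function(p, plane) {
  # p: n x 3 matrix or length-3 vector
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  drop((p - matrix(plane$point, nrow(p), 3, byrow = TRUE)) %*% plane$normal)
}

#' Zero-phase FIR low-pass filtering
#'
#' Forward-backward filtering with a Hamming-window FIR low-pass filter
#' (unit DC gain). The series is padded by odd reflection at both ends before
#' filtering so that output length equals input length without edge
#' transients on slowly varying data.
#'
#' @param x Numeric vector or n x k matrix (columns filtered independently).
#' @param cutoff Cutoff frequency in Hz; must be below `rate / 2`.
#' @param rate Sampling rate in Hz.
#' @param order FIR order (number of taps minus one).
#' @return Filtered data with the same shape as `x`.
#' @export
lowpass_filter <- function(x, cutoff = 25, rate = 100, order = 30) {
  if (cutoff >= rate / 2) ck_stop("'cutoff' must be below the Nyquist frequency", "catchkin_invalid_parameter")
  mat <- !is.null(dim(x))
  xm <- if (mat) as.matrix(x) else matrix(x, ncol = 1)
  n <- nrow(xm)
  if (n <= order + 1L) {
    ck_stop(sprintf("series too short for filter order (%d samples, order %d)", n, order),
            "catchkin_length")
  }
  pad <- min(3L * order, n - 1L)
  taps <- as.numeric(signal::fir1(order, cutoff / (rate / 2)))
  taps <- taps / sum(taps)  # exact unit DC gain
  out <- apply(xm, 2, function(col) {
    xp <- c(2 * col[1] - col[(pad + 1):2],
            col,
            2 * col[n] - col[(n - 1):(n - pad)])
    yp <- signal::filtfilt(taps, 1, xp)
    yp[(pad + 1):(pad + n)]
  })
  if (mat) out else drop(out)
}

#' Numerical differentiation of a sampled series
#'
#' Central differences at interior samples, one-sided differences at the
#' edges; exact for polynomials of degree two or less at interior samples.
#' `order = 2` applies the operator twice.
#'
#' @param x Numeric vector or n x k matrix.
#' @param rate Sampling rate in Hz.
#' @param order Derivative order, 1 or 2.
#' @return Derivative with the same shape as `x`.
#' @export
differentiate <- function(x, rate = 100, order = 1) {
  if (!order %in% c(1, 2)) ck_stop("'order' must be 1 or 2", "catchkin_invalid_parameter")
  mat <- !is.null(dim(x))
  xm <- if (mat) as.matrix(x) else matrix(x, ncol = 1)
  if (nrow(xm) < 5L) ck_stop("need at least 5 samples to differentiate", "catchkin_length")
  d <- apply(xm, 2, pracma::gradient, h1 = 1 / rate)
  if (order == 2) d <- apply(d, 2, pracma::gradient, h1 = 1 / rate)
  if (mat) d else drop(d)
}

#' Tangential speed of a marker
#'
#' Per-sample Euclidean norm of the velocity. With `planar = TRUE` only the
#' sagittal (x-z) components enter the norm, mirroring sagittal-plane speed
#' profiles.
#'
#' @param velocity n x 3 velocity matrix (m/s).
#' @param times Sample times (s).
#' @param planar If `TRUE`, restrict to the x and z components.
#' @return A `speed_series` data frame with columns `time` and `speed`.
#' @export
tangential_speed <- function(velocity, times, planar = FALSE) {
  velocity <- as.matrix(velocity)
  if (nrow(velocity) == 0) ck_stop("empty velocity series", "catchkin_length")
  cols <- if (planar) c(1, 3) else 1:3
  sp <- sqrt(rowSums(velocity[, cols, drop = FALSE]^2))
  structure(data.frame(time = times, speed = sp),
            class = c("speed_series", "data.frame"))
}

#' Ball state at a plane crossing
#'
#' Finds the earliest time at which the ball path crosses a plane, by rooting
#' the signed distance of the spline-interpolated path. If the sampled path
#' ends before the plane, the per-coordinate cubic splines are extrapolated up
#' to `extrapolate` seconds beyond the last sample.
#'
#' @param ball A [ball_trajectory()].
#' @param plane A [plane3()].
#' @param extrapolate Maximum extrapolation beyond the last sample (s).
#' @return A list with `time`, `position` (length-3) and `velocity` (length-3).
#' @export
evaluate_ball_at_plane <- function(ball, plane, extrapolate = 0.15) {
  d <- signed_distance(ball$position, plane)
  fd <- function(t) signed_distance(ball_position_at(ball, t), plane)
  n <- length(d)
  hit <- which(d == 0)
  cross <- which(d[-n] * d[-1] < 0)
  if (length(hit) && (!length(cross) || hit[1] <= cross[1])) {
    tc <- ball$times[hit[1]]
  } else if (length(cross)) {
    i <- cross[1]
    tc <- uniroot(fd, lower = ball$times[i], upper = ball$times[i + 1],
                  tol = 1e-10)$root
  } else {
    # extrapolate beyond the last sample
    t_end <- ball$times[n]
    tt <- seq(t_end, t_end + extrapolate, by = 1e-3)
    dd <- fd(tt)
    j <- which(dd[-length(dd)] * dd[-1] <= 0)
    if (!length(j)) {
      ck_stop("ball path does not cross the plane within the extrapolation window",
              "catchkin_no_crossing")
    }
    tc <- uniroot(fd, lower = tt[j[1]], upper = tt[j[1] + 1], tol = 1e-10)$root
  }
  list(time = tc,
       position = unname(ball_position_at(ball, tc)),
       velocity = unname(ball_velocity_at(ball, tc)))
}
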