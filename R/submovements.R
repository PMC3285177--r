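# Minimum-jerk submovement model and decomposition of wrist tangential speed.
#
# A submovement with displacement amplitude A (m), duration D (s) and onset
# t0 (s) has the minimum-jerk speed profile
#     v(t) = 30 (A / D) tau^2 (1 - tau)^2,   tau = (t - t0) / D in [0, 1],
# i.e. the derivative of the minimum-jerk displacement 10 tau^3 - 15 tau^4 +
# 6 tau^5 scaled by A. Its integral is A and its peak is 1.875 A / D at
# tau = 1/2. The observed speed profile is modeled as the scalar sum of N
# such components.

#' Minimum-jerk speed profile
#'
#' @param A Displacement amplitude (m).
#' @param D Duration (s); must be positive.
#' @param t0 Onset time (s).
#' @param t Times at which to evaluate (s).
#' @return Speeds (m/s); zero outside the support `[t0, t0 + D]`.
#' @export
#' @examples
#' minimum_jerk_speed(1, 1, 0, 0.5)  # peak: 1.875 * A / D
minimum_jerk_speed <- function(A, D, t0, t) {
  if (!is_scalar_num(D) || D <= 0) ck_stop("'D' must be positive", "catchkin_invalid_parameter")
  tau <- (t - t0) / D
  v <- numeric(length(t))
  in_support <- tau >= 0 & tau <= 1
  tv <- tau[in_support]
  v[in_support] <- 30 * A / D * tv^2 * (1 - tv)^2
  v
}

#' Composite speed of a set of submovements
#'
#' Scalar superposition of the component minimum-jerk speed profiles.
#'
#' @param params A data frame (or matrix) with columns `A`, `D`, `t0`.
#' @param t Times at which to evaluate (s).
#' @return Speeds (m/s).
#' @export
composite_speed <- function(params, t) {
  params <- as.data.frame(params)
  if (nrow(params) == 0) ck_stop("empty submovement set", "catchkin_invalid_parameter")
  v <- numeric(length(t))
  for (i in seq_len(nrow(params))) {
    v <- v + minimum_jerk_speed(params$A[i], params$D[i], params$t0[i], t)
  }
  v
}

#' Select the decomposition fitting window
#'
#' The window starts at movement onset. It extends 100 ms past impact when
#' the speed never drops below the movement threshold during the 100 ms after
#' impact (the mover does not stop on the ball, so the last submovement's
#' parameters stay identifiable); otherwise it ends at impact.
#'
#' @param speed A `speed_series` (columns `time`, `speed`).
#' @param LT Movement onset time (s).
#' @param IT Impact time (s).
#' @param threshold Movement threshold (m/s).
#' @return Numeric length-2 vector `c(t_start, t_end)`.
#' @export
select_fit_window <- function(speed, LT, IT, threshold = 0.05) {
  post <- speed$speed[speed$time > IT & speed$time <= IT + 0.1 + 1e-9]
  if (length(post) && min(post) >= threshold) c(LT, IT + 0.1) else c(LT, IT)
}

# Objective (penalized SSE) and its analytic gradient. Parameter vector is
# c(A_1..A_N, D_1..D_N, t0_1..t0_N). Ordering of onsets and offsets is
# encouraged by a smooth hinge penalty; box constraints are handled by
# L-BFGS-B.
submovement_objective <- function(par, t, y, lambda) {
  N <- length(par) / 3L
  A <- par[1:N]; D <- par[N + 1:N]; t0 <- par[2 * N + 1:N]
  v <- numeric(length(t))
  comp <- vector("list", N)
  for (i in seq_len(N)) {
    vi <- minimum_jerk_speed(A[i], D[i], t0[i], t)
    comp[[i]] <- vi
    v <- v + vi
  }
  r <- v - y
  sse <- sum(r^2)
  pen <- 0
  if (N > 1) {
    d_on <- t0[-N] - t0[-1]
    d_off <- (t0 + D)[-N] - (t0 + D)[-1]
    pen <- sum(pmax(0, d_on)^2) + sum(pmax(0, d_off)^2)
  }
  structure(sse + lambda * pen, sse = sse, comp = comp, r = r)
}

submovement_gradient <- function(par, t, y, lambda) {
  N <- length(par) / 3L
  A <- par[1:N]; D <- par[N + 1:N]; t0 <- par[2 * N + 1:N]
  v <- numeric(length(t))
  for (i in seq_len(N)) v <- v + minimum_jerk_speed(A[i], D[i], t0[i], t)
  r <- v - y
  gA <- gD <- gt0 <- numeric(N)
  for (i in seq_len(N)) {
    s <- t - t0[i]
    m <- s >= 0 & s <= D[i]
    sm <- s[m]; Di <- D[i]
    # v_i = 30 A s^2 (D - s)^2 / D^5 on the support
    dv_dA <- 30 * sm^2 * (Di - sm)^2 / Di^5
    dv_dD <- 30 * A[i] * sm^2 * (Di - sm) * (2 * Di - 5 * (Di - sm)) / Di^6
    dv_ds <- 60 * A[i] * sm * (Di - sm) * (Di - 2 * sm) / Di^5
    gA[i] <- 2 * sum(r[m] * dv_dA)
    gD[i] <- 2 * sum(r[m] * dv_dD)
    gt0[i] <- 2 * sum(r[m] * -dv_ds)
  }
  if (N > 1) {
    d_on <- pmax(0, t0[-N] - t0[-1])
    d_off <- pmax(0, (t0 + D)[-N] - (t0 + D)[-1])
    gt0[-N] <- gt0[-N] + lambda * 2 * d_on
    gt0[-1] <- gt0[-1] - lambda * 2 * d_on
    gt0[-N] <- gt0[-N] + lambda * 2 * d_off
    gt0[-1] <- gt0[-1] - lambda * 2 * d_off
    gD[-N] <- gD[-N] + lambda * 2 * d_off
    gD[-1] <- gD[-1] - lambda * 2 * d_off
  }
  c(gA, gD, gt0)
}

#' Fit a fixed number of submovements to a speed profile
#'
#' Scattershot optimization: repeated constrained local least-squares from
#' randomized initial onsets, keeping the best run. At each run all
#' amplitudes start at `A_M / N` and all durations at `MT / N`, while onsets
#' are sampled from Gaussians centered at equi-spaced times with sd `D / 2`.
#' Constraints: `A` in `[0.1, A_M]`, `D >= 0.1` s (the minimal submovement
#' duration), onsets in `[LT - 0.1, IT - 0.1]`, and increasing onsets and
#' offsets.
#'
#' @param speed A `speed_series`.
#' @param window Fitting window `c(t_start, t_end)`, see [select_fit_window()].
#' @param N Number of submovements (1-6).
#' @param A_M Total movement amplitude (wrist path length over the window, m).
#' @param LT Movement onset (s).
#' @param MT Movement duration `IT - LT` (s).
#' @param restarts Number of random initial conditions.
#' @param seed Integer seed for the random restarts.
#' @param min_duration Minimal submovement duration (s).
#' @param amplitude_min Lower amplitude bound (m).
#' @return A list with `params` (data frame `A`, `D`, `t0`, `t_off`, sorted
#'   by onset), `r_squared`, `sse`, and `convergence` info.
#' @export
fit_fixed_n <- function(speed, window, N, A_M, LT, MT, restarts = 20,
                        seed = 1L, min_duration = 0.1, amplitude_min = 0.1) {
  if (!N %in% 1:6) ck_stop("'N' must be in 1..6", "catchkin_invalid_parameter")
  if (A_M <= amplitude_min) ck_stop("'A_M' must exceed the amplitude lower bound", "catchkin_invalid_parameter")
  sel <- speed$time >= window[1] - 1e-9 & speed$time <= window[2] + 1e-9
  t <- speed$time[sel]; y <- speed$speed[sel]
  if (length(t) < 3 * N + 1) ck_stop("too few samples in the fitting window", "catchkin_length")
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) ck_stop("speed is constant over the window", "catchkin_degenerate")
  IT <- LT + MT
  t0_lo <- LT - min_duration
  t0_hi <- max(IT - min_duration, t0_lo + 1e-3)
  D_hi <- max(2 * (window[2] - window[1]), 3 * min_duration)
  lower <- c(rep(amplitude_min, N), rep(min_duration, N), rep(t0_lo, N))
  upper <- c(rep(A_M, N), rep(D_hi, N), rep(t0_hi, N))
  lambda <- 1e4 * sst
  A0 <- clamp(A_M / N, amplitude_min, A_M)
  D0 <- clamp(MT / N, min_duration, D_hi)
  centers <- seq(LT, t0_hi, length.out = N + 2)[2:(N + 1)] - D0 / 2
  centers <- clamp(centers, t0_lo, t0_hi)

  runs <- withr::with_seed(seed, {
    lapply(seq_len(restarts), function(r) {
      t0_init <- sort(clamp(rnorm(N, centers, D0 / 2), t0_lo, t0_hi))
      par0 <- c(rep(A0, N), rep(D0, N), t0_init)
      tryCatch(
        optim(par0,
              fn = function(p) as.numeric(submovement_objective(p, t, y, lambda)),
              gr = function(p) submovement_gradient(p, t, y, lambda),
              method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(maxit = 300, factr = 1e6)),
        error = function(e) NULL)
    })
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) {
    ck_stop(sprintf("all %d optimization restarts failed (N = %d)", restarts, N),
            "catchkin_fit_failure")
  }
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  par <- best$par
  o <- submovement_objective(par, t, y, lambda)
  params <- data.frame(A = par[1:N], D = par[N + 1:N], t0 = par[2 * N + 1:N])
  params <- params[order(params$t0), , drop = FALSE]
  rownames(params) <- NULL
  params$t_off <- params$t0 + params$D
  list(params = params,
       r_squared = 1 - attr(o, "sse") / sst,
       sse = attr(o, "sse"),
       convergence = best$convergence,
       restarts_used = length(runs))
}

#' Decompose a speed profile into minimum-jerk submovements
#'
#' Iterates over increasing numbers of components, fitting each with
#' [fit_fixed_n()], and returns the smallest N whose reconstruction reaches
#' the required variance explained (R-squared above `r2_threshold`). The best
#' fit for N components also seeds one restart of the N + 1 fit (augmented
#' with a small extra component), which makes the attained R-squared
#' non-decreasing in N. The total movement amplitude `A_M` is the wrist path
#' length over the window, i.e. the time integral of the speed.
#'
#' @param speed A `speed_series`.
#' @param LT Movement onset (s).
#' @param IT Impact time (s).
#' @param MT Movement duration (s); defaults to `IT - LT`.
#' @param seed Integer seed.
#' @param r2_threshold Required variance explained.
#' @param n_max Maximum number of components tried.
#' @param restarts Random restarts per N.
#' @param threshold Movement threshold used by the window rule (m/s).
#' @param min_duration Minimal submovement duration (s).
#' @return An object of class `submovement_set`.
#' @export
decompose <- function(speed, LT, IT, MT = IT - LT, seed = 1L,
                      r2_threshold = 0.99, n_max = 6, restarts = 20,
                      threshold = 0.05, min_duration = 0.1) {
  window <- select_fit_window(speed, LT, IT, threshold)
  sel <- speed$time >= window[1] - 1e-9 & speed$time <= window[2] + 1e-9
  A_M <- pracma::trapz(speed$time[sel], speed$speed[sel])
  best <- NULL
  prev <- NULL
  for (N in seq_len(n_max)) {
    fit <- tryCatch(
      fit_fixed_n(speed, window, N, A_M, LT, MT, restarts = restarts,
                  seed = seed + N, min_duration = min_duration),
      catchkin_error = function(e) NULL)
    if (!is.null(fit) && !is.null(prev)) {
      # nested warm start: previous best plus one near-degenerate component
      aug <- warm_start_fit(speed, window, N, A_M, LT, MT, prev, min_duration)
      if (!is.null(aug) && aug$sse < fit$sse) fit <- aug
    }
    if (!is.null(fit)) {
      if (is.null(best) || fit$r_squared > best$r_squared ||
          fit$r_squared > r2_threshold) {
        best <- fit; best$N <- N
      }
      prev <- fit
      if (fit$r_squared > r2_threshold) break
    }
  }
  if (is.null(best)) ck_stop("decomposition failed for all N", "catchkin_fit_failure")
  structure(list(params = best$params, N = best$N, window = window,
                 r_squared = best$r_squared, A_M = A_M,
                 below_threshold = best$r_squared <= r2_threshold,
                 restarts = restarts, seed = seed),
            class = "submovement_set")
}

warm_start_fit <- function(speed, window, N, A_M, LT, MT, prev, min_duration) {
  sel <- speed$time >= window[1] - 1e-9 & speed$time <= window[2] + 1e-9
  t <- speed$time[sel]; y <- speed$speed[sel]
  sst <- sum((y - mean(y))^2)
  IT <- LT + MT
  t0_lo <- LT - min_duration
  t0_hi <- max(IT - min_duration, t0_lo + 1e-3)
  D_hi <- max(2 * (window[2] - window[1]), 3 * min_duration)
  p <- prev$params
  extra_t0 <- clamp(mean(window), t0_lo, t0_hi)
  ord <- order(c(p$t0, extra_t0))
  par0 <- c(c(p$A, 0.1)[ord], c(p$D, 2 * min_duration)[ord], sort(c(p$t0, extra_t0)))
  lower <- c(rep(0.1, N), rep(min_duration, N), rep(t0_lo, N))
  upper <- c(rep(A_M, N), rep(D_hi, N), rep(t0_hi, N))
  lambda <- 1e4 * sst
  fit <- tryCatch(
    optim(clamp(par0, lower, upper),
          fn = function(pp) as.numeric(submovement_objective(pp, t, y, lambda)),
          gr = function(pp) submovement_gradient(pp, t, y, lambda),
          method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 300, factr = 1e6)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  o <- submovement_objective(fit$par, t, y, lambda)
  params <- data.frame(A = fit$par[1:N], D = fit$par[N + 1:N], t0 = fit$par[2 * N + 1:N])
  params <- params[order(params$t0), , drop = FALSE]
  rownames(params) <- NULL
  params$t_off <- params$t0 + params$D
  list(params = params, r_squared = 1 - attr(o, "sse") / sst,
       sse = attr(o, "sse"), convergence = fit$convergence, restarts_used = 1L)
}

#' @export
print.submovement_set <- function(x, ...) {
  cat(sprintf("<submovement_set> N = %d, R^2 = %.4f%s, window [%.3f, %.3f] s\n",
              x$N, x$r_squared,
              if (isTRUE(x$below_threshold)) " (below threshold)" else "",
              x$window[1], x$window[2]))
  print(round(x$params, 4))
  invisible(x)
}

#' Classify a movement from its submovement decomposition
#'
#' Type 1: a single-peaked profile (N = 1), or N = 2 with the second
#' component peaking before the speed trough (a gently decelerated approach).
#' Type 2: N = 2 with the second component peaking after the trough (a
#' distinct corrective submovement timed onto the ball). Type 3: three or
#' four components. Decompositions with more components are mapped to type 3
#' with a flag; N = 2 without a detectable trough falls back to type 1 with a
#' flag.
#'
#' @param set A `submovement_set`.
#' @param t_trough1 Time of the first speed trough (s), or `NULL` if absent.
#' @return Integer 1, 2 or 3, with attribute `flag` when a fallback applied.
#' @export
classify_movement <- function(set, t_trough1 = NULL) {
  N <- set$N
  flag <- NULL
  type <- if (N == 1) {
    1L
  } else if (N == 2) {
    peak2 <- set$params$t0[2] + set$params$D[2] / 2
    if (is.null(t_trough1) || is.na(t_trough1)) {
      flag <- "no_trough"
      1L
    } else if (peak2 < t_trough1) 1L else 2L
  } else if (N %in% c(3, 4)) {
    3L
  } else {
    flag <- "n_above_4"
    3L
  }
  if (!is.null(flag)) attr(type, "flag") <- flag
  type
}
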