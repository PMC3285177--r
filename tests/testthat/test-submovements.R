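test_that("minimum-jerk speed has the canonical support, peak and integral", {
  expect_equal(minimum_jerk_speed(1, 1, 0, c(0, 1)), c(0, 0))
  expect_equal(minimum_jerk_speed(1, 1, 0, 0.5), 1.875)
  expect_equal(minimum_jerk_speed(0.4, 0.25, 0.1, 0.225), 1.875 * 0.4 / 0.25)
  # the profile integrates to the displacement amplitude
  for (p in list(c(1, 1, 0), c(0.63, 0.38, 0.12))) {
    q <- integrate(function(t) minimum_jerk_speed(p[1], p[2], p[3], t),
                   p[3], p[3] + p[2], rel.tol = 1e-10)
    expect_equal(q$value, p[1], tolerance = 1e-6)
  }
  expect_equal(minimum_jerk_speed(1, 1, 0.2, c(0.1, 1.5)), c(0, 0))
  expect_error(minimum_jerk_speed(1, 0, 0, 0.5), class = "catchkin_invalid_parameter")
})

test_that("composite speed is the scalar superposition of its components", {
  tt <- seq(0, 1.5, by = 0.01)
  one <- data.frame(A = 0.8, D = 0.5, t0 = 0.1)
  expect_equal(composite_speed(one, tt), minimum_jerk_speed(0.8, 0.5, 0.1, tt))
  disjoint <- data.frame(A = c(0.5, 0.3), D = c(0.3, 0.3), t0 = c(0, 0.8))
  expect_equal(composite_speed(disjoint, tt)[tt <= 0.3],
               minimum_jerk_speed(0.5, 0.3, 0, tt[tt <= 0.3]))
  overlap <- data.frame(A = c(0.5, 0.3), D = c(0.4, 0.4), t0 = c(0, 0.2))
  expect_equal(composite_speed(overlap, 0.3),
               minimum_jerk_speed(0.5, 0.4, 0, 0.3) +
                 minimum_jerk_speed(0.3, 0.4, 0.2, 0.3))
})

test_that("fitting window extends past impact only when the hand keeps moving", {
  tt <- seq(0, 1, by = 0.01)
  high <- speed_series_from(data.frame(A = 1, D = 1, t0 = 0.1), 1, pad = 0)
  high$speed <- pmax(high$speed, 1)  # never drops below threshold after impact
  expect_equal(select_fit_window(high, LT = 0.1, IT = 0.6), c(0.1, 0.7))
  low <- speed_series_from(data.frame(A = 0.5, D = 0.5, t0 = 0.1), 0.6, pad = 0.2)
  expect_equal(select_fit_window(low, LT = 0.1, IT = 0.6), c(0.1, 0.6))
  ends_at_it <- low[low$time <= 0.6, ]
  expect_equal(select_fit_window(ends_at_it, LT = 0.1, IT = 0.6), c(0.1, 0.6))
})

test_that("a single noiseless bump is recovered essentially exactly, deterministically", {
  truth <- data.frame(A = 0.8, D = 0.5, t0 = 0.12)
  sp <- speed_series_from(truth, 0.62)
  fit <- fit_fixed_n(sp, c(0.14, 0.62), 1, A_M = 0.85, LT = 0.14, MT = 0.48,
                     seed = 5)
  expect_lt(abs(fit$params$A - 0.8) / 0.8, 0.01)
  expect_lt(abs(fit$params$D - 0.5) / 0.5, 0.01)
  expect_lt(abs(fit$params$t0 - 0.12), 0.005)
  expect_gt(fit$r_squared, 0.9999)
  fit2 <- fit_fixed_n(sp, c(0.14, 0.62), 1, A_M = 0.85, LT = 0.14, MT = 0.48,
                      seed = 5)
  expect_identical(fit$params, fit2$params)
})

test_that("a two-bump profile cannot be explained by one submovement", {
  truth <- data.frame(A = c(0.5, 0.4), D = c(0.32, 0.34), t0 = c(0.1, 0.48))
  sp <- speed_series_from(truth, 0.82)
  win <- c(0.1, 0.82)
  sel <- sp$time >= win[1] & sp$time <= win[2]
  t <- sp$time[sel]; y <- sp$speed[sel]
  # independent oracle: best single bump by exhaustive grid with the optimal
  # amplitude solved in closed form for each (D, t0)
  best_r2 <- 0
  sst <- sum((y - mean(y))^2)
  for (D in seq(0.1, 1.2, by = 0.02)) {
    for (t0 in seq(0, 0.7, by = 0.01)) {
      b <- minimum_jerk_speed(1, D, t0, t)
      if (sum(b^2) < 1e-12) next
      A <- sum(y * b) / sum(b^2)
      r2 <- 1 - sum((y - A * b)^2) / sst
      best_r2 <- max(best_r2, r2)
    }
  }
  expect_lt(best_r2, 0.99)
  fit1 <- fit_fixed_n(sp, win, 1, A_M = 1, LT = 0.1, MT = 0.72, seed = 2)
  expect_lt(fit1$r_squared, 0.99)
  expect_lte(fit1$r_squared, best_r2 + 0.005)
  # decompose resolves it with two components
  dec <- decompose(sp, 0.1, 0.82, seed = 3)
  expect_equal(dec$N, 2)
  expect_gt(dec$r_squared, 0.99)
  expect_lt(max(abs(sort(dec$params$t0) - truth$t0)), 0.02)
})

test_that("decompose returns the minimal N and conserves total displacement", {
  truth3 <- data.frame(A = c(0.2, 0.35, 0.3), D = c(0.22, 0.28, 0.2),
                       t0 = c(0.1, 0.28, 0.52))
  sp <- speed_series_from(truth3, 0.72)
  dec <- decompose(sp, 0.1, 0.72, seed = 4)
  expect_equal(dec$N, 3)
  expect_gt(dec$r_squared, 0.99)
  expect_false(dec$below_threshold)
  expect_lt(max(abs(dec$params$t0 - truth3$t0)), 0.02)
  # sum of amplitudes matches the path length over the window within 10%
  expect_lt(abs(sum(dec$params$A) - dec$A_M) / dec$A_M, 0.10)
  # onsets and offsets are ordered
  expect_true(all(diff(dec$params$t0) > 0))
  expect_true(all(diff(dec$params$t_off) > 0))
})

test_that("movement types follow the trough-relative classification rules", {
  mk_set <- function(params) {
    structure(list(params = params, N = nrow(params), window = c(0, 1),
                   r_squared = 0.999, A_M = sum(params$A),
                   below_threshold = FALSE), class = "submovement_set")
  }
  expect_equal(as.integer(classify_movement(
    mk_set(data.frame(A = 1, D = 0.5, t0 = 0.1)), t_trough1 = NULL)), 1L)
  # N = 2, second peak (t0 + D/2 = 0.55) after the trough at 0.52 -> type 2
  two <- mk_set(data.frame(A = c(0.5, 0.3), D = c(0.4, 0.3), t0 = c(0.1, 0.4)))
  expect_equal(as.integer(classify_movement(two, t_trough1 = 0.52)), 2L)
  # same set, trough after the second peak -> type 1
  expect_equal(as.integer(classify_movement(two, t_trough1 = 0.6)), 1L)
  # N = 2 without a trough -> type 1 with a flag
  cl <- classify_movement(two, t_trough1 = NULL)
  expect_equal(as.integer(cl), 1L)
  expect_identical(attr(cl, "flag"), "no_trough")
  expect_equal(as.integer(classify_movement(
    mk_set(data.frame(A = rep(0.3, 3), D = rep(0.3, 3), t0 = c(0, 0.3, 0.6))),
    t_trough1 = 0.3)), 3L)
})

test_that("degenerate decomposition inputs raise typed errors", {
  sp <- speed_series_from(data.frame(A = 0.8, D = 0.5, t0 = 0.1), 0.6)
  expect_error(fit_fixed_n(sp, c(0.1, 0.6), 7, 1, 0.1, 0.5),
               class = "catchkin_invalid_parameter")
  expect_error(fit_fixed_n(sp, c(0.1, 0.6), 1, 0.05, 0.1, 0.5),
               class = "catchkin_invalid_parameter")
  const <- sp; const$speed <- rep(1, nrow(const))
  expect_error(fit_fixed_n(const, c(0.1, 0.6), 1, 1, 0.1, 0.5),
               class = "catchkin_degenerate")
})
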