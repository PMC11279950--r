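test_that("double-Weibull closed form matches the divisor convention", {
  wr <- dog_release_truth()
  # at t = 0 with no lag, every exponential equals 1
  expect_identical(eval_release(wr, 0), 0)
  # asymptote equals the maximum release
  expect_equal(eval_release(wr, 1e7), 100, tolerance = 1e-9)
  # hand-computed value: 100*(1 - 0.142*exp(-24^0.717/30.88)
  #                           - 0.858*exp(-24^1.285/6370.7))
  byhand <- 100 * (1 - 0.142 * exp(-24^0.717 / 30.88) -
                     0.858 * exp(-24^1.285 / 6370.7))
  expect_equal(eval_release(wr, 24), byhand, tolerance = 1e-12)
  # half-release time found by an independent bisection on the closed form
  f <- function(t) 100 * (1 - 0.142 * exp(-t^0.717 / 30.88) -
                            0.858 * exp(-t^1.285 / 6370.7)) - 50
  lo <- 100; hi <- 1000
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  t50_oracle <- (lo + hi) / 2
  expect_gt(t50_oracle, 100)
  expect_lt(t50_oracle, 1000)
  expect_equal(invert_release(wr, 50), t50_oracle, tolerance = 1e-6)
})

test_that("constructor validates parameters, not evaluation", {
  expect_error(weibull_release(100, 0, c(0.5, 0.4), c(1, 1), c(1, 1)),
               "sum to 1")
  expect_error(weibull_release(100, 0, c(0.5, 0.5), c(1, -1), c(1, 1)),
               "time scales")
  expect_error(weibull_release(100, 0, c(0.5, 0.5), c(1, 1), c(0, 1)),
               "shapes")
  expect_error(weibull_release(0, 0, 1, 1, 1), "max_release_pct")
  expect_error(weibull_release(100, -1, 1, 1, 1), "t_lag")
  expect_error(weibull_release(100, 0, rep(0.25, 4), rep(1, 4), rep(1, 4)),
               "between 1 and 3")
})

test_that("release is monotone, bounded, and zero below the lag", {
  set.seed(7)
  tt <- sort(c(0, 10^runif(60, -2, 5)))
  for (k in 1:25) {
    n <- sample(1:3, 1)
    f <- runif(n); f <- f / sum(f)
    wr <- weibull_release(runif(1, 10, 100), runif(1, 0, 5), f,
                          10^runif(n, -2, 6), runif(n, 0.3, 4))
    y <- eval_release(wr, tt)
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(y >= 0 & y <= wr$max_release_pct + 1e-9))
    expect_identical(eval_release(wr, wr$t_lag * 0.9), 0)
  }
})

test_that("a 2-phase model with a vanishing fraction equals the 1-phase model", {
  tt <- c(0, 0.5, 2, 10, 60, 300)
  w1 <- weibull_release(90, 1, 1, 40, 0.8)
  w2 <- weibull_release(90, 1, c(1, 0), c(40, 1000), c(0.8, 2))
  expect_equal(eval_release(w2, tt), eval_release(w1, tt),
               tolerance = 1e-14)
})

test_that("release rate is the analytic derivative of cumulative release", {
  wr <- dog_release_truth()
  expect_identical(release_rate(wr, numeric(0)), numeric(0))
  # quadrature of the rate reproduces the cumulative curve
  q <- integrate(function(t) release_rate(wr, t), 0, 5000,
                 subdivisions = 2000L, rel.tol = 1e-9)
  expect_equal(q$value, eval_release(wr, 5000), tolerance = 1e-3)
  # rate is non-negative and zero before the lag
  wl <- weibull_release(100, 2, c(0.3, 0.7), c(10, 500), c(1.2, 0.9))
  expect_identical(release_rate(wl, 1), 0)
  tt <- seq(2.01, 100, length.out = 50)
  expect_true(all(release_rate(wl, tt) >= 0))
  # single-exponential phase: initial rate = Max / A
  ws <- weibull_release(100, 0, 1, 1, 1)
  expect_equal(release_rate(ws, 0), 100)
})

test_that("inversion round-trips and rejects unreachable targets", {
  wr <- dog_release_truth()
  expect_identical(invert_release(wr, 0), 0)
  for (t0 in c(10, 100, 1000)) {
    y <- eval_release(wr, t0)
    expect_equal(invert_release(wr, y), t0, tolerance = 1e-6)
  }
  expect_error(invert_release(wr, 100), "unreachable")
  expect_error(invert_release(wr, 150), "unreachable")
})

test_that("fitting recovers generating parameters from noise-free data", {
  tt <- design_invitro()$sampling_times
  wr <- dog_release_truth()
  f2 <- fit_weibull(list(times = tt,
                         cumulative_pct = eval_release(wr, tt)),
                    n_phases = 2, n_starts = 8, seed = 1)
  expect_true(f2$converged)
  expect_lt(wb_max_rel_err(f2$release, wr), 1e-3)
  # single-exponential series: shape recovered to 1e-3
  ws <- weibull_release(100, 0, 1, 10, 1)
  f1 <- fit_weibull(list(times = tt,
                         cumulative_pct = eval_release(ws, tt)),
                    n_phases = 1, n_starts = 8, seed = 1)
  expect_lt(abs(f1$release$shapes - 1), 1e-3)
})

test_that("fitting rejects degenerate and under-determined input", {
  tt <- design_invitro()$sampling_times
  expect_error(fit_weibull(list(times = tt,
                                cumulative_pct = rep(0, length(tt))),
                           n_phases = 2), "degenerate")
  expect_error(fit_weibull(list(times = c(1, 2, 4, 8),
                                cumulative_pct = c(5, 10, 20, 30)),
                           n_phases = 2), "under-determined")
})

test_that("release profiles clean small non-monotonicities and reject large ones", {
  tt <- c(1, 2, 4, 8, 16)
  p <- release_profile(tt, c(10, 20, 19.5, 30, 40))
  expect_true(all(diff(p$cumulative_pct) >= 0))
  expect_error(release_profile(tt, c(10, 30, 20, 40, 50)),
               "percentage points")
  expect_error(release_profile(tt, c(10, 30, 20, 40, 50), clean = FALSE))
})

test_that("triple-Weibull fraction sets of both strengths lie on the simplex", {
  expect_equal(sum(human_release_truth("50")$fractions), 1,
               tolerance = 1e-6)
  expect_equal(sum(human_release_truth("225")$fractions), 1,
               tolerance = 1e-6)
})
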