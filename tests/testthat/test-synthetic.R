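test_that("zero-CV datasets reproduce the truth curve exactly and seeds reproduce", {
  d <- dog_disp()
  des <- design_dog_iv()
  truth <- simulate_disposition(d, dose_event(1), des$sampling_times)
  ds0 <- gen_pk_dataset(truth, des, noise_model(cv = 0, lloq = 0,
                                                seed = 1))
  for (p in ds0) expect_equal(p$conc, truth$conc, tolerance = 1e-12)
  n1 <- noise_model(0.15, 0.05, seed = 11)
  a <- gen_pk_dataset(truth, des, n1)
  b <- gen_pk_dataset(truth, des, n1)
  expect_identical(lapply(a, `[[`, "conc"), lapply(b, `[[`, "conc"))
  c2 <- gen_pk_dataset(truth, des, noise_model(0.15, 0.05, seed = 12))
  expect_false(identical(a[[1]]$conc, c2[[1]]$conc))
})

test_that("simulated noise carries the requested geometric CV", {
  des <- study_design("flat", 1, "iv_bolus", c(1, 2), n_subjects = 1000L)
  truth <- function(t) rep(100, length(t))
  ds <- gen_pk_dataset(truth, des, noise_model(0.15, 0, seed = 5))
  x <- vapply(ds, function(p) p$conc[1], numeric(1))
  gcv <- sqrt(exp(var(log(x))) - 1)
  expect_lt(abs(gcv - 0.15) / 0.15, 0.10)
})

test_that("values below the LLOQ are reported as zero", {
  des <- study_design("low", 1, "iv_bolus", c(1, 2), n_subjects = 50L)
  ds <- gen_pk_dataset(function(t) c(0.01, 10), des,
                       noise_model(0.1, 0.05, seed = 2))
  first <- vapply(ds, function(p) p$conc[1], numeric(1))
  expect_true(all(first == 0))
})

test_that("in vitro replicates are non-decreasing for any seed and unbiased", {
  wr <- dog_release_truth()
  des <- design_invitro()
  for (s in 1:100) {
    reps <- gen_invitro_dataset(wr, des, noise_model(0.15, seed = s))
    expect_true(all(vapply(reps, function(r)
      all(diff(r$cumulative_pct) >= 0), logical(1))))
  }
  # replicate mean at the last time is centred on the truth
  des_big <- design_invitro(n_subjects = 400L)
  reps <- gen_invitro_dataset(wr, des_big, noise_model(0.15, seed = 1))
  last <- vapply(reps, function(r) r$cumulative_pct[16], numeric(1))
  truth_last <- eval_release(wr, 672)
  expect_lt(abs(mean(last) - truth_last) / truth_last, 0.02)
  # zero CV reproduces the truth
  r0 <- gen_invitro_dataset(wr, design_invitro(n_subjects = 2L),
                            noise_model(0, seed = 1))
  expect_equal(r0[[1]]$cumulative_pct,
               eval_release(wr, des$sampling_times), tolerance = 1e-12)
})

test_that("geometric-mean summary follows the lognormal identities", {
  # {1, 100} -> geometric mean 10
  pr <- list(conc_profile(c(1, 2), c(1, 5)),
             conc_profile(c(1, 2), c(100, 5)))
  expect_equal(summarize_geomean(pr)$profile$conc[1], 10)
  # identical profiles: mean equals input, CV 0
  same <- list(conc_profile(1:3, c(4, 5, 6)), conc_profile(1:3, c(4, 5, 6)))
  sg <- summarize_geomean(same)
  expect_equal(sg$profile$conc, c(4, 5, 6))
  expect_equal(sg$cv, rep(0, 3))
  # lognormal sigma 0.5: geometric CV = sqrt(exp(0.25) - 1)
  set.seed(9)
  n <- 1e4
  vals <- exp(rnorm(n, 0, 0.5))
  prof <- lapply(vals, function(v) conc_profile(1, v))
  gcv <- summarize_geomean(prof)$cv[1]
  expect_lt(abs(gcv - sqrt(exp(0.25) - 1)) / sqrt(exp(0.25) - 1), 0.02)
  # BLQ zeros are excluded with counts; all-zero points are flagged
  zz <- list(conc_profile(1:2, c(0, 0)), conc_profile(1:2, c(8, 0)))
  sz <- summarize_geomean(zz)
  expect_equal(sz$profile$conc, c(8, 0))
  expect_equal(sz$n_excluded, c(1L, 2L))
  expect_equal(sz$all_zero, c(FALSE, TRUE))
})
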