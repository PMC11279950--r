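# iv stage ------------------------------------------------------------------

test_that("iv disposition is recovered from a noise-free bolus curve", {
  d <- dog_disp()
  tt <- design_dog_iv()$sampling_times
  prof <- simulate_disposition(d, dose_event(1), tt)
  fit <- fit_iv(prof, model_order = 1, body_weight = 10, n_starts = 6,
                seed = 1)
  expect_lt(rel_err(fit$estimates$cl, 8.3), 5e-3)
  expect_lt(rel_err(fit$estimates$vc, 1.13), 5e-3)
  expect_gt(fit$r_squared, 0.999999)
  expect_true(fit$converged)
})

test_that("model order comparison: 1-compartment fit of 2-compartment data scores lower", {
  d2 <- disposition_params(8.3, 1.13, k12 = 0.8, k21 = 0.15,
                           body_weight = 10)
  tt <- design_dog_iv()$sampling_times
  prof <- simulate_disposition(d2, dose_event(1), tt)
  f1 <- fit_iv(prof, model_order = 1, body_weight = 10, n_starts = 6,
               seed = 1)
  f2 <- fit_iv(prof, model_order = 2, body_weight = 10, n_starts = 8,
               seed = 1)
  expect_lt(f1$r_squared, f2$r_squared)
  expect_gt(f2$r_squared, 0.9999)
})

test_that("iv fitting errors on under-determined input and wrong route", {
  d <- dog_disp()
  p2 <- conc_profile(c(1, 2), c(50, 20), dose = 1, route = "iv_bolus")
  expect_error(fit_iv(p2, body_weight = 10), "under-determined")
  psc <- conc_profile(1:9, 9:1, dose = 1, route = "sc_ir")
  expect_error(fit_iv(psc, body_weight = 10), "iv-route")
})

# Kp stage -------------------------------------------------------------------

ir_release <- weibull_release(100, 0, 1, 0.05, 1)

make_ir_profile <- function(kp, disp = dog_disp()) {
  tt <- design_dog_ir_sc()$sampling_times
  site <- depot_site_params(kp, 0.1, 1.2)
  p <- simulate_depot(disp, site, ir_release, dose_event(5), tt)
  conc_profile(tt, p$conc, dose = 5, route = "sc_ir")
}

test_that("Kp is recovered to 1% from a noise-free immediate-release profile", {
  prof <- make_ir_profile(1.9)
  fit <- fit_kp(prof, dog_disp())
  expect_lt(rel_err(fit$estimates$kp, 1.9), 0.01)
  expect_gt(fit$r_squared, 0.99999)
})

test_that("a truth Kp at the search bound raises the bound-hit flag", {
  prof <- make_ir_profile(100)
  fit <- fit_kp(prof, dog_disp())
  expect_true(fit$bounds_hit$kp)
})

test_that("a mismatched fixed clearance degrades the Kp-stage fit", {
  prof <- make_ir_profile(1.9)
  good <- fit_kp(prof, dog_disp())
  wrong_cl <- disposition_params(2 * 8.3, 1.13, body_weight = 10,
                                 fu = 0.083, bp = 0.51)
  bad <- fit_kp(prof, wrong_cl)
  expect_gt(bad$ssr, good$ssr * 10)
})

# in vivo release stage ------------------------------------------------------

test_that("the in vivo double Weibull is recovered through the simulator", {
  d <- dog_disp(); site <- dog_site()
  wr <- dog_release_truth()
  tt <- design_dog_lai()$sampling_times
  prof <- simulate_depot(d, site, wr, dose_event(50), tt)
  fit <- fit_release_in_vivo(prof, d, site, n_phases = 2, n_starts = 16,
                             seed = 1)
  expect_lt(wb_max_rel_err(fit$release, wr), 0.02)
  expect_gt(fit$r_squared, 0.999999)
})

test_that("geometric-mean input from noisy dogs keeps exposure within 10% of truth", {
  d <- dog_disp(); site <- dog_site()
  wr <- dog_release_truth()
  des <- design_dog_lai()
  truth_prof <- simulate_depot(d, site, wr, dose_event(50),
                               des$sampling_times)
  ds <- gen_pk_dataset(truth_prof, des, noise_model(0.15, 0.05, seed = 42))
  gm <- summarize_geomean(ds)$profile
  fit <- fit_release_in_vivo(gm, d, site, n_phases = 2, n_starts = 16,
                             seed = 1)
  tg <- sort(unique(c(seq(0.5, 672, by = 2), des$sampling_times)))
  ex_t <- exposure_summary(simulate_depot(d, site, wr, dose_event(50), tg))
  ex_f <- exposure_summary(simulate_depot(d, site, fit$release,
                                          dose_event(50), tg))
  expect_lt(rel_err(ex_f$cmax, ex_t$cmax), 0.10)
  expect_lt(rel_err(ex_f$auc_last, ex_t$auc_last), 0.10)
})

test_that("release fitting is deterministic under a fixed seed and flags bad input", {
  d <- dog_disp(); site <- dog_site()
  tt <- design_dog_lai()$sampling_times
  prof <- simulate_depot(d, site, dog_release_truth(), dose_event(50), tt)
  f1 <- fit_release_in_vivo(prof, d, site, n_phases = 2, n_starts = 4,
                            seed = 3)
  f2 <- fit_release_in_vivo(prof, d, site, n_phases = 2, n_starts = 4,
                            seed = 3)
  expect_identical(unlist(f1$estimates), unlist(f2$estimates))
  flat <- conc_profile(tt, rep(0, length(tt)), dose = 50, route = "sc_lai")
  expect_error(fit_release_in_vivo(flat, d, site), "under-determined|degenerate")
})

test_that("adding a third phase never fits worse than two (nesting)", {
  d <- dog_disp(); site <- dog_site()
  tt <- design_invitro()$sampling_times   # 16 points identify 11 parameters
  prof <- simulate_depot(d, site, dog_release_truth(), dose_event(50), tt)
  f2 <- fit_release_in_vivo(prof, d, site, n_phases = 2, n_starts = 6,
                            seed = 1)
  f3 <- fit_release_in_vivo(prof, d, site, n_phases = 3, n_starts = 6,
                            seed = 1)
  expect_gt(f3$r_squared, f2$r_squared - 1e-6)
})
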