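# one mechanistic deconvolution per file run, shared across blocks
.hd <- human_disposition_truth()
.hs <- human_site()
.th <- design_human_lai()$sampling_times
.w50 <- human_release_truth("50")
.obs50 <- simulate_depot(.hd, .hs, .w50, dose_event(50), .th)
.dec50 <- deconvolve(.obs50, .hd, .hs, n_phases = 3, n_starts = 8,
                     seed = 1)

test_that("mechanistic deconvolution recovers the generating absorbed series", {
  truth_abs <- eval_release(.w50, .th)
  expect_lt(max(abs(.dec50$absorbed$absorbed_pct - truth_abs)), 1)
  expect_true(all(diff(.dec50$absorbed$absorbed_pct) >= 0))
  expect_lt(wb_max_rel_err(.dec50$release, .w50), 0.02)
})

test_that("deconvolution rejects a flat-zero profile", {
  flat <- conc_profile(.th, rep(0, length(.th)), dose = 50,
                       route = "sc_lai")
  expect_error(deconvolve(flat, .hd, .hs), "degenerate|flat")
})

test_that("convolve-then-deconvolve round trip stays within 2% absolute", {
  # the fitted release drives a fresh simulation; deconvolved series of
  # that simulation must reproduce the original absorbed series
  resim <- simulate_depot(.hd, .hs, .dec50$release, dose_event(50), .th)
  dec2 <- deconvolve(resim, .hd, .hs, n_phases = 3, n_starts = 8, seed = 2)
  expect_lt(max(abs(dec2$absorbed$absorbed_pct -
                    .dec50$absorbed$absorbed_pct)), 2)
})

test_that("Levy scaling recovers a constructed single slope exactly", {
  wr <- dog_release_truth()
  tt <- design_invitro()$sampling_times
  vit <- release_profile(tt, eval_release(wr, tt), strength_mg = 50)
  viv <- absorbed_fraction_series(tt * 11.05, eval_release(wr, tt),
                                  strength_mg = 50)
  ts <- levy_time_scaling(vit, viv)
  expect_equal(ts$slope, 11.05, tolerance = 1e-9)
  expect_equal(ts$r_squared, 1, tolerance = 1e-12)
})

test_that("pooling strengths with different true slopes lands between them", {
  wr <- dog_release_truth()
  tt <- design_invitro()$sampling_times
  vit <- list(release_profile(tt, eval_release(wr, tt), strength_mg = 50),
              release_profile(tt, eval_release(wr, tt), strength_mg = 225))
  viv <- list(absorbed_fraction_series(tt * 10, eval_release(wr, tt),
                                       strength_mg = 50),
              absorbed_fraction_series(tt * 13, eval_release(wr, tt),
                                       strength_mg = 225))
  ts <- levy_time_scaling(vit, viv)
  expect_gt(ts$slope, 10)
  expect_lt(ts$slope, 13)
  expect_lt(ts$r_squared, 1)
})

test_that("fractions outside a profile's observed range are dropped and counted", {
  wr <- dog_release_truth()
  tt <- design_invitro()$sampling_times[1:8]   # covers only ~17% released
  vit <- release_profile(tt, eval_release(wr, tt), strength_mg = 50)
  viv <- absorbed_fraction_series(tt * 11, eval_release(wr, tt),
                                  strength_mg = 50)
  ts <- levy_time_scaling(vit, viv, fraction_grid = c(3, 5, 10, 40, 60))
  expect_equal(nrow(ts$matched_pairs), 3)
  expect_equal(ts$n_dropped, 2)
  expect_error(levy_time_scaling(vit, viv, fraction_grid = c(40, 60)),
               "fewer than 3")
})

test_that("correlation fitting recovers an exact quadratic and ranks families", {
  x <- seq(0, 100, 10)
  y <- 0.0085 * x^2 + 0.319 * x + 0.113
  corr <- fit_correlation(x, y)
  expect_equal(corr$family, "poly2")
  expect_equal(unname(corr$coefficients),
               c(0.113, 0.319, 0.0085), tolerance = 1e-10)
  expect_equal(corr$r_squared, 1, tolerance = 1e-12)
  # the quadratic evaluated at zero released is the intercept
  expect_equal(predict(corr, 0), 0.113, tolerance = 1e-10)
  # nested families never score lower than their sub-family
  lb <- corr$leaderboard
  r2 <- setNames(lb$r_squared, lb$family)
  expect_gte(r2[["poly2"]] + 1e-12, r2[["linear"]])
  expect_gte(r2[["poly3"]] + 1e-12, r2[["poly2"]])
})

test_that("linear data ties are broken toward fewer coefficients", {
  x <- seq(0, 100, 10)
  corr <- fit_correlation(x, 0.4 * x + 2)
  expect_equal(corr$family, "linear")
  expect_equal(corr$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_correlation(rep(10, 11), seq(0, 100, 10)), "singular")
})

test_that("identity correlation wiring matches direct depot simulation", {
  d <- dog_disp(); site <- dog_site()
  wrf <- weibull_release(100, 0, 1, 24, 1)
  tt <- sort(unique(c(seq(0.25, 48, by = 0.25), seq(49, 336, by = 1))))
  vit <- release_profile(tt, eval_release(wrf, tt), strength_mg = 50)
  ts1 <- structure(list(slope = 1, r_squared = 1, matched_pairs = NULL,
                        n_dropped = 0L), class = "time_scaling")
  ident <- fit_correlation(seq(0, 100, 5), seq(0, 100, 5),
                           families = "linear")
  out_t <- c(1, 2, 4, 8, 16, 24, 48, 96, 168, 240, 336)
  pred <- convolve_predict(vit, ts1, ident, d, site, dose = 50,
                           times = out_t)
  direct <- simulate_depot(d, site, wrf, dose_event(50), out_t)
  expect_lt(max(abs(pred$conc - direct$conc) / direct$conc), 0.01)
  empty <- release_profile(1, 10, strength_mg = 50)
  empty$times <- numeric(0); empty$cumulative_pct <- numeric(0)
  expect_error(convolve_predict(empty, ts1, ident, d, site, dose = 50),
               "empty")
})

test_that("internal validation reproduces the printed mean errors and verdict", {
  obs <- list(`50` = list(cmax = 5.0, auc_last = 3839),
              `225` = list(cmax = 8.7, auc_last = 8296))
  prd <- list(`50` = list(cmax = 4.3, auc_last = 2876),
              `225` = list(cmax = 7.0, auc_last = 9440))
  rep <- internal_validation(obs, prd)
  expect_lt(abs(rep$mean_pe_cmax - 16.7), 0.1)
  expect_lt(abs(rep$mean_pe_auc - 19.4), 0.1)
  expect_false(rep$level_a_pass)
  # means are the arithmetic mean of the table rows
  expect_equal(rep$mean_pe_cmax, mean(rep$table$pe_cmax))
  expect_equal(rep$mean_pe_auc, mean(rep$table$pe_auc))
})

test_that("validation criterion arithmetic: identical input passes, mismatch errors", {
  same <- list(`50` = list(cmax = 5, auc_last = 100),
               `225` = list(cmax = 8, auc_last = 200))
  rep <- internal_validation(same, same)
  expect_true(rep$level_a_pass)
  expect_equal(rep$mean_pe_cmax, 0)
  # 9% and 11% average to exactly the 10% mean bound; both within 15%
  obs <- list(a = list(cmax = 100, auc_last = 100),
              b = list(cmax = 100, auc_last = 100))
  prd <- list(a = list(cmax = 91, auc_last = 91),
              b = list(cmax = 111, auc_last = 111))
  rep2 <- internal_validation(obs, prd)
  expect_true(rep2$level_a_pass)
  expect_true(rep2$individual_within_15)
  expect_error(internal_validation(same, same[1]), "mismatch")
})
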