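test_that("closed-form bolus disposition has the textbook Cmax and AUC", {
  d <- dog_disp()
  tt <- c(0, exp(seq(log(1e-3), log(72), length.out = 199)))
  prof <- simulate_disposition(d, dose_event(1), tt)
  # C(0+) = dose / (Vc * BW): 1 mg / 11.3 L = 88.5 ng/mL
  expect_equal(prof$conc[1], 1 / (1.13 * 10) * 1000, tolerance = 1e-12)
  ex <- exposure_summary(prof)
  expect_equal(ex$auc_inf, 1 / 8.3 * 1000, tolerance = 5e-3)
})

test_that("infusion AUC is dose/CL regardless of duration", {
  d <- dog_disp()
  for (dur in c(0.25, 2)) {
    tt <- c(0, exp(seq(log(1e-3), log(120), length.out = 250)))
    prof <- simulate_disposition(d, dose_event(1, duration = dur), tt)
    ex <- exposure_summary(prof)
    expect_equal(ex$auc_inf, 1 / 8.3 * 1000, tolerance = 5e-3)
  }
})

test_that("2-compartment solution degenerates to 1-compartment when K12 = K21 = 0", {
  tt <- c(0, 0.5, 2, 8, 24)
  d1 <- disposition_params(8.3, 1.13, body_weight = 10)
  d2 <- disposition_params(8.3, 1.13, k12 = 1e-12, k21 = 1e-12,
                           body_weight = 10)
  p1 <- simulate_disposition(d1, dose_event(1), tt)
  p2 <- simulate_disposition(d2, dose_event(1), tt)
  expect_equal(p2$conc, p1$conc, tolerance = 1e-9)
  expect_error(disposition_params(8.3, 1.13, k12 = 0.5, k21 = 0,
                                  body_weight = 10), "both")
})

test_that("depot with instantaneous release, high flow and Kp 1 converges to iv bolus", {
  d <- dog_disp()
  site <- depot_site_params(1, 1e-3, 1e4)
  rel <- weibull_release(100, 0, 1, 1e-6, 1)
  tg <- c(0.05, 0.5, 1, 2, 5, 10)
  pd <- simulate_depot(d, site, rel, dose_event(1), tg)
  pb <- simulate_disposition(d, dose_event(1), tg)
  expect_lt(max(abs(pd$conc - pb$conc) / pb$conc), 0.01)
})

test_that("depot mass balance holds to 1e-8 and dose proportionality is exact", {
  d <- dog_disp()
  site <- dog_site()
  wr <- dog_release_truth()
  tg <- c(1, 3, 6, 24, 168, 336, 672)
  p1 <- simulate_depot(d, site, wr, dose_event(50), tg)
  expect_lt(attr(p1, "mass_balance_rel"), 1e-8)
  p2 <- simulate_depot(d, site, wr, dose_event(100), tg)
  expect_lt(max(abs(p2$conc / p1$conc - 2)), 1e-10)
  expect_error(dose_event(0), "amount")
})

test_that("halving the integration tolerance leaves concentrations unchanged to 0.01%", {
  d <- dog_disp()
  p1 <- simulate_depot(d, dog_site(), dog_release_truth(), dose_event(50),
                       c(1, 24, 168, 672), rtol = 1e-10)
  p2 <- simulate_depot(d, dog_site(), dog_release_truth(), dose_event(50),
                       c(1, 24, 168, 672), rtol = 5e-11)
  expect_lt(max(abs(p2$conc - p1$conc) / p1$conc), 1e-4)
})

test_that("depot AUC equals dose/CL when the full dose is eventually released", {
  d <- dog_disp()
  # moderately fast full release so the tail is well captured
  wr <- weibull_release(100, 0, 1, 24, 1)
  tt <- c(0, exp(seq(log(0.01), log(1500), length.out = 250)))
  ex <- exposure_summary(simulate_depot(d, dog_site(), wr, dose_event(50),
                                        tt))
  expect_equal(ex$auc_inf, 50 / 8.3 * 1000, tolerance = 5e-3)
})

test_that("LAI terminal half-life shows flip-flop kinetics (>100x the iv half-life)", {
  d <- dog_disp()
  tg <- seq(500, 1500, by = 50)
  pl <- simulate_depot(d, dog_site(), dog_release_truth(), dose_event(50),
                       tg)
  slope <- coef(lm(log(pl$conc) ~ tg))[2]
  t_half_lai <- log(2) / -slope
  t_half_iv <- log(2) * 1.13 * 10 / 8.3
  expect_gt(t_half_lai / t_half_iv, 100)
})

test_that("metabolite tracking conserves moles and honours fraction_formed", {
  d <- dog_disp()
  met0 <- metabolite_params(4.8, 1.13, fraction_formed = 0)
  s0 <- simulate_with_metabolite(d, met0, dose_event(1), c(1, 2, 5))
  expect_identical(max(s0$metabolite$conc), 0)
  # fraction_formed 1 with CL_met = CL: molar AUCs match
  met1 <- metabolite_params(8.3, 1.13, fraction_formed = 1)
  tt <- c(0.001, exp(seq(log(0.01), log(120), length.out = 150)))
  s1 <- simulate_with_metabolite(d, met1, dose_event(1), tt)
  auc_p <- exposure_summary(s1$parent)$auc_inf / 410.49
  auc_m <- exposure_summary(s1$metabolite)$auc_inf / 426.48
  expect_equal(auc_m, auc_p, tolerance = 5e-3)
  # steady infusion: conc ratio = ff * CL/CL_met with the molar correction
  met <- metabolite_params(2, 1.13, fraction_formed = 0.7)
  sinf <- simulate_with_metabolite(d, met, dose_event(100, 0, 2000),
                                   c(1000, 1250, 1500))
  expect_equal(sinf$metabolite$conc[3] / sinf$parent$conc[3],
               0.7 * 8.3 / 2 * 426.48 / 410.49, tolerance = 1e-4)
  expect_error(metabolite_params(4.8), "v_met")
})

test_that("IVIVE clearance follows the well-stirred model arithmetic", {
  scl <- ivive_scaling()
  # hand arithmetic for the CYP3A4 assay alone:
  # Vm/Km * abundance * MPPGL * liver mass, uL/min -> L/h, then well-stirred
  clint <- 12.4 / 37.4 * 137 * 40 * 1800 * 60 / 1e6
  fub <- 0.10 / 0.67
  clh <- 90 * fub * clint / (90 + fub * clint)
  res <- ivive_clearance(mm_params("CYP3A4", 12.4, 37.4), scl,
                         fu = 0.10, bp = 0.67)
  expect_equal(res$cl_int_u, clint, tolerance = 1e-12)
  expect_equal(res$cl_blood, clh, tolerance = 1e-12)
  expect_equal(res$cl_plasma, clh * 0.67, tolerance = 1e-12)
  # zero Vm: no clearance
  expect_equal(ivive_clearance(mm_params("CYP3A4", c(0), c(37.4)), scl,
                               fu = 0.10, bp = 0.67)$cl_blood, 0)
  # flow limit as intrinsic clearance grows
  huge <- ivive_clearance(mm_params("CYP3A4", 1e9, 1), scl,
                          fu = 0.10, bp = 0.67)
  expect_equal(huge$cl_blood, 90, tolerance = 1e-3)
  # enzyme subset selection
  mm <- risperidone_mm_truth()
  all3 <- ivive_clearance(mm, scl, fu = 0.10, bp = 0.67)
  only34 <- ivive_clearance(mm, scl, fu = 0.10, bp = 0.67,
                            enzymes = "CYP3A4")
  expect_lt(only34$cl_blood, all3$cl_blood)
  expect_equal(only34$cl_blood, clh, tolerance = 1e-12)
})
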