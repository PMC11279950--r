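#' @title Staged calibration of the depot PK model
#' @description The calibration mirrors the staging used for depot
#'   formulations: (1) iv data identify disposition (clearance first, to
#'   defeat flip-flop kinetics), (2) immediate-release sc data identify the
#'   injection-site partition coefficient Kp with clearance frozen, (3)
#'   long-acting sc data identify the in vivo Weibull release with both
#'   frozen. Each stage is a bounded least-squares problem on a
#'   geometric-mean profile.
#' @name calibration
NULL

.fit_result <- function(stage, estimates, bounds_hit, r_squared, residuals,
                        seed, n_starts, converged, extra = list()) {
  structure(c(list(stage = stage, estimates = estimates,
                   bounds_hit = bounds_hit, r_squared = r_squared,
                   residuals = residuals, seed = seed, n_starts = n_starts,
                   converged = converged), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> stage %s, R^2 = %.6f, converged = %s\n",
              x$stage, x$r_squared, x$converged))
  est <- unlist(x$estimates)
  for (nm in names(est)) {
    flag <- if (isTRUE(x$bounds_hit[[nm]])) "  [at bound]" else ""
    cat(sprintf("  %-12s %.6g%s\n", nm, est[[nm]], flag))
  }
  invisible(x)
}

# residuals on the requested objective scale; concentrations in ng/mL
.obj_resid <- function(pred, obs, log_objective) {
  if (log_objective) {
    eps <- max(obs) * 1e-9
    log(pmax(pred, eps)) - log(pmax(obs, eps))
  } else pred - obs
}

.r2 <- function(pred, obs) 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)

#' Fit iv disposition to a plasma profile
#'
#' Bounded multi-start least squares of the closed-form 1- or 2-compartment
#' iv solution against a (geometric-mean) iv profile.
#'
#' @param profile an iv-route [conc_profile()].
#' @param model_order 1 or 2 compartments.
#' @param body_weight kg (fixed, not estimated).
#' @param dose a [dose_event()] describing the administration; defaults to a
#'   bolus of `profile$dose` at time 0.
#' @param n_starts,seed multi-start control (deterministic given both).
#' @param log_objective fit on the log-concentration scale instead of the
#'   untransformed default.
#' @return A `fit_result` with estimates `cl` (L/h), `vc` (L/kg) and, for
#'   order 2, `k12`, `k21` (1/h).
#' @export
fit_iv <- function(profile, model_order = 1L, body_weight = 10,
                   dose = NULL, n_starts = 8L, seed = 1L,
                   log_objective = FALSE) {
  stopifnot(inherits(profile, "conc_profile"))
  if (!profile$route %in% c("iv_bolus", "iv_infusion"))
    stop("'fit_iv' needs an iv-route profile, got ", profile$route)
  if (is.null(dose)) dose <- dose_event(profile$dose)
  model_order <- as.integer(model_order)
  stopifnot(model_order %in% c(1L, 2L))
  n_free <- if (model_order == 1L) 2L else 4L
  keep <- profile$conc > 0
  t <- profile$times[keep]; obs <- profile$conc[keep]
  if (length(t) < 2L * n_free)
    stop("under-determined fit: ", length(t), " positive points for ",
         n_free, " free parameters")

  # theta: log10 CL, log10 Vc [, log10 k12, log10 k21]
  lower <- c(log10(0.1), log10(0.05), if (model_order == 2L) rep(-4, 2))
  upper <- c(log10(100), log10(20), if (model_order == 2L) rep(1, 2))
  mk <- function(theta) {
    disposition_params(cl = 10^theta[1], vc = 10^theta[2],
                       k12 = if (model_order == 2L) 10^theta[3] else 0,
                       k21 = if (model_order == 2L) 10^theta[4] else 0,
                       body_weight = body_weight)
  }
  resid_fun <- function(theta) {
    pr <- simulate_disposition(mk(theta), dose, t)
    .obj_resid(pr$conc, obs, log_objective)
  }
  # heuristic start: terminal slope and back-extrapolated intercept
  nca <- exposure_summary(conc_profile(profile$times, profile$conc,
                                       dose = profile$dose,
                                       route = profile$route))
  auc <- if (!is.na(nca$auc_inf)) nca$auc_inf else nca$auc_last
  cl0 <- min(max(dose$amount / (auc / 1000) / 1000 * 1e3, 0.2), 90)
  v0 <- min(max(dose$amount / (max(obs) / 1000) / body_weight, 0.06), 15)
  th0 <- c(log10(cl0), log10(v0), if (model_order == 2L) c(-1, -1))
  starts <- list(th0)
  if (n_starts > 1L)
    starts <- c(starts, .with_seed(seed, lapply(seq_len(n_starts - 1L),
      function(k) stats::runif(length(lower), lower, upper))))
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(pmin(pmax(s, lower), upper), fn = resid_fun,
                                  lower = lower, upper = upper,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 300L)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-14) best <- list(fit = fit,
                                                             ssr = ssr)
    if (best$ssr < 1e-14 * sum(obs^2)) break
  }
  if (is.null(best)) stop("iv fit failed from all starts")
  th <- best$fit$par
  est <- list(cl = 10^th[1], vc = 10^th[2])
  if (model_order == 2L) est <- c(est, list(k12 = 10^th[3], k21 = 10^th[4]))
  hit <- as.list(abs(th - lower) < 1e-8 | abs(th - upper) < 1e-8)
  names(hit) <- names(est)
  if (any(unlist(hit)))
    warning("estimate(s) pinned at a bound: ",
            paste(names(est)[unlist(hit)], collapse = ", "))
  pred <- simulate_disposition(mk(th), dose, t)$conc
  .fit_result("iv", est, hit, .r2(pred, obs), pred - obs, seed, n_starts,
              best$fit$info %in% 1:4,
              extra = list(disposition = mk(th), model_order = model_order))
}

#' Fit the injection-site partition coefficient Kp
#'
#' Single-parameter bounded search (log-scaled golden-section/optimize) for
#' Kp against an immediate-release sc profile, with disposition and site
#' geometry frozen.
#'
#' @param profile an `sc_ir`-route [conc_profile()].
#' @param disp fixed [disposition_params()] (clearance from the iv stage).
#' @param site_geometry list with `v_site` and `q_site` (L, L/h); Kp is the
#'   only free parameter.
#' @param release the immediate-release drain function; defaults to a fast
#'   single Weibull (half-release about 2 minutes).
#' @param dose a [dose_event()]; defaults to a bolus of `profile$dose`.
#' @param bounds Kp search interval.
#' @param log_objective fit on the log scale.
#' @param rtol solver tolerance used inside the objective.
#' @return A `fit_result` with estimate `kp` and the frozen site object in
#'   `$site`.
#' @export
fit_kp <- function(profile, disp, site_geometry = list(v_site = 0.1,
                                                       q_site = 1.2),
                   release = NULL, dose = NULL, bounds = c(0.01, 100),
                   log_objective = FALSE, rtol = 1e-8) {
  stopifnot(inherits(profile, "conc_profile"),
            inherits(disp, "disposition_params"))
  if (profile$route != "sc_ir")
    stop("'fit_kp' needs an sc_ir-route profile, got ", profile$route)
  if (is.null(dose)) dose <- dose_event(profile$dose)
  if (is.null(release))
    release <- weibull_release(100, 0, 1, 0.05, 1)
  keep <- profile$conc > 0
  t <- profile$times[keep]; obs <- profile$conc[keep]
  ssr_fun <- function(logkp) {
    site <- depot_site_params(exp(logkp), site_geometry$v_site,
                              site_geometry$q_site)
    pr <- simulate_depot(disp, site, release, dose, t, rtol = rtol)
    sum(.obj_resid(pr$conc, obs, log_objective)^2)
  }
  lk <- log(bounds)
  grid <- seq(lk[1], lk[2], length.out = 9L)
  gv <- vapply(grid, ssr_fun, numeric(1))
  flat <- (max(gv) - min(gv)) < 1e-10 * max(gv, 1e-300)
  if (flat)
    warning("Kp is non-identifiable: objective is flat over the bounds")
  i0 <- which.min(gv)
  span <- c(grid[max(1L, i0 - 1L)], grid[min(length(grid), i0 + 1L)])
  opt <- stats::optimize(ssr_fun, span, tol = 1e-10)
  kp <- exp(opt$minimum)
  hit <- list(kp = kp / bounds[1] < 1.001 || bounds[2] / kp < 1.001)
  site <- depot_site_params(kp, site_geometry$v_site, site_geometry$q_site)
  pred <- simulate_depot(disp, site, release, dose, t, rtol = rtol)$conc
  .fit_result("ir_sc", list(kp = kp), hit, .r2(pred, obs), pred - obs,
              seed = NA_integer_, n_starts = 1L, converged = TRUE,
              extra = list(site = site, flat_objective = flat, ssr = opt$objective))
}

# theta layout identical to fit_weibull's; objective runs the full depot
# simulator. Used by both the LAI stage and mechanistic deconvolution.
#' Fit the in vivo Weibull release through the depot simulator
#'
#' Estimates the multi-phase Weibull release driving an observed long-acting
#' sc profile, with disposition and injection-site parameters frozen.
#' Multi-start Levenberg-Marquardt with a fixed seed; the first start is a
#' mass-balance (Wagner-Nelson-like) estimate of the cumulative input,
#' fitted in closed form, which makes convergence fast and reproducible.
#'
#' @param profile an `sc_lai`-route [conc_profile()].
#' @param disp frozen [disposition_params()].
#' @param site frozen [depot_site_params()].
#' @param n_phases 2 or 3 Weibull phases.
#' @param dose a [dose_event()]; defaults to a bolus of `profile$dose`.
#' @param fix_max,fix_tlag optionally fix the asymptote / lag.
#' @param n_starts,seed multi-start control (default 16 starts).
#' @param log_objective fit on the log-concentration scale.
#' @param rtol solver tolerance inside the objective (the returned fit is
#'   re-evaluated at 1e-10).
#' @return A `fit_result`; `$release` holds the fitted [weibull_release()].
#' @export
fit_release_in_vivo <- function(profile, disp, site, n_phases = 2L,
                                dose = NULL, fix_max = NULL, fix_tlag = NULL,
                                n_starts = 16L, seed = 1L,
                                log_objective = FALSE, rtol = 1e-8) {
  stopifnot(inherits(profile, "conc_profile"),
            inherits(disp, "disposition_params"),
            inherits(site, "depot_site_params"))
  if (profile$route != "sc_lai")
    stop("'fit_release_in_vivo' needs an sc_lai profile, got ",
         profile$route)
  if (is.null(dose)) dose <- dose_event(profile$dose)
  n_phases <- as.integer(n_phases)
  stopifnot(n_phases %in% c(1L, 2L, 3L))
  keep <- profile$times > 0 | profile$conc > 0
  t <- profile$times[keep]; obs <- profile$conc[keep]
  n_free <- (is.null(fix_max)) + (is.null(fix_tlag)) + (3L * n_phases - 1L)
  if (sum(obs > 0) < n_free)
    stop("under-determined fit: ", sum(obs > 0), " positive points for ",
         n_free, " free parameters")
  if (max(obs) <= 0) stop("degenerate data: all concentrations are zero")

  bnd <- .wb_bounds(n_phases, fix_max, fix_tlag, max(t))
  resid_fun <- function(theta) {
    wr <- try(.wb_unpack(theta, n_phases, fix_max, fix_tlag), silent = TRUE)
    if (inherits(wr, "try-error")) return(rep(1e6, length(obs)))
    pr <- try(.depot_fast(disp, site, wr, dose, t), silent = TRUE)
    if (inherits(pr, "try-error")) return(rep(1e6, length(obs)))
    .obj_resid(pr, obs, log_objective)
  }

  # variable projection through the simulator: the plasma response is
  # linear in the phase coefficients c_i = Max * f_i, with per-phase basis
  # columns given by unit-coefficient depot simulations (cached)
  resp_cache <- new.env(parent = emptyenv())
  basis_fun <- function(tl, b, a) {
    vapply(seq_along(b), function(i) {
      key <- paste(signif(c(tl, b[i], a[i]), 12), collapse = "_")
      if (!is.null(resp_cache[[key]])) return(resp_cache[[key]])
      wr1 <- weibull_release(100, tl, 1, a[i], b[i])
      col <- .depot_fast(disp, site, wr1, dose, t, n_nodes = 300L) / 100
      resp_cache[[key]] <- col
      col
    }, numeric(length(t)))
  }
  prj <- .with_seed(seed, .wb_varpro_optim(
    t, obs, n_phases, fix_max, fix_tlag, n_starts,
    basis_fun = basis_fun, n_samples = 30L,
    n_local = min(n_starts, 10L)))
  best <- NULL
  for (th0 in prj$starts) {
    fit <- try(minpack.lm::nls.lm(pmin(pmax(th0, bnd$lower), bnd$upper),
                                  fn = resid_fun, lower = bnd$lower,
                                  upper = bnd$upper,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 150L, ftol = 1e-13,
                                    ptol = 1e-13)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-14)
      best <- list(fit = fit, ssr = ssr)
    if (best$ssr < 1e-10 * sum(obs^2)) break
  }
  if (is.null(best)) stop("in vivo release fit failed from all starts")
  th <- best$fit$par
  wr <- .wb_unpack(th, n_phases, fix_max, fix_tlag)
  pred <- .depot_fast(disp, site, wr, dose, t, n_nodes = 2000L)
  est <- list(max_release_pct = wr$max_release_pct, t_lag = wr$t_lag,
              fractions = wr$fractions, scales = wr$scales,
              shapes = wr$shapes)
  hit <- as.list(abs(th - bnd$lower) < 1e-9 | abs(th - bnd$upper) < 1e-9)
  .fit_result("lai_sc", est,
              stats::setNames(hit, paste0("theta", seq_along(hit))),
              .r2(pred, obs), pred - obs, seed, n_starts,
              best$fit$info %in% 1:4,
              extra = list(release = wr, ssr = best$ssr))
}
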