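#' In vivo absorbed-fraction series
#'
#' @param times h, strictly increasing.
#' @param absorbed_pct cumulative percent absorbed; forced non-decreasing by
#'   construction (running maximum).
#' @param strength_mg dose strength, mg.
#' @param source `"deconvolved"` or `"ivivc_predicted"`.
#' @return An object of class `absorbed_series`.
#' @export
absorbed_fraction_series <- function(times, absorbed_pct,
                                     strength_mg = NA_real_,
                                     source = "deconvolved") {
  if (length(times) != length(absorbed_pct))
    stop("'times' and 'absorbed_pct' must have equal length")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("'times' must be finite and strictly increasing")
  if (any(!is.finite(absorbed_pct)))
    stop("'absorbed_pct' must be finite")
  source <- match.arg(source, c("deconvolved", "ivivc_predicted"))
  structure(list(times = as.numeric(times),
                 absorbed_pct = cummax(as.numeric(absorbed_pct)),
                 strength_mg = strength_mg, source = source),
            class = "absorbed_series")
}

#' @export
print.absorbed_series <- function(x, ...) {
  cat(sprintf(
    "<absorbed_series> %s, %.4g mg, %d points, final = %.3g%% at %.4g h\n",
    x$source, x$strength_mg, length(x$times),
    x$absorbed_pct[length(x$absorbed_pct)], max(x$times)))
  invisible(x)
}

#' Mechanistic deconvolution by triple-Weibull absorption
#'
#' Fits a depot model with a multi-phase (default triple) Weibull absorption
#' function to an observed plasma profile with the disposition and
#' injection-site parameters frozen, then evaluates the fitted Weibull at
#' the observation times to emit the in vivo absorbed-fraction series.
#'
#' @param observed a single-strength `sc_lai` [conc_profile()].
#' @param disp frozen [disposition_params()] (calibrated human model).
#' @param site frozen [depot_site_params()].
#' @param n_phases number of Weibull phases (default 3).
#' @param normalize if `TRUE`, the absorbed series is renormalised to the
#'   fitted asymptote (0-100%); the default evaluates the Weibull literally,
#'   so the series plateaus at `max_release_pct`.
#' @param ... passed to [fit_release_in_vivo()] (`n_starts`, `seed`,
#'   `log_objective`, `rtol`, `fix_max`, `fix_tlag`).
#' @return list of class `deconvolution`: `absorbed`
#'   (an `absorbed_series`), `release` (the fitted [weibull_release()]),
#'   `fit` (the underlying `fit_result`).
#' @export
deconvolve <- function(observed, disp, site, n_phases = 3L,
                       normalize = FALSE, ...) {
  stopifnot(inherits(observed, "conc_profile"))
  if (max(observed$conc) <= 0)
    stop("degenerate data: observed profile is flat zero")
  fit <- fit_release_in_vivo(observed, disp, site, n_phases = n_phases, ...)
  wr <- fit$release
  tt <- observed$times[observed$times >= 0]
  abs_pct <- eval_release(wr, tt)
  if (normalize) abs_pct <- abs_pct / wr$max_release_pct * 100
  structure(list(
    absorbed = absorbed_fraction_series(tt, abs_pct,
                                        strength_mg = observed$dose,
                                        source = "deconvolved"),
    release = wr, fit = fit), class = "deconvolution")
}

#' @export
print.deconvolution <- function(x, ...) {
  cat("<deconvolution>\n")
  print(x$fit)
  print(x$absorbed)
  invisible(x)
}

# time at which a monotone series crosses `frac` percent, by linear
# interpolation; NA when outside the observed range
.time_at_fraction_interp <- function(times, pct, frac) {
  if (frac > max(pct) || frac < min(pct)) return(NA_real_)
  stats::approx(pct, times, xout = frac, ties = "ordered")$y
}

#' Levy-plot time scaling
#'
#' Pairs in vitro and in vivo times at matched released/absorbed fractions
#' and fits a straight line through the origin; the slope is the
#' time-scaling factor (in vivo hours per in vitro hour) between the
#' accelerated assay and in vivo release.
#'
#' @param vitro list of [release_profile()] objects (one per strength).
#' @param vivo list of `absorbed_series` objects (matching order).
#' @param fraction_grid percent fractions at which to pair times (default
#'   5-80% in 5% steps).
#' @param method `"interp"` pairs by piecewise-linear interpolation of the
#'   raw series; `"weibull"` fits a double Weibull to each in vitro profile
#'   and inverts it.
#' @param seed seed for the Weibull fits when `method = "weibull"`.
#' @return An object of class `time_scaling`: `slope`, `r_squared`,
#'   `matched_pairs` (data.frame `fraction`, `strength`, `t_vitro`,
#'   `t_vivo`), `n_dropped`.
#' @export
levy_time_scaling <- function(vitro, vivo, fraction_grid = seq(5, 80, by = 5),
                              method = c("interp", "weibull"), seed = 1L) {
  method <- match.arg(method)
  if (inherits(vitro, "release_profile")) vitro <- list(vitro)
  if (inherits(vivo, "absorbed_series")) vivo <- list(vivo)
  if (length(vitro) != length(vivo))
    stop("'vitro' and 'vivo' must have the same number of strengths")
  pairs <- list(); dropped <- 0L
  for (j in seq_along(vitro)) {
    rp <- vitro[[j]]; av <- vivo[[j]]
    wfit <- if (method == "weibull")
      fit_weibull(rp, n_phases = min(2L, max(1L,
        (length(rp$times) >= 14L) + 1L)), seed = seed)$release else NULL
    for (fr in fraction_grid) {
      tvt <- if (method == "weibull") {
        if (fr >= wfit$max_release_pct) NA_real_
        else invert_release(wfit, fr)
      } else .time_at_fraction_interp(rp$times, rp$cumulative_pct, fr)
      tvv <- .time_at_fraction_interp(av$times, av$absorbed_pct, fr)
      if (is.na(tvt) || is.na(tvv)) { dropped <- dropped + 1L; next }
      pairs[[length(pairs) + 1L]] <-
        data.frame(fraction = fr, strength = rp$strength_mg,
                   t_vitro = tvt, t_vivo = tvv)
    }
  }
  if (length(pairs) < 3L)
    stop("fewer than 3 matched (t_vitro, t_vivo) pairs (",
         length(pairs), " found, ", dropped, " dropped)")
  mp <- do.call(rbind, pairs)
  slope <- sum(mp$t_vitro * mp$t_vivo) / sum(mp$t_vitro^2)  # through origin
  fitted <- slope * mp$t_vitro
  r2 <- 1 - sum((mp$t_vivo - fitted)^2) / sum(mp$t_vivo^2)
  structure(list(slope = slope, r_squared = r2, matched_pairs = mp,
                 n_dropped = dropped, method = method),
            class = "time_scaling")
}

#' @export
print.time_scaling <- function(x, ...) {
  cat(sprintf(
    "<time_scaling> Tvivo = %.4g x Tvitro (through origin), R^2 = %.4f, %d pairs (%d dropped)\n",
    x$slope, x$r_squared, nrow(x$matched_pairs), x$n_dropped))
  invisible(x)
}

.corr_families <- c("linear", "poly2", "poly3", "higuchi", "sigmoid",
                    "gompertz")

.corr_n_coef <- c(linear = 2, poly2 = 3, poly3 = 4, higuchi = 2,
                  sigmoid = 3, gompertz = 3)

.corr_fit_one <- function(family, x, y) {
  n <- length(x)
  switch(family,
    linear = {
      f <- stats::lm(y ~ x)
      list(coef = c(c0 = unname(stats::coef(f)[1]),
                    c1 = unname(stats::coef(f)[2])),
           pred = function(z) stats::coef(f)[1] + stats::coef(f)[2] * z)
    },
    poly2 = {
      f <- stats::lm(y ~ x + I(x^2))
      cf <- unname(stats::coef(f))
      list(coef = c(c0 = cf[1], c1 = cf[2], c2 = cf[3]),
           pred = function(z) cf[1] + cf[2] * z + cf[3] * z^2)
    },
    poly3 = {
      f <- stats::lm(y ~ x + I(x^2) + I(x^3))
      cf <- unname(stats::coef(f))
      list(coef = c(c0 = cf[1], c1 = cf[2], c2 = cf[3], c3 = cf[4]),
           pred = function(z) cf[1] + cf[2] * z + cf[3] * z^2 + cf[4] * z^3)
    },
    higuchi = {
      f <- stats::lm(y ~ sqrt(x))
      cf <- unname(stats::coef(f))
      list(coef = c(c0 = cf[1], k = cf[2]),
           pred = function(z) cf[1] + cf[2] * sqrt(pmax(z, 0)))
    },
    sigmoid = {
      st <- c(A = max(y) * 1.05, x0 = stats::median(x), s = diff(range(x)) / 6)
      f <- stats::nls(y ~ A / (1 + exp(-(x - x0) / s)), start = as.list(st),
                      control = stats::nls.control(maxiter = 200,
                                                   warnOnly = TRUE))
      cf <- stats::coef(f)
      list(coef = cf,
           pred = function(z) cf["A"] / (1 + exp(-(z - cf["x0"]) / cf["s"])))
    },
    gompertz = {
      st <- c(A = max(y) * 1.05, k = 4 / diff(range(x)),
              x0 = stats::median(x))
      f <- stats::nls(y ~ A * exp(-exp(-k * (x - x0))), start = as.list(st),
                      control = stats::nls.control(maxiter = 200,
                                                   warnOnly = TRUE))
      cf <- stats::coef(f)
      list(coef = cf,
           pred = function(z) cf["A"] * exp(-exp(-cf["k"] * (z - cf["x0"]))))
    })
}

#' Fit and select the IVIVC correlation model
#'
#' Fits each candidate family of the in vivo percent absorbed versus in
#' vitro percent released relationship by least squares, selects the family
#' with the highest R-squared, and returns the full leaderboard. Exact ties
#' (within 1e-9) are broken toward fewer coefficients.
#'
#' @param released_pct in vitro percent released (after time scaling).
#' @param absorbed_pct in vivo percent absorbed at the shared scaled times.
#' @param families candidate families, a subset of `"linear"`, `"poly2"`,
#'   `"poly3"`, `"higuchi"`, `"sigmoid"`, `"gompertz"`.
#' @return An object of class `correlation_model`: `family`,
#'   `coefficients`, `r_squared`, `leaderboard`, and a `predict` method.
#' @export
fit_correlation <- function(released_pct, absorbed_pct,
                            families = .corr_families) {
  x <- as.numeric(released_pct); y <- as.numeric(absorbed_pct)
  if (length(x) != length(y)) stop("series must be aligned (equal length)")
  families <- match.arg(families, .corr_families, several.ok = TRUE)
  if (stats::sd(x) == 0)
    stop("singular design: percent released is constant")
  nmin <- max(.corr_n_coef[families]) + 2
  if (length(x) < nmin)
    stop("need at least ", nmin, " points for the requested families")
  rows <- list(); fits <- list()
  for (fam in families) {
    ft <- try(.corr_fit_one(fam, x, y), silent = TRUE)
    if (inherits(ft, "try-error")) {
      rows[[fam]] <- data.frame(family = fam, r_squared = NA_real_,
                                n_coef = .corr_n_coef[[fam]],
                                converged = FALSE)
      next
    }
    res <- y - ft$pred(x)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    fits[[fam]] <- ft
    rows[[fam]] <- data.frame(family = fam, r_squared = r2,
                              n_coef = .corr_n_coef[[fam]], converged = TRUE)
  }
  lb <- do.call(rbind, rows); rownames(lb) <- NULL
  ok <- lb[lb$converged & is.finite(lb$r_squared), ]
  if (nrow(ok) == 0L) stop("no correlation family could be fitted")
  best_r2 <- max(ok$r_squared)
  cand <- ok[ok$r_squared > best_r2 - 1e-9, ]
  winner <- cand$family[which.min(cand$n_coef)]
  structure(list(family = winner, coefficients = fits[[winner]]$coef,
                 r_squared = ok$r_squared[ok$family == winner],
                 leaderboard = lb[order(-lb$r_squared), ],
                 .pred = fits[[winner]]$pred),
            class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("<correlation_model> %s, R^2 = %.6f\n", x$family,
              x$r_squared))
  print(round(x$coefficients, 6))
  cat("leaderboard:\n")
  print(x$leaderboard, row.names = FALSE)
  invisible(x)
}

#' @export
predict.correlation_model <- function(object, newdata, ...) {
  object$.pred(as.numeric(newdata))
}

#' Convolution prediction of a plasma profile from in vitro release
#'
#' Scales the in vitro times by the Levy slope, maps percent released
#' through the correlation model into predicted percent absorbed, builds a
#' monotone piecewise-linear absorbed-fraction schedule (flat beyond the
#' last point), and uses it as the depot drain in the human PK model.
#'
#' @param vitro a [release_profile()].
#' @param scaling a `time_scaling` object.
#' @param corr a `correlation_model`.
#' @param disp,site the human PK model ([disposition_params()],
#'   [depot_site_params()]).
#' @param dose mg (defaults to the profile's strength).
#' @param times output times, h (defaults to the scaled in vitro times).
#' @param cap optional upper clamp for predicted percent absorbed (`NULL` =
#'   uncapped; values above 100 are possible and deliberately not removed by
#'   default).
#' @param rtol solver tolerance.
#' @return A [conc_profile()] with attributes `absorbed`
#'   (the `absorbed_series` used as input) and `n_clamped_low` (count of
#'   negative correlation outputs clamped to 0).
#' @export
convolve_predict <- function(vitro, scaling, corr, disp, site, dose = NULL,
                             times = NULL, cap = NULL, rtol = 1e-10) {
  stopifnot(inherits(vitro, "release_profile"),
            inherits(scaling, "time_scaling"),
            inherits(corr, "correlation_model"),
            inherits(disp, "disposition_params"),
            inherits(site, "depot_site_params"))
  if (length(vitro$times) == 0L) stop("empty in vitro profile")
  if (is.null(dose)) dose <- vitro$strength_mg
  if (!is.finite(dose) || dose <= 0) stop("a positive dose is required")
  t_scaled <- scaling$slope * vitro$times
  absorbed <- predict(corr, vitro$cumulative_pct)
  n_low <- sum(absorbed < 0)
  if (n_low > 0) {
    warning(n_low, " predicted percent-absorbed value(s) below 0 clamped")
    absorbed <- pmax(absorbed, 0)
  }
  if (!is.null(cap)) absorbed <- pmin(absorbed, cap)
  ser <- absorbed_fraction_series(t_scaled, absorbed, strength_mg = dose,
                                  source = "ivivc_predicted")
  if (is.null(times)) times <- t_scaled
  out <- simulate_depot(disp, site, ser, dose_event(dose), times,
                        rtol = rtol)
  attr(out, "absorbed") <- ser
  attr(out, "n_clamped_low") <- n_low
  out
}

#' Internal (Level-A) validation of the IVIVC model
#'
#' Computes per-strength percent prediction errors for Cmax and AUC and
#' their arithmetic means, and renders the Level-A verdict: mean PE at most
#' 10% for both metrics (per the FDA extended-release guidance bound), with
#' each individual strength also checked against 15%.
#'
#' @param observed named list (by strength label) of `exposure_summary`
#'   objects or lists with `cmax` and an AUC field.
#' @param predicted matching named list.
#' @param auc_metric which AUC field to compare (default `"auc_last"`,
#'   i.e. AUC to the last shared time point).
#' @return An object of class `validation_report`.
#' @export
internal_validation <- function(observed, predicted,
                                auc_metric = "auc_last") {
  if (!setequal(names(observed), names(predicted)) ||
      is.null(names(observed)))
    stop("strength mismatch between observed and predicted summaries")
  strengths <- names(observed)
  rows <- lapply(strengths, function(s) {
    o <- observed[[s]]; p <- predicted[[s]]
    data.frame(strength = s,
               observed_cmax = o$cmax, predicted_cmax = p$cmax,
               observed_auc = o[[auc_metric]],
               predicted_auc = p[[auc_metric]],
               pe_cmax = prediction_error(o$cmax, p$cmax),
               pe_auc = prediction_error(o[[auc_metric]], p[[auc_metric]]))
  })
  tab <- do.call(rbind, rows)
  mean_pe_cmax <- mean(tab$pe_cmax)
  mean_pe_auc <- mean(tab$pe_auc)
  structure(list(
    table = tab,
    mean_pe_cmax = mean_pe_cmax,
    mean_pe_auc = mean_pe_auc,
    level_a_pass = mean_pe_cmax <= 10 && mean_pe_auc <= 10,
    individual_within_15 = all(tab$pe_cmax <= 15) && all(tab$pe_auc <= 15),
    criterion = "mean PE <= 10% (both metrics); each strength <= 15%"),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("mean PE: Cmax %.1f%%, AUC %.1f%%\n", x$mean_pe_cmax,
              x$mean_pe_auc))
  cat(sprintf("Level A (%s): %s; all strengths within 15%%: %s\n",
              x$criterion, if (x$level_a_pass) "PASS" else "FAIL",
              x$individual_within_15))
  invisible(x)
}
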