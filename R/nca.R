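#' Noncompartmental exposure summary
#'
#' Computes Cmax/Tmax (maximum observed point, earliest time on ties),
#' AUC to the last observation by the linear trapezoid rule, the terminal
#' slope `lambda_z` by log-linear regression, and the extrapolated
#' `AUC(0-Inf) = AUC_last + C_last / lambda_z`.
#'
#' The terminal window for `lambda_z` is chosen among all windows of at
#' least 3 positive-concentration points strictly after Tmax and ending at
#' the last positive point, maximising adjusted R-squared (ties broken
#' toward fewer points). If no window reaches adjusted R-squared 0.80,
#' `AUC(0-Inf)` is reported as `NA` with a reason code. Embedded zero
#' concentrations are excluded from the regression; leading zeros before the
#' first quantifiable point are kept in the trapezoid.
#'
#' @param profile a [conc_profile()].
#' @param lambda_z_min_r2adj minimum adjusted R-squared to accept a terminal
#'   slope (default 0.80).
#' @return An object of class `exposure_summary`: `cmax`, `tmax`,
#'   `auc_last`, `auc_inf` (possibly `NA`), `lambda_z`,
#'   `n_points_lambda_z`, `extrapolated_fraction`, `reason` (why
#'   `auc_inf` is absent, or `NA`).
#' @export
exposure_summary <- function(profile, lambda_z_min_r2adj = 0.80) {
  stopifnot(inherits(profile, "conc_profile"))
  t <- profile$times; c_ <- profile$conc
  if (length(t) == 0L) stop("empty profile")
  imax <- which.max(c_)        # first index at the max -> earliest tie
  cmax <- c_[imax]; tmax <- t[imax]
  auc_last <- if (length(t) > 1L)
    sum(diff(t) * (utils::head(c_, -1) + utils::tail(c_, -1)) / 2) else 0

  out <- list(cmax = cmax, tmax = tmax, auc_last = auc_last,
              auc_inf = NA_real_, lambda_z = NA_real_,
              n_points_lambda_z = 0L, extrapolated_fraction = NA_real_,
              reason = NA_character_)
  if (cmax <= 0) {
    out$reason <- "all_zero_profile"
    return(structure(out, class = "exposure_summary"))
  }
  cand <- which(t > tmax & c_ > 0)
  if (length(cand) < 3L) {
    out$reason <- "fewer_than_3_terminal_points"
    return(structure(out, class = "exposure_summary"))
  }
  best <- NULL
  for (k in rev(seq(3L, length(cand)))) {       # larger windows first
    idx <- utils::tail(cand, k)
    x <- t[idx]; y <- log(c_[idx])
    sxx <- sum((x - mean(x))^2)
    sl <- sum((x - mean(x)) * (y - mean(y))) / sxx
    res <- y - mean(y) - sl * (x - mean(x))
    syy <- sum((y - mean(y))^2)
    r2 <- if (syy > 0) 1 - sum(res^2) / syy else 1
    r2a <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (sl < 0 && (is.null(best) || r2a > best$r2a + 1e-12))
      best <- list(idx = idx, lz = -sl, r2a = r2a)
  }
  if (is.null(best) || best$r2a < lambda_z_min_r2adj) {
    out$reason <- "lambda_z_not_estimable"
    return(structure(out, class = "exposure_summary"))
  }
  c_last <- c_[max(cand)]
  out$lambda_z <- unname(best$lz)
  out$n_points_lambda_z <- length(best$idx)
  out$auc_inf <- auc_last + c_last / best$lz
  out$extrapolated_fraction <- (c_last / best$lz) / out$auc_inf
  structure(out, class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf(
    "<exposure_summary> Cmax = %.4g ng/mL at %.4g h; AUC_last = %.6g; AUC_inf = %s",
    x$cmax, x$tmax, x$auc_last,
    if (is.na(x$auc_inf)) paste0("NA (", x$reason, ")")
    else sprintf("%.6g (lambda_z = %.4g /h, %d pts, %.1f%% extrapolated)",
                 x$auc_inf, x$lambda_z, x$n_points_lambda_z,
                 100 * x$extrapolated_fraction)))
  cat("\n")
  invisible(x)
}

#' Percent prediction error
#'
#' `100 * |observed - predicted| / observed`, the IVIVC validation
#' statistic. The observed value is the reference (denominator).
#'
#' @param observed observed value (> 0).
#' @param predicted predicted value.
#' @return percent prediction error (unrounded; round to one decimal for
#'   reporting).
#' @export
prediction_error <- function(observed, predicted) {
  if (any(!is.finite(observed)) || any(observed <= 0))
    stop("'observed' must be > 0")
  100 * abs(observed - predicted) / observed
}
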