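#' Multi-phase Weibull cumulative release model
#'
#' Constructs a 1- to 3-phase Weibull cumulative release (or in vivo
#' absorption) function
#' \deqn{F(t) = Max \left(1 - \sum_i f_i \exp\{-(t - T_{lag})^{b_i}/A_i\}\right)}
#' for \eqn{t \ge T_{lag}} and \eqn{F(t) = 0} below the lag. The time-scale
#' factor \eqn{A_i} divides the *powered* time, so its unit is
#' \eqn{h^{b_i}}; the equivalent characteristic time in the alternative
#' \eqn{((t-T_{lag})/A')^{b}} convention is \eqn{A' = A^{1/b}}.
#'
#' @param max_release_pct asymptotic release, percent of dose (0, 100]
#'   (a small tolerance above 100 is allowed for fitted values).
#' @param t_lag lag time, h (\eqn{\ge 0}).
#' @param fractions per-phase fractions \eqn{f_i}; must be non-negative and
#'   sum to 1 within 1e-6.
#' @param scales per-phase time-scale factors \eqn{A_i} in \eqn{h^{b_i}}
#'   (> 0).
#' @param shapes per-phase shape parameters \eqn{b_i} (> 0).
#' @return An object of class `weibull_release`.
#' @examples
#' wr <- weibull_release(100, 0, c(0.142, 0.858), c(30.88, 6370.7),
#'                       c(0.717, 1.285))
#' eval_release(wr, c(0, 24, 672))
#' @export
weibull_release <- function(max_release_pct, t_lag = 0, fractions, scales,
                            shapes) {
  n <- length(fractions)
  if (n < 1L || n > 3L)
    stop("between 1 and 3 Weibull phases are supported, got ", n)
  if (length(scales) != n || length(shapes) != n)
    stop("'fractions', 'scales' and 'shapes' must have equal length")
  if (!is.numeric(max_release_pct) || length(max_release_pct) != 1L ||
      !is.finite(max_release_pct) || max_release_pct <= 0 ||
      max_release_pct > 100 + 1e-6)
    stop("'max_release_pct' must be a single value in (0, 100]")
  if (!is.finite(t_lag) || t_lag < 0)
    stop("'t_lag' must be >= 0")
  if (any(!is.finite(fractions)) || any(fractions < 0))
    stop("phase fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("phase fractions must sum to 1 (got ", format(sum(fractions)), ")")
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("phase time scales must be > 0")
  if (any(!is.finite(shapes)) || any(shapes <= 0))
    stop("phase shapes must be > 0")
  structure(
    list(max_release_pct = as.numeric(max_release_pct),
         t_lag = as.numeric(t_lag),
         fractions = as.numeric(fractions),
         scales = as.numeric(scales),
         shapes = as.numeric(shapes)),
    class = "weibull_release")
}

#' @export
print.weibull_release <- function(x, ...) {
  cat(sprintf("<weibull_release> %d phase(s), Max = %.4g%%, Tlag = %.4g h\n",
              length(x$fractions), x$max_release_pct, x$t_lag))
  tab <- data.frame(fraction = x$fractions, time_scale = x$scales,
                    shape = x$shapes,
                    half_release_h = (log(2) * x$scales)^(1 / x$shapes))
  print(tab, row.names = TRUE)
  invisible(x)
}

#' Evaluate cumulative release
#'
#' @param params a [weibull_release()] object.
#' @param t times, h (\eqn{\ge 0}); vectorised.
#' @return percent of dose released at each time; 0 for `t < t_lag`,
#'   non-decreasing, bounded above by `max_release_pct`.
#' @export
eval_release <- function(params, t) {
  stopifnot(inherits(params, "weibull_release"))
  if (any(t < 0)) stop("'t' must be >= 0")
  tt <- pmax(t - params$t_lag, 0)
  s <- numeric(length(tt))
  for (i in seq_along(params$fractions))
    s <- s + params$fractions[i] *
      exp(-(tt^params$shapes[i]) / params$scales[i])
  out <- params$max_release_pct * (1 - s)
  out[tt <= 0] <- 0     # exactly zero at and below the lag
  out
}

#' Instantaneous release rate
#'
#' Analytic time-derivative of [eval_release()], in percent of dose per hour.
#' At `t == t_lag` the rate is the one-sided limit: finite for shapes
#' \eqn{\ge 1}, `Inf` for shapes < 1 (integrable singularity).
#'
#' @inheritParams eval_release
#' @return release rate, percent/h; 0 for `t < t_lag`.
#' @export
release_rate <- function(params, t) {
  stopifnot(inherits(params, "weibull_release"))
  if (any(t < 0)) stop("'t' must be >= 0")
  tt <- t - params$t_lag
  out <- numeric(length(tt))
  pos <- tt > 0
  for (i in seq_along(params$fractions)) {
    f <- params$fractions[i]; A <- params$scales[i]; b <- params$shapes[i]
    out[pos] <- out[pos] + f * b * tt[pos]^(b - 1) / A *
      exp(-(tt[pos]^b) / A)
  }
  # one-sided limit at the lag itself
  at0 <- tt == 0
  if (any(at0)) {
    r0 <- 0
    for (i in seq_along(params$fractions)) {
      f <- params$fractions[i]; A <- params$scales[i]; b <- params$shapes[i]
      r0 <- r0 + if (b > 1) 0 else if (b == 1) f / A else Inf
    }
    out[at0] <- r0
  }
  params$max_release_pct * out
}

#' Invert the cumulative release function
#'
#' Finds the unique time at which `eval_release(params, t) == target_pct`,
#' by bisection on the monotone closed form.
#'
#' @inheritParams eval_release
#' @param target_pct target percent released; must be below the asymptote
#'   `max_release_pct`.
#' @return time in h with `eval_release` within 1e-6 (percent) of the target.
#' @export
invert_release <- function(params, target_pct) {
  stopifnot(inherits(params, "weibull_release"))
  if (length(target_pct) != 1L || !is.finite(target_pct) || target_pct < 0)
    stop("'target_pct' must be a single value >= 0")
  if (target_pct >= params$max_release_pct)
    stop("unreachable target: ", format(target_pct),
         "% is at or above the asymptote ", format(params$max_release_pct),
         "% (never attained at finite time)")
  if (target_pct == 0) return(params$t_lag)
  lo <- params$t_lag
  hi <- params$t_lag + 1
  while (eval_release(params, hi) < target_pct) {
    hi <- params$t_lag + (hi - params$t_lag) * 2
    if (hi > 1e15) stop("failed to bracket the target time")
  }
  f <- function(t) eval_release(params, t) - target_pct
  root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75,
                         maxiter = 2000L)$root
  root
}

#' Canonical phase ordering
#'
#' Returns the same release model with phases sorted by characteristic time
#' \eqn{A^{1/b}}. Phase order does not change the curve, so fitted models
#' can be compared phase-by-phase after sorting.
#'
#' @param params a [weibull_release()] object.
#' @export
sort_phases <- function(params) {
  stopifnot(inherits(params, "weibull_release"))
  o <- order(params$scales^(1 / params$shapes))
  weibull_release(params$max_release_pct, params$t_lag,
                  params$fractions[o], params$scales[o], params$shapes[o])
}

#' Cumulative release profile (one replicate)
#'
#' @param times sampling times, h; strictly increasing.
#' @param cumulative_pct cumulative percent released at each time.
#' @param strength_mg dose strength, mg.
#' @param replicate_id replicate label.
#' @param clean if `TRUE`, slightly non-monotone series (violations below
#'   2 percentage points) are replaced by their isotonic non-decreasing
#'   projection; larger violations are an error.
#' @return An object of class `release_profile`.
#' @export
release_profile <- function(times, cumulative_pct, strength_mg = NA_real_,
                            replicate_id = "rep1", clean = TRUE) {
  if (length(times) != length(cumulative_pct))
    stop("'times' and 'cumulative_pct' must have equal length")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("'times' must be finite and strictly increasing")
  if (any(!is.finite(cumulative_pct)))
    stop("'cumulative_pct' must be finite")
  y <- as.numeric(cumulative_pct)
  viol <- max(c(0, cummax(y) - y))
  if (viol > 0) {
    if (!clean || viol >= 2)
      stop(sprintf(
        "cumulative release decreases by up to %.3g percentage points%s",
        viol, if (clean) " (>= 2, too large for isotonic cleaning)" else ""))
    y <- stats::isoreg(times, y)$yf
  }
  structure(list(times = as.numeric(times), cumulative_pct = y,
                 strength_mg = strength_mg, replicate_id = replicate_id),
            class = "release_profile")
}

#' @export
print.release_profile <- function(x, ...) {
  cat(sprintf(
    "<release_profile> %s, %.4g mg, %d points over [%.3g, %.3g] h, last = %.3g%%\n",
    x$replicate_id, x$strength_mg, length(x$times), min(x$times),
    max(x$times), x$cumulative_pct[length(x$cumulative_pct)]))
  invisible(x)
}

# stick-breaking <-> simplex maps used by the fitters: p (length n-1 in [0,1])
# to fractions (length n summing to 1) and back
.stick_to_frac <- function(p) {
  n <- length(p) + 1L
  f <- numeric(n)
  rest <- 1
  for (i in seq_len(n - 1L)) {
    f[i] <- rest * p[i]
    rest <- rest - f[i]
  }
  f[n] <- rest
  f
}

.frac_to_stick <- function(f) {
  n <- length(f)
  if (n == 1L) return(numeric(0))
  p <- numeric(n - 1L)
  rest <- 1
  for (i in seq_len(n - 1L)) {
    p[i] <- if (rest > 0) f[i] / rest else 0
    rest <- rest - f[i]
  }
  pmin(pmax(p, 0), 1)
}

# pack/unpack fit parameters. theta layout:
#   [max (opt)] [tlag (opt)] [stick p (n-1)] [log10 A (n)] [b (n)]
.wb_unpack <- function(theta, n_phases, fix_max, fix_tlag) {
  i <- 1L
  if (is.null(fix_max)) { mx <- theta[i]; i <- i + 1L } else mx <- fix_max
  if (is.null(fix_tlag)) { tl <- theta[i]; i <- i + 1L } else tl <- fix_tlag
  p <- if (n_phases > 1L) theta[i:(i + n_phases - 2L)] else numeric(0)
  i <- i + n_phases - 1L
  a <- 10^theta[i:(i + n_phases - 1L)]; i <- i + n_phases
  b <- theta[i:(i + n_phases - 1L)]
  weibull_release(mx, tl, .stick_to_frac(p), a, b)
}

.wb_bounds <- function(n_phases, fix_max, fix_tlag, t_max) {
  lower <- c(if (is.null(fix_max)) 1e-3, if (is.null(fix_tlag)) 0,
             rep(0, n_phases - 1L), rep(-3, n_phases), rep(0.2, n_phases))
  upper <- c(if (is.null(fix_max)) 100 + 1e-6, if (is.null(fix_tlag)) t_max,
             rep(1, n_phases - 1L), rep(8, n_phases), rep(5, n_phases))
  list(lower = lower, upper = upper)
}

#' Fit a multi-phase Weibull to a cumulative release series
#'
#' Bounded least squares on the untransformed percent scale with uniform
#' weights, multi-start Levenberg-Marquardt (fixed seed) to escape local
#' minima. Phase fractions are parameterised on the simplex (stick-breaking),
#' time scales on log10.
#'
#' @param profile a [release_profile()], or a list with elements `times` and
#'   `cumulative_pct` (e.g. a deconvolved fraction-absorbed series).
#' @param n_phases number of Weibull phases, 1-3.
#' @param fix_max optionally fix the asymptote (percent).
#' @param fix_tlag optionally fix the lag time (h).
#' @param n_starts number of optimiser starts (>= 1; the first start is a
#'   data-driven heuristic, the rest are randomised within bounds).
#' @param seed RNG seed for the randomised starts.
#' @return An object of class `weibull_fit`: fields `release`
#'   (a `weibull_release`), `r_squared`, `residuals`, `converged`,
#'   `n_starts`, `seed`, `ssr`.
#' @export
fit_weibull <- function(profile, n_phases = 2L, fix_max = NULL,
                        fix_tlag = NULL, n_starts = 8L, seed = 1L) {
  if (inherits(profile, "release_profile")) {
    t <- profile$times; y <- profile$cumulative_pct
  } else {
    t <- profile$times
    y <- if (!is.null(profile$cumulative_pct)) profile$cumulative_pct
         else profile$absorbed_pct
  }
  if (is.null(t) || is.null(y)) stop("profile must carry times and values")
  n_phases <- as.integer(n_phases)
  if (n_phases < 1L || n_phases > 3L) stop("'n_phases' must be 1, 2 or 3")
  n_free <- (is.null(fix_max)) + (is.null(fix_tlag)) + (3L * n_phases - 1L)
  keep <- t > 0 | y > 0
  if (length(t) < 2L * n_free)
    stop("under-determined fit: ", length(t), " points for ", n_free,
         " free parameters (need >= ", 2L * n_free, ")")
  if (max(y) <= 0 || stats::sd(y) == 0)
    stop("degenerate data: cumulative series is constant")
  if (any(cummax(y) - y > 2))
    stop("cumulative series decreases by more than 2 percentage points")

  t_max <- max(t)
  bnd <- .wb_bounds(n_phases, fix_max, fix_tlag, t_max)
  resid_fun <- function(theta) {
    wr <- try(.wb_unpack(theta, n_phases, fix_max, fix_tlag), silent = TRUE)
    if (inherits(wr, "try-error")) return(rep(1e6, length(y)))
    eval_release(wr, t) - y
  }

  # optimisation by variable projection: the model is linear in the
  # coefficients c_i = Max * f_i given (Tlag, b_i, A_i), so the nonlinear
  # search runs over (tlag?, shapes, log10 characteristic times) with the
  # linear part solved in closed form, multi-started from a deterministic
  # grid plus seeded random draws; a full-parameter Levenberg-Marquardt
  # polish enforces the exact simplex/bound constraints afterwards
  prj <- .with_seed(seed, .wb_varpro_optim(t, y, n_phases, fix_max,
                                           fix_tlag, n_starts))
  conv <- TRUE
  best <- NULL
  for (th0 in prj$starts) {
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(th0, bnd$lower), bnd$upper), fn = resid_fun,
      lower = bnd$lower, upper = bnd$upper,
      control = minpack.lm::nls.lm.control(maxiter = 500L, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-12)
      best <- list(fit = fit, ssr = ssr)
    if (!is.null(best) && best$ssr < 1e-12 * max(1, sum(y^2))) break
  }
  if (is.null(best)) stop("Weibull fit failed from all starts")
  wr <- .wb_unpack(best$fit$par, n_phases, fix_max, fix_tlag)
  res <- eval_release(wr, t) - y
  sst <- sum((y - mean(y))^2)
  structure(list(
    release = wr,
    r_squared = 1 - sum(res^2) / sst,
    residuals = res,
    ssr = sum(res^2),
    converged = best$fit$info %in% c(1, 2, 3, 4),
    n_starts = n_starts, seed = seed), class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull_fit> R^2 = %.6f, SSR = %.4g, converged = %s\n",
              x$r_squared, x$ssr, x$converged))
  print(x$release)
  invisible(x)
}

# variable-projection optimiser shared by the closed-form and
# through-the-simulator Weibull fitters. phi layout:
# [tlag (if free)] [shapes (n)] [log10 characteristic times (n)]; the
# model is linear in the coefficients c_i = Max * f_i given phi, with the
# per-phase basis columns supplied by `basis_fun(tl, b, a)` (closed-form
# release curves, or unit-coefficient depot responses). Coefficients are
# solved by least squares (clipped to >= 0; rescaled to sum(c) = fix_max
# when the asymptote is fixed, capped at 100 otherwise). Returns packed
# full-parameter theta starts ranked by projected SSR.
.wb_varpro_optim <- function(t, y, n_phases, fix_max, fix_tlag, n_starts,
                             basis_fun = NULL, n_samples = 120L,
                             n_local = NULL) {
  t_pos <- t[t > 0]
  lo_tc <- log10(max(min(t_pos) / 10, 1e-3))
  hi_tc <- log10(max(t) * 100)
  free_tlag <- is.null(fix_tlag)
  if (is.null(basis_fun))
    basis_fun <- function(tl, b, a) {
      tt <- pmax(t - tl, 0)
      vapply(seq_along(b), function(i) 1 - exp(-(tt^b[i]) / a[i]),
             numeric(length(tt)))
    }

  solve_lin <- function(basis) {
    cf <- tryCatch(stats::coef(stats::lm.fit(basis, y)),
                   error = function(e) rep(NA_real_, n_phases))
    if (any(!is.finite(cf))) return(NULL)
    cf <- pmax(cf, 0)
    if (sum(cf) == 0) return(NULL)
    if (!is.null(fix_max)) cf <- cf * fix_max / sum(cf)
    else if (sum(cf) > 100) cf <- cf * 100 / sum(cf)
    cf
  }
  proj_ssr <- function(phi) {
    tl <- if (free_tlag) phi[1] else fix_tlag
    b <- phi[free_tlag + seq_len(n_phases)]
    a <- (10^phi[free_tlag + n_phases + seq_len(n_phases)])^b
    basis <- try(basis_fun(tl, b, a), silent = TRUE)
    if (inherits(basis, "try-error")) return(1e10)
    cf <- solve_lin(basis)
    if (is.null(cf)) return(1e10)
    sum((drop(basis %*% cf) - y)^2)
  }
  phi_lower <- c(if (free_tlag) 0, rep(0.2, n_phases), rep(lo_tc, n_phases))
  phi_upper <- c(if (free_tlag) max(t) / 4, rep(5, n_phases),
                 rep(hi_tc, n_phases))

  # deterministic coarse grid plus seeded random candidates; characteristic
  # times are multiset combinations (phases may share a similar time scale
  # and differ only in shape)
  bg <- c(0.5, 0.8, 1.2, 2)
  tg <- seq(lo_tc, hi_tc, length.out = if (n_phases == 3L) 6L else 8L)
  cand <- list()
  grid_b <- as.matrix(do.call(expand.grid, rep(list(bg), n_phases)))
  grid_tc <- as.matrix(do.call(expand.grid, rep(list(tg), n_phases)))
  grid_tc <- grid_tc[!apply(grid_tc, 1L, is.unsorted), , drop = FALSE]
  for (ib in seq_len(nrow(grid_b)))
    for (ic in seq_len(nrow(grid_tc)))
      cand[[length(cand) + 1L]] <- c(if (free_tlag) 0,
                                     unname(grid_b[ib, ]),
                                     unname(grid_tc[ic, ]))
  for (k in seq_len(n_samples))
    cand[[length(cand) + 1L]] <- c(if (free_tlag) 0,
                                   stats::runif(n_phases, 0.25, 4),
                                   sort(stats::runif(n_phases, lo_tc,
                                                     hi_tc)))
  sc <- vapply(cand, proj_ssr, numeric(1))
  ord <- order(sc)
  n_loc <- min(if (is.null(n_local)) max(n_starts, 4L) else n_local,
               length(cand))
  sols <- list(); vals <- numeric(0)
  for (k in ord[seq_len(n_loc)]) {
    o <- try(stats::nlminb(cand[[k]], proj_ssr, lower = phi_lower,
                           upper = phi_upper,
                           control = list(iter.max = 400L)), silent = TRUE)
    if (inherits(o, "try-error")) next
    sols[[length(sols) + 1L]] <- o$par
    vals <- c(vals, o$objective)
    if (o$objective < 1e-14 * max(1, sum(y^2))) break
  }
  if (length(sols) == 0L) stop("variable-projection search failed")
  # convert the best projected solutions into packed full-theta starts
  pack_phi <- function(phi) {
    tl <- if (free_tlag) phi[1] else fix_tlag
    b <- phi[free_tlag + seq_len(n_phases)]
    a <- (10^phi[free_tlag + n_phases + seq_len(n_phases)])^b
    basis <- try(basis_fun(tl, b, a), silent = TRUE)
    if (inherits(basis, "try-error")) return(NULL)
    cf <- solve_lin(basis)
    if (is.null(cf)) return(NULL)
    cf <- pmax(cf, 1e-6)
    mx <- sum(cf)
    c(if (is.null(fix_max)) mx, if (free_tlag) tl,
      .frac_to_stick(cf / mx), log10(a), b)
  }
  keep <- order(vals)[seq_len(min(3L, length(vals)))]
  starts <- Filter(Negate(is.null), lapply(sols[keep], pack_phi))
  if (length(starts) == 0L) stop("variable-projection search failed")
  list(starts = starts, ssr = vals[keep])
}

# evaluate expr with a temporary RNG state (restores the caller's state)
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
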