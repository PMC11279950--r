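#' Central-compartment disposition parameters
#'
#' @param cl total clearance from the central compartment, L/h.
#' @param vc central volume of distribution, L/kg.
#' @param k12,k21 inter-compartmental rate constants, 1/h (both 0 for a
#'   1-compartment model; either both zero or both positive).
#' @param body_weight kg.
#' @param fu fraction unbound in plasma (0, 1].
#' @param bp blood-to-plasma concentration ratio (> 0).
#' @return An object of class `disposition_params`.
#' @export
disposition_params <- function(cl, vc, k12 = 0, k21 = 0, body_weight,
                               fu = 1, bp = 1) {
  stopifnot(is.finite(cl), cl > 0, is.finite(vc), vc > 0,
            is.finite(k12), k12 >= 0, is.finite(k21), k21 >= 0,
            is.finite(body_weight), body_weight > 0,
            is.finite(fu), fu > 0, fu <= 1, is.finite(bp), bp > 0)
  if ((k12 > 0) != (k21 > 0))
    stop("'k12' and 'k21' must be both zero or both positive")
  structure(list(cl = cl, vc = vc, k12 = k12, k21 = k21,
                 body_weight = body_weight, fu = fu, bp = bp),
            class = "disposition_params")
}

#' @export
print.disposition_params <- function(x, ...) {
  cat(sprintf(
    "<disposition_params> CL = %.4g L/h, Vc = %.4g L/kg, BW = %.4g kg",
    x$cl, x$vc, x$body_weight))
  if (x$k12 > 0)
    cat(sprintf(", K12 = %.4g /h, K21 = %.4g /h", x$k12, x$k21))
  cat(sprintf(", fu = %.3g, B/P = %.3g\n", x$fu, x$bp))
  invisible(x)
}

#' Subcutaneous injection-site parameters
#'
#' The injection-site tissue exchanges drug with plasma in a
#' perfusion-limited manner; `kp` is the tissue:plasma partition coefficient
#' of the site (adipose for sc depots).
#'
#' @param kp tissue:plasma partition coefficient (> 0).
#' @param v_site site volume, L.
#' @param q_site site blood flow, L/h.
#' @export
depot_site_params <- function(kp, v_site, q_site) {
  stopifnot(is.finite(kp), kp > 0, is.finite(v_site), v_site > 0,
            is.finite(q_site), q_site > 0)
  structure(list(kp = kp, v_site = v_site, q_site = q_site),
            class = "depot_site_params")
}

#' Default injection-site physiology scaled by body weight
#'
#' Reference values are for a 10-kg dog (`v_site` 0.1 L, `q_site` 1.2 L/h)
#' and scale linearly with body weight.
#'
#' @param body_weight kg.
#' @param kp tissue:plasma partition coefficient.
#' @export
default_site_params <- function(body_weight, kp = 1.9) {
  depot_site_params(kp = kp, v_site = 0.1 * body_weight / 10,
                    q_site = 1.2 * body_weight / 10)
}

#' Dosing event
#'
#' @param amount dose, mg (> 0).
#' @param start start time, h.
#' @param duration infusion duration, h; 0 means a bolus.
#' @export
dose_event <- function(amount, start = 0, duration = 0) {
  stopifnot(is.finite(amount), is.finite(start), is.finite(duration))
  if (amount <= 0) stop("'amount' must be > 0")
  if (duration < 0) stop("'duration' must be >= 0")
  structure(list(amount = amount, start = start, duration = duration),
            class = "dose_event")
}

#' Concentration-time profile
#'
#' The universal currency between modelling stages.
#'
#' @param times h, strictly increasing.
#' @param conc ng/mL, non-negative.
#' @param analyte `"parent"` or `"metabolite"`.
#' @param dose mg.
#' @param route one of `"iv_bolus"`, `"iv_infusion"`, `"sc_ir"`, `"sc_lai"`.
#' @param subject_id label.
#' @export
conc_profile <- function(times, conc, analyte = "parent", dose = NA_real_,
                         route = "iv_bolus", subject_id = "s1") {
  if (length(times) != length(conc))
    stop("'times' and 'conc' must have equal length")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("'times' must be finite and strictly increasing")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("'conc' must be finite and >= 0")
  route <- match.arg(route, c("iv_bolus", "iv_infusion", "sc_ir", "sc_lai"))
  analyte <- match.arg(analyte, c("parent", "metabolite"))
  structure(list(times = as.numeric(times), conc = as.numeric(conc),
                 analyte = analyte, dose = dose, route = route,
                 subject_id = subject_id),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf(
    "<conc_profile> %s [%s], %s, dose %.4g mg, %d points over [%.3g, %.3g] h, Cmax = %.4g ng/mL\n",
    x$subject_id, x$analyte, x$route, x$dose, length(x$times),
    min(x$times), max(x$times), max(x$conc)))
  invisible(x)
}

# molar masses, g/mol (risperidone and its 9-hydroxy metabolite)
.MW_PARENT <- 410.49
.MW_METABOLITE <- 426.48

#' Closed-form iv disposition simulation
#'
#' Analytic 1-compartment (mono-exponential) or 2-compartment
#' (bi-exponential) plasma profile for an iv bolus or a constant-rate
#' infusion. For a bolus, `C(0+) = dose / (Vc * BW)`; for any infusion
#' duration, `AUC(0-Inf) = dose / CL`.
#'
#' @param params a [disposition_params()] object.
#' @param dose a [dose_event()] object.
#' @param times output times, h.
#' @param subject_id label carried into the output.
#' @return A [conc_profile()] in ng/mL.
#' @export
simulate_disposition <- function(params, dose, times, subject_id = "sim") {
  stopifnot(inherits(params, "disposition_params"),
            inherits(dose, "dose_event"))
  if (any(times < 0)) stop("'times' must be >= 0")
  v <- params$vc * params$body_weight           # L
  k10 <- params$cl / v
  t <- times - dose$start

  if (params$k12 > 0) {
    ssum <- k10 + params$k12 + params$k21
    disc <- sqrt(ssum^2 - 4 * k10 * params$k21)
    al <- (ssum + disc) / 2
    be <- (ssum - disc) / 2
    ca <- (al - params$k21) / (al - be)
    cb <- (params$k21 - be) / (al - be)
    unit_bolus <- function(tt) ca * exp(-al * tt) + cb * exp(-be * tt)
    unit_int <- function(tt) ca / al * (1 - exp(-al * tt)) +
      cb / be * (1 - exp(-be * tt))
  } else {
    unit_bolus <- function(tt) exp(-k10 * tt)
    unit_int <- function(tt) (1 - exp(-k10 * tt)) / k10
  }

  conc_mgL <- numeric(length(t))
  pos <- t >= 0
  if (dose$duration == 0) {
    conc_mgL[pos] <- dose$amount / v * unit_bolus(t[pos])
  } else {
    r0 <- dose$amount / dose$duration            # mg/h
    tp <- t[pos]
    conc_mgL[pos] <- r0 / v *
      (unit_int(tp) - ifelse(tp > dose$duration,
                             unit_int(tp - dose$duration), 0))
  }
  conc_profile(times, conc_mgL * 1000, analyte = "parent",
               dose = dose$amount,
               route = if (dose$duration == 0) "iv_bolus" else "iv_infusion",
               subject_id = subject_id)
}

# build the depot drain-rate function (percent of dose per hour) for either a
# weibull_release or an absorbed_series input; returns list(rate, cum)
.release_input <- function(release) {
  if (inherits(release, "weibull_release")) {
    rate <- function(t) {
      r <- release_rate(release, t)
      # shapes < 1 have an integrable singularity at the lag; evaluate a
      # hair above it so the stiff solver sees a finite right-hand side
      if (!is.finite(r)) r <- release_rate(release, t + 1e-9)
      r
    }
    list(rate = rate, cum = function(t) eval_release(release, t))
  } else if (inherits(release, "absorbed_series")) {
    tt <- release$times; yy <- release$absorbed_pct
    if (tt[1] > 0) { tt <- c(0, tt); yy <- c(0, yy) }
    slopes <- diff(yy) / diff(tt)
    rate <- function(t) {
      if (t <= tt[1] || t >= tt[length(tt)]) return(0)  # flat extrapolation
      slopes[findInterval(t, tt, rightmost.closed = TRUE)]
    }
    cumf <- stats::approxfun(tt, yy, rule = 2)
    list(rate = rate, cum = cumf, hmax = max(min(diff(tt)), 1e-3))
  } else {
    stop("'release' must be a weibull_release or an absorbed_series")
  }
}

#' Mechanistic depot simulation
#'
#' Integrates a formulation depot draining at the release rate into a
#' perfusion-limited injection-site tissue, which exchanges with the central
#' compartment at flux `Q_site * (C_plasma * BP - C_site * BP / Kp)`
#' (amount/h), plus first-order elimination `CL * C_plasma` and an optional
#' peripheral compartment. Mass balance
#' (released = site + central + peripheral + eliminated) is tracked and
#' reported as the attribute `mass_balance_rel`.
#'
#' @param disp a [disposition_params()] object.
#' @param site a [depot_site_params()] object.
#' @param release a [weibull_release()] object, or an `absorbed_series`
#'   (see [absorbed_fraction_series()]) used as the drain schedule.
#' @param dose a [dose_event()]; the infusion fields are ignored (the depot
#'   is deposited at `start`).
#' @param times output times, h.
#' @param rtol,atol_scale solver tolerances (`atol = atol_scale * dose`
#'   keeps the error control dose-proportional, preserving linearity).
#' @param subject_id label.
#' @return A [conc_profile()] (ng/mL) with attributes `states` (matrix of
#'   amounts, mg) and `mass_balance_rel`.
#' @export
simulate_depot <- function(disp, site, release, dose, times,
                           rtol = 1e-10, atol_scale = 1e-12,
                           subject_id = "sim") {
  stopifnot(inherits(disp, "disposition_params"),
            inherits(site, "depot_site_params"),
            inherits(dose, "dose_event"))
  if (any(times < 0)) stop("'times' must be >= 0")
  inp <- .release_input(release)
  v <- disp$vc * disp$body_weight
  two_cpt <- disp$k12 > 0

  deriv <- function(t, y, p) {
    tr <- t - dose$start
    r_in <- if (tr >= 0) dose$amount * inp$rate(tr) / 100 else 0  # mg/h
    cp <- y["central"] / v                       # mg/L plasma
    cs <- y["site"] / site$v_site                # mg/L tissue
    flux_in_site <- site$q_site * disp$bp * (cp - cs / site$kp)
    elim <- disp$cl * cp
    d_site <- r_in + flux_in_site
    d_central <- -flux_in_site - elim
    d_per <- 0
    if (two_cpt) {
      d_central <- d_central - disp$k12 * y["central"] + disp$k21 * y["periph"]
      d_per <- disp$k12 * y["central"] - disp$k21 * y["periph"]
    }
    list(c(cum_rel = r_in, site = d_site, central = d_central,
           periph = d_per, elim = elim))
  }

  y0 <- c(cum_rel = 0, site = 0, central = 0, periph = 0, elim = 0)
  tgrid <- sort(unique(c(0, times)))
  args <- list(y = y0, times = tgrid, func = deriv, parms = NULL,
               rtol = rtol, atol = atol_scale * dose$amount,
               maxsteps = 50000L)
  if (!is.null(inp$hmax)) args$hmax <- inp$hmax
  sol <- try(do.call(deSolve::lsoda, args), silent = TRUE)
  if (inherits(sol, "try-error") ||
      nrow(sol) < length(tgrid) || any(!is.finite(sol)))
    stop("stiff integration failed for depot simulation (CL = ", disp$cl,
         ", Vc = ", disp$vc, ", Kp = ", site$kp, ", dose = ", dose$amount,
         " mg)")
  sol <- sol[match(times, tgrid), , drop = FALSE]
  mb <- max(abs(sol[, "cum_rel"] -
                (sol[, "site"] + sol[, "central"] + sol[, "periph"] +
                 sol[, "elim"]))) / dose$amount
  out <- conc_profile(times, pmax(sol[, "central"] / v, 0) * 1000,
                      analyte = "parent", dose = dose$amount,
                      route = "sc_lai", subject_id = subject_id)
  attr(out, "states") <- sol
  attr(out, "mass_balance_rel") <- mb
  out
}

# fast exponential-integrator path for the (linear, time-invariant) depot
# system, used inside fitting objectives: states (site, central[, periph])
# with the release input entering the site. The input is taken
# piecewise-linear on a dense node grid and propagated exactly through the
# eigendecomposition of the system matrix. Accuracy is set by the node
# density; the public lsoda simulator remains the reference.
.depot_fast <- function(disp, site, release, dose, times, n_nodes = 500L) {
  v <- disp$vc * disp$body_weight
  qb <- site$q_site * disp$bp
  two_cpt <- disp$k12 > 0
  n <- if (two_cpt) 3L else 2L
  m <- matrix(0, n, n)
  m[1, 1] <- -qb / (site$v_site * site$kp)
  m[1, 2] <- qb / v
  m[2, 1] <- qb / (site$v_site * site$kp)
  m[2, 2] <- -qb / v - disp$cl / v
  if (two_cpt) {
    m[2, 2] <- m[2, 2] - disp$k12
    m[2, 3] <- disp$k21
    m[3, 2] <- disp$k12
    m[3, 3] <- -disp$k21
  }
  eg <- eigen(m)
  vr <- eg$vectors; vi <- solve(vr); lam <- eg$values
  t_max <- max(times)
  t_rel <- pmax(times - dose$start, 0)
  nodes <- sort(unique(c(0, 10^seq(-6, log10(max(t_max - dose$start,
                                                 1e-5)),
                                   length.out = n_nodes), t_rel)))
  if (inherits(release, "weibull_release")) {
    u <- release_rate(release, nodes)
    bad <- !is.finite(u)
    if (any(bad)) u[bad] <- release_rate(release, nodes[bad] + 1e-9)
    u <- dose$amount * u / 100
    cumF <- dose$amount * eval_release(release, nodes) / 100
  } else {
    inp <- .release_input(release)
    u <- dose$amount *
      vapply(nodes, function(tt) inp$rate(tt), numeric(1)) / 100
    cumF <- dose$amount * inp$cum(nodes) / 100
  }
  x <- numeric(n)
  bvec <- c(1, rep(0, n - 1L))
  out <- matrix(NA_real_, length(nodes), n)
  out[1, ] <- x
  # propagate in the eigenbasis: z' = lam z + w u(t), u linear per interval
  z <- vi %*% x
  w <- vi %*% bvec
  for (k in seq_len(length(nodes) - 1L)) {
    dt <- nodes[k + 1L] - nodes[k]
    u0 <- u[k]; u1 <- u[k + 1L]
    # rescale the linear input so each interval delivers the exact
    # cumulative-release increment (mass-matched; handles the integrable
    # singularity of shapes < 1 at the lag)
    dF <- cumF[k + 1L] - cumF[k]
    trap <- dt * (u0 + u1) / 2
    if (trap > 0) {
      s <- dF / trap
      u0 <- u0 * s; u1 <- u1 * s
    } else if (dt > 0) {
      u0 <- u1 <- dF / dt
    }
    cslope <- (u1 - u0) / dt
    e <- exp(lam * dt)
    phi1 <- (e - 1) / lam
    phi2 <- (phi1 - dt) / lam
    z <- e * z + w * (phi1 * u0 + phi2 * cslope)
    out[k + 1L, ] <- Re(vr %*% z)
  }
  central <- out[match(t_rel, nodes), 2L]
  central[times < dose$start] <- 0
  pmax(central, 0) / v * 1000
}

#' Metabolite kinetic parameters
#'
#' @param cl_met metabolite total clearance, L/h.
#' @param v_met metabolite volume of distribution, L/kg; required (no silent
#'   default).
#' @param fraction_formed fraction of parent elimination converted to the
#'   metabolite, in `[0, 1]`.
#' @export
metabolite_params <- function(cl_met, v_met, fraction_formed = 1) {
  if (missing(v_met) || is.null(v_met) || !is.finite(v_met) || v_met <= 0)
    stop("metabolite volume of distribution 'v_met' must be supplied and > 0")
  stopifnot(is.finite(cl_met), cl_met > 0,
            is.finite(fraction_formed), fraction_formed >= 0,
            fraction_formed <= 1)
  structure(list(cl_met = cl_met, v_met = v_met,
                 fraction_formed = fraction_formed),
            class = "metabolite_params")
}

#' Simulate parent and metabolite together
#'
#' The metabolite compartment is fed at
#' `fraction_formed * (parent hepatic elimination rate)` with the molar-mass
#' correction (410.49 -> 426.48 g/mol), and eliminated with `cl_met`.
#'
#' @param disp parent [disposition_params()].
#' @param met [metabolite_params()].
#' @param input either a [dose_event()] (iv administration) or a list
#'   `list(site = depot_site_params, release = weibull_release or
#'   absorbed_series, dose = dose_event)` for a depot administration.
#' @param times output times, h.
#' @param rtol solver relative tolerance.
#' @return list with elements `parent` and `metabolite`, both
#'   [conc_profile()] objects.
#' @export
simulate_with_metabolite <- function(disp, met, input, times, rtol = 1e-10) {
  stopifnot(inherits(disp, "disposition_params"),
            inherits(met, "metabolite_params"))
  v <- disp$vc * disp$body_weight
  vm <- met$v_met * disp$body_weight
  mw_ratio <- .MW_METABOLITE / .MW_PARENT
  two_cpt <- disp$k12 > 0

  if (inherits(input, "dose_event")) {
    dose <- input
    rate_in <- function(t) {
      tr <- t - dose$start
      if (dose$duration == 0 || tr < 0 || tr > dose$duration) 0
      else dose$amount / dose$duration
    }
    bolus0 <- if (dose$duration == 0) dose$amount else 0
    site <- NULL
  } else {
    stopifnot(inherits(input$site, "depot_site_params"),
              inherits(input$dose, "dose_event"))
    site <- input$site
    dose <- input$dose
    inp <- .release_input(input$release)
    rate_in <- function(t) {
      tr <- t - dose$start
      if (tr >= 0) dose$amount * inp$rate(tr) / 100 else 0
    }
    bolus0 <- 0
  }

  deriv <- function(t, y, p) {
    cp <- y["central"] / v
    elim <- disp$cl * cp
    d_central <- -elim
    d_site <- 0
    if (!is.null(site)) {
      cs <- y["site"] / site$v_site
      flux <- site$q_site * disp$bp * (cp - cs / site$kp)
      d_site <- rate_in(t) + flux
      d_central <- d_central - flux
    } else {
      d_central <- d_central + rate_in(t)
    }
    d_per <- 0
    if (two_cpt) {
      d_central <- d_central - disp$k12 * y["central"] + disp$k21 * y["periph"]
      d_per <- disp$k12 * y["central"] - disp$k21 * y["periph"]
    }
    cm <- y["met"] / vm
    d_met <- met$fraction_formed * elim * mw_ratio - met$cl_met * cm
    list(c(site = d_site, central = d_central, periph = d_per, met = d_met))
  }
  y0 <- c(site = 0, central = 0, periph = 0, met = 0)
  if (is.null(site)) y0["central"] <- 0
  tgrid <- sort(unique(c(0, dose$start, times)))
  y0["central"] <- if (is.null(site) && dose$start == 0) bolus0 else 0
  evts <- NULL
  if (is.null(site) && dose$duration == 0 && dose$start > 0)
    evts <- list(data = data.frame(var = "central", time = dose$start,
                                   value = dose$amount, method = "add"))
  sol <- deSolve::lsoda(y0, tgrid, deriv, parms = NULL, rtol = rtol,
                        atol = 1e-12 * dose$amount, events = evts,
                        maxsteps = 50000L)
  sol <- sol[match(times, tgrid), , drop = FALSE]
  route <- if (is.null(site)) {
    if (dose$duration == 0) "iv_bolus" else "iv_infusion"
  } else "sc_lai"
  list(
    parent = conc_profile(times, pmax(sol[, "central"] / v, 0) * 1000,
                          analyte = "parent", dose = dose$amount,
                          route = route, subject_id = "sim"),
    metabolite = conc_profile(times, pmax(sol[, "met"] / vm, 0) * 1000,
                              analyte = "metabolite", dose = dose$amount,
                              route = route, subject_id = "sim"))
}

#' Michaelis-Menten parameters per enzyme
#'
#' @param enzyme character labels.
#' @param vm maximum velocity, pmol/min/pmol CYP.
#' @param km Michaelis constant, uM.
#' @export
mm_params <- function(enzyme, vm, km) {
  stopifnot(length(enzyme) == length(vm), length(vm) == length(km),
            all(is.finite(vm)), all(vm >= 0), all(is.finite(km)), all(km > 0))
  structure(list(enzyme = as.character(enzyme), vm = as.numeric(vm),
                 km = as.numeric(km)), class = "mm_params")
}

#' IVIVE scaling constants
#'
#' Literature-typical defaults for an adult human liver; the per-enzyme
#' hepatic abundances are named by enzyme label.
#'
#' @param abundance named vector, pmol CYP per mg microsomal protein.
#' @param mppgl mg microsomal protein per g liver.
#' @param liver_mass g.
#' @param q_h hepatic blood flow, L/h.
#' @export
ivive_scaling <- function(abundance = c(CYP3A4 = 137, CYP2D6 = 8),
                          mppgl = 40, liver_mass = 1800, q_h = 90) {
  stopifnot(all(is.finite(abundance)), all(abundance > 0),
            is.finite(mppgl), mppgl > 0, is.finite(liver_mass),
            liver_mass > 0, is.finite(q_h), q_h > 0)
  if (is.null(names(abundance)) || any(names(abundance) == ""))
    stop("'abundance' must be a named vector (per-enzyme)")
  structure(list(abundance = abundance, mppgl = mppgl,
                 liver_mass = liver_mass, q_h = q_h),
            class = "ivive_scaling")
}

#' IVIVE hepatic clearance (well-stirred model)
#'
#' Scales intrinsic clearance `sum(Vm/Km * abundance) * MPPGL * liver_mass`
#' from recombinant-CYP kinetics to the whole organ, then applies the
#' well-stirred model `CL_h = Q_h * fu_b * CL_int / (Q_h + fu_b * CL_int)`
#' with blood unbound fraction `fu_b = fu / BP`. Plasma clearance is
#' `CL_blood * BP`.
#'
#' Units: `Vm/Km` in uL/min/pmol CYP; after abundance (pmol/mg), MPPGL
#' (mg/g) and liver mass (g), intrinsic clearance is in uL/min, converted to
#' L/h by `* 60 / 1e6`.
#'
#' @param mm [mm_params()].
#' @param scaling [ivive_scaling()]; abundance must cover every enzyme whose
#'   label is matched by a name (matching is by prefix so e.g. two
#'   `"CYP2D6 1"`/`"CYP2D6 2"` assays share the `"CYP2D6"` abundance).
#' @param fu fraction unbound in plasma.
#' @param bp blood-to-plasma ratio.
#' @param enzymes optional subset of enzyme labels to include in the sum
#'   (default: all entries).
#' @return list with `cl_int_u` (L/h), `cl_blood` (L/h), `cl_plasma` (L/h).
#' @export
ivive_clearance <- function(mm, scaling, fu, bp, enzymes = NULL) {
  stopifnot(inherits(mm, "mm_params"), inherits(scaling, "ivive_scaling"),
            is.finite(fu), fu > 0, fu <= 1, is.finite(bp), bp > 0)
  idx <- if (is.null(enzymes)) seq_along(mm$enzyme)
         else which(mm$enzyme %in% enzymes)
  if (length(idx) == 0L) stop("no enzymes selected")
  ab <- vapply(mm$enzyme[idx], function(e) {
    hit <- which(vapply(names(scaling$abundance),
                        function(nm) startsWith(e, nm), logical(1)))
    if (length(hit) == 0L)
      stop("no abundance entry matching enzyme '", e, "'")
    scaling$abundance[[hit[1]]]
  }, numeric(1))
  clint_uL_min <- sum(mm$vm[idx] / mm$km[idx] * ab) *
    scaling$mppgl * scaling$liver_mass
  cl_int <- clint_uL_min * 60 / 1e6                # L/h
  fu_b <- fu / bp
  cl_blood <- scaling$q_h * fu_b * cl_int / (scaling$q_h + fu_b * cl_int)
  list(cl_int_u = cl_int, cl_blood = cl_blood, cl_plasma = cl_blood * bp)
}
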