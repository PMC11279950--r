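#' Multiplicative lognormal noise model
#'
#' Lognormal sigma is `sqrt(log(1 + cv^2))` so that `cv` is the geometric
#' coefficient of variation of the noise.
#'
#' @param cv geometric CV as a fraction (default 0.15, typical of combined
#'   bioanalytical and inter-animal variability).
#' @param lloq lower limit of quantification, ng/mL; simulated values below
#'   it are reported as 0.
#' @param seed integer RNG seed.
#' @export
noise_model <- function(cv = 0.15, lloq = 0.05, seed = 1L) {
  stopifnot(is.finite(cv), cv >= 0, is.finite(lloq), lloq >= 0)
  structure(list(cv = cv, sigma = sqrt(log(1 + cv^2)), lloq = lloq,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Study design (arm)
#'
#' @param label arm label.
#' @param dose mg.
#' @param route one of the [conc_profile()] routes, or `"invitro"`.
#' @param sampling_times h, strictly increasing.
#' @param n_subjects number of subjects or replicates.
#' @export
study_design <- function(label, dose, route, sampling_times, n_subjects) {
  if (any(diff(sampling_times) <= 0))
    stop("'sampling_times' must be strictly increasing")
  structure(list(label = label, dose = dose, route = route,
                 sampling_times = as.numeric(sampling_times),
                 n_subjects = as.integer(n_subjects)),
            class = "study_design")
}

#' Built-in study designs
#'
#' Sampling schedules of the dog iv / immediate-release sc / long-acting sc
#' studies, the human single-dose study, and the 16-point accelerated
#' in vitro release assay.
#'
#' @param dose mg (defaults: 1 mg iv, 5 mg IR sc, 50 mg LAI, 50 mg human).
#' @param n_subjects number of subjects or replicates.
#' @name designs
NULL

#' @rdname designs
#' @export
design_dog_iv <- function(dose = 1, n_subjects = 6L) {
  study_design("dog_iv", dose, "iv_bolus",
               c(5 / 60, 0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 18, 24, 36, 48,
                 72), n_subjects)
}

#' @rdname designs
#' @export
design_dog_ir_sc <- function(dose = 5, n_subjects = 6L) {
  study_design("dog_ir_sc", dose, "sc_ir",
               c(5 / 60, 0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 18, 24, 36, 48,
                 60, 72, 96, 120), n_subjects)
}

#' @rdname designs
#' @export
design_dog_lai <- function(dose = 50, n_subjects = 10L) {
  study_design("dog_lai", dose, "sc_lai",
               c(1, 3, 6, 24, 168, 336, 672), n_subjects)
}

#' @rdname designs
#' @export
design_human_lai <- function(dose = 50, n_subjects = 12L) {
  study_design("human_lai", dose, "sc_lai",
               c(0.5, 1, 2, 3, 4, 6, 8, 12, 24, 30, 36,
                 24 * c(3, 4, 5, 6, 7, 8, 10, 12, 15, 18, 22, 25, 29, 36,
                        43, 50, 57, 64, 71, 78, 85, 92, 99, 106, 112)),
               n_subjects)
}

#' @rdname designs
#' @export
design_invitro <- function(dose = 50, n_subjects = 12L) {
  study_design("invitro", dose, "invitro",
               c(2, 6, 12, 24, 30, 48, 72, 96, 168, 192, 216, 264, 336,
                 408, 504, 672), n_subjects)
}

#' Generate a noisy multi-subject PK dataset
#'
#' Applies per-subject multiplicative lognormal noise (median-unbiased:
#' meanlog 0, so the geometric mean of many subjects recovers the truth) to
#' a model-generated truth curve; values below the LLOQ are reported as 0.
#'
#' @param truth either a function `f(times) -> ng/mL` or a [conc_profile()]
#'   evaluated on the design's sampling times.
#' @param design a [study_design()].
#' @param noise a [noise_model()].
#' @return list of [conc_profile()] objects, one per subject.
#' @export
gen_pk_dataset <- function(truth, design, noise) {
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_model"))
  tt <- design$sampling_times
  base <- if (is.function(truth)) truth(tt) else {
    stopifnot(inherits(truth, "conc_profile"))
    stats::approx(truth$times, truth$conc, xout = tt, rule = 2)$y
  }
  if (length(base) != length(tt) || any(!is.finite(base)) || any(base < 0))
    stop("truth curve must be finite and non-negative on the design times")
  .with_seed(noise$seed, {
    lapply(seq_len(design$n_subjects), function(i) {
      cc <- base * exp(stats::rnorm(length(tt), 0, noise$sigma))
      cc[cc < noise$lloq] <- 0
      conc_profile(tt, cc, analyte = "parent", dose = design$dose,
                   route = if (design$route == "invitro") "sc_lai"
                           else design$route,
                   subject_id = sprintf("%s_%02d", design$label, i))
    })
  })
}

#' Generate a noisy in vitro release dataset
#'
#' Replicate noise is applied to the *increments* of the truth curve
#' (mean-unbiased lognormal, meanlog `-sigma^2/2`), so every replicate is
#' non-decreasing by construction and the arithmetic replicate mean is
#' centred on the truth.
#'
#' @param truth a [weibull_release()].
#' @param design a [study_design()] (use [design_invitro()]).
#' @param noise a [noise_model()] (the LLOQ is ignored: release percentages
#'   are not concentrations).
#' @return list of [release_profile()] objects.
#' @export
gen_invitro_dataset <- function(truth, design, noise) {
  stopifnot(inherits(truth, "weibull_release"),
            inherits(design, "study_design"), inherits(noise, "noise_model"))
  tt <- design$sampling_times
  cum <- eval_release(truth, tt)
  incr <- diff(c(0, cum))
  .with_seed(noise$seed, {
    lapply(seq_len(design$n_subjects), function(i) {
      mult <- exp(stats::rnorm(length(incr), -noise$sigma^2 / 2,
                               noise$sigma))
      release_profile(tt, cumsum(incr * mult), strength_mg = design$dose,
                      replicate_id = sprintf("rep%02d", i))
    })
  })
}

#' Average replicate release profiles
#'
#' Arithmetic mean of the cumulative percent released across replicates at
#' each time point (the conventional summary for dissolution data).
#'
#' @param profiles list of [release_profile()] on a shared time grid.
#' @return A single [release_profile()] with `replicate_id = "mean"`.
#' @export
mean_release_profile <- function(profiles) {
  tt <- profiles[[1]]$times
  for (p in profiles)
    if (!isTRUE(all.equal(p$times, tt)))
      stop("replicates must share the same time grid")
  m <- rowMeans(vapply(profiles, function(p) p$cumulative_pct,
                       numeric(length(tt))))
  release_profile(tt, m, strength_mg = profiles[[1]]$strength_mg,
                  replicate_id = "mean")
}

#' Geometric-mean summary of PK profiles
#'
#' Per-time geometric mean over positive concentrations, with the geometric
#' CV `sqrt(exp(var(log)) - 1)`. Zero (BLQ) values are excluded from the
#' mean, with exclusion counts reported; an all-zero time point yields a
#' mean of 0 and a flag.
#'
#' @param profiles list of at least 2 [conc_profile()] on a shared grid.
#' @return list: `profile` (the geometric-mean [conc_profile()]), `cv`
#'   (geometric CV per time; `NA` where fewer than 2 positive values),
#'   `n_excluded` (per time), `all_zero` (logical per time).
#' @export
summarize_geomean <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  tt <- profiles[[1]]$times
  for (p in profiles)
    if (!isTRUE(all.equal(p$times, tt)))
      stop("profiles must share the same time grid")
  mat <- matrix(vapply(profiles, function(p) p$conc,
                       numeric(length(tt))), nrow = length(tt))
  gm <- cv <- numeric(length(tt))
  nexcl <- integer(length(tt))
  for (i in seq_along(tt)) {
    x <- mat[i, ]
    pos <- x[x > 0]
    nexcl[i] <- sum(x <= 0)
    if (length(pos) == 0L) {
      gm[i] <- 0; cv[i] <- NA_real_
    } else {
      lx <- log(pos)
      gm[i] <- exp(mean(lx))
      cv[i] <- if (length(pos) >= 2L) sqrt(exp(stats::var(lx)) - 1)
               else NA_real_
    }
  }
  list(profile = conc_profile(tt, gm, analyte = profiles[[1]]$analyte,
                              dose = profiles[[1]]$dose,
                              route = profiles[[1]]$route,
                              subject_id = "geomean"),
       cv = cv, n_excluded = nexcl, all_zero = nexcl == length(profiles))
}

#' Printed parameter sets used as synthetic truth
#'
#' Convenience constructors for the fitted parameter sets reported for this
#' formulation: the dog double-Weibull release, the human triple-Weibull
#' absorption (per strength), the dog disposition, and the in vitro
#' Michaelis-Menten constants.
#'
#' @name truth-sets
NULL

#' @rdname truth-sets
#' @export
dog_release_truth <- function() {
  weibull_release(100, 0, c(0.142, 0.858), c(30.88, 6370.7),
                  c(0.717, 1.285))
}

#' @rdname truth-sets
#' @param strength `"50"` or `"225"` (mg).
#' @export
human_release_truth <- function(strength = c("50", "225")) {
  strength <- match.arg(strength)
  if (strength == "50")
    weibull_release(99.75, 0.090, c(0.197, 0.367, 0.436),
                    c(102.1, 2745.8, 1823000), c(0.68, 1.32, 2.05))
  else
    weibull_release(60.0, 0.095, c(0.187, 0.367, 0.446),
                    c(107.2, 2745.8, 1914000), c(0.65, 1.32, 2.05))
}

#' @rdname truth-sets
#' @export
dog_disposition_truth <- function() {
  disposition_params(cl = 8.3, vc = 1.13, body_weight = 10, fu = 0.083,
                     bp = 0.51)
}

#' @rdname truth-sets
#' @export
risperidone_mm_truth <- function() {
  mm_params(c("CYP2D6 1", "CYP2D6 2", "CYP3A4"),
            vm = c(13.9, 3.155, 12.4), km = c(40.4, 0.534, 37.4))
}

#' @rdname truth-sets
#' @param body_weight kg.
#' @export
human_disposition_truth <- function(body_weight = 65) {
  cl <- ivive_clearance(risperidone_mm_truth(), ivive_scaling(),
                        fu = 0.10, bp = 0.67)$cl_plasma
  disposition_params(cl = cl, vc = 1.13, body_weight = body_weight,
                     fu = 0.10, bp = 0.67)
}
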