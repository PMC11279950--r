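#' Read / write concentration CSV files
#'
#' The concentration interchange format has columns `subject_id`,
#' `analyte`, `time_h`, `conc_ng_ml`, `dose_mg`, `route` (header required,
#' decimal point, comma separator).
#'
#' @param path file path.
#' @return `read_conc_csv()`: a list of [conc_profile()] objects (one per
#'   `subject_id` x `analyte`).
#' @export
read_conc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "analyte", "time_h", "conc_ng_ml", "dose_mg",
            "route")
  if (!all(need %in% names(df)))
    stop("concentration CSV must have columns: ", paste(need, collapse = ", "))
  sp <- split(df, interaction(df$subject_id, df$analyte, drop = TRUE))
  lapply(unname(sp), function(d) {
    d <- d[order(d$time_h), ]
    conc_profile(d$time_h, d$conc_ng_ml, analyte = d$analyte[1],
                 dose = d$dose_mg[1], route = d$route[1],
                 subject_id = d$subject_id[1])
  })
}

#' @rdname read_conc_csv
#' @param profiles a [conc_profile()] or list of them.
#' @export
write_conc_csv <- function(profiles, path) {
  if (inherits(profiles, "conc_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, analyte = p$analyte,
               time_h = p$times, conc_ng_ml = p$conc, dose_mg = p$dose,
               route = p$route))
  df <- do.call(rbind, rows)
  df$time_h <- format(df$time_h, digits = 15, trim = TRUE,
                      scientific = FALSE)
  df$conc_ng_ml <- format(df$conc_ng_ml, digits = 15, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write in vitro release CSV files
#'
#' Columns `time_h`, `pct_released`, `replicate`, `strength_mg`.
#'
#' @param path file path.
#' @return `read_release_csv()`: a list of [release_profile()] objects.
#' @export
read_release_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "pct_released", "replicate", "strength_mg")
  if (!all(need %in% names(df)))
    stop("release CSV must have columns: ", paste(need, collapse = ", "))
  sp <- split(df, interaction(df$replicate, df$strength_mg, drop = TRUE))
  lapply(unname(sp), function(d) {
    d <- d[order(d$time_h), ]
    release_profile(d$time_h, d$pct_released, strength_mg = d$strength_mg[1],
                    replicate_id = as.character(d$replicate[1]))
  })
}

#' @rdname read_release_csv
#' @param profiles a [release_profile()] or list of them.
#' @export
write_release_csv <- function(profiles, path) {
  if (inherits(profiles, "release_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p)
    data.frame(time_h = p$times, pct_released = p$cumulative_pct,
               replicate = p$replicate_id, strength_mg = p$strength_mg))
  df <- do.call(rbind, rows)
  df$time_h <- format(df$time_h, digits = 15, trim = TRUE,
                      scientific = FALSE)
  df$pct_released <- format(df$pct_released, digits = 15, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.config_keys <- c("seed", "species", "site", "ivive", "noise", "fitting",
                  "ivivc", "doses", "paths")

#' Demonstration run configuration
#'
#' A fully-specified configuration for an end-to-end synthetic run: the
#' synthetic truths are the printed dog and human parameter sets, with
#' study designs and noise as in the emulated studies.
#'
#' @param seed master seed; every stage derives its sub-seed from it.
#' @param n_starts_lai,n_starts_deconv optimiser starts for the expensive
#'   stages (reduce for quick runs).
#' @param cv geometric CV of the simulated noise.
#' @return A named list of class `run_config`.
#' @export
demo_config <- function(seed = 1L, n_starts_lai = 16L, n_starts_deconv = 8L,
                        cv = 0.15) {
  structure(list(
    seed = as.integer(seed),
    species = list(
      dog = list(body_weight_kg = 10, fu = 0.083, bp_ratio = 0.51),
      human = list(body_weight_kg = 65, fu = 0.10, bp_ratio = 0.67,
                   vc_l_kg = 1.13, metabolite_cl_ml_min = 80,
                   metabolite_v_l_kg = 1.13)),
    site = list(kp = 1.9, v_site_ref_l = 0.1, q_site_ref_lh = 1.2),
    ivive = list(abundance = c(CYP3A4 = 137, CYP2D6 = 8), mppgl = 40,
                 liver_mass_g = 1800, q_h_lh = 90),
    noise = list(cv = cv, lloq = 0.05),
    fitting = list(n_starts_iv = 6L, n_starts_lai = as.integer(n_starts_lai),
                   n_starts_deconv = as.integer(n_starts_deconv),
                   log_objective = FALSE),
    ivivc = list(fraction_grid = seq(5, 80, by = 5), cap = NULL,
                 levy_method = "interp", normalize = FALSE),
    doses = list(dog_iv = 1, dog_ir = 5, dog_lai = 50,
                 human = c(50, 225))),
    class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown top-level keys are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$ivive$abundance))
    cfg$ivive$abundance <- unlist(cfg$ivive$abundance)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Hash of the resolved configuration
#'
#' MD5 of the canonical (sorted-key) JSON serialisation; stamped into every
#' artifact so outputs can be traced to the exact configuration.
#'
#' @param config a `run_config`.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       sort_keys = TRUE)
  unname(tools::md5sum(tmp))
}

.write_artifact <- function(x, path, config, stage) {
  x$stage <- stage
  x$seed <- config$seed
  x$config_hash <- config_hash(config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

.read_artifact <- function(out_dir, name, needed_by) {
  p <- file.path(out_dir, paste0(name, ".json"))
  if (!file.exists(p))
    stop("stage '", needed_by, "' needs the artifact of stage '", name,
         "' (", p, " not found); run that stage first")
  jsonlite::read_json(p, simplifyVector = TRUE)
}

.wr_to_list <- function(wr)
  list(max_release_pct = wr$max_release_pct, t_lag = wr$t_lag,
       fractions = wr$fractions, scales = wr$scales, shapes = wr$shapes)

.wr_from_list <- function(x)
  weibull_release(x$max_release_pct, x$t_lag, x$fractions, x$scales,
                  x$shapes)

.corr_from_artifact <- function(a) {
  cf <- unlist(a$coefficients)
  pred <- switch(a$family,
    linear = function(z) cf[1] + cf[2] * z,
    poly2 = function(z) cf[1] + cf[2] * z + cf[3] * z^2,
    poly3 = function(z) cf[1] + cf[2] * z + cf[3] * z^2 + cf[4] * z^3,
    higuchi = function(z) cf[1] + cf[2] * sqrt(pmax(z, 0)),
    sigmoid = function(z) cf["A"] / (1 + exp(-(z - cf["x0"]) / cf["s"])),
    gompertz = function(z) cf["A"] * exp(-exp(-cf["k"] * (z - cf["x0"]))))
  structure(list(family = a$family, coefficients = cf,
                 r_squared = a$r_squared, leaderboard = NULL, .pred = pred),
            class = "correlation_model")
}

.pipeline_stages <- c("simulate", "fit-iv", "fit-irsc", "fit-lai",
                      "human-predict", "deconvolve", "levy", "correlate",
                      "predict", "validate")

#' Run the full pipeline
#'
#' Executes the modelling stages in dependency order: synthetic data
#' generation, iv disposition fit, Kp fit, in vivo release fit, human
#' prediction with metabolite tracking, per-strength mechanistic
#' deconvolution, Levy time scaling, correlation fitting, convolution
#' prediction, and Level-A internal validation. Each stage writes a JSON
#' artifact (stamped with the seed and the configuration hash) into
#' `out_dir`; rerunning with an identical configuration reproduces the
#' artifacts bit for bit. Missing upstream artifacts raise an error naming
#' the missing stage.
#'
#' @param config a `run_config` (see [demo_config()]).
#' @param out_dir artifact directory (created if needed).
#' @param stages subset of stages to run, in any order (executed in
#'   dependency order).
#' @param plots write SVG figures (concentration-time, Levy, correlation)
#'   into `out_dir/plots`.
#' @param quiet suppress per-stage log lines.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = demo_config(), out_dir,
                         stages = .pipeline_stages, plots = FALSE,
                         quiet = FALSE) {
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  seed <- config$seed
  log <- function(stage, n, obj) {
    if (!quiet)
      message(sprintf("[%s] seed=%d n=%d objective=%.6g elapsed=%.2fs",
                      stage, seed, n, obj[1], obj[2]))
  }
  dog <- config$species$dog
  hum <- config$species$human
  site_geom_dog <- list(v_site = config$site$v_site_ref_l *
                          dog$body_weight_kg / 10,
                        q_site = config$site$q_site_ref_lh *
                          dog$body_weight_kg / 10)
  site_geom_hum <- list(v_site = config$site$v_site_ref_l *
                          hum$body_weight_kg / 10,
                        q_site = config$site$q_site_ref_lh *
                          hum$body_weight_kg / 10)
  scl <- ivive_scaling(abundance = config$ivive$abundance,
                       mppgl = config$ivive$mppgl,
                       liver_mass = config$ivive$liver_mass_g,
                       q_h = config$ivive$q_h_lh)
  human_cl <- ivive_clearance(risperidone_mm_truth(), scl, fu = hum$fu,
                              bp = hum$bp_ratio)$cl_plasma
  human_disp <- disposition_params(human_cl, hum$vc_l_kg,
                                   body_weight = hum$body_weight_kg,
                                   fu = hum$fu, bp = hum$bp_ratio)
  human_site <- depot_site_params(config$site$kp, site_geom_hum$v_site,
                                  site_geom_hum$q_site)

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    el <- function() proc.time()[["elapsed"]] - t0
    switch(stage,
      "simulate" = {
        disp_d <- disposition_params(8.3, 1.13,
                                     body_weight = dog$body_weight_kg,
                                     fu = dog$fu, bp = dog$bp_ratio)
        site_d <- depot_site_params(config$site$kp, site_geom_dog$v_site,
                                    site_geom_dog$q_site)
        nm <- function(k) noise_model(config$noise$cv, config$noise$lloq,
                                      seed + k)
        d_iv <- design_dog_iv(config$doses$dog_iv)
        iv_truth <- simulate_disposition(disp_d,
                                         dose_event(config$doses$dog_iv),
                                         d_iv$sampling_times)
        write_conc_csv(gen_pk_dataset(iv_truth, d_iv, nm(1L)),
                       file.path(out_dir, "dog_iv.csv"))
        ir_rel <- weibull_release(100, 0, 1, 0.05, 1)
        d_ir <- design_dog_ir_sc(config$doses$dog_ir)
        ir_truth <- simulate_depot(disp_d, site_d, ir_rel,
                                   dose_event(config$doses$dog_ir),
                                   d_ir$sampling_times)
        ir_ds <- gen_pk_dataset(ir_truth, d_ir, nm(2L))
        ir_ds <- lapply(ir_ds, function(p) { p$route <- "sc_ir"; p })
        write_conc_csv(ir_ds, file.path(out_dir, "dog_ir.csv"))
        d_lai <- design_dog_lai(config$doses$dog_lai)
        lai_truth <- simulate_depot(disp_d, site_d, dog_release_truth(),
                                    dose_event(config$doses$dog_lai),
                                    d_lai$sampling_times)
        write_conc_csv(gen_pk_dataset(lai_truth, d_lai, nm(3L)),
                       file.path(out_dir, "dog_lai.csv"))
        for (i in seq_along(config$doses$human)) {
          dmg <- config$doses$human[i]
          d_h <- design_human_lai(dmg)
          tr <- human_release_truth(as.character(dmg))
          h_truth <- simulate_depot(human_disp, human_site, tr,
                                    dose_event(dmg), d_h$sampling_times)
          write_conc_csv(gen_pk_dataset(h_truth, d_h, nm(10L + i)),
                         file.path(out_dir, sprintf("human_%d.csv", dmg)))
          # the in vitro assay is the in vivo release on an accelerated
          # clock: truth scales the human absorption times down
          vit_truth <- weibull_release(
            tr$max_release_pct, tr$t_lag / 11,
            tr$fractions, tr$scales / 11^tr$shapes, tr$shapes)
          write_release_csv(
            gen_invitro_dataset(vit_truth, design_invitro(dmg),
                                nm(20L + i)),
            file.path(out_dir, sprintf("invitro_%d.csv", dmg)))
        }
        truth <- list(dog_disposition = list(cl = 8.3, vc = 1.13),
                      kp = config$site$kp,
                      dog_release = .wr_to_list(dog_release_truth()),
                      human_release_50 =
                        .wr_to_list(human_release_truth("50")),
                      human_release_225 =
                        .wr_to_list(human_release_truth("225")),
                      human_cl_plasma = human_cl,
                      invitro_time_scale = 11)
        paths$simulate <- .write_artifact(truth,
          file.path(out_dir, "simulate.json"), config, "simulate")
        log(stage, length(d_iv$sampling_times), c(NA, el()))
      },
      "fit-iv" = {
        if (!file.exists(file.path(out_dir, "dog_iv.csv")))
          stop("stage 'fit-iv' needs dog_iv.csv from stage 'simulate'")
        ds <- read_conc_csv(file.path(out_dir, "dog_iv.csv"))
        gm <- summarize_geomean(ds)$profile
        fit <- fit_iv(gm, model_order = 1L,
                      body_weight = dog$body_weight_kg,
                      n_starts = config$fitting$n_starts_iv, seed = seed,
                      log_objective = config$fitting$log_objective)
        paths[["fit-iv"]] <- .write_artifact(
          list(estimates = fit$estimates, r_squared = fit$r_squared,
               n_starts = fit$n_starts),
          file.path(out_dir, "fit-iv.json"), config, "fit-iv")
        log(stage, length(gm$times), c(1 - fit$r_squared, el()))
      },
      "fit-irsc" = {
        iv_art <- .read_artifact(out_dir, "fit-iv", "fit-irsc")
        ds <- read_conc_csv(file.path(out_dir, "dog_ir.csv"))
        gm <- summarize_geomean(ds)$profile
        disp <- disposition_params(iv_art$estimates$cl, iv_art$estimates$vc,
                                   body_weight = dog$body_weight_kg,
                                   fu = dog$fu, bp = dog$bp_ratio)
        fit <- fit_kp(gm, disp, site_geometry = site_geom_dog,
                      log_objective = config$fitting$log_objective)
        paths[["fit-irsc"]] <- .write_artifact(
          list(estimates = fit$estimates, r_squared = fit$r_squared),
          file.path(out_dir, "fit-irsc.json"), config, "fit-irsc")
        log(stage, length(gm$times), c(1 - fit$r_squared, el()))
      },
      "fit-lai" = {
        iv_art <- .read_artifact(out_dir, "fit-iv", "fit-lai")
        kp_art <- .read_artifact(out_dir, "fit-irsc", "fit-lai")
        ds <- read_conc_csv(file.path(out_dir, "dog_lai.csv"))
        gm <- summarize_geomean(ds)$profile
        disp <- disposition_params(iv_art$estimates$cl, iv_art$estimates$vc,
                                   body_weight = dog$body_weight_kg,
                                   fu = dog$fu, bp = dog$bp_ratio)
        site <- depot_site_params(kp_art$estimates$kp,
                                  site_geom_dog$v_site,
                                  site_geom_dog$q_site)
        fit <- fit_release_in_vivo(gm, disp, site, n_phases = 2L,
                                   n_starts = config$fitting$n_starts_lai,
                                   seed = seed,
                                   log_objective =
                                     config$fitting$log_objective)
        paths[["fit-lai"]] <- .write_artifact(
          list(release = .wr_to_list(fit$release),
               r_squared = fit$r_squared),
          file.path(out_dir, "fit-lai.json"), config, "fit-lai")
        log(stage, length(gm$times), c(1 - fit$r_squared, el()))
      },
      "human-predict" = {
        lai_art <- .read_artifact(out_dir, "fit-lai", "human-predict")
        rel <- .wr_from_list(lai_art$release)
        dmg <- config$doses$human[1]
        d_h <- design_human_lai(dmg)
        met <- metabolite_params(hum$metabolite_cl_ml_min * 60 / 1000,
                                 hum$metabolite_v_l_kg)
        sim <- simulate_with_metabolite(
          human_disp, met,
          list(site = human_site, release = rel, dose = dose_event(dmg)),
          d_h$sampling_times)
        obs <- summarize_geomean(read_conc_csv(
          file.path(out_dir, sprintf("human_%d.csv", dmg))))$profile
        nca_p <- exposure_summary(sim$parent)
        nca_o <- exposure_summary(obs)
        paths[["human-predict"]] <- .write_artifact(
          list(dose_mg = dmg,
               predicted = list(cmax = nca_p$cmax,
                                auc_last = nca_p$auc_last),
               observed = list(cmax = nca_o$cmax,
                               auc_last = nca_o$auc_last),
               pe_cmax = prediction_error(nca_o$cmax, nca_p$cmax),
               pe_auc = prediction_error(nca_o$auc_last, nca_p$auc_last),
               metabolite_cmax = max(sim$metabolite$conc)),
          file.path(out_dir, "human-predict.json"), config,
          "human-predict")
        log(stage, length(d_h$sampling_times), c(NA, el()))
      },
      "deconvolve" = {
        for (dmg in config$doses$human) {
          obs <- summarize_geomean(read_conc_csv(
            file.path(out_dir, sprintf("human_%d.csv", dmg))))$profile
          dec <- deconvolve(obs, human_disp, human_site, n_phases = 3L,
                            normalize = config$ivivc$normalize,
                            n_starts = config$fitting$n_starts_deconv,
                            seed = seed)
          nm <- sprintf("deconvolve_%d", dmg)
          paths[[nm]] <- .write_artifact(
            list(release = .wr_to_list(dec$release),
                 r_squared = dec$fit$r_squared,
                 absorbed = list(times = dec$absorbed$times,
                                 absorbed_pct = dec$absorbed$absorbed_pct)),
            file.path(out_dir, paste0(nm, ".json")), config, nm)
          log(stage, length(obs$times), c(1 - dec$fit$r_squared, el()))
        }
      },
      "levy" = {
        vitro <- list(); vivo <- list()
        for (dmg in config$doses$human) {
          dec <- .read_artifact(out_dir, sprintf("deconvolve_%d", dmg),
                                "levy")
          reps <- read_release_csv(
            file.path(out_dir, sprintf("invitro_%d.csv", dmg)))
          vitro[[as.character(dmg)]] <- mean_release_profile(reps)
          vivo[[as.character(dmg)]] <- absorbed_fraction_series(
            dec$absorbed$times, dec$absorbed$absorbed_pct,
            strength_mg = dmg)
        }
        ts <- levy_time_scaling(vitro, vivo,
                                fraction_grid = config$ivivc$fraction_grid,
                                method = config$ivivc$levy_method,
                                seed = seed)
        paths$levy <- .write_artifact(
          list(slope = ts$slope, r_squared = ts$r_squared,
               n_pairs = nrow(ts$matched_pairs), n_dropped = ts$n_dropped,
               matched_pairs = ts$matched_pairs),
          file.path(out_dir, "levy.json"), config, "levy")
        if (plots) .plot_levy_file(ts, file.path(out_dir, "plots"))
        log(stage, nrow(ts$matched_pairs), c(ts$r_squared, el()))
      },
      "correlate" = {
        lv <- .read_artifact(out_dir, "levy", "correlate")
        xs <- ys <- numeric(0)
        for (dmg in config$doses$human) {
          dec <- .read_artifact(out_dir, sprintf("deconvolve_%d", dmg),
                                "correlate")
          reps <- read_release_csv(
            file.path(out_dir, sprintf("invitro_%d.csv", dmg)))
          mp <- mean_release_profile(reps)
          t_scaled <- lv$slope * mp$times
          absf <- stats::approx(dec$absorbed$times,
                                dec$absorbed$absorbed_pct,
                                xout = t_scaled, rule = 2)$y
          keep <- t_scaled <= max(dec$absorbed$times)
          xs <- c(xs, mp$cumulative_pct[keep]); ys <- c(ys, absf[keep])
        }
        corr <- fit_correlation(xs, ys)
        paths$correlate <- .write_artifact(
          list(family = corr$family,
               coefficients = as.list(corr$coefficients),
               r_squared = corr$r_squared,
               leaderboard = corr$leaderboard),
          file.path(out_dir, "correlate.json"), config, "correlate")
        if (plots) .plot_corr_file(xs, ys, corr, file.path(out_dir, "plots"))
        log(stage, length(xs), c(corr$r_squared, el()))
      },
      "predict" = {
        lv <- .read_artifact(out_dir, "levy", "predict")
        co <- .read_artifact(out_dir, "correlate", "predict")
        corr <- .corr_from_artifact(co)
        ts <- structure(list(slope = lv$slope, r_squared = lv$r_squared,
                             matched_pairs = NULL, n_dropped = 0L),
                        class = "time_scaling")
        for (dmg in config$doses$human) {
          reps <- read_release_csv(
            file.path(out_dir, sprintf("invitro_%d.csv", dmg)))
          mp <- mean_release_profile(reps)
          d_h <- design_human_lai(dmg)
          pred <- convolve_predict(mp, ts, corr, human_disp, human_site,
                                   dose = dmg,
                                   times = d_h$sampling_times,
                                   cap = config$ivivc$cap)
          nm <- sprintf("predict_%d", dmg)
          ex <- exposure_summary(pred)
          paths[[nm]] <- .write_artifact(
            list(times = pred$times, conc = pred$conc,
                 cmax = ex$cmax, auc_last = ex$auc_last),
            file.path(out_dir, paste0(nm, ".json")), config, nm)
          if (plots) .plot_profile_file(pred, sprintf("predicted_%dmg", dmg),
                                        file.path(out_dir, "plots"))
          log(stage, length(pred$times), c(ex$cmax, el()))
        }
      },
      "validate" = {
        obs <- list(); prd <- list()
        for (dmg in config$doses$human) {
          pa <- .read_artifact(out_dir, sprintf("predict_%d", dmg),
                               "validate")
          gm <- summarize_geomean(read_conc_csv(
            file.path(out_dir, sprintf("human_%d.csv", dmg))))$profile
          s <- as.character(dmg)
          obs[[s]] <- exposure_summary(gm)
          prd[[s]] <- list(cmax = pa$cmax, auc_last = pa$auc_last)
        }
        rep <- internal_validation(obs, prd, auc_metric = "auc_last")
        paths$validate <- .write_artifact(
          list(table = rep$table, mean_pe_cmax = rep$mean_pe_cmax,
               mean_pe_auc = rep$mean_pe_auc,
               level_a_pass = rep$level_a_pass,
               individual_within_15 = rep$individual_within_15),
          file.path(out_dir, "validate.json"), config, "validate")
        log(stage, nrow(rep$table), c(rep$mean_pe_cmax, el()))
      })
  }
  invisible(paths)
}

# ---- plotting helpers (SVG via cairo; silently skipped if unavailable) ----

.plot_profile_file <- function(profile, name, dir) {
  if (!capabilities("cairo")) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grDevices::svg(file.path(dir, paste0(name, ".svg")), width = 7,
                 height = 5)
  on.exit(grDevices::dev.off())
  pos <- profile$conc > 0
  graphics::plot(profile$times[pos], profile$conc[pos], log = "y",
                 type = "b", pch = 16, xlab = "Time (h)",
                 ylab = "Concentration (ng/mL)", main = name)
  invisible(NULL)
}

.plot_levy_file <- function(ts, dir) {
  if (!capabilities("cairo")) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grDevices::svg(file.path(dir, "levy.svg"), width = 6, height = 6)
  on.exit(grDevices::dev.off())
  mp <- ts$matched_pairs
  graphics::plot(mp$t_vitro, mp$t_vivo, pch = 16,
                 xlab = "In vitro time (h)", ylab = "In vivo time (h)",
                 main = sprintf("Levy plot: slope %.2f, R2 %.3f",
                                ts$slope, ts$r_squared))
  graphics::abline(0, ts$slope, lty = 2)
  invisible(NULL)
}

.plot_corr_file <- function(x, y, corr, dir) {
  if (!capabilities("cairo")) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grDevices::svg(file.path(dir, "correlation.svg"), width = 6, height = 6)
  on.exit(grDevices::dev.off())
  graphics::plot(x, y, pch = 16, xlab = "% released (in vitro)",
                 ylab = "% absorbed (in vivo)",
                 main = sprintf("IVIVC: %s, R2 %.3f", corr$family,
                                corr$r_squared))
  xv <- seq(min(x), max(x), length.out = 200)
  graphics::lines(xv, predict(corr, xv), lty = 2)
  invisible(NULL)
}
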