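# Configuration, result serialization, and reproducible run entry points.

KCAL_PER_MJ <- 1 / 0.004184

#' Convert kilocalories per day to MJ per day
#' @param kcal energy in kcal
#' @return energy in MJ (1 kcal = 0.004184 MJ)
#' @export
kcal <- function(kcal) kcal * 0.004184

default_config <- function() {
  list(
    curves = list(source = "synthetic", sex = "male", race = "nh_white",
                  lms_files = NULL, params = list()),
    subject = list(height_factor = 1, bmi_factor = 1, fmi_offset = 0,
                   pa_factor = 1, bioage_multiplier = 1),
    composition = as.list(unclass(composition_params()))[
      c("lambda_bmi", "gamma", "age_slope", "adult_age_years", "rho_fm",
        "rho_ffm_adult", "rho_ffm_intercept", "rho_ffm_sat")],
    metabolic = as.list(unclass(metabolic_params()))[
      c("tef_fraction", "at_coefficient", "at_includes_growth", "dep_eff_fm",
        "dep_eff_ffm", "turnover_rate", "sigma_fm", "sigma_residual",
        "pa_scales_with_weight")],
    simulation = as.list(unclass(sim_params())),
    scenario = list(t_start_years = 0, t_end_years = 20,
                    ei_multiplier = 1, ei_constant_mj = NULL,
                    windows = NULL))
}

check_known_keys <- function(cfg, ref, path = "") {
  for (k in names(cfg)) {
    if (!k %in% names(ref))
      stop(sprintf("unknown config key: %s%s", path, k))
    if (is.list(cfg[[k]]) && is.list(ref[[k]]) && length(ref[[k]]) &&
        !is.null(names(ref[[k]])) && !k %in% c("params", "lms_files", "windows"))
      check_known_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

#' Read and validate a run configuration
#'
#' YAML configuration with sections `curves`, `subject`, `composition`,
#' `metabolic`, `simulation`, `scenario`; every key has a documented default
#' and unknown keys are rejected. The scenario section supports a constant
#' multiplier of reference intake, a constant absolute intake, and piecewise
#' `windows` (list of `from_years`/`to_years` with either `multiplier` or
#' `offset_kcal_day` entries).
#'
#' @param path YAML file path
#' @return validated config list of class `gs_config`
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- default_config()
  check_known_keys(cfg, ref)
  merged <- utils::modifyList(ref, cfg)
  structure(merged, class = "gs_config")
}

#' Write a configuration to YAML
#' @param config a config list
#' @param path output path
#' @return invisibly, `path`
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_objects <- function(cfg) {
  curves <- if (identical(cfg$curves$source, "lms")) {
    load_lms_table(unlist(cfg$curves$lms_files), sex = cfg$curves$sex,
                   race = cfg$curves$race, params = cfg$curves$params)
  } else {
    synthetic_reference(cfg$curves$sex, cfg$curves$race, cfg$curves$params)
  }
  subj <- do.call(subject, c(list(sex = cfg$curves$sex, race = cfg$curves$race),
                             cfg$subject))
  params <- model_params(
    composition = do.call(composition_params, cfg$composition),
    metabolic = do.call(metabolic_params, cfg$metabolic),
    simulation = do.call(sim_params, cfg$simulation))
  sc <- cfg$scenario
  ei_fun <- function(age, ref_ei) {
    ei <- if (!is.null(sc$ei_constant_mj)) sc$ei_constant_mj
          else sc$ei_multiplier * ref_ei
    if (!is.null(sc$windows)) {
      for (w in sc$windows) {
        if (age >= yr(w$from_years) && age < yr(w$to_years)) {
          if (!is.null(w$multiplier)) ei <- w$multiplier * ref_ei
          if (!is.null(w$offset_kcal_day)) ei <- ei + kcal(w$offset_kcal_day)
        }
      }
    }
    max(0, ei)
  }
  scn <- scenario(yr(sc$t_start_years), yr(sc$t_end_years), ei = ei_fun)
  list(curves = curves, subject = subj, params = params, scenario = scn)
}

write_manifest <- function(dir, files) {
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
}

#' Run a simulation scenario from a configuration file
#'
#' Writes the per-day result CSV, a resolved-config snapshot, and a manifest
#' with content hashes into `out_dir`. Runs are deterministic: the same
#' config produces byte-identical outputs.
#'
#' @param config_path YAML config path (or a `gs_config` list)
#' @param out_dir output directory
#' @return invisibly, the simulation result
#' @export
run_scenario <- function(config_path, out_dir = ".") {
  cfg <- if (inherits(config_path, "gs_config")) config_path
         else read_config(config_path)
  obj <- config_objects(cfg)
  res <- simulate_scenario(obj$subject, obj$curves, obj$scenario, obj$params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res_path <- file.path(out_dir, "simulation.csv")
  utils::write.csv(format(res, digits = 10, trim = TRUE), res_path,
                   row.names = FALSE, quote = FALSE)
  cfg_path <- file.path(out_dir, "config_resolved.yaml")
  write_config(cfg, cfg_path)
  write_manifest(out_dir, c(res_path, cfg_path))
  invisible(res)
}

#' Run an analysis from a configuration file
#'
#' Dispatches to the analysis operations: `"maintenance_gap"` (against the
#' reference curve shifted by `delta_bmi`), `"energy_gap"` (one-year BMI
#' reduction), `"percentile"` (track a BMI curve given as a multiplier of
#' reference), or `"calibrate"` (intake multiplier to a target weight).
#'
#' @param config_path YAML config path (or `gs_config` list)
#' @param analysis one of `"energy_gap"`, `"maintenance_gap"`,
#'   `"percentile"`, `"calibrate"`
#' @param out_dir output directory
#' @param ... analysis-specific arguments (`delta_bmi`, `age_years`,
#'   `bmi_multiplier`, `target_weight`, `target_age_years`)
#' @return invisibly, the analysis result
#' @export
run_analysis <- function(config_path,
                         analysis = c("energy_gap", "maintenance_gap",
                                      "percentile", "calibrate"),
                         out_dir = ".", ...) {
  analysis <- match.arg(analysis)
  cfg <- if (inherits(config_path, "gs_config")) config_path
         else read_config(config_path)
  obj <- config_objects(cfg)
  args <- list(...)
  res <- switch(analysis,
    energy_gap = {
      out <- weight_loss_energy_gap(obj$subject, obj$curves,
                                    delta_bmi = args$delta_bmi %||% 1,
                                    age = yr(args$age_years %||% 30),
                                    params = obj$params)
      as.data.frame(out)
    },
    maintenance_gap = {
      delta <- args$delta_bmi %||% 0
      actual <- function(a) obj$subject$bmi_factor *
        obj$curves$bmi_ref(biological_age(a, obj$subject)) + delta
      grid <- yr(args$age_years %||% seq(5, 60, by = 5))
      maintenance_energy_gap(obj$subject, obj$curves, actual, grid, obj$params)
    },
    percentile = {
      mult <- args$bmi_multiplier %||% 1
      curve <- function(a) mult * obj$curves$bmi_ref(biological_age(a, obj$subject))
      percentile_tracking_intake(obj$subject, obj$curves, curve,
                                 obj$scenario$t_start, obj$scenario$t_end,
                                 obj$params)
    },
    calibrate = {
      out <- calibrate_intake_multiplier(obj$subject, obj$curves,
                                         target_weight = args$target_weight,
                                         target_age = yr(args$target_age_years),
                                         params = obj$params)
      data.frame(multiplier = out$multiplier,
                 achieved_weight = out$achieved_weight)
    })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res_path <- file.path(out_dir, paste0(analysis, ".csv"))
  utils::write.csv(as.data.frame(res), res_path, row.names = FALSE)
  write_manifest(out_dir, res_path)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
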