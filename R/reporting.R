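# Run configuration and report generation: each command reads one YAML
# config, executes a stage of the pipeline, and writes its outputs plus
# a manifest sufficient to reproduce the run (config echo + hash, seed,
# package version). Progress goes to messages (stderr); results go to
# files only.

#' Read and validate a run configuration
#'
#' YAML with unit-suffixed keys. Sections: \code{geometry}
#' (\code{plate_format}, \code{coculture}, \code{grid_spacing_cm},
#' optional \code{conductivity_S_per_m} or a field-dependent
#' \code{conductivity} block), \code{electrodes} (\code{layout},
#' \code{spacing_cm}), \code{plan} (list of \code{pair},
#' \code{amplitude_V}, \code{n_pulses}, optional \code{pulse_width_us},
#' \code{frequency_Hz}; \code{pair} may be \code{all} or
#' \code{adjacent}), \code{sweep} (\code{E_min_V_per_cm},
#' \code{E_max_V_per_cm}, \code{step_V_per_cm}), \code{thresholds}
#' (\code{exp_V_per_cm}, \code{rep_V_per_cm}), \code{simulate}
#' (\code{true_threshold_V_per_cm}, \code{noise_cv}, \code{n_samples}),
#' and a top-level \code{seed}.
#'
#' @param path YAML file, or a pre-parsed list.
#' @return The validated config list (class \code{run_config}).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config error: file not found: ", path)
    yaml::read_yaml(path)
  } else path
  if (!is.list(cfg)) stop("config error: top level must be a mapping")
  for (sec in c("geometry", "electrodes", "plan"))
    if (is.null(cfg[[sec]]))
      stop("config error: missing required section '", sec, "'")
  req <- function(sec, key) {
    if (is.null(cfg[[sec]][[key]]))
      stop(sprintf("config error: missing key %s.%s", sec, key))
    cfg[[sec]][[key]]
  }
  fmt <- req("geometry", "plate_format")
  if (!fmt %in% c(24, 12, 6))
    stop("config error: geometry.plate_format must be 24, 12 or 6")
  lay <- req("electrodes", "layout")
  if (!lay %in% c("pair", "triangle", "square"))
    stop("config error: electrodes.layout must be pair/triangle/square")
  if (!is.list(cfg$plan) || length(cfg$plan) == 0)
    stop("config error: plan must be a non-empty list of activations")
  for (i in seq_along(cfg$plan)) {
    a <- cfg$plan[[i]]
    if (is.null(a$amplitude_V) || is.null(a$n_pulses))
      stop(sprintf("config error: plan[%d] needs amplitude_V and n_pulses", i))
  }
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

config_conductivity <- function(gcfg) {
  if (!is.null(gcfg$conductivity_S_per_m))
    return(conductivity_model(gcfg$conductivity_S_per_m))
  cc <- gcfg$conductivity
  if (is.null(cc)) return(NULL)  # geometry defaults
  conductivity_model(
    sigma0 = cc$sigma0_S_per_m %||% 0.4,
    sigmaf = cc$sigmaf_S_per_m %||% cc$sigma0_S_per_m %||% 0.4,
    form = cc$form %||% "field_dependent",
    E_center = cc$E_center_V_per_cm %||% 500,
    E_width = cc$E_width_V_per_cm %||% 100)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# geometry + electrodes + plan from a validated config
build_run <- function(cfg) {
  g <- make_well_geometry(
    plate_format = cfg$geometry$plate_format,
    coculture = isTRUE(cfg$geometry$coculture),
    grid_spacing = cfg$geometry$grid_spacing_cm %||% 0.01,
    conductivity = config_conductivity(cfg$geometry))
  e <- place_electrodes(g, cfg$electrodes$layout,
                        spacing = cfg$electrodes$spacing_cm,
                        electrode_radius =
                          cfg$electrodes$electrode_radius_cm %||% 0.0455)
  pairs <- list(); protos <- list()
  for (a in cfg$plan) {
    pp <- pulse_protocol(a$amplitude_V, a$n_pulses,
                         a$pulse_width_us %||% 100, a$frequency_Hz %||% 1)
    pr <- a$pair %||% "all"
    pset <- if (identical(pr, "all") || identical(pr, "adjacent"))
      enumerate_pairs(e, pr) else list(as.character(pr))
    for (p in pset) { pairs <- c(pairs, list(p)); protos <- c(protos, list(pp)) }
  }
  list(geometry = g, electrodes = e,
       plan = activation_plan(pairs, protos), config = cfg)
}

config_sweep_args <- function(cfg) {
  list(E_min = cfg$sweep$E_min_V_per_cm %||% 200,
       E_max = cfg$sweep$E_max_V_per_cm %||% 1200,
       step = cfg$sweep$step_V_per_cm %||% 1)
}

write_manifest <- function(out_dir, cfg, extra = list()) {
  tmp <- tempfile()
  saveRDS(unclass(cfg), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- c(list(package = "ireplan",
                     version = as.character(utils::packageVersion("ireplan")),
                     config = unclass(cfg), config_md5 = hash,
                     seed = cfg$seed), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Plan a treatment and write coverage reports
#'
#' Delivers the configured activation plan, then writes to
#' \code{out_dir}: the cumulative field map (CSV and VTK), the tri-level
#' coverage map (8-bit TIFF and VTK), the ablation sweep CSV, a
#' \code{coverage.json} with coverage fractions at the experimental and
#' reported thresholds plus the treatment time, and a manifest.
#'
#' @param config Path to a YAML run config, or a parsed list.
#' @param out_dir Output directory (created if needed).
#' @return The coverage summary list, invisibly.
#' @export
cmd_plan <- function(config, out_dir) {
  cfg <- read_run_config(config)
  run <- build_run(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message("ireplan: delivering ", length(run$plan$activations),
          " activation(s)")
  cum <- run_plan(run$geometry, run$electrodes, run$plan)
  sw <- do.call(ablation_sweep, c(list(cum), config_sweep_args(cfg)))
  thr_exp <- cfg$thresholds$exp_V_per_cm %||% 544
  thr_rep <- cfg$thresholds$rep_V_per_cm %||% 800
  labels <- classify_field_map(cum, thr_exp, thr_rep)
  write_field_csv(cum, file.path(out_dir, "field.csv"))
  write_field_vtk(cum, file.path(out_dir, "field.vtk"))
  write_sweep_csv(sw, file.path(out_dir, "sweep.csv"))
  write_stack_tiff(labels, file.path(out_dir, "coverage_map.tif"))
  write_field_vtk(labels, file.path(out_dir, "coverage_map.vtk"),
                  geometry = run$geometry)
  summary <- list(
    coverage_exp = coverage_fraction(cum, thr_exp),
    coverage_rep = coverage_fraction(cum, thr_rep),
    exp_threshold_V_per_cm = thr_exp, rep_threshold_V_per_cm = thr_rep,
    treatment_time_s = treatment_time(run$plan),
    domain_measure = attr(sw, "domain_measure"),
    unit = attr(sw, "unit"))
  jsonlite::write_json(summary, file.path(out_dir, "coverage.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, cfg, list(command = "plan"))
  message(sprintf("ireplan: coverage %.1f%% (exp) / %.1f%% (rep), %g s",
                  100 * summary$coverage_exp, 100 * summary$coverage_rep,
                  summary$treatment_time_s))
  invisible(summary)
}

#' Invert measured ablation areas to thresholds
#'
#' Reads a CSV of measured ablation areas (columns \code{sample_id},
#' \code{area_mm2}), inverts each through the configured forward model's
#' ablation sweep, and writes per-sample thresholds
#' (\code{thresholds.csv}) plus a JSON summary (mean, sd, n). Samples
#' whose area is outside the simulated range are flagged in the CSV,
#' excluded from the summary, and counted in a message; the run
#' continues.
#'
#' @param config Path to a YAML run config, or a parsed list.
#' @param measured_csv CSV of measurements.
#' @param out_dir Output directory.
#' @return The \code{\link{aggregate_thresholds}} estimate, invisibly.
#' @export
cmd_invert <- function(config, measured_csv, out_dir) {
  cfg <- read_run_config(config)
  meas <- utils::read.csv(measured_csv)
  if (!all(c("sample_id", "area_mm2") %in% names(meas)) || nrow(meas) == 0)
    stop("config error: measured CSV needs non-empty sample_id, area_mm2 columns")
  run <- build_run(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cum <- run_plan(run$geometry, run$electrodes, run$plan)
  sw <- do.call(ablation_sweep, c(list(cum), config_sweep_args(cfg)))
  res <- lapply(seq_len(nrow(meas)), function(i)
    tryCatch(list(threshold = as.numeric(
      invert_threshold(sw, meas$area_mm2[i])), note = ""),
      error = function(e) list(threshold = NA_real_,
                               note = conditionMessage(e))))
  df <- data.frame(sample_id = meas$sample_id,
                   threshold_V_per_cm = vapply(res, `[[`, 0, "threshold"),
                   note = vapply(res, `[[`, "", "note"))
  utils::write.csv(df, file.path(out_dir, "thresholds.csv"),
                   row.names = FALSE)
  ok <- is.finite(df$threshold_V_per_cm)
  if (any(!ok))
    message("ireplan: ", sum(!ok),
            " sample(s) outside the simulated ablation range were excluded")
  if (!any(ok)) stop("no sample could be inverted")
  est <- aggregate_thresholds(df$threshold_V_per_cm[ok])
  jsonlite::write_json(
    list(mean_V_per_cm = est$mean, sd_V_per_cm = est$sd, n = est$n,
         n_excluded = sum(!ok)),
    file.path(out_dir, "threshold_estimate.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  write_manifest(out_dir, cfg, list(command = "invert",
                                    measured_csv = basename(measured_csv)))
  message(sprintf("ireplan: threshold %.0f +/- %.0f V/cm (n = %d)",
                  est$mean, est$sd, est$n))
  invisible(est)
}

#' Generate a synthetic measurement dataset
#'
#' Runs the configured forward model, draws noisy synthetic ablation
#' areas at the configured ground-truth threshold, and writes
#' \code{measurements.csv} (sample_id, area_mm2), a live/dead z-stack
#' TIFF rendered at the ground-truth threshold, and a manifest with all
#' parameters and seeds. Re-running with the same config is
#' bit-identical.
#'
#' @param config Path to a YAML run config (with a \code{simulate}
#'   section), or a parsed list.
#' @param out_dir Output directory.
#' @return The \code{synthetic_measurements}, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  cfg <- read_run_config(config)
  sim <- cfg$simulate
  if (is.null(sim) || is.null(sim$true_threshold_V_per_cm))
    stop("config error: missing simulate.true_threshold_V_per_cm")
  run <- build_run(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cum <- run_plan(run$geometry, run$electrodes, run$plan)
  meas <- synth_ablation_measurements(
    cum, true_threshold = sim$true_threshold_V_per_cm,
    noise_cv = sim$noise_cv %||% 0.05, n = sim$n_samples %||% 9,
    seed = cfg$seed)
  df <- data.frame(sample_id = sprintf("S%02d", seq_along(meas$areas)),
                   area_mm2 = meas$areas)
  utils::write.csv(df, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE, quote = FALSE)
  stack <- render_ablation_stack(cum, sim$true_threshold_V_per_cm)
  write_stack_tiff(stack, file.path(out_dir, "ablation_stack.tif"))
  write_manifest(out_dir, cfg, list(
    command = "simulate",
    true_threshold_V_per_cm = meas$true_threshold,
    true_area = meas$true_area, unit = meas$unit,
    noise_cv = meas$noise_cv, n_samples = length(meas$areas)))
  message(sprintf("ireplan: wrote %d synthetic measurement(s), truth %.4g %s",
                  length(meas$areas), meas$true_area, meas$unit))
  invisible(meas)
}
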