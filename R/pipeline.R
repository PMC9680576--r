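#' Assemble a reproducible run configuration
#'
#' Collects every input of the end-to-end pipeline — phantom, arcs,
#' detector, aperture-search settings, registration settings, motion trace
#' — together with an explicit seed. Validation happens up front: a
#' missing seed is an error before any computation. Defaults are the
#' desk-scale study conditions (1 mm phantom, 0.6 mm detector sampling at
#' the isocenter plane, 15-degree control-point spacing, 300 apertures per
#' control point).
#'
#' @param phantom A [phantom_spec()].
#' @param arcs List of [arc_spec()] (default the three-arc geometry at
#'   15-degree spacing).
#' @param detector A [detector_spec()].
#' @param search List: `threshold`, `n`, `fraction`, `shifts`, `interp`.
#' @param registration List: `bins`, `tol`.
#' @param trace List: `kind`, `magnitude`, `onset`.
#' @param seed Integer master seed (required).
#' @param out_dir Output directory for [run_pipeline()].
#' @return A list of class `run_config` with a `hash` field.
#' @export
run_config <- function(phantom = phantom_spec(spacing = 1, seed = seed),
                       arcs = table1_arcs(spacing = 15),
                       detector = detector_spec(field_mm = 220,
                                                pitch_iso = 0.6),
                       search = list(threshold = 60, n = 300,
                                     fraction = 0.1,
                                     shifts = shift_grid(2, 3),
                                     interp = "bilinear"),
                       registration = list(bins = 50L, tol = 0.01),
                       trace = list(kind = "sudden", magnitude = 1.5,
                                    onset = NULL),
                       seed = NULL, out_dir = "mvroi-run") {
  if (is.null(seed) || !is.finite(seed))
    abort("`seed` must be supplied explicitly in the run configuration")
  seed <- as.integer(seed)
  cfg <- list(phantom = phantom, arcs = arcs, detector = detector,
              search = search, registration = registration, trace = trace,
              seed = seed, out_dir = out_dir)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> seed %d, %d arcs, threshold %s, n %d, hash %s\n",
    x$seed, length(x$arcs), x$search$threshold, x$search$n, x$hash))
  invisible(x)
}

#' Run the full imaging pipeline
#'
#' Executes phantom generation, control-point enumeration, the aperture
#' search and plan build, the grid-shift registration-error study, the
#' motion-trace delivery simulation with both detection methods, and the
#' anatomy-vs-BB error evaluation. Every stage writes its artifacts under
#' `config$out_dir` (plan JSON, per-point CSVs, a summary JSON), each
#' stamped with the configuration hash. Deterministic: two runs of the
#' same configuration produce identical summaries.
#'
#' @param config A [run_config()].
#' @param error_study Run the grid-shift registration-error study stage.
#' @param simulate Run the delivery-simulation stage.
#' @return Invisibly, a list with the phantom, plan, study, runs, error
#'   summary, and output paths.
#' @export
run_pipeline <- function(config, error_study = TRUE, simulate = TRUE) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(x) c(x, list(config_hash = config$hash))
  t_start <- Sys.time()
  stage <- function(name) message(sprintf("[%s] %s", format(Sys.time(),
                                                            "%H:%M:%S"), name))

  stage("phantom: generating digital skull")
  phantom <- generate_skull_phantom(config$phantom)
  cps <- control_points_from_arcs(config$arcs)
  stage(sprintf("plan: %d control points, threshold %s",
                nrow(cps), config$search$threshold))
  plan <- build_imaging_plan(
    phantom, cps, threshold = config$search$threshold,
    detector = config$detector, n = config$search$n,
    fraction = config$search$fraction, shifts = config$search$shifts,
    seed = config$seed, interp = config$search$interp %||% "bilinear",
    tol = config$search$tol %||% 0.02,
    bins = config$registration$bins %||% 50L)
  plan_path <- file.path(config$out_dir, "plan.json")
  write_plan(plan, plan_path)

  study <- NULL
  if (error_study) {
    stage("error study: grid-shift registrations")
    study <- registration_error_study(phantom, plan,
                                      tol = config$registration$tol %||% 0.01,
                                      bins = config$registration$bins %||% 50L)
    write.csv(study$errors,
              file.path(config$out_dir, "registration_errors.csv"),
              row.names = FALSE)
  }

  runs <- NULL
  errors <- NULL
  if (simulate) {
    stage(sprintf("simulate: %s trace, BB and anatomy detection",
                  config$trace$kind))
    trace <- make_motion_trace(config$trace$kind, cps,
                               magnitude = config$trace$magnitude %||% 1.5,
                               onset = config$trace$onset)
    run_bb <- simulate_delivery(phantom, plan, trace, method = "bb")
    run_an <- simulate_delivery(phantom, plan, trace, method = "anatomy",
                                tol = config$registration$tol %||% 0.01,
                                bins = config$registration$bins %||% 50L)
    write.csv(run_bb, file.path(config$out_dir, "delivery_bb.csv"),
              row.names = FALSE)
    write.csv(run_an, file.path(config$out_dir, "delivery_anatomy.csv"),
              row.names = FALSE)
    errors <- evaluate_errors(run_an, run_bb)
    write.csv(errors$per_point,
              file.path(config$out_dir, "errors_per_point.csv"),
              row.names = FALSE)
    runs <- list(bb = run_bb, anatomy = run_an)
  }

  summary <- list(
    seed = config$seed,
    threshold = as.character(config$search$threshold),
    n_control_points = nrow(cps),
    plan = list(mean_area_cm2 = mean(plan$area_cm2),
                n_fallback = sum(plan$fallback)),
    error_study = if (!is.null(study)) as.list(study$summary),
    delivery = if (!is.null(errors)) as.list(errors$summary),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  json_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(stamp(summary[setdiff(names(summary), "elapsed_s")]),
                       json_path, auto_unbox = TRUE, digits = 10,
                       na = "null")
  stage("done")
  invisible(list(phantom = phantom, plan = plan, study = study,
                 runs = runs, errors = errors,
                 paths = list(plan = plan_path, summary = json_path,
                              dir = config$out_dir)))
}
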