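#' Build a control-point-specific imaging plan
#'
#' Runs the full aperture design chain at every control point: reference
#' DRR (with the BB region replaced by fill material), random aperture
#' sampling, grid-shift error scoring, top-fraction selection, topographic
#' map, and threshold-aperture extraction. With `threshold = "open"` the
#' search is skipped and every control point carries the open square field.
#'
#' A control point whose search fails (no valid aperture, or an empty
#' superlevel set) falls back to the open field with a warning. The
#' per-control-point sampling seed is `seed + cp`, so plans are
#' reproducible and control points independent.
#'
#' @param volume A [ct_volume()]; if it still carries BB metadata the BB
#'   neighborhood is replaced via [remove_bb_region()] first.
#' @param control_points Tibble from [control_points_from_arcs()].
#' @param threshold Threshold level in percent (typically 50-90), or
#'   `"open"`.
#' @param detector A [detector_spec()].
#' @param n Apertures sampled per control point.
#' @param fraction Fraction selected into the topographic map.
#' @param shifts Scoring shift grid ([shift_grid()]).
#' @param area_range,aspect_range Sampling bounds (see
#'   [sample_apertures()]).
#' @param seed Integer base seed.
#' @param mu_water Attenuation calibration for DRRs.
#' @param interp,tol,bins Registration settings for scoring.
#' @param bb_fill_hu,bb_neighborhood Passed to [remove_bb_region()].
#' @param keep_maps Keep each control point's topographic map in the
#'   result's `maps` attribute (memory-heavy for long arcs).
#' @param verbose Emit per-control-point progress messages.
#' @return An `imaging_plan`: a tibble with one row per control point
#'   (geometry plus aperture), with attributes `seed`, `threshold`,
#'   `detector`, `config_hash`.
#' @export
build_imaging_plan <- function(volume, control_points, threshold = 60,
                               detector = detector_spec(), n = 3000,
                               fraction = 0.1, shifts = shift_grid(),
                               area_range = c(0.375, 37.5),
                               aspect_range = c(1 / 3, 3),
                               seed = 1L, mu_water = 0.00505,
                               interp = "bilinear", tol = 0.02, bins = 50L,
                               bb_fill_hu = 36.1,
                               bb_neighborhood = c(60, 60, 40),
                               keep_maps = FALSE, verbose = FALSE) {
  open_field <- !is.numeric(threshold) || identical(threshold, "open")
  if (!open_field && (threshold <= 0 || threshold > 100))
    abort("`threshold` must be in (0, 100] or \"open\"")
  if (!is.null(volume$bb)) {
    message("replacing the BB neighborhood with fill material before DRRs")
    volume <- remove_bb_region(volume, bb_neighborhood, bb_fill_hu)
  }

  config <- list(threshold = threshold, detector = unclass(detector), n = n,
                 fraction = fraction, shifts = shifts,
                 area_range = area_range, aspect_range = aspect_range,
                 seed = as.integer(seed), mu_water = mu_water,
                 interp = interp, tol = tol, bins = as.integer(bins))
  maps <- if (keep_maps) vector("list", nrow(control_points)) else NULL

  rows <- purrr::map(seq_len(nrow(control_points)), function(i) {
    cpr <- control_points[i, ]
    if (open_field) {
      ap <- aperture(0, 0, detector$field_mm, detector$field_mm)
      ap$level <- NA_real_
      ap$fallback <- FALSE
      return(dplyr::bind_cols(cpr, ap))
    }
    if (verbose)
      message(sprintf("control point %d/%d (gantry %.1f, couch %.1f)",
                      i, nrow(control_points), cpr$gantry, cpr$couch))
    drr <- compute_drr(volume, cpr, detector, mu_water)
    ap <- tryCatch({
      cand <- sample_apertures(n, area_range, aspect_range,
                               field_mm = detector$field_mm,
                               seed = as.integer(seed) + cpr$cp)
      scored <- evaluate_apertures(drr, cand, shifts, interp = interp,
                                   tol = tol, bins = bins)
      top <- select_top(scored, fraction)
      map <- build_topographic_map(top, drr)
      if (keep_maps) maps[[i]] <<- map
      out <- extract_threshold_aperture(map, threshold)
      out$fallback <- FALSE
      out
    }, error = function(e) {
      warn(sprintf("control point %d: %s; falling back to the open field",
                   cpr$cp, conditionMessage(e)))
      out <- aperture(0, 0, detector$field_mm, detector$field_mm)
      out$level <- NA_real_
      out$fallback <- TRUE
      out
    })
    dplyr::bind_cols(cpr, ap)
  })

  plan <- bind_rows(rows)
  attr(plan, "seed") <- as.integer(seed)
  attr(plan, "threshold") <- if (open_field) "open" else threshold
  attr(plan, "detector") <- detector
  attr(plan, "config_hash") <- rlang::hash(config)
  if (keep_maps) attr(plan, "maps") <- maps
  class(plan) <- c("imaging_plan", class(plan))
  plan
}

#' Serialize and restore imaging plans
#'
#' Plans round-trip through JSON with full provenance (seed, threshold,
#' detector, config hash). Serialization is deterministic: identical
#' seed/config yields byte-identical files.
#'
#' @param plan An `imaging_plan`.
#' @param path Output path.
#' @return `write_plan()` returns `path` invisibly; `read_plan()` the plan.
#' @export
write_plan <- function(plan, path) {
  payload <- list(
    seed = attr(plan, "seed"),
    threshold = attr(plan, "threshold"),
    config_hash = attr(plan, "config_hash"),
    detector = unclass(attr(plan, "detector")),
    control_points = as_tibble(as.data.frame(plan))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- as_tibble(payload$control_points)
  attr(plan, "seed") <- payload$seed
  attr(plan, "threshold") <- payload$threshold
  attr(plan, "config_hash") <- payload$config_hash
  attr(plan, "detector") <- detector_spec(payload$detector$field_mm,
                                          payload$detector$pitch_iso)
  class(plan) <- c("imaging_plan", class(plan))
  plan
}

#' @export
print.imaging_plan <- function(x, ...) {
  cat(sprintf("<imaging_plan> %d control points, threshold %s, seed %s\n",
              nrow(x), attr(x, "threshold"), attr(x, "seed")))
  NextMethod()
}
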