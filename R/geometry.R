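#' Arc geometry specification
#'
#' One treatment/imaging arc: a fixed couch angle with a gantry sweep.
#' Angles use the planning-system (Eclipse/Varian) scale throughout the
#' package: gantry values are numerically identical in the Varian-IEC and
#' IEC 61217 scales, and the couch angle is the one the couch-shift matrix
#' of [derive_couch_shift()] expects (0 = axial arc). Use
#' [couch_eclipse_to_iec()] when an IEC 61217 couch readout is needed.
#'
#' @param couch Couch angle in degrees.
#' @param gantry_start,gantry_stop Gantry sweep endpoints in degrees,
#'   honored exactly as given (e.g. 180.1, no snapping).
#' @param direction `"CW"` (gantry angle increasing) or `"CCW"`.
#' @param spacing Control-point spacing in degrees of gantry rotation.
#' @return A list of class `arc_spec`.
#' @export
arc_spec <- function(couch, gantry_start, gantry_stop,
                     direction = c("CW", "CCW"), spacing = 5) {
  direction <- match.arg(direction)
  if (spacing <= 0) abort("control-point spacing must be positive")
  structure(list(couch = couch %% 360,
                 gantry_start = gantry_start %% 360,
                 gantry_stop = gantry_stop %% 360,
                 direction = direction, spacing = spacing),
            class = "arc_spec")
}

#' The three-arc cranial geometry
#'
#' One full axial arc and two partial arcs with the couch at +/-45 degrees,
#' the standard noncoplanar cranial arrangement the imaging study uses
#' (planning-system coordinates).
#'
#' @param spacing Control-point spacing in degrees (default 5).
#' @return A list of three [arc_spec()] objects.
#' @export
table1_arcs <- function(spacing = 5) {
  list(arc_spec(0, 180.1, 179.9, "CW", spacing),
       arc_spec(45, 179.9, 355, "CCW", spacing),
       arc_spec(315, 180.1, 5, "CW", spacing))
}

arc_span <- function(arc) {
  if (arc$direction == "CW")
    (arc$gantry_stop - arc$gantry_start) %% 360
  else
    (arc$gantry_start - arc$gantry_stop) %% 360
}

#' Enumerate imaging control points from arc specifications
#'
#' Expands each arc into gantry/couch control points at the arc's spacing,
#' starting at `gantry_start` and stepping in the stated rotation direction
#' until the stop angle. The full axial arc at 5 degree spacing yields 72
#' points; each 184.9 degree partial arc yields 38.
#'
#' The EPID is assumed retracted to 50 cm below isocenter for the axial arc
#' (SID 1500 mm) and 80 cm for the couch-rotated arcs (SID 1800 mm, to
#' clear the couch), following the delivery configuration the method was
#' developed with.
#'
#' @param arcs A list of [arc_spec()] objects (or a single one).
#' @param sad Source-axis distance in mm.
#' @param sid_axial,sid_couch Source-imager distances (mm) used when the
#'   couch is at 0 and rotated, respectively.
#' @return A tibble with one row per control point: `cp`, `arc`, `gantry`,
#'   `couch`, `sad`, `sid`.
#' @export
control_points_from_arcs <- function(arcs, sad = 1000,
                                     sid_axial = 1500, sid_couch = 1800) {
  if (inherits(arcs, "arc_spec")) arcs <- list(arcs)
  if (!length(arcs)) abort("`arcs` must contain at least one arc")
  rows <- purrr::imap(arcs, function(spec, k) {
    span <- arc_span(spec)
    if (span == 0) span <- 360        # full rotation (start == stop)
    n_steps <- floor(span / spec$spacing + 1e-9)
    sgn <- if (spec$direction == "CW") 1 else -1
    gantry <- (spec$gantry_start + sgn * spec$spacing * (0:n_steps)) %% 360
    tibble(arc = k, gantry = gantry, couch = spec$couch,
           sad = sad,
           sid = if (spec$couch %% 360 == 0) sid_axial else sid_couch)
  })
  out <- bind_rows(rows)
  out$cp <- seq_len(nrow(out))
  out[, c("cp", "arc", "gantry", "couch", "sad", "sid")]
}

#' Couch angle scale conversion
#'
#' Maps a planning-system (Eclipse/Varian) couch angle to the IEC 61217
#' scale and back; the axial position (Eclipse 0) reads 180 on an IEC
#' display, and Eclipse 45/315 read 135/225.
#'
#' @param couch Couch angle in degrees.
#' @return Angle in degrees on the other scale, in `[0, 360)`.
#' @export
couch_eclipse_to_iec <- function(couch) (180 - couch) %% 360

#' @rdname couch_eclipse_to_iec
#' @export
couch_iec_to_eclipse <- function(couch) (180 - couch) %% 360

#' Imaging geometry of one control point
#'
#' @param gantry Gantry angle in degrees (Varian-IEC scale, 0 = beam
#'   pointing down onto a supine patient).
#' @param couch Couch angle in degrees (planning-system scale, 0 = axial).
#' @param sad Source-axis distance (mm).
#' @param sid Source-imager distance (mm); must exceed `sad`.
#' @return A list of class `beam_geometry`.
#' @export
beam_geometry <- function(gantry, couch = 0, sad = 1000, sid = 1500) {
  if (!(sid > sad && sad > 0)) abort("must have SID > SAD > 0")
  structure(list(gantry = gantry %% 360, couch = couch %% 360,
                 sad = sad, sid = sid),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> gantry %.1f, couch %.1f, SAD %g mm, SID %g mm\n",
              x$gantry, x$couch, x$sad, x$sid))
  invisible(x)
}

as_beam_geometry <- function(x) {
  if (inherits(x, "beam_geometry")) return(x)
  beam_geometry(x$gantry, x$couch, x$sad %||% 1000, x$sid %||% 1500)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Beam's-eye-view orthonormal basis in the room frame
# (lateral, longitudinal, vertical). Chosen so that a room-frame
# displacement o projects to BEV coordinates (o.u, o.v) and the couch-shift
# matrix reconstructs exactly the visible component of o.
bev_basis <- function(geometry) {
  th <- geometry$gantry * pi / 180
  ph <- geometry$couch * pi / 180
  u <- c(cos(th) * cos(ph), cos(th) * sin(ph), sin(th))
  v <- c(-sin(ph), cos(ph), 0)
  w <- c(-sin(th) * cos(ph), -sin(th) * sin(ph), cos(th))  # towards source
  list(u = u, v = v, w = w)
}

#' Project a room-frame point into the beam's-eye-view
#'
#' Perspective projection of a 3D room point onto the detector, rescaled to
#' the isocenter plane (magnification SAD/SID undone), so that the
#' isocenter itself projects to (0, 0) and a point displaced laterally at
#' the isocenter depth projects with unit magnification.
#'
#' @param geometry A [beam_geometry()].
#' @param point Numeric length-3 room coordinates (mm), or an n x 3 matrix.
#' @param isocenter Room position of the isocenter (default origin).
#' @return A tibble with columns `x_mm`, `y_mm` (BEV, isocenter plane).
#' @export
project_point <- function(geometry, point, isocenter = c(0, 0, 0)) {
  geometry <- as_beam_geometry(geometry)
  basis <- bev_basis(geometry)
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  src <- isocenter + geometry$sad * basis$w
  rel <- sweep(p, 2, src)
  depth <- -(rel %*% basis$w)   # distance from source along the beam
  if (any(depth <= 0))
    abort("point lies at or behind the source")
  tibble(x_mm = as.numeric((rel %*% basis$u) * geometry$sad / depth),
         y_mm = as.numeric((rel %*% basis$v) * geometry$sad / depth))
}
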