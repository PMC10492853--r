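#' Parameters of the complex-logarithmic SC motor map
#'
#' The afferent mapping from gaze-shift vectors (amplitude, direction) onto
#' anatomical coordinates of the superior colliculus motor map is a
#' complex-logarithmic transformation with three fixed parameters, calibrated
#' from classical microstimulation data.
#'
#' @param Bu Scale along the rostral-caudal axis (mm). Default 1.4 mm.
#' @param Bv Scale along the medial-lateral axis (mm/rad). Default 1.8 mm/rad.
#' @param A Foveal shift (deg). Default 3.0 deg.
#'
#' @return An object of class `"map_params"`.
#' @seealso [afferent_map()], [efferent_map()]
#' @export
#' @examples
#' map_params()          # standard primate SC map
#' map_params(A = 2.5)
map_params <- function(Bu = 1.4, Bv = 1.8, A = 3.0) {
  stopifnot(is.numeric(Bu), is.numeric(Bv), is.numeric(A),
            length(Bu) == 1L, length(Bv) == 1L, length(A) == 1L)
  if (!(Bu > 0 && Bv > 0 && A > 0))
    stop("map parameters Bu, Bv and A must all be positive")
  structure(list(Bu = Bu, Bv = Bv, A = A), class = "map_params")
}

#' @export
print.map_params <- function(x, ...) {
  cat(sprintf("SC motor map: Bu = %g mm, Bv = %g mm/rad, A = %g deg\n",
              x$Bu, x$Bv, x$A))
  invisible(x)
}

#' Afferent mapping of gaze-shift vectors onto SC map coordinates
#'
#' Projects gaze-shift vectors (amplitude `dG` in deg, direction `phi` in deg)
#' onto the anatomical coordinates (u, v) in mm of the SC motor map, with
#' `u` along the rostral-caudal and `v` along the medial-lateral axis:
#' \deqn{u = B_u \ln(\sqrt{\Delta G^2 + 2 A \Delta G \cos\Phi + A^2} / A)}
#' \deqn{v = B_v \,\mathrm{atan2}(\Delta G \sin\Phi,\; \Delta G \cos\Phi + A)}
#'
#' Directions are given in degrees (0 = horizontal, positive = upward); the
#' medial-lateral scale `Bv` is in mm/rad, and the conversion is internal.
#' The two-argument arctangent preserves the quadrant for directions beyond
#' +/-90 deg, but the map calibration covers the contralateral hemifield, so a
#' warning is issued for |phi| > 90 deg.
#'
#' @param dG Gaze-shift amplitude(s), deg, non-negative.
#' @param phi Gaze-shift direction(s), deg.
#' @param params A [map_params()] object.
#'
#' @return A list with numeric vectors `u` and `v` (mm).
#' @export
#' @examples
#' afferent_map(3, 0)                  # u = 1.4*log(2), v = 0
#' afferent_map(90, 90)                # large oblique vector
afferent_map <- function(dG, phi, params = map_params()) {
  stopifnot(inherits(params, "map_params"))
  if (anyNA(dG) || anyNA(phi)) stop("NA/NaN in gaze vector")
  stopifnot(is.numeric(dG), is.numeric(phi))
  if (any(dG < 0)) stop("gaze amplitude dG must be non-negative")
  if (any(abs(phi) > 90))
    warning("direction(s) beyond +/-90 deg lie outside the calibrated hemifield")
  ph <- phi * pi / 180
  u <- params$Bu * log(sqrt(dG^2 + 2 * params$A * dG * cos(ph) + params$A^2) /
                         params$A)
  v <- params$Bv * atan2(dG * sin(ph), dG * cos(ph) + params$A)
  list(u = u, v = v)
}

#' Efferent mapping of SC map coordinates back to gaze-shift vectors
#'
#' Analytic inverse of [afferent_map()]: converts SC map coordinates (mm) back
#' to the gaze-shift vector they encode. Used to assign the mini spike-vector
#' of each map site when decoding population activity.
#'
#' @param u Rostral-caudal coordinate(s), mm, `u >= 0` (rostral pole at origin).
#' @param v Medial-lateral coordinate(s), mm.
#' @param params A [map_params()] object.
#'
#' @return A list with numeric vectors `dG` (deg) and `phi` (deg).
#' @export
#' @examples
#' efferent_map(1.4 * log(2), 0)   # the 3-deg horizontal vector
efferent_map <- function(u, v, params = map_params()) {
  stopifnot(inherits(params, "map_params"))
  if (anyNA(u) || anyNA(v)) stop("NA/NaN in map coordinates")
  stopifnot(is.numeric(u), is.numeric(v))
  # (u, v) identifies the point z + A = rho*exp(i*theta) in shifted polar form
  rho <- params$A * exp(u / params$Bu)
  theta <- v / params$Bv
  x <- rho * cos(theta) - params$A
  y <- rho * sin(theta)
  dG <- sqrt(x^2 + y^2)
  phi <- ifelse(dG > 0, atan2(y, x), 0) * 180 / pi
  list(dG = dG, phi = phi)
}
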