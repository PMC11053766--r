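#' Dioptric demand of an object at a given distance
#'
#' The vergence an eye must produce to focus an object at \code{distance_m}
#' metres: the reciprocal distance, in diopters.  An object at 0.30 m (reading
#' distance) demands 3.33 D; one at 6 m demands 0.167 D.
#'
#' @param distance_m object distance in metres; must be > 0 (vectorised)
#' @return dioptric demand, D
#' @examples
#' dioptricDemand(c(0.3, 1, 6))
#' @export
dioptricDemand <- function(distance_m) {
  if (any(!is.finite(distance_m)) || any(distance_m <= 0))
    stop("distance must be positive and finite")
  1 / distance_m
}

#' Accommodation achieved by an eye with limited amplitude
#'
#' The eye accommodates optimally within its residual range: it produces the
#' accommodation that minimises defocus, clamped to [0, amplitude].  The
#' accommodation required to null defocus is demand - lens_aid + refraction
#' (a myope needs less accommodation for near, a lens aid substitutes for it).
#' No lag or lead is modelled.
#'
#' @param demand_D object dioptric demand, D (vectorised)
#' @param lens_aid_D optical power of any aiding lens, D
#' @param eye an \linkS4class{EyeModel}
#' @return achieved accommodation, D
#' @examples
#' presbyope <- eyeModel(accommodation_amplitude_D = 0)
#' accommodationResponse(1 / 0.3, 0, presbyope)  # 0: cannot accommodate
#' @export
accommodationResponse <- function(demand_D, lens_aid_D, eye) {
  stopifnot(is(eye, "EyeModel"))
  validObject(eye)
  needed <- demand_D - lens_aid_D + eye@refraction_D
  pmin(pmax(needed, 0), eye@amplitude_D)
}

#' Residual defocus error for an object given lens aid and accommodation
#'
#' Total focusing power brought to bear is lens power plus achieved
#' accommodation minus the far refractive error; the defocus error is the
#' absolute difference from the object's demand.
#'
#' @inheritParams accommodationResponse
#' @return nonnegative defocus error, D
#' @export
defocusError <- function(demand_D, lens_aid_D, eye) {
  acc <- accommodationResponse(demand_D, lens_aid_D, eye)
  total <- lens_aid_D + acc - eye@refraction_D
  abs(demand_D - total)
}

#' Angular diameter of the circle of confusion
#'
#' Thin-lens small-angle relation: a point defocused by \eqn{\Delta D}
#' diopters seen through a pupil of diameter p metres blurs into a disk of
#' angular diameter \eqn{\beta = p \cdot \Delta D} radians.  A 3 mm pupil and
#' 1 D of defocus give 3 mrad (about 10.3 arcmin) of blur.  Exactly linear in
#' both arguments.
#'
#' @param eye an \linkS4class{EyeModel} (pupil diameter is used)
#' @param defocus_D nonnegative defocus error, D (vectorised)
#' @return angular blur-disk diameter, radians
#' @examples
#' cocAngular(eyeModel(pupil_mm = 3), 1)  # 0.003 rad
#' @export
cocAngular <- function(eye, defocus_D) {
  stopifnot(is(eye, "EyeModel"))
  if (any(defocus_D < 0)) stop("defocus error must be nonnegative")
  (eye@pupil_mm / 1000) * defocus_D
}

#' Convert an angular blur diameter to pixels under a pinhole camera
#'
#' Uses the small-angle mapping blur_px = beta * f_px with
#' f_px = (W/2) / tan(FOV/2).
#'
#' @param beta_rad angular diameter, radians
#' @param width_px image width, pixels
#' @param fov_deg horizontal field of view, degrees
#' @return blur diameter in pixels
#' @export
angularToPixels <- function(beta_rad, width_px, fov_deg) {
  beta_rad * focalLengthPx(width_px, fov_deg)
}

#' Read an EyeModel from a config list or YAML/JSON file
#'
#' Recognised keys: \code{pupil_mm}, \code{accommodation_amplitude_D},
#' \code{distance_refraction_D}; missing keys take the constructor defaults.
#'
#' @param config a named list, or the path of a YAML or JSON file
#' @return an \linkS4class{EyeModel}
#' @export
eyeModelFromConfig <- function(config) {
  if (is.character(config)) config <- readConfigFile(config)
  eyeModel(
    pupil_mm = config$pupil_mm %||% 3,
    accommodation_amplitude_D = config$accommodation_amplitude_D %||% 0,
    distance_refraction_D = config$distance_refraction_D %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

readConfigFile <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
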