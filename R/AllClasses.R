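#' @import methods
NULL

#' Eye model for first-order defocus simulation
#'
#' Bundles the physiological parameters that determine how much retinal blur a
#' given focus error produces: the entrance-pupil diameter and the residual
#' accommodation amplitude.  A presbyopic eye is modelled simply by a reduced
#' (possibly zero) amplitude; a refractive error at far is carried as a
#' spherical equivalent in diopters (0 = emmetrope, negative = myope).
#'
#' @slot pupil_mm entrance pupil diameter in millimetres (> 0)
#' @slot amplitude_D residual accommodation amplitude in diopters (>= 0)
#' @slot refraction_D spherical refractive error at far, diopters
#' @export
setClass("EyeModel",
  representation(pupil_mm = "numeric", amplitude_D = "numeric",
                 refraction_D = "numeric"),
  prototype(pupil_mm = 3, amplitude_D = 0, refraction_D = 0))

setValidity("EyeModel", function(object) {
  msg <- character()
  if (length(object@pupil_mm) != 1 || !is.finite(object@pupil_mm) ||
      object@pupil_mm <= 0)
    msg <- c(msg, "pupil_mm must be a single positive finite number")
  if (length(object@amplitude_D) != 1 || !is.finite(object@amplitude_D) ||
      object@amplitude_D < 0)
    msg <- c(msg, "amplitude_D must be a single nonnegative finite number")
  if (length(object@refraction_D) != 1 || !is.finite(object@refraction_D))
    msg <- c(msg, "refraction_D must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct an EyeModel
#'
#' @param pupil_mm pupil diameter, mm
#' @param accommodation_amplitude_D residual accommodation amplitude, D
#' @param distance_refraction_D spherical refractive error at far, D
#' @return an \linkS4class{EyeModel}
#' @examples
#' presbyope <- eyeModel(pupil_mm = 3, accommodation_amplitude_D = 0)
#' @export
eyeModel <- function(pupil_mm = 3, accommodation_amplitude_D = 0,
                     distance_refraction_D = 0) {
  new("EyeModel", pupil_mm = pupil_mm, amplitude_D = accommodation_amplitude_D,
      refraction_D = distance_refraction_D)
}

#' A physical screen placed in the simulated office
#'
#' @slot distance_m viewing distance along the optical axis, metres (> 0)
#' @slot azimuth_deg,elevation_deg angular position of the screen centre,
#'   degrees; elevation positive upward
#' @slot width_m,height_m physical extent, metres
#' @slot label one of "near", "intermediate", "far" (free-form allowed)
#' @export
setClass("ScreenSpec",
  representation(distance_m = "numeric", azimuth_deg = "numeric",
                 elevation_deg = "numeric", width_m = "numeric",
                 height_m = "numeric", label = "character"))

setValidity("ScreenSpec", function(object) {
  if (object@distance_m <= 0) return("distance_m must be > 0")
  if (object@width_m <= 0 || object@height_m <= 0)
    return("screen physical size must be positive")
  TRUE
})

#' Construct a ScreenSpec
#' @param distance_m viewing distance, m
#' @param azimuth_deg,elevation_deg angular position of the centre, degrees
#' @param width_m,height_m physical size, m
#' @param label screen label
#' @return a \linkS4class{ScreenSpec}
#' @export
screenSpec <- function(distance_m, azimuth_deg = 0, elevation_deg = 0,
                       width_m = 0.5, height_m = 0.3, label = "screen") {
  new("ScreenSpec", distance_m = distance_m, azimuth_deg = azimuth_deg,
      elevation_deg = elevation_deg, width_m = width_m, height_m = height_m,
      label = label)
}

#' RGB-D scene: colour raster plus co-registered metric depth
#'
#' The substrate of the blur simulation.  Colour values live in [0, 1]; depth
#' is metres along the viewing axis, strictly positive and finite everywhere.
#' The camera is a pinhole with the image centre on the optical axis and a
#' stated horizontal field of view.
#'
#' @slot rgb numeric array H x W x 3, values in [0, 1]
#' @slot depth numeric matrix H x W, metres, all finite and > 0
#' @slot fov_deg horizontal field of view, degrees
#' @slot metadata free-form list (e.g. screen layout of an office scene)
#' @export
setClass("RGBDScene",
  representation(rgb = "array", depth = "matrix", fov_deg = "numeric",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("RGBDScene", function(object) {
  msg <- character()
  d <- dim(object@rgb)
  if (length(d) != 3 || d[3] != 3)
    msg <- c(msg, "rgb must be an H x W x 3 array")
  else if (!identical(d[1:2], dim(object@depth)))
    msg <- c(msg, "rgb and depth must have identical spatial dimensions")
  if (any(!is.finite(object@depth)) || any(object@depth <= 0))
    msg <- c(msg, "every depth value must be finite and > 0")
  if (any(!is.finite(object@rgb)) || any(object@rgb < 0) ||
      any(object@rgb > 1))
    msg <- c(msg, "rgb values must lie in [0, 1]")
  if (length(object@fov_deg) != 1 || object@fov_deg <= 0 ||
      object@fov_deg >= 180)
    msg <- c(msg, "fov_deg must lie in (0, 180)")
  if (length(msg)) msg else TRUE
})

#' Construct an RGBDScene
#' @param rgb H x W x 3 array in [0, 1]
#' @param depth H x W matrix of metric depth
#' @param fov_deg horizontal field of view, degrees
#' @param metadata free-form list
#' @return an \linkS4class{RGBDScene}
#' @export
rgbdScene <- function(rgb, depth, fov_deg = 90, metadata = list()) {
  new("RGBDScene", rgb = rgb, depth = depth, fov_deg = fov_deg,
      metadata = metadata)
}

#' Focus-tunable lens with transport delay and slew-rate limit
#'
#' State of a simulated focus-tunable (autofocal) lens.  Commands enter a
#' queue and become effective after a fixed transport \code{delay_s}; the
#' realised power then tracks the effective command at no more than
#' \code{rate_D_s} diopters per second, settling exactly on the (range
#' clamped) command with no overshoot.
#'
#' @slot power_min_D,power_max_D optical power range, D
#' @slot rate_D_s slew-rate limit, D/s (may be Inf for an ideal lens)
#' @slot delay_s transport delay before a command takes effect, seconds
#' @slot power_D current realised optical power, D
#' @slot time_s current simulation time, seconds
#' @slot queue data.frame of pending commands (t_s, command_D)
#' @export
setClass("TunableLens",
  representation(power_min_D = "numeric", power_max_D = "numeric",
                 rate_D_s = "numeric", delay_s = "numeric",
                 power_D = "numeric", time_s = "numeric",
                 queue = "data.frame"),
  prototype(queue = data.frame(t_s = numeric(), command_D = numeric()),
            time_s = 0))

setValidity("TunableLens", function(object) {
  msg <- character()
  if (object@power_min_D > object@power_max_D)
    msg <- c(msg, "power_min_D must not exceed power_max_D")
  if (object@power_D < object@power_min_D - 1e-9 ||
      object@power_D > object@power_max_D + 1e-9)
    msg <- c(msg, "current power must lie within [power_min_D, power_max_D]")
  if (object@rate_D_s <= 0) msg <- c(msg, "rate_D_s must be > 0")
  if (object@delay_s < 0) msg <- c(msg, "delay_s must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TunableLens
#' @param power_min_D,power_max_D optical power range, D
#' @param rate_D_s slew-rate limit, D/s; Inf gives an ideal (instant) lens
#' @param delay_s transport delay, s
#' @param power_D initial power, D
#' @return a \linkS4class{TunableLens}
#' @examples
#' lens <- tunableLens(rate_D_s = 10, delay_s = 0.05)
#' @export
tunableLens <- function(power_min_D = 0, power_max_D = 4, rate_D_s = Inf,
                        delay_s = 0, power_D = 0) {
  new("TunableLens", power_min_D = power_min_D, power_max_D = power_max_D,
      rate_D_s = rate_D_s, delay_s = delay_s, power_D = power_D, time_s = 0,
      queue = data.frame(t_s = numeric(), command_D = numeric()))
}

#' Progressive-addition lens power map
#'
#' Distance power in the upper visual field, distance + add power in the lower
#' field, with a linear power corridor between the two corridor elevations.
#'
#' @slot distance_power_D distance-zone power, D
#' @slot add_power_D near addition, D
#' @slot corridor_deg numeric length-2: c(elevation_far, elevation_near)
#'   degrees, elevation_far > elevation_near (far zone is the upper field)
#' @export
setClass("ProgressiveLensMap",
  representation(distance_power_D = "numeric", add_power_D = "numeric",
                 corridor_deg = "numeric"))

setValidity("ProgressiveLensMap", function(object) {
  if (length(object@corridor_deg) != 2)
    return("corridor_deg must have length 2: c(elevation_far, elevation_near)")
  if (object@corridor_deg[1] <= object@corridor_deg[2])
    return("elevation_far must be greater than elevation_near")
  TRUE
})

#' Construct a ProgressiveLensMap
#' @param distance_power_D distance-zone power, D
#' @param add_power_D near addition, D
#' @param corridor_deg c(elevation_far, elevation_near), degrees
#' @return a \linkS4class{ProgressiveLensMap}
#' @export
progressiveLensMap <- function(distance_power_D = 0, add_power_D = 2.5,
                               corridor_deg = c(5, -15)) {
  new("ProgressiveLensMap", distance_power_D = distance_power_D,
      add_power_D = add_power_D, corridor_deg = corridor_deg)
}

#' Controller state for gaze-driven focus policies
#'
#' @slot policy one of "gaze_point", "depth_mode", "manual"
#' @slot window_n smoothing window length in samples (>= 1)
#' @slot foveal_radius_deg foveal pooling radius for the depth-mode policy
#' @slot events data.frame (t_s, command_D) for the manual policy
#' @slot history recent raw commands (most recent last), used for smoothing
#' @slot last_command_D last emitted command, D
#' @export
setClass("ControllerState",
  representation(policy = "character", window_n = "numeric",
                 foveal_radius_deg = "numeric", events = "data.frame",
                 history = "numeric", last_command_D = "numeric"),
  prototype(window_n = 1, foveal_radius_deg = 2,
            events = data.frame(t_s = numeric(), command_D = numeric()),
            history = numeric(), last_command_D = 0))

setValidity("ControllerState", function(object) {
  if (object@window_n < 1) return("smoothing window must be >= 1")
  if (!object@policy %in% c("gaze_point", "depth_mode", "manual"))
    return("policy must be one of gaze_point, depth_mode, manual")
  TRUE
})

#' Construct a ControllerState
#' @param policy "gaze_point", "depth_mode" or "manual"
#' @param window_n smoothing window, samples
#' @param foveal_radius_deg pooling radius for depth_mode, degrees
#' @param events manual-policy events: data.frame(t_s, command_D), time-ordered
#' @param initial_command_D command before any input, D
#' @return a \linkS4class{ControllerState}
#' @export
controllerState <- function(policy = "gaze_point", window_n = 1,
                            foveal_radius_deg = 2,
                            events = data.frame(t_s = numeric(),
                                                command_D = numeric()),
                            initial_command_D = 0) {
  if (nrow(events) > 1 && is.unsorted(events$t_s, strictly = FALSE))
    stop("manual controller events must be time-ordered")
  new("ControllerState", policy = policy, window_n = window_n,
      foveal_radius_deg = foveal_radius_deg, events = events,
      history = numeric(), last_command_D = initial_command_D)
}

#' Blur-dependent observer model for the matching task
#'
#' Synthetic observer used to exercise the matching task without human
#' subjects.  Each optotype is identified correctly with probability
#' \deqn{p = 1/8 + 7/8 \cdot \mathrm{logistic}(-s (\log r - \log r_{50}))}
#' where r is the ratio of blur-disk diameter to optotype gap size, s the
#' psychometric slope and r_50 the threshold ratio at which p is halfway
#' between chance (1/8) and ceiling.  Table-column lookup is errorless once
#' both optotypes are identified; the match response follows the identified
#' pair.
#'
#' @slot slope psychometric slope on the log blur/gap axis
#' @slot threshold_ratio blur/gap ratio at the psychometric midpoint
#' @slot chance identification chance level (1/8 for 8 alternatives)
#' @export
setClass("ObserverModel",
  representation(slope = "numeric", threshold_ratio = "numeric",
                 chance = "numeric"),
  prototype(slope = 4, threshold_ratio = 1, chance = 1 / 8))

setValidity("ObserverModel", function(object) {
  if (object@slope <= 0) return("slope must be > 0")
  if (object@threshold_ratio <= 0) return("threshold_ratio must be > 0")
  if (object@chance <= 0 || object@chance >= 1)
    return("chance must lie in (0, 1)")
  TRUE
})

#' Construct an ObserverModel
#' @param slope psychometric slope (log blur/gap axis)
#' @param threshold_ratio blur/gap ratio at the halfway point
#' @return an \linkS4class{ObserverModel}
#' @export
observerModel <- function(slope = 4, threshold_ratio = 1) {
  new("ObserverModel", slope = slope, threshold_ratio = threshold_ratio,
      chance = 1 / 8)
}

#' One matching-task trial
#'
#' A Landolt ring (one of 8 orientations) and a Sloan letter (one of 8) are
#' shown on two of the three screens; the third screen carries an 8-column
#' table pairing orientations with letters.  The trial is a match iff the
#' presented (orientation, letter) pair occupies a single table column.
#'
#' @slot id trial identifier
#' @slot orientation presented Landolt gap direction (compass point)
#' @slot letter presented Sloan letter
#' @slot screens named character: which screen label hosts landolt / sloan /
#'   table (a permutation of near, intermediate, far)
#' @slot table_orientations,table_letters the 8 table columns
#' @slot is_match logical
#' @slot placement named character ("center" or "corner") per stimulus
#' @slot gap_arcmin Landolt gap angular size, arcmin
#' @export
setClass("Trial",
  representation(id = "integer", orientation = "character",
                 letter = "character", screens = "character",
                 table_orientations = "character", table_letters = "character",
                 is_match = "logical", placement = "character",
                 gap_arcmin = "numeric"))

setValidity("Trial", function(object) {
  msg <- character()
  if (!setequal(names(object@screens), c("landolt", "sloan", "table")) ||
      anyDuplicated(object@screens))
    msg <- c(msg, "screens must assign landolt, sloan, table to distinct screens")
  if (length(object@table_orientations) != 8 ||
      anyDuplicated(object@table_orientations))
    msg <- c(msg, "table must have 8 columns covering all orientations once")
  if (length(object@table_letters) != 8)
    msg <- c(msg, "table must pair 8 letters")
  in_table <- any(object@table_orientations == object@orientation &
                  object@table_letters == object@letter)
  if (!identical(in_table, object@is_match))
    msg <- c(msg, "is_match must equal presence of the pair as a table column")
  if (length(msg)) msg else TRUE
})

#' Device/sampling state of the gaze recorder
#'
#' Mirrors a device-agnostic eye-tracker control surface: the device and the
#' sampling thread are started and stopped separately, and sampling requires a
#' started device.
#'
#' @slot device "stopped" or "started"
#' @slot sampling "stopped" or "sampling"
#' @slot rate_hz sampling rate, Hz
#' @slot folder output folder for gaze files
#' @export
setClass("GazeRecorder",
  representation(device = "character", sampling = "character",
                 rate_hz = "numeric", folder = "character"),
  prototype(device = "stopped", sampling = "stopped", rate_hz = 120,
            folder = "."))

setValidity("GazeRecorder", function(object) {
  if (object@sampling == "sampling" && object@device != "started")
    return("sampling requires a started device")
  TRUE
})

#' Construct a GazeRecorder
#' @param rate_hz sampling rate, Hz
#' @param folder output folder for gaze files
#' @return a \linkS4class{GazeRecorder} in the all-stopped state
#' @export
gazeRecorder <- function(rate_hz = 120, folder = ".") {
  new("GazeRecorder", device = "stopped", sampling = "stopped",
      rate_hz = rate_hz, folder = folder)
}

#' An experiment protocol: an ordered, parameterized scene list
#'
#' @slot name protocol name (unique within a pool)
#' @slot scenes data.frame with columns id (scene identifier) and param
#'   (parameter string; "0" means no extra configuration)
#' @export
setClass("Protocol",
  representation(name = "character", scenes = "data.frame"))

setValidity("Protocol", function(object) {
  if (nrow(object@scenes) == 0) return("protocol scene list must be nonempty")
  if (!all(c("id", "param") %in% names(object@scenes)))
    return("scenes must have columns id and param")
  TRUE
})

#' A questionnaire definition loaded from JSON
#'
#' @slot abbreviation short name used in protocol parameters (e.g. "TLX")
#' @slot items data.frame: id, prompt, scale_min, scale_max, low_label,
#'   high_label, in file order
#' @export
setClass("Questionnaire",
  representation(abbreviation = "character", items = "data.frame"))

setValidity("Questionnaire", function(object) {
  if (anyDuplicated(object@items$id)) return("item ids must be unique")
  TRUE
})
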