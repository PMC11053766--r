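#' @describeIn RGBDScene-class colour raster accessor
#' @param object,x an object
#' @export
setGeneric("rgbRaster", function(x) standardGeneric("rgbRaster"))

#' @describeIn RGBDScene-class depth map accessor (metres)
#' @export
setGeneric("depthMap", function(x) standardGeneric("depthMap"))

#' @describeIn RGBDScene-class horizontal field of view, degrees
#' @export
setGeneric("fieldOfView", function(x) standardGeneric("fieldOfView"))

#' @describeIn RGBDScene-class image width in pixels
#' @export
setGeneric("sceneWidth", function(x) standardGeneric("sceneWidth"))

#' @describeIn RGBDScene-class image height in pixels
#' @export
setGeneric("sceneHeight", function(x) standardGeneric("sceneHeight"))

#' @describeIn TunableLens-class current realised optical power, D
#' @export
setGeneric("currentPower", function(x) standardGeneric("currentPower"))

#' @export
#' @describeIn EyeModel-class pupil diameter accessor, mm
setGeneric("pupilDiameter", function(x) standardGeneric("pupilDiameter"))

setMethod("rgbRaster", "RGBDScene", function(x) x@rgb)
setMethod("depthMap", "RGBDScene", function(x) x@depth)
setMethod("fieldOfView", "RGBDScene", function(x) x@fov_deg)
setMethod("sceneWidth", "RGBDScene", function(x) dim(x@depth)[2])
setMethod("sceneHeight", "RGBDScene", function(x) dim(x@depth)[1])
setMethod("currentPower", "TunableLens", function(x) x@power_D)
setMethod("pupilDiameter", "EyeModel", function(x) x@pupil_mm)

setMethod("show", "EyeModel", function(object) {
  cat("EyeModel: pupil", object@pupil_mm, "mm, accommodation amplitude",
      object@amplitude_D, "D, far refraction", object@refraction_D, "D\n")
})

setMethod("show", "RGBDScene", function(object) {
  d <- dim(object@depth)
  cat(sprintf("RGBDScene %d x %d px, FOV %g deg, depth %.3g-%.3g m\n",
              d[2], d[1], object@fov_deg, min(object@depth),
              max(object@depth)))
  if (length(object@metadata$screens))
    cat("  screens:",
        paste(vapply(object@metadata$screens, function(s)
          sprintf("%s@%gm", s@label, s@distance_m), character(1)),
          collapse = ", "), "\n")
})

setMethod("show", "TunableLens", function(object) {
  cat(sprintf(
    "TunableLens: power %.3f D in [%g, %g], rate %g D/s, delay %g s, t=%.3f s\n",
    object@power_D, object@power_min_D, object@power_max_D, object@rate_D_s,
    object@delay_s, object@time_s))
})

setMethod("show", "Trial", function(object) {
  cat(sprintf(
    "Trial %d: Landolt %s on %s, Sloan %s on %s, table on %s (%s)\n",
    object@id, object@orientation, object@screens[["landolt"]],
    object@letter, object@screens[["sloan"]], object@screens[["table"]],
    if (object@is_match) "match" else "no match"))
})

setMethod("show", "Protocol", function(object) {
  cat(sprintf("Protocol '%s': %d scenes\n", object@name, nrow(object@scenes)))
  for (i in seq_len(nrow(object@scenes)))
    cat(sprintf("  %2d. %s [%s]\n", i, object@scenes$id[i],
                object@scenes$param[i]))
})

setMethod("show", "GazeRecorder", function(object) {
  cat(sprintf("GazeRecorder: device %s, sampling %s, %g Hz -> %s\n",
              object@device, object@sampling, object@rate_hz, object@folder))
})
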