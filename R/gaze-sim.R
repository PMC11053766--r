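#' Simulate a gaze trace over a scene (fixations, saccades, noise)
#'
#' Generates the synthetic stand-in for hardware eye-tracking: the gaze
#' fixates each scheduled target in turn for its dwell time, with isotropic
#' Gaussian angular noise on fixation samples, and sweeps linearly (in visual
#' angle) between consecutive targets during saccades, which are labelled as
#' such and carry no noise.  Deterministic given the seed.
#'
#' @param schedule data.frame with columns x_px, y_px, dwell_s (one row per
#'   fixation target, in order); dwell_s must be positive
#' @param scene an \linkS4class{RGBDScene}, supplies the camera geometry
#' @param rate_hz sampling rate, Hz (> 0)
#' @param noise_sd_deg fixation noise SD per angular component, degrees
#' @param saccade_duration_s duration of each inter-target saccade, s
#' @param pupil_mm pupil diameter written into every sample
#' @param seed RNG seed; NULL uses the current RNG state
#' @param t0_s timestamp of the first sample
#' @return data.frame with columns timestamp_s, gaze_x_px, gaze_y_px,
#'   azimuth_deg, elevation_deg, pupil_mm, validity, label
#' @export
simulateGazeTrace <- function(schedule, scene, rate_hz = 120,
                              noise_sd_deg = 0.3, saccade_duration_s = 0.04,
                              pupil_mm = 4, seed = NULL, t0_s = 0) {
  if (is.null(schedule) || nrow(schedule) == 0) stop("schedule is empty")
  if (any(schedule$dwell_s <= 0)) stop("dwell times must be positive")
  if (rate_hz <= 0) stop("sampling rate must be positive")
  W <- ncol(scene@depth); H <- nrow(scene@depth)
  nseg <- nrow(schedule)
  ang <- pixelToAngle(schedule$x_px, schedule$y_px, W, H, scene@fov_deg)
  # segments alternate fixation(i), saccade(i->i+1); no saccade after last
  seg_dur <- as.vector(rbind(schedule$dwell_s,
                             c(rep(saccade_duration_s, max(nseg - 1, 0)), 0)))
  seg_dur <- seg_dur[-length(seg_dur)]
  starts <- cumsum(c(0, seg_dur[-length(seg_dur)]))
  total <- sum(seg_dur)
  n <- round(total * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  seg <- findInterval(t, starts)
  withSeed(seed, {
    az <- numeric(n); el <- numeric(n); lab <- character(n)
    for (s in unique(seg)) {
      idx <- which(seg == s)
      fix_i <- (s + 1) %/% 2
      if (s %% 2 == 1) {                       # fixation on target fix_i
        az[idx] <- ang$azimuth_deg[fix_i] +
          stats::rnorm(length(idx), 0, noise_sd_deg)
        el[idx] <- ang$elevation_deg[fix_i] +
          stats::rnorm(length(idx), 0, noise_sd_deg)
        lab[idx] <- "fixation"
      } else {                                 # saccade fix_i -> fix_i + 1
        frac <- (t[idx] - starts[s]) / seg_dur[s]
        az[idx] <- ang$azimuth_deg[fix_i] +
          frac * (ang$azimuth_deg[fix_i + 1] - ang$azimuth_deg[fix_i])
        el[idx] <- ang$elevation_deg[fix_i] +
          frac * (ang$elevation_deg[fix_i + 1] - ang$elevation_deg[fix_i])
        lab[idx] <- "saccade"
      }
    }
    px <- angleToPixel(az, el, W, H, scene@fov_deg)
    data.frame(timestamp_s = t0_s + t,
               gaze_x_px = px$x_px, gaze_y_px = px$y_px,
               azimuth_deg = az, elevation_deg = el,
               pupil_mm = pupil_mm, validity = TRUE, label = lab,
               stringsAsFactors = FALSE)
  })
}

.gazeHeader <- c("timestamp_s", "gaze_x_px", "gaze_y_px", "azimuth_deg",
                 "elevation_deg", "pupil_mm", "validity", "label")

#' Write a gaze trace in the generic gaze CSV format
#'
#' Fixed canonical header (timestamp_s, gaze_x_px, gaze_y_px, azimuth_deg,
#' elevation_deg, pupil_mm, validity, label), comma separated, '.' decimal;
#' the filename carries a system timestamp, so repeated writes in one session
#' yield distinct files and never overwrite.
#'
#' @param trace a gaze trace data.frame
#' @param folder output folder (created if missing)
#' @param session_id optional tag inserted into the filename
#' @return the path written
#' @export
writeGazeFile <- function(trace, folder, session_id = NULL) {
  stopifnot(all(.gazeHeader %in% names(trace)))
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  prefix <- if (is.null(session_id)) "gaze" else paste0("gaze_", session_id)
  path <- timestampedPath(folder, prefix)
  utils::write.csv(trace[, .gazeHeader], path, row.names = FALSE)
  path
}

#' Read a gaze trace from the generic gaze CSV format
#'
#' Validates the canonical header and that timestamps increase strictly.
#'
#' @param path CSV path
#' @return gaze trace data.frame
#' @export
readGazeFile <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(tr), .gazeHeader))
    stop("malformed gaze file header: ", paste(names(tr), collapse = ","))
  if (nrow(tr) > 1 && any(diff(tr$timestamp_s) <= 0))
    stop("gaze timestamps must be strictly increasing")
  tr
}

#' Drive the gaze recorder state machine
#'
#' The device and the sampling thread are controlled separately; sampling can
#' only start on a started device, and stopping the device cascades to stop
#' sampling.
#'
#' @param recorder a \linkS4class{GazeRecorder}
#' @param action one of "start_device", "stop_device", "start_sampling",
#'   "stop_sampling"
#' @return the updated \linkS4class{GazeRecorder}
#' @export
recorderControl <- function(recorder,
                            action = c("start_device", "stop_device",
                                       "start_sampling", "stop_sampling")) {
  stopifnot(is(recorder, "GazeRecorder"))
  action <- match.arg(action)
  switch(action,
    start_device = { recorder@device <- "started" },
    stop_device = {
      recorder@device <- "stopped"
      recorder@sampling <- "stopped"   # cascade
    },
    start_sampling = {
      if (recorder@device != "started")
        stop("cannot start sampling: device is stopped")
      recorder@sampling <- "sampling"
    },
    stop_sampling = { recorder@sampling <- "stopped" })
  validObject(recorder)
  recorder
}
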