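#' Matching-task configuration
#'
#' @param gap_arcmin Landolt gap angular size, arcmin (glyph diameter is five
#'   gaps; Sloan letters share the glyph size)
#' @param screen_labels the three screen labels hosting the stimuli
#' @param placement_jitter_frac SD of the Gaussian placement jitter, as a
#'   fraction of the screen rectangle extent
#' @return a list of task parameters
#' @export
taskConfig <- function(gap_arcmin = 10,
                       screen_labels = c("near", "intermediate", "far"),
                       placement_jitter_frac = 0.05) {
  list(gap_arcmin = gap_arcmin, screen_labels = screen_labels,
       placement_jitter_frac = placement_jitter_frac)
}

#' Generate one randomized matching-task trial
#'
#' The table screen is uniform over the three screens (so subjects cannot
#' follow a fixed fixation order); the remaining two screens host the Landolt
#' ring and the Sloan letter in random order.  The presented orientation is
#' uniform over the 8 compass directions; match trials occur with probability
#' 1/2.  The table pairs a permutation of the 8 orientations with a
#' permutation of the 8 letters; on match trials the presented pair is one of
#' its columns, on non-match trials the pair is guaranteed absent.
#'
#' @param id trial id
#' @param config from \code{\link{taskConfig}}
#' @param seed optional RNG seed (NULL draws from the current RNG stream)
#' @return a \linkS4class{Trial}
#' @export
generateTrial <- function(id = 1L, config = taskConfig(), seed = NULL) {
  withSeed(seed, {
    labels <- config$screen_labels
    table_screen <- sample(labels, 1)
    rest <- sample(setdiff(labels, table_screen))
    screens <- c(landolt = rest[1], sloan = rest[2], table = table_screen)
    tab_or <- sample(landoltOrientations())
    tab_le <- sample(sloanLetters())
    is_match <- stats::runif(1) < 0.5
    orientation <- sample(landoltOrientations(), 1)
    col <- which(tab_or == orientation)
    letter <- if (is_match) tab_le[col]
              else sample(tab_le[-col], 1)
    placement <- c(landolt = sample(c("center", "corner"), 1),
                   sloan = sample(c("center", "corner"), 1),
                   table = "center")
    new("Trial", id = as.integer(id), orientation = orientation,
        letter = letter, screens = screens, table_orientations = tab_or,
        table_letters = tab_le, is_match = is_match, placement = placement,
        gap_arcmin = config$gap_arcmin)
  })
}

# Anchor (top-left) of a glyph of size gs inside rect at the trial placement,
# with Gaussian jitter (sd = frac of rect extent), clamped to containment.
glyphAnchor <- function(rect, gs, placement, jitter_frac) {
  rw <- rect$x1 - rect$x0 + 1
  rh <- rect$y1 - rect$y0 + 1
  if (gs > rw || gs > rh) stop("stimulus exceeds screen bounds")
  base <- if (placement == "center") {
    c(x = rect$x0 + floor((rw - gs) / 2), y = rect$y0 + floor((rh - gs) / 2))
  } else {
    corner <- sample(1:4, 1)
    switch(corner,
      c(x = rect$x0, y = rect$y0),
      c(x = rect$x1 - gs + 1, y = rect$y0),
      c(x = rect$x0, y = rect$y1 - gs + 1),
      c(x = rect$x1 - gs + 1, y = rect$y1 - gs + 1))
  }
  jx <- round(stats::rnorm(1, 0, jitter_frac * rw))
  jy <- round(stats::rnorm(1, 0, jitter_frac * rh))
  x <- min(max(base["x"] + jx, rect$x0), rect$x1 - gs + 1)
  y <- min(max(base["y"] + jy, rect$y0), rect$y1 - gs + 1)
  c(x = unname(x), y = unname(y))
}

#' Render a trial's optotypes onto an office scene
#'
#' Draws the Landolt ring, the Sloan letter and the 8-column matching table
#' onto their assigned screens.  Glyphs are sized in visual angle (the
#' configured gap subtends the same angle on every screen, so physical size
#' scales with distance automatically under the pinhole model) and placed at
#' the trial's center/corner anchors with Gaussian jitter.
#'
#' @param scene an office \linkS4class{RGBDScene} from
#'   \code{\link{makeOfficeScene}} (must carry screen metadata)
#' @param trial a \linkS4class{Trial}
#' @param config from \code{\link{taskConfig}}
#' @param seed optional RNG seed for placement jitter
#' @return the scene with stimuli stamped into its rgb raster; glyph
#'   positions are recorded in \code{metadata()$stimuli}
#' @export
placeStimuli <- function(scene, trial, config = taskConfig(), seed = NULL) {
  rects <- scene@metadata$rects
  if (is.null(rects)) stop("scene carries no screen layout metadata")
  withSeed(seed, {
    f <- focalLengthPx(ncol(scene@depth), scene@fov_deg)
    gap_rad <- trial@gap_arcmin / 60 * pi / 180
    gs <- max(5L, as.integer(round(5 * gap_rad * f)))  # glyph = 5 gaps
    rgb <- scene@rgb
    stim <- list()
    # Landolt ring
    r <- rects[[trial@screens[["landolt"]]]]
    a <- glyphAnchor(r, gs, trial@placement[["landolt"]],
                     config$placement_jitter_frac)
    rgb <- stampGlyph(rgb, landoltRaster(gs, trial@orientation), a["y"],
                      a["x"])
    stim$landolt <- c(a, size = gs)
    # Sloan letter
    r <- rects[[trial@screens[["sloan"]]]]
    a <- glyphAnchor(r, gs, trial@placement[["sloan"]],
                     config$placement_jitter_frac)
    rgb <- stampGlyph(rgb, sloanRaster(trial@letter, gs), a["y"], a["x"])
    stim$sloan <- c(a, size = gs)
    # 8-column table: Landolt row above Sloan row
    r <- rects[[trial@screens[["table"]]]]
    rw <- r$x1 - r$x0 + 1; rh <- r$y1 - r$y0 + 1
    cell <- max(3L, min(floor(rw / 8), floor(rh / 2)))
    if (8 * cell > rw || 2 * cell > rh) stop("stimulus exceeds screen bounds")
    x0 <- r$x0 + floor((rw - 8 * cell) / 2)
    y0 <- r$y0 + floor((rh - 2 * cell) / 2)
    for (j in 1:8) {
      rgb <- stampGlyph(rgb, landoltRaster(cell, trial@table_orientations[j]),
                        y0, x0 + (j - 1) * cell)
      rgb <- stampGlyph(rgb, sloanRaster(trial@table_letters[j], cell),
                        y0 + cell, x0 + (j - 1) * cell)
    }
    stim$table <- c(x = x0, y = y0, size = cell)
    out <- scene
    out@rgb <- rgb
    out@metadata$stimuli <- stim
    out
  })
}

identificationProbability <- function(observer, blur_over_gap) {
  p <- ifelse(blur_over_gap <= 0, 1,
              observer@chance + (1 - observer@chance) *
                stats::plogis(-observer@slope *
                                (log(blur_over_gap) -
                                   log(observer@threshold_ratio))))
  p
}

#' Simulate the observer's response to one trial
#'
#' Each optotype is identified correctly with the observer's psychometric
#' probability at its blur/gap ratio, otherwise confused uniformly with the
#' 7 alternatives.  Table lookup is errorless once both are identified: the
#' answer is "match" iff the identified pair occupies a table column.
#' Reaction time is base 0.8 s plus 0.4 s per focus shift exceeding 1 D,
#' with multiplicative lognormal jitter (sigma 0.15).
#'
#' @param trial a \linkS4class{Trial}
#' @param observer an \linkS4class{ObserverModel}
#' @param blur_arcmin named numeric: blur-disk angular diameters (arcmin) at
#'   the landolt and sloan stimuli (names "landolt", "sloan")
#' @param n_refocus number of focus shifts exceeding 1 D during the trial
#' @param onset_s trial onset timestamp
#' @param defocus_D optional named numeric of per-screen defocus (logged)
#' @param seed optional RNG seed
#' @return one-row data.frame: trial_id, onset_s, rt_s, answer, correct,
#'   identified_orientation, identified_letter, defocus_near_D,
#'   defocus_mid_D, defocus_far_D
#' @export
observeAndRespond <- function(trial, observer, blur_arcmin,
                              n_refocus = 2, onset_s = 0,
                              defocus_D = c(near = NA_real_, mid = NA_real_,
                                            far = NA_real_),
                              seed = NULL) {
  stopifnot(is(trial, "Trial"), is(observer, "ObserverModel"))
  if (any(blur_arcmin < 0)) stop("blur values must be nonnegative")
  withSeed(seed, {
    gap <- trial@gap_arcmin
    p_l <- identificationProbability(observer,
                                     blur_arcmin[["landolt"]] / gap)
    p_s <- identificationProbability(observer, blur_arcmin[["sloan"]] / gap)
    ident_or <- if (stats::runif(1) < p_l) trial@orientation
      else sample(setdiff(landoltOrientations(), trial@orientation), 1)
    ident_le <- if (stats::runif(1) < p_s) trial@letter
      else sample(setdiff(sloanLetters(), trial@letter), 1)
    answer_match <- any(trial@table_orientations == ident_or &
                          trial@table_letters == ident_le)
    rt <- (0.8 + 0.4 * n_refocus) * exp(stats::rnorm(1, 0, 0.15))
    data.frame(trial_id = trial@id, onset_s = onset_s, rt_s = rt,
               answer = if (answer_match) "match" else "no-match",
               correct = identical(answer_match, trial@is_match),
               identified_orientation = ident_or,
               identified_letter = ident_le,
               defocus_near_D = defocus_D[["near"]],
               defocus_mid_D = defocus_D[["mid"]],
               defocus_far_D = defocus_D[["far"]],
               stringsAsFactors = FALSE)
  })
}

#' Run a block of matching-task trials through the full simulation loop
#'
#' Per trial: generate a randomized trial, render its stimuli onto the office
#' scene, simulate gaze visiting the Landolt, Sloan and table screens, run
#' the closed-loop lens controller over the gaze trace, evaluate the defocus
#' blur at each stimulus at its fixation time, and score the observer's
#' response.  Lens and controller state persist across trials.
#'
#' @param n_trials number of trials (>= 1)
#' @param scene office \linkS4class{RGBDScene} with screen metadata
#' @param eye an \linkS4class{EyeModel}
#' @param lens a \linkS4class{TunableLens}
#' @param state a \linkS4class{ControllerState} (or NULL for a lens held at
#'   its initial power via the manual policy with no events)
#' @param observer an \linkS4class{ObserverModel}
#' @param seed RNG seed for the whole block
#' @param config from \code{\link{taskConfig}}
#' @param dwell_s fixation dwell per screen, s
#' @param rate_hz gaze sampling rate, Hz
#' @param dt_s closed-loop step, s
#' @param noise_sd_deg gaze fixation noise, degrees
#' @param out_dir optional folder: writes timestamped gaze, tuning and
#'   response CSV logs
#' @param render if FALSE, skip rasterising the optotypes (the observer uses
#'   defocus directly; much faster for large blocks)
#' @return list(accuracy, mean_rt_s, records, tuning) where records is the
#'   per-trial data.frame
#' @export
runBlock <- function(n_trials, scene, eye, lens, state, observer,
                     seed = 1, config = taskConfig(), dwell_s = 0.5,
                     rate_hz = 60, dt_s = 1 / 60, noise_sd_deg = 0.2,
                     out_dir = NULL, render = TRUE) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  rects <- scene@metadata$rects
  if (is.null(rects)) stop("scene carries no screen layout metadata")
  if (is.null(state))
    state <- controllerState("manual", initial_command_D = lens@power_D)
  records <- vector("list", n_trials)
  tuning <- vector("list", n_trials)
  gazes <- vector("list", n_trials)
  label_of <- c(near = "near", intermediate = "mid", far = "far")
  withSeed(seed, {
    t_clock <- 0
    for (i in seq_len(n_trials)) {
      trial <- generateTrial(i, config)
      sc <- if (render) placeStimuli(scene, trial, config) else scene
      visit <- c(trial@screens[["landolt"]], trial@screens[["sloan"]],
                 trial@screens[["table"]])
      centers <- lapply(visit, function(lb) {
        r <- rects[[lb]]
        c(x = (r$x0 + r$x1) / 2, y = (r$y0 + r$y1) / 2)
      })
      sched <- data.frame(
        x_px = vapply(centers, `[[`, numeric(1), "x"),
        y_px = vapply(centers, `[[`, numeric(1), "y"),
        dwell_s = dwell_s)
      trace <- simulateGazeTrace(sched, sc, rate_hz = rate_hz,
                                 noise_sd_deg = noise_sd_deg, t0_s = t_clock)
      dur <- max(trace$timestamp_s) - t_clock + 1 / rate_hz
      loop <- runClosedLoop(sc, trace, state, lens, eye, dur, dt_s)
      state <- loop$state; lens <- loop$lens
      # defocus at the end of each dwell (fixation settled)
      dists <- vapply(visit, function(lb)
        sc@metadata$screens[[which(names(rects) == lb)]]@distance_m,
        numeric(1))
      fix_end <- cumsum(rep(dwell_s, 3) + c(0, 0.04, 0.04))
      defoc <- vapply(seq_along(visit), function(j) {
        k <- max(1, min(nrow(loop$series), round(fix_end[j] / dt_s)))
        defocusError(1 / dists[j], loop$series$power_D[k], eye)
      }, numeric(1))
      names(defoc) <- visit
      demands <- dioptricDemand(dists)
      n_refocus <- sum(abs(diff(demands)) > 1)
      blur <- cocAngular(eye, defoc) * 180 / pi * 60  # arcmin
      per_screen <- rep(NA_real_, 3)
      names(per_screen) <- c("near", "mid", "far")
      per_screen[label_of[visit]] <- defoc
      rec <- observeAndRespond(trial, observer,
                               c(landolt = unname(blur[1]),
                                 sloan = unname(blur[2])),
                               n_refocus = n_refocus, onset_s = t_clock,
                               defocus_D = as.list(per_screen))
      records[[i]] <- rec
      tuning[[i]] <- loop$series
      gazes[[i]] <- trace
      t_clock <- t_clock + dur + 0.2
    }
  })
  records <- do.call(rbind, records)
  tuning <- do.call(rbind, tuning)
  gaze_all <- do.call(rbind, gazes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, timestampedPath(out_dir, "responses"),
                     row.names = FALSE)
    writeTuningLog(tuning, out_dir)
    writeGazeFile(gaze_all, out_dir)
  }
  list(accuracy = mean(records$correct), mean_rt_s = mean(records$rt_s),
       records = records, tuning = tuning)
}
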