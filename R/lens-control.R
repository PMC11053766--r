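#' Advance a focus-tunable lens by one simulation step
#'
#' The new command is queued at the lens's current time and becomes effective
#' after the lens's transport delay.  Within the step the realised power moves
#' toward the currently effective (range-clamped) command at no more than the
#' slew-rate limit, settling exactly on it with no overshoot; maturation times
#' falling inside the step are honoured by piecewise integration, so
#' trajectories are independent of the step size up to the rate limit.
#'
#' @param lens a \linkS4class{TunableLens}
#' @param commanded_D commanded optical power, D
#' @param dt_s step duration, seconds (> 0)
#' @return the updated \linkS4class{TunableLens}
#' @examples
#' l <- tunableLens(rate_D_s = 10)
#' l <- lensStep(l, 3, 0.1)
#' currentPower(l)  # 1.0
#' @export
lensStep <- function(lens, commanded_D, dt_s) {
  stopifnot(is(lens, "TunableLens"))
  if (!is.finite(dt_s) || dt_s <= 0) stop("dt must be positive")
  t0 <- lens@time_s
  t1 <- t0 + dt_s
  queue <- rbind(lens@queue,
                 data.frame(t_s = t0, command_D = commanded_D))
  mature <- queue$t_s + lens@delay_s
  # breakpoints: maturation times inside (t0, t1)
  bps <- sort(unique(c(t0, mature[mature > t0 & mature < t1], t1)))
  power <- lens@power_D
  for (i in seq_len(length(bps) - 1)) {
    tau <- bps[i]; dtau <- bps[i + 1] - bps[i]
    idx <- which(mature <= tau + 1e-12)
    if (length(idx)) {
      target <- queue$command_D[idx[which.max(queue$t_s[idx])]]
      target <- min(max(target, lens@power_min_D), lens@power_max_D)
      step_max <- lens@rate_D_s * dtau
      delta <- target - power
      power <- power + sign(delta) * min(abs(delta), step_max)
    }
  }
  # drop commands fully superseded: keep the latest matured plus all pending
  matured_idx <- which(mature <= t1 + 1e-12)
  keep <- rep(TRUE, nrow(queue))
  if (length(matured_idx) > 1)
    keep[setdiff(matured_idx, matured_idx[which.max(queue$t_s[matured_idx])])] <-
      FALSE
  lens@queue <- queue[keep, , drop = FALSE]
  lens@power_D <- power
  lens@time_s <- t1
  validObject(lens)
  lens
}

#' Gaze-point focus controller
#'
#' Commands the dioptric demand of the depth under the current gaze point,
#' robustified as the median over a 5x5 pixel window and smoothed over the
#' controller's window of recent commands.  An invalid or out-of-image gaze
#' sample holds the last command.
#'
#' @param gaze a gaze sample: list or one-row data.frame with at least
#'   \code{gaze_x_px}, \code{gaze_y_px}, \code{validity}
#' @param scene an \linkS4class{RGBDScene}
#' @param state a \linkS4class{ControllerState}
#' @return list(command_D, state) with the updated state
#' @export
gazePointController <- function(gaze, scene, state) {
  x <- round(gaze$gaze_x_px[1]); y <- round(gaze$gaze_y_px[1])
  H <- nrow(scene@depth); W <- ncol(scene@depth)
  if (!isTRUE(gaze$validity[1]) || is.na(x) || is.na(y) ||
      x < 1 || x > W || y < 1 || y > H)
    return(list(command_D = state@last_command_D, state = state))
  ys <- max(1, y - 2):min(H, y + 2)
  xs <- max(1, x - 2):min(W, x + 2)
  raw <- 1 / stats::median(scene@depth[ys, xs])
  smoothCommand(raw, state)
}

#' Depth-distribution (modal) focus controller
#'
#' Pools the dioptric demands of all pixels within the foveal radius of the
#' gaze point, histograms them into 0.25 D bins, and commands the median
#' demand of the most frequent bin; ties break toward the nearer (higher
#' demand) bin.  An invalid gaze or an empty foveal mask holds the last
#' command.
#'
#' @inheritParams gazePointController
#' @param foveal_radius_deg pooling radius, degrees (default: the state's)
#' @return list(command_D, state)
#' @export
depthModeController <- function(gaze, scene, state,
                                foveal_radius_deg = state@foveal_radius_deg) {
  x <- gaze$gaze_x_px[1]; y <- gaze$gaze_y_px[1]
  H <- nrow(scene@depth); W <- ncol(scene@depth)
  if (!isTRUE(gaze$validity[1]) || is.na(x) || is.na(y) ||
      x < 1 || x > W || y < 1 || y > H)
    return(list(command_D = state@last_command_D, state = state))
  f <- focalLengthPx(W, scene@fov_deg)
  r_px <- f * tan(deg2rad(foveal_radius_deg))
  ys <- max(1, floor(y - r_px)):min(H, ceiling(y + r_px))
  xs <- max(1, floor(x - r_px)):min(W, ceiling(x + r_px))
  ang <- pixelToAngle(rep(xs, each = length(ys)), rep(ys, length(xs)),
                      W, H, scene@fov_deg)
  g <- pixelToAngle(x, y, W, H, scene@fov_deg)
  dist2 <- (ang$azimuth_deg - g$azimuth_deg)^2 +
    (ang$elevation_deg - g$elevation_deg)^2
  sel <- dist2 <= foveal_radius_deg^2
  if (!any(sel))
    return(list(command_D = state@last_command_D, state = state))
  demands <- (1 / scene@depth[ys, xs])[sel]
  bins <- floor(demands / 0.25)
  tab <- table(bins)
  best <- max(tab)
  # ties toward the nearer (higher-demand) bin
  modal <- max(as.numeric(names(tab)[tab == best]))
  raw <- stats::median(demands[bins == modal])
  smoothCommand(raw, state)
}

#' Manual focus controller
#'
#' Piecewise-constant command equal to the latest user event at or before the
#' current time (inclusive boundary); before the first event the initial
#' command holds.
#'
#' @param state a \linkS4class{ControllerState} carrying the time-ordered
#'   event table (t_s, command_D)
#' @param t_s current simulation time, seconds
#' @return list(command_D, state)
#' @export
manualController <- function(state, t_s) {
  ev <- state@events
  if (nrow(ev) && is.unsorted(ev$t_s, strictly = FALSE))
    stop("manual controller events must be time-ordered")
  idx <- which(ev$t_s <= t_s)
  cmd <- if (length(idx)) ev$command_D[max(idx)] else state@last_command_D
  state@last_command_D <- cmd
  list(command_D = cmd, state = state)
}

smoothCommand <- function(raw, state) {
  hist <- c(state@history, raw)
  if (length(hist) > state@window_n)
    hist <- hist[(length(hist) - state@window_n + 1):length(hist)]
  cmd <- mean(hist)
  state@history <- hist
  state@last_command_D <- cmd
  list(command_D = cmd, state = state)
}

#' Effective power of a progressive lens at a gaze elevation
#'
#' Distance power at or above the corridor top, distance + add at or below
#' the corridor bottom, linear interpolation inside: continuous and monotone
#' nonincreasing in elevation.
#'
#' @param map a \linkS4class{ProgressiveLensMap}
#' @param elevation_deg gaze elevation, degrees (vectorised)
#' @return effective optical power, D
#' @examples
#' m <- progressiveLensMap(0, 2.5, c(5, -15))
#' progressivePower(m, c(15, -5, -20))  # 0, 1.25, 2.5
#' @export
progressivePower <- function(map, elevation_deg) {
  stopifnot(is(map, "ProgressiveLensMap"))
  ef <- map@corridor_deg[1]; en <- map@corridor_deg[2]
  frac <- pmin(pmax((ef - elevation_deg) / (ef - en), 0), 1)
  map@distance_power_D + map@add_power_D * frac
}

#' Per-pixel power map of a progressive lens over a scene's image plane
#'
#' @param map a \linkS4class{ProgressiveLensMap}
#' @param scene an \linkS4class{RGBDScene} (supplies geometry)
#' @return H x W matrix of effective powers, D
#' @export
progressivePowerMap <- function(map, scene) {
  H <- nrow(scene@depth); W <- ncol(scene@depth)
  el <- pixelToAngle(rep((W + 1) / 2, H), seq_len(H), W, H,
                     scene@fov_deg)$elevation_deg
  matrix(rep(progressivePower(map, el), W), H, W)
}

#' Closed-loop autofocal simulation over a gaze trace
#'
#' At each step the controller turns the current gaze sample (the latest one
#' at or before step time) into a power command, the lens integrates it
#' through its delay and slew-rate dynamics, and the defocus at the gaze
#' pixel is evaluated through the eye model.  Deterministic given the trace.
#'
#' @param scene an \linkS4class{RGBDScene}
#' @param trace gaze trace data.frame (from \code{\link{simulateGazeTrace}}
#'   or \code{\link{readGazeFile}})
#' @param state a \linkS4class{ControllerState}
#' @param lens a \linkS4class{TunableLens}
#' @param eye an \linkS4class{EyeModel}
#' @param duration_s simulated duration, s
#' @param dt_s controller/lens step, s
#' @return list with \code{series} (data.frame t_s, command_D, power_D,
#'   defocus_D), the final \code{lens} and controller \code{state}
#' @export
runClosedLoop <- function(scene, trace, state, lens, eye, duration_s,
                          dt_s = 0.01) {
  if (dt_s <= 0) stop("dt must be positive")
  n <- floor(duration_s / dt_s + 1e-9)
  out <- data.frame(t_s = numeric(n), command_D = numeric(n),
                    power_D = numeric(n), defocus_D = numeric(n))
  t_rel <- trace$timestamp_s - trace$timestamp_s[1]
  for (k in seq_len(n)) {
    t <- k * dt_s
    i <- findInterval(t, t_rel)
    i <- max(1L, i)
    gz <- trace[i, , drop = FALSE]
    res <- switch(state@policy,
      gaze_point = gazePointController(gz, scene, state),
      depth_mode = depthModeController(gz, scene, state),
      manual = manualController(state, t))
    state <- res$state
    lens <- lensStep(lens, res$command_D, dt_s)
    x <- min(max(round(gz$gaze_x_px), 1), ncol(scene@depth))
    y <- min(max(round(gz$gaze_y_px), 1), nrow(scene@depth))
    demand <- 1 / scene@depth[y, x]
    out$t_s[k] <- t
    out$command_D[k] <- res$command_D
    out$power_D[k] <- lens@power_D
    out$defocus_D[k] <- defocusError(demand, lens@power_D, eye)
  }
  list(series = out, lens = lens, state = state)
}

#' Write a closed-loop tuning log as a timestamped CSV
#'
#' Columns: t_s, command_D, power_D, defocus_D — the autofocal controller
#' tuning-power-change log.
#'
#' @param series the \code{series} element of \code{\link{runClosedLoop}}
#' @param folder output folder (created if missing)
#' @return the path written, invisibly
#' @export
writeTuningLog <- function(series, folder) {
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  path <- timestampedPath(folder, "tuning")
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}
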