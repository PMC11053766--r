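test_that("lens tracks commands at the slew-rate limit and settles exactly", {
  l <- tunableLens(0, 4, rate_D_s = 10, delay_s = 0)
  l <- lensStep(l, 3, 0.1)
  expect_equal(currentPower(l), 1.0)
  l <- lensStep(l, 3, 0.1); l <- lensStep(l, 3, 0.1)
  expect_equal(currentPower(l), 3.0)
  l <- lensStep(l, 3, 0.1)
  expect_equal(currentPower(l), 3.0)  # settled, no overshoot
})

test_that("commands are inert until the transport delay elapses", {
  l <- tunableLens(0, 4, rate_D_s = 10, delay_s = 0.2)
  for (k in 1:3) {  # 0.15 s < delay
    l <- lensStep(l, 3, 0.05)
    expect_equal(currentPower(l), 0)
  }
  l <- lensStep(l, 3, 0.05)  # 0.15 -> 0.20: matures exactly at 0.2
  expect_equal(currentPower(l), 0)
  l <- lensStep(l, 3, 0.1)
  expect_equal(currentPower(l), 1.0)
})

test_that("delay shifts the whole trajectory exactly", {
  run <- function(delay) {
    l <- tunableLens(0, 4, rate_D_s = 10, delay_s = delay)
    vapply(1:60, function(k) {
      l <<- lensStep(l, 3, 0.01)
      currentPower(l)
    }, numeric(1))
  }
  p0 <- run(0)
  p2 <- run(0.2)
  expect_equal(p2[21:60], p0[1:40], tolerance = 1e-12)
  expect_lt(max(abs(p2[1:20])), 1e-9)
})

test_that("commands clamp to the power range", {
  l <- tunableLens(0, 4, rate_D_s = 100, delay_s = 0)
  l <- lensStep(l, 10, 1)
  expect_equal(currentPower(l), 4)
  expect_error(lensStep(l, 1, 0), "positive")
  expect_error(lensStep(l, 1, -0.1), "positive")
})

test_that("slew-rate invariant holds on random command sequences", {
  set.seed(99)
  for (rep in 1:5) {
    rate <- runif(1, 2, 20)
    l <- tunableLens(0, 4, rate_D_s = rate, delay_s = runif(1, 0, 0.1))
    prev <- currentPower(l)
    for (k in 1:100) {
      dt <- runif(1, 0.005, 0.05)
      l <- lensStep(l, runif(1, 0, 4), dt)
      expect_lte(abs(currentPower(l) - prev), rate * dt + 1e-9)
      prev <- currentPower(l)
    }
  }
})

test_that("gaze-point controller commands the 5x5-median depth demand", {
  sc <- smallOffice()
  rects <- sc@metadata$rects
  st <- controllerState("gaze_point")
  ctr <- function(lb) {
    r <- rects[[lb]]
    list(gaze_x_px = (r$x0 + r$x1) / 2, gaze_y_px = (r$y0 + r$y1) / 2,
         validity = TRUE)
  }
  res <- gazePointController(ctr("near"), sc, st)
  expect_equal(res$command_D, 1 / 0.3)
  # window straddling near screen and background, majority far
  r <- rects[["near"]]
  # place gaze so that the 5x5 window has >= 13 background pixels
  gz <- list(gaze_x_px = r$x0 - 1, gaze_y_px = (r$y0 + r$y1) / 2,
             validity = TRUE)
  win <- depthMap(sc)[(gz$gaze_y_px - 2):(gz$gaze_y_px + 2),
                      (gz$gaze_x_px - 2):(gz$gaze_x_px + 2)]
  res2 <- gazePointController(gz, sc, controllerState("gaze_point"))
  expect_equal(res2$command_D, 1 / median(win))
  # invalid sample holds the last command
  st3 <- res$state
  res3 <- gazePointController(list(gaze_x_px = NA, gaze_y_px = NA,
                                   validity = FALSE), sc, st3)
  expect_equal(res3$command_D, res$command_D)
})

test_that("depth-mode controller returns the modal dioptric bin's demand", {
  sc <- smallOffice()
  rects <- sc@metadata$rects
  ctr <- function(lb) {
    r <- rects[[lb]]
    list(gaze_x_px = (r$x0 + r$x1) / 2, gaze_y_px = (r$y0 + r$y1) / 2,
         validity = TRUE)
  }
  # fovea fully on the intermediate screen -> exactly its demand
  res <- depthModeController(ctr("intermediate"), sc,
                             controllerState("depth_mode"),
                             foveal_radius_deg = 1)
  expect_equal(res$command_D, 1.0)
  # fovea majority on the near screen, rest background -> near demand
  r <- rects[["near"]]
  gz <- list(gaze_x_px = r$x1 - 2, gaze_y_px = (r$y0 + r$y1) / 2,
             validity = TRUE)
  res2 <- depthModeController(gz, sc, controllerState("depth_mode"),
                              foveal_radius_deg = 2)
  expect_equal(res2$command_D, 1 / 0.3)
  # gaze outside the image -> hold last command
  st <- res2$state
  res3 <- depthModeController(list(gaze_x_px = -5, gaze_y_px = -5,
                                   validity = TRUE), sc, st)
  expect_equal(res3$command_D, res2$command_D)
})

test_that("manual controller is piecewise constant with inclusive boundary", {
  ev <- data.frame(t_s = c(1, 3), command_D = c(2, 0.5))
  st <- controllerState("manual", events = ev, initial_command_D = 0.25)
  expect_equal(manualController(st, 0.5)$command_D, 0.25)  # before any event
  expect_equal(manualController(st, 2)$command_D, 2)
  expect_equal(manualController(st, 3)$command_D, 0.5)     # inclusive at t=3
  expect_equal(manualController(st, 10)$command_D, 0.5)
  expect_error(controllerState("manual",
    events = data.frame(t_s = c(3, 1), command_D = c(1, 2))), "time-ordered")
})

test_that("progressive power is continuous, monotone, and interpolates", {
  m <- progressiveLensMap(0.5, 2.0, c(5, -15))
  expect_equal(progressivePower(m, 15), 0.5)
  expect_equal(progressivePower(m, -20), 2.5)
  expect_equal(progressivePower(m, -5), 0.5 + 1.0)  # corridor midpoint
  el <- seq(20, -25, by = -0.25)
  p <- progressivePower(m, el)
  expect_true(all(diff(p) >= 0))               # nonincreasing in elevation
  expect_lt(max(abs(diff(p))), 0.2 * 0.25 + 1e-9)  # no jumps: continuous
  expect_error(progressiveLensMap(corridor_deg = c(-15, 5)))
})

test_that("closed loop: ideal lens nulls defocus at the gaze immediately", {
  sc <- smallOffice()
  eye <- eyeModel(3, 0)
  tr <- stepGazeTrace(sc, "intermediate", "intermediate", 0, 0.5)
  res <- runClosedLoop(sc, tr, controllerState("gaze_point"),
                       tunableLens(0, 4, rate_D_s = Inf, delay_s = 0),
                       eye, 0.5, dt_s = 0.01)
  expect_true(all(res$series$defocus_D[-1] < 1e-9))
  expect_true(all(res$series$defocus_D < 1e-9))
})

test_that("closed loop: rate-limited refocus takes (delta D)/rate seconds", {
  sc <- smallOffice()
  eye <- eyeModel(3, 0)
  dt <- 0.005
  tr <- stepGazeTrace(sc, "far", "near", 0.3, 1.2)
  run1 <- runClosedLoop(sc, tr, controllerState("gaze_point"),
                        tunableLens(0, 4, rate_D_s = 10, delay_s = 0),
                        eye, 1.2, dt_s = dt)
  s <- run1$series
  idx <- which(s$t_s > 0.3 + dt)
  t_zero <- s$t_s[idx[which(s$defocus_D[idx] < 1e-9)[1]]]
  expected <- (1 / 0.3 - 1 / 6) / 10          # 0.3167 s of slewing
  start <- s$t_s[which(s$t_s >= 0.3)[1]]      # first step seeing new gaze
  expect_lt(abs((t_zero - start) - expected), 2 * dt)
  # defocus decays linearly during the slew
  slew <- s[s$t_s > start + dt & s$t_s < t_zero - dt, ]
  fit <- stats::lm(defocus_D ~ t_s, data = slew)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_equal(unname(stats::coef(fit)[2]), -10, tolerance = 0.05)
  # adding delay shifts the zero-defocus time by exactly that delay
  run2 <- runClosedLoop(sc, tr, controllerState("gaze_point"),
                        tunableLens(0, 4, rate_D_s = 10, delay_s = 0.3),
                        eye, 1.2, dt_s = dt)
  s2 <- run2$series
  t_zero2 <- s2$t_s[idx[which(s2$defocus_D[idx] < 1e-9)[1]]]
  expect_equal(t_zero2 - t_zero, 0.3, tolerance = dt + 1e-9)
})

test_that("tuning logs are written as timestamped CSV", {
  sc <- smallOffice()
  tr <- stepGazeTrace(sc, "near", "near", 0, 0.2)
  res <- runClosedLoop(sc, tr, controllerState("gaze_point"),
                       tunableLens(), eyeModel(), 0.2, 0.02)
  td <- tempfile()
  p <- writeTuningLog(res$series, td)
  expect_true(file.exists(p))
  expect_match(basename(p), "^tuning_\\d{8}T\\d{6}")
  back <- read.csv(p)
  expect_equal(names(back), c("t_s", "command_D", "power_D", "defocus_D"))
  expect_equal(nrow(back), nrow(res$series))
})
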