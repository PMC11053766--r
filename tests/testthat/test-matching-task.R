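test_that("trials are reproducible and structurally valid", {
  a <- generateTrial(1, seed = 42)
  b <- generateTrial(1, seed = 42)
  expect_identical(a@orientation, b@orientation)
  expect_identical(a@table_letters, b@table_letters)
  expect_identical(a@is_match, b@is_match)
  set.seed(7)
  for (k in 1:200) {
    tr <- generateTrial(k)
    expect_true(validObject(tr))
    expect_setequal(tr@table_orientations, landoltOrientations())
    expect_setequal(tr@table_letters, sloanLetters())
    expect_true(tr@orientation %in% landoltOrientations())
    expect_true(tr@letter %in% sloanLetters())
    # match flag consistent with table membership (also in the validity
    # method, asserted explicitly here as the task's core rule)
    hit <- sum(tr@table_orientations == tr@orientation &
                 tr@table_letters == tr@letter)
    expect_equal(hit == 1, tr@is_match)
  }
})

test_that("randomization balances table screen and match prior", {
  set.seed(2024)
  n <- 3000
  screens <- character(n); matches <- logical(n)
  for (k in seq_len(n)) {
    tr <- generateTrial(k)
    screens[k] <- tr@screens[["table"]]
    matches[k] <- tr@is_match
  }
  counts <- table(screens)
  expect_setequal(names(counts), c("near", "intermediate", "far"))
  bound <- 3 * sqrt(n * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - n / 3) <= bound))
  expect_lt(abs(mean(matches) - 0.5), 0.03)
})

test_that("stimuli land on their screens at the configured angular size", {
  sc <- makeOfficeScene()
  trial <- generateTrial(1, seed = 5)
  placed <- placeStimuli(sc, trial, seed = 5)
  stim <- placed@metadata$stimuli
  f <- focalLengthPx(sceneWidth(sc), fieldOfView(sc))
  expected_gap_px <- 10 / 60 * pi / 180 * f
  expect_equal(stim$landolt[["size"]], max(5, round(5 * expected_gap_px)))
  rects <- sc@metadata$rects
  for (nm in c("landolt", "sloan", "table")) {
    r <- rects[[trial@screens[[nm]]]]
    s <- stim[[nm]]
    w <- if (nm == "table") 8 * s[["size"]] else s[["size"]]
    h <- if (nm == "table") 2 * s[["size"]] else s[["size"]]
    expect_gte(s[["x"]], r$x0); expect_gte(s[["y"]], r$y0)
    expect_lte(s[["x"]] + w - 1, r$x1)
    expect_lte(s[["y"]] + h - 1, r$y1)
  }
  # center placement without jitter: centroid at the rect center +- 1 px
  cfg0 <- taskConfig(placement_jitter_frac = 0)
  tr2 <- generateTrial(2, cfg0, seed = 8)
  tr2@placement[["landolt"]] <- "center"
  p2 <- placeStimuli(sc, tr2, cfg0, seed = 8)
  s2 <- p2@metadata$stimuli$landolt
  r2 <- rects[[tr2@screens[["landolt"]]]]
  expect_lte(abs((s2[["x"]] + (s2[["size"]] - 1) / 2) -
                   (r2$x0 + r2$x1) / 2), 1)
  expect_lte(abs((s2[["y"]] + (s2[["size"]] - 1) / 2) -
                   (r2$y0 + r2$y1) / 2), 1)
  # rendering changed the raster on the stimulus screens
  expect_false(identical(rgbRaster(placed), rgbRaster(sc)))
})

test_that("exactly 8 orientations and 8 letters exist", {
  expect_length(landoltOrientations(), 8)
  expect_length(sloanLetters(), 8)
  expect_setequal(sloanLetters(), c("C", "D", "H", "K", "N", "O", "R", "S"))
  for (o in landoltOrientations())
    expect_true(any(landoltRaster(15, o) > 0))
  for (l in sloanLetters())
    expect_true(any(sloanRaster(l, 15) > 0))
})

test_that("observer hits ceiling with no blur and chance with heavy blur", {
  obs <- observerModel()
  set.seed(31)
  n <- 2000
  rec0 <- vapply(seq_len(n), function(k)
    observeAndRespond(generateTrial(k), obs,
                      c(landolt = 0, sloan = 0))$correct, logical(1))
  expect_equal(mean(rec0), 1.0)
  recInf <- vapply(seq_len(n), function(k)
    observeAndRespond(generateTrial(k), obs,
                      c(landolt = 1e4, sloan = 1e4))$correct, logical(1))
  expect_lt(abs(mean(recInf) - 0.5), 0.03)
  # reproducible given seed; RT positive
  r1 <- observeAndRespond(generateTrial(1, seed = 3), obs,
                          c(landolt = 5, sloan = 5), seed = 9)
  r2 <- observeAndRespond(generateTrial(1, seed = 3), obs,
                          c(landolt = 5, sloan = 5), seed = 9)
  expect_identical(r1, r2)
  expect_gt(r1$rt_s, 0)
  expect_error(observeAndRespond(generateTrial(1, seed = 1), obs,
                                 c(landolt = -1, sloan = 0)), "nonnegative")
})

test_that("identification probability decreases in blur and spans its range", {
  obs <- observerModel()
  r <- c(0, 0.25, 0.5, 1, 2, 4, 16, 1e6)
  p <- focalsim:::identificationProbability(obs, r)
  expect_true(all(diff(p) <= 0))
  expect_equal(p[1], 1)
  expect_lt(p[length(p)], 1 / 8 + 1e-3)
  expect_true(all(p >= 1 / 8 & p <= 1))
  # halfway between chance and ceiling at the threshold ratio
  expect_equal(focalsim:::identificationProbability(obs, 1),
               1 / 8 + 7 / 8 / 2)
})

test_that("block accuracy is nonincreasing in a global blur multiplier", {
  obs <- observerModel()
  mults <- c(0, 0.5, 1, 2, 8)
  acc <- vapply(mults, function(m) {
    set.seed(555)  # paired seeds across multipliers
    mean(vapply(1:1000, function(k)
      observeAndRespond(generateTrial(k), obs,
                        c(landolt = 8 * m, sloan = 8 * m))$correct,
      logical(1)))
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.02))  # nonincreasing up to binomial noise
  expect_equal(acc[1], 1)
})

test_that("autofocal correction recovers presbyopic performance in a block", {
  sc <- makeOfficeScene()
  eye <- eyeModel(3, 0)  # absolute presbyope
  obs <- observerModel()
  ideal <- runBlock(6, sc, eye, tunableLens(0, 4, rate_D_s = Inf),
                    controllerState("gaze_point"), obs, seed = 77,
                    rate_hz = 30, dt_s = 1 / 30)
  fixed <- runBlock(6, sc, eye,
                    tunableLens(0, 0.001, rate_D_s = 1e-9), NULL, obs,
                    seed = 77, rate_hz = 30, dt_s = 1 / 30)
  expect_equal(ideal$accuracy, 1.0)
  expect_lt(fixed$accuracy, ideal$accuracy)
  # uncorrected near-screen defocus is the full near demand
  expect_equal(max(fixed$records$defocus_near_D, na.rm = TRUE), 1 / 0.3,
               tolerance = 1e-3)
  expect_error(runBlock(0, sc, eye, tunableLens(), NULL, obs), "n_trials")
})
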