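# Fixtures built in code; nothing binary on disk.

# Random-texture scene split into two depth planes (right half near).
# Narrow FOV so defocus produces multi-pixel kernels at 32 px width.
twoPlaneScene <- function(seed, near_m = 0.3, far_m = 1, size = 32,
                          fov = 10) {
  sc <- makePlaneScene(far_m, "noise", width_px = size, height_px = size,
                       fov_deg = fov, seed = seed)
  d <- depthMap(sc)
  d[, (size %/% 2 + 1):size] <- near_m
  rgbdScene(rgbRaster(sc), d, fov)
}

# Pixels farther than the largest kernel radius from the image border and
# from any blur-level boundary: where layered compositing is single-layer.
interiorMask <- function(blur_field) {
  H <- nrow(blur_field); W <- ncol(blur_field)
  r <- ceiling(max(blur_field) / 2) + 1
  lev <- round(blur_field, 6)
  edge <- matrix(FALSE, H, W)
  for (dy in -r:r) for (dx in -r:r) {
    ys <- pmin(pmax(seq_len(H) + dy, 1), H)
    xs <- pmin(pmax(seq_len(W) + dx, 1), W)
    edge <- edge | (lev[ys, xs] != lev)
  }
  m <- !edge
  m[c(seq_len(r), (H - r + 1):H), ] <- FALSE
  m[, c(seq_len(r), (W - r + 1):W)] <- FALSE
  m
}

# Gaze trace that steps instantaneously between two screen centres at
# t_switch (no saccade sweep), for exact rate-limit arithmetic.
stepGazeTrace <- function(scene, from_label, to_label, t_switch, duration,
                          rate_hz = 200) {
  rects <- scene@metadata$rects
  ctr <- function(lb) {
    r <- rects[[lb]]
    c(x = (r$x0 + r$x1) / 2, y = (r$y0 + r$y1) / 2)
  }
  a <- ctr(from_label); b <- ctr(to_label)
  t <- seq(0, duration, by = 1 / rate_hz)
  on_b <- t >= t_switch
  data.frame(timestamp_s = t,
             gaze_x_px = ifelse(on_b, b["x"], a["x"]),
             gaze_y_px = ifelse(on_b, b["y"], a["y"]),
             azimuth_deg = 0, elevation_deg = 0, pupil_mm = 4,
             validity = TRUE,
             label = "fixation", stringsAsFactors = FALSE)
}

smallOffice <- function(width_px = 128, height_px = 96)
  makeOfficeScene(width_px = width_px, height_px = height_px)
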