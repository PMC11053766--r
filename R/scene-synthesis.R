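#' Default three-screen office layout
#'
#' The canonical task environment: a smartphone at reading distance (0.30 m),
#' a computer display at 1 m and a far TV screen at 6 m, placed at
#' non-overlapping visual directions within a 90 degree field of view.
#' Physical sizes are typical devices (phone 12 x 7 cm landscape, 24-inch
#' monitor,
#' 55-inch TV).
#'
#' @return list of three \linkS4class{ScreenSpec} objects labelled
#'   "near", "intermediate", "far"
#' @export
defaultOfficeScreens <- function() {
  list(
    screenSpec(0.30, azimuth_deg = -30, elevation_deg = -8,
               width_m = 0.12, height_m = 0.07, label = "near"),
    screenSpec(1.00, azimuth_deg = 0, elevation_deg = 0,
               width_m = 0.53, height_m = 0.30, label = "intermediate"),
    screenSpec(6.00, azimuth_deg = 25, elevation_deg = 8,
               width_m = 1.22, height_m = 0.69, label = "far"))
}

#' Synthesize an office RGB-D scene with screens at several distances
#'
#' Builds the simulator's stand-in for a typical office: bright rectangular
#' screens at their specified distances and visual directions in front of a
#' flat background wall.  The depth map equals each screen's distance inside
#' its projected rectangle and \code{background_depth_m} elsewhere, so the
#' depth histogram has a mode per screen plus the background.
#'
#' @param screens nonempty list of \linkS4class{ScreenSpec}; projected
#'   rectangles must not overlap
#' @param background_depth_m depth of the background wall, m
#' @param width_px,height_px raster resolution
#' @param fov_deg horizontal field of view, degrees
#' @param background_gray background wall albedo in [0, 1]
#' @return an \linkS4class{RGBDScene}; \code{metadata(scene)$screens} carries
#'   the screen list and \code{$rects} their projected pixel rectangles
#' @examples
#' sc <- makeOfficeScene()
#' sort(unique(as.vector(depthMap(sc))))  # 0.3, 1, 6, 6.5
#' @export
makeOfficeScene <- function(screens = defaultOfficeScreens(),
                            background_depth_m = 6.5,
                            width_px = 256, height_px = 192, fov_deg = 90,
                            background_gray = 0.35) {
  if (length(screens) == 0) stop("screens must be nonempty")
  rects <- lapply(screens, screenRectPx, width_px = width_px,
                  height_px = height_px, fov_deg = fov_deg)
  occ <- matrix(0L, height_px, width_px)
  for (r in rects) {
    if (r$x1 < r$x0 || r$y1 < r$y0)
      stop("screen projects outside the image")
    occ[r$y0:r$y1, r$x0:r$x1] <- occ[r$y0:r$y1, r$x0:r$x1] + 1L
  }
  if (any(occ > 1L)) stop("screen projections overlap")
  depth <- matrix(background_depth_m, height_px, width_px)
  gray <- matrix(background_gray, height_px, width_px)
  for (i in seq_along(screens)) {
    r <- rects[[i]]
    depth[r$y0:r$y1, r$x0:r$x1] <- screens[[i]]@distance_m
    gray[r$y0:r$y1, r$x0:r$x1] <- 0.95
  }
  rgb <- array(gray, dim = c(height_px, width_px, 3))
  names(rects) <- vapply(screens, function(s) s@label, character(1))
  rgbdScene(rgb, depth, fov_deg,
            metadata = list(screens = screens, rects = rects,
                            background_depth_m = background_depth_m))
}

#' Synthesize a constant-depth plane scene (test fixture)
#'
#' A full-field fronto-parallel plane at a single distance carrying a
#' deterministic pattern.  Useful as the simplest substrate for blur tests:
#' every pixel shares one dioptric demand.
#'
#' @param distance_m plane distance, m (> 0)
#' @param pattern "checker", "letter" or "noise"
#' @param width_px,height_px raster resolution
#' @param fov_deg horizontal field of view, degrees
#' @param seed RNG seed for the noise pattern (ignored otherwise)
#' @param checker_px checker square size, pixels
#' @return an \linkS4class{RGBDScene} with constant depth
#' @export
makePlaneScene <- function(distance_m, pattern = c("checker", "letter",
                                                   "noise"),
                           width_px = 64, height_px = 64, fov_deg = 90,
                           seed = 1, checker_px = 8) {
  if (!is.finite(distance_m) || distance_m <= 0)
    stop("distance must be positive")
  pattern <- match.arg(pattern)
  gray <- switch(pattern,
    checker = {
      ix <- (seq_len(width_px) - 1) %/% checker_px
      iy <- (seq_len(height_px) - 1) %/% checker_px
      outer(iy, ix, function(a, b) (a + b) %% 2)
    },
    noise = withSeed(seed, matrix(stats::runif(height_px * width_px),
                                  height_px, width_px)),
    letter = {
      m <- matrix(0.9, height_px, width_px)
      size <- floor(min(height_px, width_px) * 0.6)
      glyph <- sloanRaster("C", size)
      y0 <- floor((height_px - size) / 2)
      x0 <- floor((width_px - size) / 2)
      m[y0 + seq_len(size), x0 + seq_len(size)] <-
        ifelse(glyph > 0, 0.05, 0.9)
      m
    })
  rgb <- array(gray, dim = c(height_px, width_px, 3))
  depth <- matrix(distance_m, height_px, width_px)
  rgbdScene(rgb, depth, fov_deg, metadata = list(pattern = pattern))
}

#' Write an RGB-D scene to disk (PNG raster + textual depth)
#'
#' The colour raster is written as an 8-bit PNG; the depth map as a plain CSV
#' with one row per raster row, full-precision decimal text, so that depth
#' round-trips exactly.  A small YAML sidecar carries the field of view.
#'
#' @param scene an \linkS4class{RGBDScene}
#' @param rgb_path PNG output path
#' @param depth_path CSV output path
#' @param meta_path optional YAML sidecar path (default: depth path with
#'   .yaml); set NULL to skip
#' @return invisibly, the paths written
#' @export
writeRGBD <- function(scene, rgb_path, depth_path,
                      meta_path = sub("\\.[^.]*$", ".yaml", depth_path)) {
  stopifnot(is(scene, "RGBDScene"))
  png::writePNG(scene@rgb, rgb_path)
  txt <- apply(scene@depth, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, depth_path)
  if (!is.null(meta_path))
    yaml::write_yaml(list(fov_deg = scene@fov_deg), meta_path)
  invisible(list(rgb = rgb_path, depth = depth_path, meta = meta_path))
}

#' Read an RGB-D scene from disk
#'
#' @param rgb_path PNG raster path
#' @param depth_path depth CSV path (one row per raster row, metres)
#' @param fov_deg field of view; overridden by the YAML sidecar if present
#' @param meta_path optional sidecar path (default: alongside depth)
#' @return an \linkS4class{RGBDScene}
#' @export
readRGBD <- function(rgb_path, depth_path, fov_deg = 90,
                     meta_path = sub("\\.[^.]*$", ".yaml", depth_path)) {
  rgb <- png::readPNG(rgb_path)
  if (length(dim(rgb)) == 2) rgb <- array(rgb, dim = c(dim(rgb), 3))
  if (dim(rgb)[3] == 4) rgb <- rgb[, , 1:3, drop = FALSE]
  rows <- strsplit(readLines(depth_path), ",", fixed = TRUE)
  depth <- do.call(rbind, lapply(rows, as.numeric))
  if (!identical(dim(rgb)[1:2], dim(depth)))
    stop("rgb and depth files have mismatched dimensions")
  if (any(!is.finite(depth)) || any(depth <= 0))
    stop("depth file contains nonpositive or non-finite values")
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    if (!is.null(meta$fov_deg)) fov_deg <- meta$fov_deg
  }
  rgbdScene(rgb, depth, fov_deg)
}
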