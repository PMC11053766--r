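# Pinhole projection helpers. Convention (used everywhere): row 0/1 at the
# top of the image, x rightward, y downward; azimuth positive rightward,
# elevation positive upward; the image centre lies on the optical axis.

#' Pinhole focal length in pixels
#'
#' f_px = (W/2) / tan(FOV/2) for a horizontal field of view FOV over an image
#' of width W.
#'
#' @param width_px image width, pixels
#' @param fov_deg horizontal field of view, degrees
#' @return focal length in pixel units
#' @export
focalLengthPx <- function(width_px, fov_deg) {
  (width_px / 2) / tan(fov_deg * pi / 360)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Convert visual angles to pixel coordinates
#'
#' @param azimuth_deg,elevation_deg visual angle, degrees (elevation positive
#'   upward)
#' @param width_px,height_px image dimensions
#' @param fov_deg horizontal field of view, degrees
#' @return data.frame with columns x_px, y_px (1-based pixel coordinates,
#'   y increasing downward)
#' @export
angleToPixel <- function(azimuth_deg, elevation_deg, width_px, height_px,
                         fov_deg) {
  f <- focalLengthPx(width_px, fov_deg)
  cx <- (width_px + 1) / 2
  cy <- (height_px + 1) / 2
  data.frame(x_px = cx + f * tan(deg2rad(azimuth_deg)),
             y_px = cy - f * tan(deg2rad(elevation_deg)))
}

#' Convert pixel coordinates to visual angles
#'
#' Inverse of \code{\link{angleToPixel}}.
#'
#' @param x_px,y_px pixel coordinates (1-based)
#' @inheritParams angleToPixel
#' @return data.frame with columns azimuth_deg, elevation_deg
#' @export
pixelToAngle <- function(x_px, y_px, width_px, height_px, fov_deg) {
  f <- focalLengthPx(width_px, fov_deg)
  cx <- (width_px + 1) / 2
  cy <- (height_px + 1) / 2
  data.frame(azimuth_deg = rad2deg(atan((x_px - cx) / f)),
             elevation_deg = rad2deg(atan((cy - y_px) / f)))
}

# Projected pixel rectangle of a fronto-parallel screen. Returns
# list(x0, x1, y0, y1) (1-based, inclusive), clipped to the image.
screenRectPx <- function(screen, width_px, height_px, fov_deg) {
  half_az <- rad2deg(atan(screen@width_m / (2 * screen@distance_m)))
  half_el <- rad2deg(atan(screen@height_m / (2 * screen@distance_m)))
  tl <- angleToPixel(screen@azimuth_deg - half_az,
                     screen@elevation_deg + half_el,
                     width_px, height_px, fov_deg)
  br <- angleToPixel(screen@azimuth_deg + half_az,
                     screen@elevation_deg - half_el,
                     width_px, height_px, fov_deg)
  list(x0 = max(1L, floor(tl$x_px)), x1 = min(width_px, ceiling(br$x_px)),
       y0 = max(1L, floor(tl$y_px)), y1 = min(height_px, ceiling(br$y_px)))
}
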