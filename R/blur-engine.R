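#' Normalised disk kernel for defocus blur
#'
#' Discretised circle-of-confusion kernel: a pixel belongs to the support if
#' its centre lies within diameter/2 of the kernel centre.  Sub-pixel
#' diameters (<= 1 px) yield the 1x1 identity kernel, so zero defocus leaves
#' an image bit-identical.  Entries are nonnegative and sum to 1.
#'
#' @param diameter_px blur-disk diameter, pixels (>= 0)
#' @return a square numeric matrix of odd size summing to 1
#' @examples
#' diskKernel(0)         # identity
#' sum(diskKernel(5.5))  # 1
#' @export
diskKernel <- function(diameter_px) {
  if (!is.finite(diameter_px) || diameter_px < 0)
    stop("kernel diameter must be nonnegative")
  if (diameter_px <= 1) return(matrix(1, 1, 1))
  r <- diameter_px / 2
  m <- floor(r)
  off <- -m:m
  d2 <- outer(off^2, off^2, "+")
  k <- (d2 <= r^2) * 1
  k / sum(k)
}

#' Elliptical kernel for sphero-cylindrical (astigmatic) defocus
#'
#' The blur disk of a sphero-cylindrical error is an ellipse whose principal
#' diameters correspond to the two principal-meridian defocus errors
#' |sphere| and |sphere + cylinder|, rotated to the cylinder axis.  Reduces
#' to \code{\link{diskKernel}} when the cylinder is zero; a pure cylinder
#' gives a line-like kernel along the axis.
#'
#' @param eye an \linkS4class{EyeModel}
#' @param sphere_defocus_D spherical defocus error, D
#' @param cylinder_D cylinder power, D
#' @param axis_deg cylinder axis, degrees in [0, 180), measured from the
#'   horizontal
#' @param width_px,fov_deg camera geometry used to convert angles to pixels
#' @return a square numeric matrix summing to 1
#' @export
astigmaticKernel <- function(eye, sphere_defocus_D, cylinder_D = 0,
                             axis_deg = 0, width_px = 256, fov_deg = 90) {
  if (axis_deg < 0 || axis_deg >= 180)
    stop("axis must lie in [0, 180)")
  f <- focalLengthPx(width_px, fov_deg)
  d1 <- cocAngular(eye, abs(sphere_defocus_D)) * f
  d2 <- cocAngular(eye, abs(sphere_defocus_D + cylinder_D)) * f
  if (d1 <= 1 && d2 <= 1) return(matrix(1, 1, 1))
  # focal-line convention: the |sphere + cylinder| extent lies along the
  # cylinder axis, so a pure cylinder gives a line parallel to its axis
  a <- max(d2, 1) / 2   # semi-axis along the cylinder axis direction
  b <- max(d1, 1) / 2
  m <- floor(max(a, b))
  off <- -m:m
  xs <- matrix(off, length(off), length(off), byrow = TRUE)
  ys <- matrix(-off, length(off), length(off))  # y up for the rotation
  th <- deg2rad(axis_deg)
  u <- xs * cos(th) + ys * sin(th)
  v <- -xs * sin(th) + ys * cos(th)
  k <- ((u / a)^2 + (v / b)^2 <= 1) * 1
  if (sum(k) == 0) k[m + 1, m + 1] <- 1
  k / sum(k)
}

# 2-D convolution with reflect (symmetric) padding; the heavy lifting is
# EBImage's FFT-based filter2. A 1x1 kernel short-circuits so that identity
# blur is bit-exact.
convolveReflect <- function(x, kernel) {
  if (nrow(kernel) == 1 && ncol(kernel) == 1) return(x * kernel[1, 1])
  p <- (nrow(kernel) - 1) / 2
  H <- nrow(x); W <- ncol(x)
  ry <- c(pmin(p:1, H), 1:H, pmax(H - seq_len(p) + 1, 1))
  rx <- c(pmin(p:1, W), 1:W, pmax(W - seq_len(p) + 1, 1))
  padded <- x[ry, rx, drop = FALSE]
  out <- EBImage::filter2(padded, kernel, boundary = "replicate")
  out[p + seq_len(H), p + seq_len(W), drop = FALSE]
}

#' Per-pixel circle-of-confusion field for a scene, eye and lens power
#'
#' For every pixel the dioptric demand is the reciprocal of its depth; the
#' defocus error is the absolute difference between demand and total focus
#' (lens power + achieved accommodation - far refraction); the blur-disk
#' diameter is the angular circle of confusion converted to pixels through
#' the pinhole focal length.
#'
#' By default accommodation responds per pixel (each location treated as if
#' fixated, within the eye's amplitude); pass \code{accommodation_demand_D}
#' to pin accommodation to a single fixated demand instead, as in
#' gaze-contingent runs.
#'
#' @param scene an \linkS4class{RGBDScene}
#' @param eye an \linkS4class{EyeModel}
#' @param lens_power_D scalar lens power, or an H x W matrix of per-pixel
#'   power (e.g. from \code{\link{progressivePowerMap}})
#' @param accommodation_demand_D optional fixated demand, D; if given,
#'   accommodation is fixed at the response to this demand
#' @return H x W matrix of blur-disk diameters in pixels (the blur field)
#' @examples
#' sc <- makePlaneScene(1)
#' max(computeBlurField(sc, eyeModel(), 1.0))  # 0: plane in focus
#' @export
computeBlurField <- function(scene, eye, lens_power_D,
                             accommodation_demand_D = NULL) {
  stopifnot(is(scene, "RGBDScene"), is(eye, "EyeModel"))
  validObject(scene); validObject(eye)
  demand <- 1 / scene@depth
  if (is.matrix(lens_power_D)) {
    if (!identical(dim(lens_power_D), dim(scene@depth)))
      stop("per-pixel lens power map must match scene dimensions")
    power <- lens_power_D
  } else power <- matrix(lens_power_D, nrow(scene@depth), ncol(scene@depth))
  if (is.null(accommodation_demand_D)) {
    acc <- pmin(pmax(demand - power + eye@refraction_D, 0), eye@amplitude_D)
  } else {
    acc <- accommodationResponse(accommodation_demand_D, mean(power), eye)
  }
  total <- power + acc - eye@refraction_D
  defocus <- abs(demand - total)
  beta <- (eye@pupil_mm / 1000) * defocus
  beta * focalLengthPx(ncol(scene@depth), scene@fov_deg)
}

# Quantise a blur field into at most n_levels representative diameters.
# Exact when the field has <= n_levels unique values (rounded to 1e-6 px).
quantizeBlurLevels <- function(coc, n_levels = 16) {
  vals <- round(coc, 6)
  u <- sort(unique(as.vector(vals)))
  if (length(u) <= n_levels) {
    idx <- match(vals, u)
    dim(idx) <- dim(coc)
    return(list(level = idx, diameters = u))
  }
  br <- seq(min(u), max(u), length.out = n_levels + 1)
  idx <- findInterval(vals, br, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  diam <- vapply(seq_len(n_levels),
                 function(i) mean(coc[idx == i]), numeric(1))
  diam[!is.finite(diam)] <- 0
  dim(idx) <- dim(coc)
  list(level = idx, diameters = diam)
}

#' Apply spatially varying disk-kernel blur to a scene
#'
#' Two renderers share one contract: \code{"gather"} is the reference
#' per-pixel convolution (each output pixel is its own disk kernel applied to
#' the input: the testing oracle, exact but slow); \code{"layered"}
#' quantises the blur field into at most 16 diameter levels, blurs each
#' level's layer with its kernel, and composites far-to-near with blurred
#' coverage masks, renormalising by accumulated coverage.  In level interiors
#' the two agree to floating-point precision; near level boundaries layered
#' rendering blends layers (the usual edge-bleed of layered depth of field).
#' An all-zero blur field returns the input bit-identically.
#'
#' @param scene an \linkS4class{RGBDScene}
#' @param blur_field H x W matrix of blur-disk diameters, pixels (e.g. from
#'   \code{\link{computeBlurField}})
#' @param method "layered" (default) or "gather"
#' @param n_levels maximum number of quantisation levels for layered
#'   rendering
#' @return H x W x 3 blurred rgb array in [0, 1]
#' @export
applyDepthBlur <- function(scene, blur_field, method = c("layered", "gather"),
                           n_levels = 16) {
  method <- match.arg(method)
  stopifnot(is(scene, "RGBDScene"))
  if (!identical(dim(blur_field), dim(scene@depth)))
    stop("blur field dimensions must match the scene")
  if (any(!is.finite(blur_field)) || any(blur_field < 0))
    stop("blur field must be nonnegative and finite")
  rgb <- scene@rgb
  if (all(blur_field <= 1)) return(rgb)
  if (method == "gather") return(gatherBlur(rgb, blur_field))
  q <- quantizeBlurLevels(blur_field, n_levels)
  # composite order: farthest mean depth first
  mean_depth <- vapply(seq_along(q$diameters), function(i)
    mean(scene@depth[q$level == i]), numeric(1))
  order_far_first <- order(mean_depth, decreasing = TRUE, na.last = TRUE)
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  acc <- array(0, dim = c(H, W, 3))
  wt <- matrix(0, H, W)
  for (i in order_far_first) {
    mask <- (q$level == i) * 1
    if (!any(mask > 0)) next
    k <- diskKernel(q$diameters[i])
    mb <- convolveReflect(mask, k)
    for (ch in 1:3)
      acc[, , ch] <- convolveReflect(rgb[, , ch] * mask, k) +
        (1 - mb) * acc[, , ch]
    wt <- mb + (1 - mb) * wt
  }
  wt <- pmax(wt, 1e-12)
  for (ch in 1:3) acc[, , ch] <- acc[, , ch] / wt
  acc[acc < 0] <- 0
  acc[acc > 1] <- 1
  acc
}

# Reference per-pixel gather convolution: O(H W k^2), used as the oracle.
gatherBlur <- function(rgb, blur_field) {
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  pmax_r <- floor(max(blur_field) / 2)
  ry <- c(pmin(pmax_r:1, H), 1:H, pmax(H - seq_len(pmax_r) + 1, 1))
  rx <- c(pmin(pmax_r:1, W), 1:W, pmax(W - seq_len(pmax_r) + 1, 1))
  if (pmax_r == 0) { ry <- 1:H; rx <- 1:W }
  pad <- rgb[ry, rx, , drop = FALSE]
  out <- array(0, dim = dim(rgb))
  kcache <- list()
  for (y in seq_len(H)) for (x in seq_len(W)) {
    d <- round(blur_field[y, x], 6)
    key <- sprintf("%.6f", d)
    k <- kcache[[key]]
    if (is.null(k)) { k <- diskKernel(d); kcache[[key]] <- k }
    m <- (nrow(k) - 1) / 2
    if (m == 0) { out[y, x, ] <- rgb[y, x, ]; next }
    ys <- (y + pmax_r - m):(y + pmax_r + m)
    xs <- (x + pmax_r - m):(x + pmax_r + m)
    for (ch in 1:3)
      out[y, x, ch] <- sum(pad[ys, xs, ch] * k)
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
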