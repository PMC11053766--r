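# Optotype rasterisation. Landolt rings follow the standard geometry: stroke
# width and gap both 1/5 of the outer diameter. Sloan letters are drawn on the
# standard 5x5 stroke grid, here as coarse 5x5 bitmaps scaled by nearest
# neighbour; adequate for a simulated observer that never reads pixel glyphs
# directly.

#' The eight compass orientations of the Landolt gap
#' @return character vector of length 8
#' @export
landoltOrientations <- function()
  c("E", "NE", "N", "NW", "W", "SW", "S", "SE")

#' The eight-letter Sloan alphabet used by the matching task
#' @return character vector of length 8
#' @export
sloanLetters <- function() c("C", "D", "H", "K", "N", "O", "R", "S")

.orientationAngle <- c(E = 0, NE = 45, N = 90, NW = 135, W = 180,
                       SW = 225, S = 270, SE = 315)

#' Rasterise a Landolt ring
#'
#' @param size_px outer diameter, pixels
#' @param orientation gap direction, one of \code{landoltOrientations()}
#' @return size_px x size_px 0/1 matrix (1 = ink)
#' @export
landoltRaster <- function(size_px, orientation = "E") {
  orientation <- match.arg(orientation, landoltOrientations())
  size_px <- max(3L, as.integer(round(size_px)))
  r_out <- size_px / 2
  r_in <- r_out * 3 / 5          # stroke = diameter/5
  gap_half <- size_px / 5 / 2    # gap width = diameter/5
  theta <- deg2rad(.orientationAngle[[orientation]])
  ux <- cos(theta); uy <- sin(theta)   # gap direction, y up
  c0 <- (size_px + 1) / 2
  xs <- matrix(seq_len(size_px) - c0, size_px, size_px, byrow = TRUE)
  ys <- matrix(c0 - seq_len(size_px), size_px, size_px)  # y up
  rr <- sqrt(xs^2 + ys^2)
  ring <- rr <= r_out & rr >= r_in
  along <- xs * ux + ys * uy
  perp <- abs(-xs * uy + ys * ux)
  gap <- along > 0 & perp <= gap_half
  (ring & !gap) * 1
}

.sloanBitmaps <- local({
  rows <- function(...) {
    m <- do.call(rbind, lapply(list(...), function(s)
      as.integer(strsplit(s, "")[[1]])))
    m
  }
  list(
    C = rows("11111", "10000", "10000", "10000", "11111"),
    D = rows("11110", "10001", "10001", "10001", "11110"),
    H = rows("10001", "10001", "11111", "10001", "10001"),
    K = rows("10001", "10010", "11100", "10010", "10001"),
    N = rows("10001", "11001", "10101", "10011", "10001"),
    O = rows("11111", "10001", "10001", "10001", "11111"),
    R = rows("11110", "10001", "11110", "10010", "10001"),
    S = rows("11111", "10000", "11111", "00001", "11111"))
})

#' Rasterise a Sloan letter
#'
#' @param letter one of \code{sloanLetters()}
#' @param size_px glyph height/width, pixels
#' @return size_px x size_px 0/1 matrix (1 = ink)
#' @export
sloanRaster <- function(letter, size_px) {
  letter <- match.arg(letter, sloanLetters())
  size_px <- max(3L, as.integer(round(size_px)))
  bm <- .sloanBitmaps[[letter]]
  idx <- pmin(5L, 1L + ((seq_len(size_px) - 1L) * 5L) %/% size_px)
  bm[idx, idx]
}

# Stamp a 0/1 glyph onto all three channels of an rgb array at (y0, x0)
# (top-left, 1-based), dark ink on whatever is beneath.
stampGlyph <- function(rgb, glyph, y0, x0, ink = 0.05) {
  h <- nrow(glyph); w <- ncol(glyph)
  ys <- y0:(y0 + h - 1); xs <- x0:(x0 + w - 1)
  if (min(ys) < 1 || min(xs) < 1 || max(ys) > dim(rgb)[1] ||
      max(xs) > dim(rgb)[2])
    stop("glyph exceeds raster bounds")
  for (ch in 1:3) {
    sub <- rgb[ys, xs, ch]
    sub[glyph > 0] <- ink
    rgb[ys, xs, ch] <- sub
  }
  rgb
}
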