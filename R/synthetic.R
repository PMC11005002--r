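#' @include grid.R geometry.R
NULL

#' Synthetic droplet fields for testing and calibration
#'
#' Rasterize smooth reference solids as phase-field-like scalar fields
#' (value ~ 1 inside, ~ 0 outside, tanh-like interface of width `width`):
#' a ball, an axis-aligned box, and an axis-aligned ellipsoid. The smooth
#' interface lets linear edge interpolation recover the true surface, so
#' these are the fixtures of choice for validating droplet volumes,
#' isosurface areas, and sphericity against closed forms. All synthetic —
#' no simulation involved.
#'
#' @param grid a [SimGrid-class].
#' @param center solid center in um.
#' @param radius ball radius in um.
#' @param width interface width in um (default: one voxel).
#' @return a 3D array with the grid's shape.
#' @name synthetic-fields
#' @export
syntheticBallField <- function(grid, center, radius,
                               width = min(grid@spacing)) {
  cc <- .coordArrays(grid)
  d <- sqrt((cc$x - center[1])^2 + (cc$y - center[2])^2 +
            (cc$z - center[3])^2)
  0.5 * (1 - tanh((d - radius) / width))
}

#' @rdname synthetic-fields
#' @param halfSides numeric(3): the box's half side lengths in um.
#' @export
syntheticBoxField <- function(grid, center, halfSides,
                              width = min(grid@spacing)) {
  cc <- .coordArrays(grid)
  # signed distance to an axis-aligned box (exact outside, max-metric inside)
  qx <- abs(cc$x - center[1]) - halfSides[1]
  qy <- abs(cc$y - center[2]) - halfSides[2]
  qz <- abs(cc$z - center[3]) - halfSides[3]
  outside <- sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2 + pmax(qz, 0)^2)
  inside <- pmin(pmax(qx, pmax(qy, qz)), 0)
  d <- outside + inside
  0.5 * (1 - tanh(d / width))
}

#' @rdname synthetic-fields
#' @param semiaxes numeric(3): ellipsoid semiaxes in um.
#' @export
syntheticEllipsoidField <- function(grid, center, semiaxes,
                                    width = min(grid@spacing)) {
  cc <- .coordArrays(grid)
  rell <- sqrt(((cc$x - center[1]) / semiaxes[1])^2 +
               ((cc$y - center[2]) / semiaxes[2])^2 +
               ((cc$z - center[3]) / semiaxes[3])^2)
  # approximate signed distance: (r_ell - 1) scaled by the local semiaxis
  # mix; the 1/2-level set is exactly the ellipsoid surface
  d <- (rell - 1) * min(semiaxes)
  0.5 * (1 - tanh(d / width))
}

#' Surface area of a prolate spheroid (closed form)
#'
#' For semiaxes (a, b, b) with a >= b:
#' \eqn{S = 2\pi b^2 (1 + (a/(b e)) \arcsin e)},
#' \eqn{e = \sqrt{1 - b^2/a^2}}. Used as the independent oracle when
#' validating sphericity on rasterized spheroids.
#'
#' @param a polar (long) semiaxis in um.
#' @param b equatorial semiaxis in um, `b <= a`.
#' @return surface area in um^2.
#' @export
prolateSpheroidArea <- function(a, b) {
  if (b > a) stop("prolate spheroid needs b <= a")
  if (abs(a - b) < 1e-12 * a) return(4 * pi * a^2)
  e <- sqrt(1 - b^2 / a^2)
  2 * pi * b^2 * (1 + a / (b * e) * asin(e))
}

#' Miniature grid for tests and reduced-resolution runs
#'
#' The reference 180 x 225 x 90 mesh of the 6 x 9 x 3 um domain scaled
#' down by a linear factor.
#'
#' @param divisor linear reduction factor (e.g. 4 = quarter resolution).
#' @param boundary grid boundary contract.
#' @return a [SimGrid-class].
#' @export
miniatureGrid <- function(divisor = 8, boundary = "zero-flux") {
  simGrid(as.integer(round(c(180, 225, 90) / divisor)),
          extents = c(6, 9, 3), boundary = boundary)
}
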