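#' @include grid.R geometry.R
NULL

#' Radial density profile along a named nuclear axis
#'
#' Mean field value in slab-of-revolution bins along one of the nucleus's
#' principal axes: voxels within a cylinder of radius `cylinderRadius`
#' around the chosen axis (through the nuclear center) are binned by
#' their absolute projection onto that axis, from the center out to the
#' corresponding semiaxis. Axis naming follows the oblate geometry:
#' `"major"` is y (semiaxis b), `"minor"` is x (semiaxis a), `"z"` is the
#' flattened axis (semiaxis c).
#'
#' @param field 3D array.
#' @param grid a [SimGrid-class].
#' @param geom a [NucleusGeometry-class].
#' @param axis `"major"`, `"minor"`, or `"z"`.
#' @param nBins number of bins (default 20).
#' @param cylinderRadius sampling cylinder radius in um (default 0.5).
#' @param fieldName label stored with the profile.
#' @return a [RadialProfile-class]; bins no voxel falls in carry `NA`.
#' @export
radialProfile <- function(field, grid, geom,
                          axis = c("major", "minor", "z"),
                          nBins = 20L, cylinderRadius = 0.5,
                          fieldName = "field") {
  axis <- match.arg(axis)
  axIdx <- switch(axis, minor = 1L, major = 2L, z = 3L)
  semi <- geom@semiaxes[axIdx]
  cc <- .coordArrays(grid)
  d <- list(cc$x - geom@center[1], cc$y - geom@center[2],
            cc$z - geom@center[3])
  along <- abs(d[[axIdx]])
  perp <- sqrt(Reduce(`+`, lapply(setdiff(1:3, axIdx),
                                  function(k) d[[k]]^2)))
  sel <- perp <= cylinderRadius & along <= semi
  edges <- seq(0, semi, length.out = nBins + 1L)
  bin <- findInterval(along[sel], edges, rightmost.closed = TRUE)
  dens <- rep(NA_real_, nBins)
  if (any(sel)) {
    sums <- rowsum(field[sel], bin)
    counts <- tabulate(bin, nbins = nBins)
    at <- as.integer(rownames(sums))
    dens[at] <- sums[, 1] / counts[at]
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  new("RadialProfile", axis = axis, binCenters = centers, density = dens,
      fieldName = fieldName, cylinderRadius = cylinderRadius)
}

#' Convert a RadialProfile to a data.frame
#'
#' @param x a [RadialProfile-class].
#' @param ... ignored.
#' @return data.frame with columns `distance` and `density`.
#' @export
as.data.frame.RadialProfile <- function(x, ...) {
  data.frame(distance = x@binCenters, density = x@density)
}

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf("RadialProfile of %s along the %s axis: %d bins to %.3g um\n",
              object@fieldName, object@axis, length(object@binCenters),
              max(object@binCenters)))
})
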