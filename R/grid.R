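#' @include AllGenerics.R
NULL

#' Create a simulation grid
#'
#' @param shape integer(3): voxels per axis (nx, ny, nz).
#' @param extents numeric(3): physical domain lengths (Lx, Ly, Lz) in um.
#'   Exactly one of `extents` or `spacing` must be given.
#' @param spacing numeric(3) or scalar: voxel edge length(s) in um.
#' @param boundary `"zero-flux"` (default) or `"periodic"`.
#' @return a [SimGrid-class].
#' @examples
#' g <- simGrid(c(24, 36, 12), extents = c(6, 9, 3))
#' voxelVolume(g)
#' @export
simGrid <- function(shape, extents = NULL, spacing = NULL,
                    boundary = c("zero-flux", "periodic")) {
  boundary <- match.arg(boundary)
  shape <- as.integer(shape)
  if (is.null(extents) == is.null(spacing))
    stop("give exactly one of 'extents' or 'spacing'")
  if (is.null(spacing)) {
    spacing <- extents / shape
  } else {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    extents <- shape * spacing
  }
  new("SimGrid", shape = shape, spacing = as.numeric(spacing),
      extents = as.numeric(extents), boundary = boundary)
}

#' @rdname grid-accessors
setMethod("gridShape", "SimGrid", function(object) object@shape)

#' @rdname grid-accessors
setMethod("gridSpacing", "SimGrid", function(object) object@spacing)

#' @rdname grid-accessors
setMethod("gridExtents", "SimGrid", function(object) object@extents)

#' @rdname grid-accessors
setMethod("voxelVolume", "SimGrid", function(object) prod(object@spacing))

#' @rdname grid-accessors
setMethod("boundaryMode", "SimGrid", function(object) object@boundary)

#' Voxel-center coordinates of a grid
#'
#' @param grid a [SimGrid-class].
#' @return list with components `x`, `y`, `z`: midpoint coordinates
#'   \eqn{(i - 1/2) h} along each axis, in micrometers.
#' @export
axisCoords <- function(grid) {
  s <- grid@shape; h <- grid@spacing
  list(x = (seq_len(s[1]) - 0.5) * h[1],
       y = (seq_len(s[2]) - 0.5) * h[2],
       z = (seq_len(s[3]) - 0.5) * h[3])
}

# Full 3D arrays of voxel-center coordinates (internal; used by geometry,
# seeding, and the analysis module).
.coordArrays <- function(grid) {
  s <- grid@shape
  cc <- axisCoords(grid)
  list(
    x = array(cc$x, dim = s),
    y = array(rep(cc$y, each = s[1]), dim = s),
    z = array(rep(cc$z, each = s[1] * s[2]), dim = s)
  )
}

setMethod("show", "SimGrid", function(object) {
  cat(sprintf("SimGrid: %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) um\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  domain %.3g x %.3g x %.3g um, %s boundaries\n",
              object@extents[1], object@extents[2], object@extents[3],
              object@boundary))
})
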