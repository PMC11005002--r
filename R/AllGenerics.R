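#' @include AllClasses.R
NULL

#' Grid accessors
#'
#' @param object a [SimGrid-class].
#' @return `gridShape`: integer(3) voxel counts; `gridSpacing` and
#'   `gridExtents`: numeric(3) in micrometers; `voxelVolume`: scalar um^3;
#'   `boundaryMode`: the boundary contract string.
#' @name grid-accessors
#' @export
setGeneric("gridShape", function(object) standardGeneric("gridShape"))

#' @rdname grid-accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))

#' @rdname grid-accessors
#' @export
setGeneric("gridExtents", function(object) standardGeneric("gridExtents"))

#' @rdname grid-accessors
#' @export
setGeneric("voxelVolume", function(object) standardGeneric("voxelVolume"))

#' @rdname grid-accessors
#' @export
setGeneric("boundaryMode", function(object) standardGeneric("boundaryMode"))

#' Total free energy of an EnergyBreakdown or Trajectory series
#'
#' @param object an [EnergyBreakdown-class].
#' @return scalar total energy (kBT units).
#' @export
setGeneric("totalEnergy", function(object) standardGeneric("totalEnergy"))

#' Components of an EnergyBreakdown as a named vector
#'
#' @param object an [EnergyBreakdown-class].
#' @return named numeric vector with one entry per energy term.
#' @export
setGeneric("energyComponents",
           function(object) standardGeneric("energyComponents"))

#' Trajectory accessors
#'
#' @param object a [Trajectory-class].
#' @return `finalState`/`initialState`: the [FieldState-class] at the end /
#'   start; `energySeries`: data.frame of recorded energies; `snapshots`:
#'   list of intermediate states.
#' @name trajectory-accessors
#' @export
setGeneric("finalState", function(object) standardGeneric("finalState"))

#' @rdname trajectory-accessors
#' @export
setGeneric("initialState", function(object) standardGeneric("initialState"))

#' @rdname trajectory-accessors
#' @export
setGeneric("energySeries", function(object) standardGeneric("energySeries"))

#' @rdname trajectory-accessors
#' @export
setGeneric("snapshots", function(object) standardGeneric("snapshots"))

#' Droplet accessors
#'
#' @param object a [DropletSet-class].
#' @return `dropletTable`: the per-droplet data.frame; `dropletCount`: the
#'   number of droplets.
#' @name droplet-accessors
#' @export
setGeneric("dropletTable", function(object) standardGeneric("dropletTable"))

#' @rdname droplet-accessors
#' @export
setGeneric("dropletCount", function(object) standardGeneric("dropletCount"))

#' Morphology accessors
#'
#' @param object a [MorphologyCall-class].
#' @return `regime`: the regime string; `morphologyEvidence`: the evidence
#'   list backing the call.
#' @name morphology-accessors
#' @export
setGeneric("regime", function(object) standardGeneric("regime"))

#' @rdname morphology-accessors
#' @export
setGeneric("morphologyEvidence",
           function(object) standardGeneric("morphologyEvidence"))

#' Analytic nuclear volume of an ellipsoidal geometry
#'
#' @param object a [NucleusGeometry-class].
#' @return \eqn{(4/3)\pi a b c} in cubic micrometers.
#' @export
setGeneric("nuclearVolume", function(object) standardGeneric("nuclearVolume"))
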