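#' @import methods
NULL

#' SimGrid: the discretized simulation domain
#'
#' A uniform Cartesian voxel grid over the rectangular domain
#' \eqn{\Omega = [0,L_x]\times[0,L_y]\times[0,L_z]}. Field values live at
#' voxel centers \eqn{x_i=(i-1/2)h_x} and all integrals are midpoint
#' (voxel-sum) quadrature.
#'
#' @slot shape integer(3), voxels per axis (nx, ny, nz).
#' @slot spacing numeric(3), voxel edge lengths in micrometers.
#' @slot extents numeric(3), domain lengths (Lx, Ly, Lz) in micrometers;
#'   `shape * spacing == extents` axis-wise.
#' @slot boundary either `"zero-flux"` (mirror/Neumann) or `"periodic"`;
#'   the contract every differential operator in the package honours.
#' @export
setClass("SimGrid", representation(
  shape = "integer",
  spacing = "numeric",
  extents = "numeric",
  boundary = "character"
))

setValidity("SimGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three positive integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three strictly positive lengths")
  if (length(object@extents) != 3L ||
      any(abs(object@shape * object@spacing - object@extents) >
          1e-9 * pmax(object@extents, 1)))
    msg <- c(msg, "shape * spacing must equal extents on every axis")
  if (!object@boundary %in% c("zero-flux", "periodic"))
    msg <- c(msg, "boundary must be 'zero-flux' or 'periodic'")
  if (length(msg)) msg else TRUE
})

#' FieldState: all order parameters at one instant
#'
#' Holds the N chromosomal-territory fields \eqn{\varphi_i}, the two
#' heterochromatin fields \eqn{\psi_1} (facultative, fHC) and \eqn{\psi_2}
#' (constitutive, cHC/chromocenter), and the static nucleus indicator
#' \eqn{\eta}. The euchromatin fraction is implicit
#' (\eqn{\psi_3 = 1-\psi_1-\psi_2}) and never stored. Fields are smooth
#' order parameters nominally in \[0, 1\]; Allen-Cahn dynamics does not
#' hard-bound them, so transient overshoot is tolerated.
#'
#' @slot phi list of N 3D arrays, one per chromosomal territory.
#' @slot psi1,psi2 3D arrays for the two heterochromatin subtypes.
#' @slot eta 3D array, time-independent nucleus indicator (0 inside the
#'   nucleus, 1 outside; the envelope is the 1/2-isocontour).
#' @slot time simulation time in dimensionless units.
#' @export
setClass("FieldState", representation(
  phi = "list",
  psi1 = "array",
  psi2 = "array",
  eta = "array",
  time = "numeric"
))

setValidity("FieldState", function(object) {
  msg <- character()
  d <- dim(object@eta)
  if (length(d) != 3L) msg <- c(msg, "fields must be 3D arrays")
  same <- function(a) identical(dim(a), d)
  if (!all(vapply(object@phi, same, logical(1))) ||
      !same(object@psi1) || !same(object@psi2))
    msg <- c(msg, "all fields must share the grid shape")
  allfin <- function(a) all(is.finite(a))
  if (!all(vapply(object@phi, allfin, logical(1))) ||
      !allfin(object@psi1) || !allfin(object@psi2) || !allfin(object@eta))
    msg <- c(msg, "fields contain non-finite values")
  if (length(object@time) != 1L) msg <- c(msg, "time must be scalar")
  if (length(msg)) msg else TRUE
})

#' ModelParameters: every coefficient of the free energy and dynamics
#'
#' Dimensionless parameters of the bulk functional (gradient coefficients,
#' multi-well depth, volume-constraint strengths a1..a4), the interaction
#' functional (envelope confinement beta0, CT-CT exclusion betaPhi, HC-HC
#' subtype exclusion betaPsi12, HC-outside-CT penalties betaPsi1/betaPsi2,
#' lamina adhesion gamma1/gamma2), mobilities, noise amplitudes, and the
#' prescribed compartment volumes. Lengths are micrometers; `lengthScale`
#' (um) and `timeScale` (s) convert dimensionless quantities to physical
#' units. Gradient coefficients are tied to diffusion coefficients through
#' D = L * eps^2 (see [epsilonFromDiffusion()]).
#'
#' @slot nChromosomes integer N, number of territory fields.
#' @slot epsPhi,epsPsi1,epsPsi2 interface-width (gradient) coefficients.
#' @slot LPhi,LPsi1,LPsi2 Allen-Cahn mobilities.
#' @slot a1,a2,a3,a4 volume-constraint coefficients (nucleus fill, CT
#'   volumes, fHC volumes, cHC volumes).
#' @slot beta0,betaPhi,betaPsi1,betaPsi2,betaPsi12 coupling strengths.
#' @slot gamma1,gamma2 lamina-adhesion strengths (0 = no adhesion).
#' @slot noiseAmp numeric(2), fluctuation amplitudes (A1, A2) for psi1, psi2.
#' @slot targetV,targetv,targetw length-N prescribed volumes (um^3) of each
#'   CT, its fHC content, and its cHC content.
#' @slot nuclearVolume nominal nuclear volume VN in um^3.
#' @slot lengthScale,timeScale characteristic length (um) and time (s).
#' @export
setClass("ModelParameters", representation(
  nChromosomes = "integer",
  epsPhi = "numeric", epsPsi1 = "numeric", epsPsi2 = "numeric",
  LPhi = "numeric", LPsi1 = "numeric", LPsi2 = "numeric",
  a1 = "numeric", a2 = "numeric", a3 = "numeric", a4 = "numeric",
  beta0 = "numeric", betaPhi = "numeric",
  betaPsi1 = "numeric", betaPsi2 = "numeric", betaPsi12 = "numeric",
  gamma1 = "numeric", gamma2 = "numeric",
  noiseAmp = "numeric",
  targetV = "numeric", targetv = "numeric", targetw = "numeric",
  nuclearVolume = "numeric",
  lengthScale = "numeric", timeScale = "numeric"
))

setValidity("ModelParameters", function(object) {
  msg <- character()
  nn <- c(epsPhi = object@epsPhi, epsPsi1 = object@epsPsi1,
          epsPsi2 = object@epsPsi2, LPhi = object@LPhi,
          LPsi1 = object@LPsi1, LPsi2 = object@LPsi2,
          a1 = object@a1, a2 = object@a2, a3 = object@a3, a4 = object@a4,
          beta0 = object@beta0, betaPhi = object@betaPhi,
          betaPsi1 = object@betaPsi1, betaPsi2 = object@betaPsi2,
          betaPsi12 = object@betaPsi12)
  if (any(nn < 0))
    msg <- c(msg, paste("negative coefficient:",
                        paste(names(nn)[nn < 0], collapse = ", ")))
  if (object@gamma1 < 0 || object@gamma2 < 0)
    msg <- c(msg, "adhesion strengths gamma1, gamma2 must be >= 0")
  if (length(object@noiseAmp) != 2L || any(object@noiseAmp < 0))
    msg <- c(msg, "noiseAmp must be two non-negative amplitudes (A1, A2)")
  N <- object@nChromosomes
  if (length(N) != 1L || N < 1L) msg <- c(msg, "nChromosomes must be >= 1")
  for (s in c("targetV", "targetv", "targetw")) {
    v <- slot(object, s)
    if (length(v) != N || any(v < 0))
      msg <- c(msg, sprintf("%s must be %d non-negative volumes", s, N))
  }
  if (object@lengthScale <= 0 || object@timeScale <= 0)
    msg <- c(msg, "lengthScale and timeScale must be positive")
  if (length(msg)) msg else TRUE
})

#' EnergyBreakdown: the free energy split into its terms
#'
#' Every component of the bulk functional FB (gradient, multi-well bulk,
#' four volume penalties) and the interaction functional FI (confinement,
#' CT exclusion, HC subtype exclusion, HC-outside-CT penalty, lamina
#' adhesion). All components are non-negative for non-negative coefficients
#' except the adhesion term, which is negative when heterochromatin wets
#' the envelope. `total` is their sum.
#'
#' @slot gradient,bulk numeric scalars (interfacial and multi-well energy).
#' @slot volumePenalty named numeric(4): the a1..a4 penalties.
#' @slot confinement,ctExclusion,hcExclusion,hcOutsideCt,adhesion scalars.
#' @slot total sum of all components.
#' @export
setClass("EnergyBreakdown", representation(
  gradient = "numeric", bulk = "numeric",
  volumePenalty = "numeric",
  confinement = "numeric", ctExclusion = "numeric",
  hcExclusion = "numeric", hcOutsideCt = "numeric",
  adhesion = "numeric", total = "numeric"
))

setValidity("EnergyBreakdown", function(object) {
  s <- object@gradient + object@bulk + sum(object@volumePenalty) +
    object@confinement + object@ctExclusion + object@hcExclusion +
    object@hcOutsideCt + object@adhesion
  scale <- max(abs(s), abs(object@total), 1)
  if (abs(s - object@total) > 1e-8 * scale)
    "total does not equal the sum of the components" else TRUE
})

#' NucleusGeometry: the fixed ellipsoidal nucleus
#'
#' Oblate ellipsoid with semiaxes (a, b, c) along (x, y, z); the nuclear
#' envelope is the smooth 1/2-isocontour of the indicator field eta. The
#' interface width is controlled by `epsEta` in the normalized ellipsoidal
#' coordinate (see [buildNucleusIndicator()]).
#'
#' @slot semiaxes numeric(3), (a, b, c) in micrometers.
#' @slot center numeric(3), ellipsoid center in micrometers.
#' @slot epsEta envelope interface-width parameter (dimensionless).
#' @export
setClass("NucleusGeometry", representation(
  semiaxes = "numeric", center = "numeric", epsEta = "numeric"
))

setValidity("NucleusGeometry", function(object) {
  msg <- character()
  if (length(object@semiaxes) != 3L || any(object@semiaxes <= 0))
    msg <- c(msg, "semiaxes must be three positive lengths")
  if (length(object@center) != 3L) msg <- c(msg, "center must be length 3")
  if (object@epsEta <= 0) msg <- c(msg, "epsEta must be positive")
  if (length(msg)) msg else TRUE
})

#' SeedLayout: initial positions and sizes of territories and HC cores
#'
#' @slot ctCenters N x 3 matrix of territory seed centers (um).
#' @slot ctRadius initial territory sphere radius (um).
#' @slot fhcRadius,chcRadius initial fHC / cHC core radii (um); the cHC core
#'   is a central sphere and the fHC seed the concentric shell around it, so
#'   psi1 + psi2 <= 1 by construction.
#' @slot hcFraction target heterochromatin volume fraction of the nucleus.
#' @slot fhcShare fraction of the heterochromatin volume assigned to fHC.
#' @export
setClass("SeedLayout", representation(
  ctCenters = "matrix",
  ctRadius = "numeric",
  fhcRadius = "numeric",
  chcRadius = "numeric",
  hcFraction = "numeric",
  fhcShare = "numeric"
))

setValidity("SeedLayout", function(object) {
  msg <- character()
  if (ncol(object@ctCenters) != 3L)
    msg <- c(msg, "ctCenters must be an N x 3 matrix")
  if (object@ctRadius <= 0) msg <- c(msg, "ctRadius must be positive")
  if (object@fhcRadius < 0 || object@chcRadius < 0)
    msg <- c(msg, "core radii must be non-negative")
  if (object@hcFraction < 0 || object@hcFraction > 1)
    msg <- c(msg, "hcFraction must lie in [0, 1]")
  if (object@fhcShare < 0 || object@fhcShare > 1)
    msg <- c(msg, "fhcShare must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' IntegratorConfig: time-stepping controls
#'
#' @slot dt dimensionless time step (default 0.04).
#' @slot nSteps number of steps to integrate.
#' @slot scheme `"semi-implicit-spectral"` (stabilized IMEX, diffusion
#'   solved spectrally under the grid's boundary contract) or
#'   `"explicit-euler"`.
#' @slot rngSeed integer seed; noise-on trajectories are bitwise
#'   reproducible given the seed.
#' @slot snapshotEvery keep/write a snapshot every this many steps
#'   (0 = none beyond initial and final).
#' @slot energyEvery record the energy breakdown every this many steps.
#' @slot noiseOn logical; interfacial white noise on the psi fields.
#' @slot stabilization `NA` for the automatic per-step Lipschitz bound, or
#'   an explicit non-negative constant.
#' @slot maxHalvings blowup retries: a non-finite step is re-attempted with
#'   halved dt (substeps) at most this many times before erroring.
#' @export
setClass("IntegratorConfig", representation(
  dt = "numeric", nSteps = "integer", scheme = "character",
  rngSeed = "integer", snapshotEvery = "integer", energyEvery = "integer",
  noiseOn = "logical", stabilization = "numeric", maxHalvings = "integer"
))

setValidity("IntegratorConfig", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@nSteps < 0L) msg <- c(msg, "nSteps must be >= 0")
  if (!object@scheme %in% c("semi-implicit-spectral", "explicit-euler"))
    msg <- c(msg, "unknown scheme")
  if (object@snapshotEvery < 0L || object@energyEvery < 1L)
    msg <- c(msg, "snapshotEvery must be >= 0 and energyEvery >= 1")
  if (!is.na(object@stabilization) && object@stabilization < 0)
    msg <- c(msg, "stabilization must be NA (auto) or >= 0")
  if (object@maxHalvings < 0L) msg <- c(msg, "maxHalvings must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Trajectory: the result of a simulation run
#'
#' @slot initial,final FieldState at the start and end of the run.
#' @slot snapshots list of intermediate FieldState objects (possibly empty).
#' @slot energies data.frame with one row per recorded step: step, time,
#'   every EnergyBreakdown component, and total.
#' @slot diagnostics list: wall-clock seconds, steps taken, dt halvings.
#' @export
setClass("Trajectory", representation(
  initial = "FieldState", final = "FieldState",
  snapshots = "list", energies = "data.frame", diagnostics = "list"
))

#' DropletSet: labeled connected heterochromatin compartments
#'
#' One row per connected component of the thresholded field, with voxel
#' count, volume (voxel-sum), triangulated isosurface area, field-weighted
#' centroid, sphericity, owning chromosome, and the number of territories
#' the droplet spans.
#'
#' @slot table data.frame of per-droplet metrics.
#' @slot labelArray integer 3D array, 0 outside droplets.
#' @slot threshold the level-set threshold used (default 0.5).
#' @slot subtype `"fHC"`, `"cHC"`, or `"HC"` label for provenance.
#' @export
setClass("DropletSet", representation(
  table = "data.frame", labelArray = "array",
  threshold = "numeric", subtype = "character"
))

setValidity("DropletSet", function(object) {
  tb <- object@table
  msg <- character()
  if (nrow(tb) && any(tb$volume <= 0))
    msg <- c(msg, "droplet volumes must be positive")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' RadialProfile: mean field density along a named nuclear axis
#'
#' @slot axis `"major"` (y, semiaxis b), `"minor"` (x, semiaxis a), or
#'   `"z"` (semiaxis c).
#' @slot binCenters distances from the nuclear center in micrometers.
#' @slot density mean field value per bin.
#' @slot fieldName which field was profiled.
#' @slot cylinderRadius radius (um) of the sampling cylinder around the axis.
#' @export
setClass("RadialProfile", representation(
  axis = "character", binCenters = "numeric", density = "numeric",
  fieldName = "character", cylinderRadius = "numeric"
))

#' MorphologyCall: regime classification of a final architecture
#'
#' @slot regime one of `"disconnected-within-CT"`, `"connected-interior"`,
#'   `"connected-across-boundaries"`, or `NA` for a degenerate state.
#' @slot evidence list: droplet count, count of droplets spanning several
#'   territories, central volume fraction, mean normalized centroid radius.
#' @export
setClass("MorphologyCall", representation(
  regime = "character", evidence = "list"
))

#' RunConfig: a fully resolved simulation configuration
#'
#' Bundles grid, geometry, seed layout, model parameters, integrator
#' settings and output options under a named preset. Built by
#' [runConfig()] or parsed from JSON by [loadConfig()].
#'
#' @slot preset `"two-component-conventional"`, `"two-component-adhesive"`,
#'   or `"three-component"`.
#' @slot grid,geometry,layout,params,integrator the component objects.
#' @slot output list: `dir` (or NA), `formats` (e.g. "rds", "vti").
#' @export
setClass("RunConfig", representation(
  preset = "character",
  grid = "SimGrid", geometry = "NucleusGeometry", layout = "SeedLayout",
  params = "ModelParameters", integrator = "IntegratorConfig",
  output = "list"
))

#' SweepPlan: a parameter sweep over coupling strengths
#'
#' The Cartesian product of the swept value lists defines the run set;
#' every (grid point, replicate) gets a distinct deterministic seed derived
#' from the plan seed.
#'
#' @slot base RunConfig used for every run.
#' @slot sweep named list of numeric vectors; names are ModelParameters
#'   slots (e.g. `betaPhi`, `betaPsi1`).
#' @slot replicates number of replicates per grid point.
#' @slot seed plan-level integer seed.
#' @export
setClass("SweepPlan", representation(
  base = "RunConfig", sweep = "list", replicates = "integer",
  seed = "integer"
))

setValidity("SweepPlan", function(object) {
  msg <- character()
  if (!length(object@sweep) || is.null(names(object@sweep)) ||
      any(!nzchar(names(object@sweep))))
    msg <- c(msg, "sweep must be a named list of value vectors")
  bad <- setdiff(names(object@sweep), slotNames("ModelParameters"))
  if (length(bad))
    msg <- c(msg, paste("unknown swept parameter(s):",
                        paste(bad, collapse = ", ")))
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (length(msg)) msg else TRUE
})
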