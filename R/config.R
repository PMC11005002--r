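#' @include dynamics.R
NULL

.presets <- c("two-component-conventional", "two-component-adhesive",
              "three-component")

# Preset contract: two-component runs must not switch on the cHC channel
# or its adhesion; the conventional preset has no adhesion at all.
.checkPresetContract <- function(preset, params) {
  if (startsWith(preset, "two-component")) {
    if (params@betaPsi2 != 0 || params@betaPsi12 != 0 ||
        params@gamma2 != 0 || any(params@targetw != 0))
      stop("preset '", preset, "' is a two-component model: betaPsi2, ",
           "betaPsi12, gamma2 and the cHC target volumes must be zero")
  }
  if (preset == "two-component-conventional" && params@gamma1 != 0)
    stop("preset 'two-component-conventional' has no lamina adhesion; ",
         "use 'two-component-adhesive' for gamma1 > 0")
  invisible(TRUE)
}

#' Build a fully resolved run configuration
#'
#' Bundles grid, geometry, seed layout, model parameters and integrator
#' settings, pre-filled with the reference parametrization of each
#' preset. The default mesh is the full 180 x 225 x 90 discretization of
#' the 6 x 9 x 3 um domain; `meshDivisor` scales it down linearly for
#' reduced-resolution work (e.g. 4 gives the quarter-resolution mesh).
#'
#' @param preset `"two-component-conventional"`,
#'   `"two-component-adhesive"`, or `"three-component"`.
#' @param meshDivisor linear mesh reduction factor (default 1 = full).
#' @param boundary grid boundary contract.
#' @param dt,nSteps,scheme,rngSeed,snapshotEvery,energyEvery,noiseOn,
#'   stabilization,maxHalvings integrator settings, see
#'   [integratorConfig()].
#' @param epsEta envelope width parameter, see [nucleusGeometry()].
#' @param hcFraction heterochromatin volume fraction (default 0.25).
#' @param outputDir output directory or `NA`.
#' @param formats snapshot formats, subset of `c("rds", "vti")`.
#' @param parameters named list of [ModelParameters-class] slot overrides.
#' @return a [RunConfig-class].
#' @examples
#' cfg <- runConfig("two-component-conventional", meshDivisor = 8)
#' cfg@params@betaPhi  # 40
#' @export
runConfig <- function(preset = .presets, meshDivisor = 1,
                      boundary = "zero-flux",
                      dt = 0.04, nSteps = 500L,
                      scheme = "semi-implicit-spectral",
                      rngSeed = 1L, snapshotEvery = 0L, energyEvery = 1L,
                      noiseOn = TRUE, stabilization = NA_real_,
                      maxHalvings = 2L,
                      epsEta = 0.04, hcFraction = 0.25,
                      outputDir = NA_character_, formats = "rds",
                      parameters = list()) {
  preset <- match.arg(preset)
  shape <- as.integer(round(c(180L, 225L, 90L) / meshDivisor))
  grid <- simGrid(shape, extents = c(6, 9, 3), boundary = boundary)
  geom <- nucleusGeometry(epsEta = epsEta)
  fhcShare <- if (preset == "three-component") 0.5 else 1
  layout <- seedLayout(geom, hcFraction = hcFraction, fhcShare = fhcShare)
  params <- do.call(modelParameters,
                    c(list(preset = preset, hcFraction = hcFraction),
                      parameters))
  .checkPresetContract(preset, params)
  integ <- integratorConfig(dt = dt, nSteps = nSteps, scheme = scheme,
                            rngSeed = rngSeed,
                            snapshotEvery = snapshotEvery,
                            energyEvery = energyEvery, noiseOn = noiseOn,
                            stabilization = stabilization,
                            maxHalvings = maxHalvings)
  new("RunConfig", preset = preset, grid = grid, geometry = geom,
      layout = layout, params = params, integrator = integ,
      output = list(dir = outputDir, formats = formats))
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: preset '%s'\n", object@preset))
  show(object@grid)
  show(object@params)
})

.configToList <- function(cfg) {
  p <- cfg@params
  list(
    preset = cfg@preset,
    grid = list(shape = cfg@grid@shape, extents = cfg@grid@extents,
                boundary = cfg@grid@boundary),
    geometry = list(semiaxes = cfg@geometry@semiaxes,
                    center = cfg@geometry@center,
                    epsEta = cfg@geometry@epsEta),
    seeds = list(centers = unname(apply(cfg@layout@ctCenters, 1, c,
                                        simplify = FALSE)),
                 ctRadius = cfg@layout@ctRadius,
                 fhcRadius = cfg@layout@fhcRadius,
                 chcRadius = cfg@layout@chcRadius,
                 hcFraction = cfg@layout@hcFraction,
                 fhcShare = cfg@layout@fhcShare),
    parameters = stats::setNames(
      lapply(slotNames("ModelParameters"), function(s) slot(p, s)),
      slotNames("ModelParameters")),
    integrator = list(dt = cfg@integrator@dt, nSteps = cfg@integrator@nSteps,
                      scheme = cfg@integrator@scheme,
                      rngSeed = cfg@integrator@rngSeed,
                      snapshotEvery = cfg@integrator@snapshotEvery,
                      energyEvery = cfg@integrator@energyEvery,
                      noiseOn = cfg@integrator@noiseOn,
                      stabilization = cfg@integrator@stabilization,
                      maxHalvings = cfg@integrator@maxHalvings),
    output = cfg@output)
}

#' Write a resolved configuration to JSON
#'
#' @param cfg a [RunConfig-class].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(cfg, path) {
  jsonlite::write_json(.configToList(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Load and validate a configuration file
#'
#' Reads the JSON key-value format written by [writeConfig()]. Every
#' field has a preset default, so an empty object with just a `preset`
#' key resolves to the full reference parameter set. Unknown keys are
#' rejected (typo safety), and preset contracts are enforced (e.g. a
#' two-component preset with a nonzero `gamma2` is a validation error).
#'
#' @param path JSON configuration file.
#' @return a fully resolved [RunConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("preset", "grid", "geometry", "seeds", "parameters",
             "integrator", "output")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  checkKeys <- function(section, allowed) {
    extra <- setdiff(names(raw[[section]]), allowed)
    if (length(extra))
      stop("unknown key(s) in '", section, "': ",
           paste(extra, collapse = ", "))
  }
  checkKeys("grid", c("shape", "extents", "boundary"))
  checkKeys("geometry", c("semiaxes", "center", "epsEta"))
  checkKeys("seeds", c("centers", "ctRadius", "fhcRadius", "chcRadius",
                       "hcFraction", "fhcShare"))
  checkKeys("parameters", slotNames("ModelParameters"))
  checkKeys("integrator", c("dt", "nSteps", "scheme", "rngSeed",
                            "snapshotEvery", "energyEvery", "noiseOn",
                            "stabilization", "maxHalvings"))
  checkKeys("output", c("dir", "formats"))

  preset <- if (is.null(raw$preset)) .presets[1] else raw$preset
  if (!preset %in% .presets)
    stop("unknown preset '", preset, "'")
  cfg <- runConfig(preset = preset)

  g <- raw$grid
  if (!is.null(g)) {
    shape <- if (is.null(g$shape)) cfg@grid@shape else as.integer(g$shape)
    extents <- if (is.null(g$extents)) cfg@grid@extents else g$extents
    boundary <- if (is.null(g$boundary)) cfg@grid@boundary else g$boundary
    cfg@grid <- simGrid(shape, extents = extents, boundary = boundary)
  }
  ge <- raw$geometry
  if (!is.null(ge)) {
    cfg@geometry <- nucleusGeometry(
      semiaxes = if (is.null(ge$semiaxes)) cfg@geometry@semiaxes else ge$semiaxes,
      center = if (is.null(ge$center)) cfg@geometry@center else ge$center,
      epsEta = if (is.null(ge$epsEta)) cfg@geometry@epsEta else ge$epsEta)
  }
  se <- raw$seeds
  if (!is.null(se)) {
    centers <- if (is.null(se$centers)) cfg@layout@ctCenters else {
      m <- if (is.matrix(se$centers)) se$centers
           else do.call(rbind, lapply(se$centers, as.numeric))
      m <- matrix(as.numeric(m), ncol = 3)
      colnames(m) <- c("x", "y", "z"); m
    }
    lay <- seedLayout(
      cfg@geometry, ctCenters = centers,
      hcFraction = if (is.null(se$hcFraction)) cfg@layout@hcFraction else se$hcFraction,
      fhcShare = if (is.null(se$fhcShare)) cfg@layout@fhcShare else se$fhcShare,
      ctRadius = se$ctRadius)
    if (!is.null(se$fhcRadius)) lay@fhcRadius <- se$fhcRadius
    if (!is.null(se$chcRadius)) lay@chcRadius <- se$chcRadius
    cfg@layout <- lay
  }
  pa <- raw$parameters
  if (!is.null(pa) && length(pa)) {
    for (nm in names(pa)) {
      v <- pa[[nm]]
      if (nm == "nChromosomes") v <- as.integer(v)
      slot(cfg@params, nm) <- v
    }
    validObject(cfg@params)
  }
  it <- raw$integrator
  if (!is.null(it)) {
    old <- cfg@integrator
    pick <- function(key, def) if (is.null(it[[key]])) def else it[[key]]
    cfg@integrator <- integratorConfig(
      dt = pick("dt", old@dt), nSteps = pick("nSteps", old@nSteps),
      scheme = pick("scheme", old@scheme),
      rngSeed = pick("rngSeed", old@rngSeed),
      snapshotEvery = pick("snapshotEvery", old@snapshotEvery),
      energyEvery = pick("energyEvery", old@energyEvery),
      noiseOn = pick("noiseOn", old@noiseOn),
      stabilization = pick("stabilization", old@stabilization),
      maxHalvings = pick("maxHalvings", old@maxHalvings))
  }
  if (!is.null(raw$output)) {
    cfg@output$dir <- if (is.null(raw$output$dir)) NA_character_ else raw$output$dir
    if (!is.null(raw$output$formats)) cfg@output$formats <- raw$output$formats
  }
  .checkPresetContract(cfg@preset, cfg@params)
  validObject(cfg)
  cfg
}

#' Run a simulation from a configuration
#'
#' Seeds the initial state, runs the dynamics, and (when an output
#' directory is configured) writes the resolved configuration echo, the
#' energy log, and snapshots there — enough provenance to reproduce the
#' run bit for bit.
#'
#' @param cfg a [RunConfig-class].
#' @return a [Trajectory-class].
#' @export
runFromConfig <- function(cfg) {
  state <- seedInitialState(cfg@grid, cfg@geometry, cfg@layout, cfg@params)
  outDir <- cfg@output$dir
  if (is.na(outDir)) outDir <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeConfig(cfg, file.path(outDir, "config.json"))
    writeLines(c(paste("package:", as.character(utils::packageVersion("nucphase"))),
                 paste("rngSeed:", cfg@integrator@rngSeed)),
               file.path(outDir, "provenance.txt"))
  }
  runSimulation(state, cfg@params, cfg@grid, cfg@integrator,
                outputDir = outDir)
}
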