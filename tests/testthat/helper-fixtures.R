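# Shared fixtures: tiny grids, coupling-free parameter sets, and random
# states. Everything is generated in code at test time.

tinyGrid <- function(shape = c(10L, 8L, 9L), extents = c(2.5, 2, 2.25),
                     boundary = "zero-flux") {
  simGrid(as.integer(shape), extents = extents, boundary = boundary)
}

# all couplings and constraints off; N territories
paramsOff <- function(N = 2L, ...) {
  modelParameters(nChromosomes = N, a1 = 0, a2 = 0, a3 = 0, a4 = 0,
                  beta0 = 0, betaPhi = 0, betaPsi1 = 0, betaPsi2 = 0,
                  betaPsi12 = 0, gamma1 = 0, gamma2 = 0,
                  targetV = rep(1, N), targetv = rep(0.3, N),
                  targetw = rep(0.1, N), ...)
}

# random smooth-ish state with an ellipsoid eta inside the tiny grid
randState <- function(grid, N = 2L, seed = 1) {
  set.seed(seed)
  mk <- function() array(runif(prod(gridShape(grid)), 0.05, 0.95),
                         dim = gridShape(grid))
  ext <- gridExtents(grid)
  geom <- nucleusGeometry(semiaxes = ext * 0.3, center = ext / 2,
                          epsEta = 0.1)
  fieldState(phi = replicate(N, mk(), simplify = FALSE),
             psi1 = mk(), psi2 = mk(),
             eta = buildNucleusIndicator(grid, geom))
}

uniformState <- function(grid, N = 1L, value = 0) {
  z <- array(value, dim = gridShape(grid))
  fieldState(phi = replicate(N, z, simplify = FALSE), psi1 = z, psi2 = z,
             eta = z)
}

quietSeedState <- function(cfg) {
  suppressWarnings(seedInitialState(cfg@grid, cfg@geometry, cfg@layout,
                                    cfg@params))
}

quietRun <- function(cfg) suppressWarnings(runFromConfig(cfg))
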