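# time stepping: fixed points, determinism, noise statistics, gradient flow

test_that("a uniform bulk minimum is a fixed point with everything off", {
  g <- tinyGrid(shape = c(12L, 10L, 8L), extents = c(1.2, 1, 0.8))
  st <- uniformState(g, N = 2, value = 0)
  p <- paramsOff(2L, targetV = rep(0, 2), targetv = rep(0, 2),
                 targetw = rep(0, 2))
  for (scheme in c("semi-implicit-spectral", "explicit-euler")) {
    out <- stepState(st, p, g,
                     integratorConfig(dt = 0.01, scheme = scheme,
                                      noiseOn = FALSE))
    expect_equal(out@phi[[1]], st@phi[[1]], tolerance = 1e-14)
    expect_equal(out@psi1, st@psi1, tolerance = 1e-14)
  }
})

test_that("trajectories are bitwise reproducible given the rng seed", {
  cfg <- runConfig("two-component-conventional", meshDivisor = 10,
                   nSteps = 4L, noiseOn = TRUE, rngSeed = 99L,
                   parameters = list(noiseAmp = c(0.01, 0.01)))
  t1 <- quietRun(cfg)
  t2 <- quietRun(cfg)
  expect_identical(finalState(t1)@psi1, finalState(t2)@psi1)
  expect_identical(finalState(t1)@phi[[3]], finalState(t2)@phi[[3]])
  cfg@integrator@rngSeed <- 100L
  t3 <- quietRun(cfg)
  expect_false(identical(finalState(t1)@psi1, finalState(t3)@psi1))
})

test_that("nSteps = 0 returns a trajectory holding only the initial state", {
  cfg <- runConfig("two-component-conventional", meshDivisor = 10,
                   nSteps = 0L, noiseOn = FALSE)
  tr <- quietRun(cfg)
  expect_identical(finalState(tr)@psi1, initialState(tr)@psi1)
  expect_equal(nrow(energySeries(tr)), 1L)
  expect_length(snapshots(tr), 0L)
})

test_that("pure-noise increments have the white-noise variance scaling", {
  g <- simGrid(c(24L, 24L, 24L), extents = c(6, 6, 6))
  p <- modelParameters(nChromosomes = 1L, LPhi = 0, LPsi1 = 0, LPsi2 = 0,
                       noiseAmp = c(5, 5), targetV = 1, targetv = 0.3,
                       targetw = 0.1)
  st <- uniformState(g, N = 1, value = 0.5)
  set.seed(123)
  out <- stepState(st, p, g, integratorConfig(dt = 0.04, noiseOn = TRUE))
  inc <- as.vector(out@psi1 - 0.5)
  n <- length(inc)
  expect_gte(n, 1e4)
  vex <- 5 * 0.04 / voxelVolume(g)
  se <- vex * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(inc) - vex), 3 * se)
  # noise never touches the territory fields
  expect_identical(out@phi[[1]], st@phi[[1]])
})

test_that("noise-off dynamics descends the free energy (gradient flow)", {
  cfg <- runConfig("two-component-conventional", meshDivisor = 10,
                   nSteps = 40L, noiseOn = FALSE, energyEvery = 1L)
  tr <- quietRun(cfg)
  e <- energySeries(tr)$total
  expect_true(all(diff(e) <= 1e-10 * pmax(abs(e[-length(e)]), 1)))
})

test_that("soft exclusion keeps psi1 + psi2 within bounds in the ternary preset", {
  cfg <- runConfig("three-component", meshDivisor = 10, nSteps = 60L,
                   noiseOn = FALSE, energyEvery = 20L)
  tr <- quietRun(cfg)
  fs <- finalState(tr)
  expect_lte(max(fs@psi1 + fs@psi2), 1 + 0.05)
  expect_gte(min(fs@psi1), -0.05)
})

test_that("the explicit scheme warns outside its stability bound", {
  g <- simGrid(c(12L, 12L, 12L), spacing = 0.05)  # bound ~ 0.004 << 0.04
  st <- uniformState(g, N = 1, value = 0)
  p <- paramsOff(1L)
  cfgE <- integratorConfig(dt = 0.04, nSteps = 0L,
                           scheme = "explicit-euler", noiseOn = FALSE)
  expect_warning(runSimulation(st, p, g, cfgE), "stability bound")
  cfgOk <- integratorConfig(dt = 0.001, nSteps = 0L,
                            scheme = "explicit-euler", noiseOn = FALSE)
  expect_no_warning(runSimulation(st, p, g, cfgOk))
})
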