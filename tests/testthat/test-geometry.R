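# nucleus indicator, seed layout, and initial-state construction

test_that("analytic nuclear volume matches the reference ellipsoid", {
  geom <- nucleusGeometry()
  expect_equal(round(nuclearVolume(geom), 2), 50.27)  # (4/3) pi 2.5*4*1.2
})

test_that("nucleus indicator has the right plateaus and 1/2-isocontour", {
  g <- simGrid(c(48L, 72L, 24L), extents = c(6, 9, 3))
  geom <- nucleusGeometry()
  eta <- buildNucleusIndicator(g, geom)
  cc <- axisCoords(g)
  near <- function(v, x) which.min(abs(v - x))
  # center: interior plateau (0 by convention)
  expect_lt(eta[near(cc$x, 3), near(cc$y, 4.5), near(cc$z, 1.5)], 1e-6)
  # domain corner: exterior plateau (1)
  expect_gt(eta[1, 1, 1], 1 - 1e-6)
  # exactly sampled surface point: eta = 1/2 on the isocontour
  g2 <- simGrid(c(11L, 9L, 5L), extents = c(5.5, 9, 3))
  geom2 <- nucleusGeometry(center = c(2.75, 4.5, 1.5),
                           semiaxes = c(2.5, 4, 1.2), epsEta = 0.02)
  eta2 <- buildNucleusIndicator(g2, geom2)
  expect_equal(eta2[11, 5, 3], 0.5, tolerance = 1e-9)  # x = 5.25 = c + a
  expect_error(buildNucleusIndicator(
    simGrid(c(16L, 16L, 16L), extents = c(5, 9, 3)), geom), "fit")
})

test_that("indicator volume quadrature and mirror symmetry hold", {
  g <- simGrid(c(48L, 72L, 24L), extents = c(6, 9, 3))
  geom <- nucleusGeometry()
  eta <- buildNucleusIndicator(g, geom)
  vq <- sum(interpolationH(1 - eta)) * voxelVolume(g)
  expect_equal(vq, nuclearVolume(geom), tolerance = 0.02)
  # reflecting the geometry across x reflects eta exactly
  geomR <- nucleusGeometry(center = c(6 - 3, 4.5, 1.5))
  etaR <- buildNucleusIndicator(g, geomR)
  expect_equal(etaR, eta[rev(seq_len(48)), , ], tolerance = 1e-14)
})

test_that("seed layout solves radii from the prescribed volumes", {
  geom <- nucleusGeometry()
  lay <- seedLayout(geom)
  VN <- nuclearVolume(geom)
  expect_equal(4 / 3 * pi * lay@ctRadius^3, VN / 8)
  expect_equal(4 / 3 * pi * lay@fhcRadius^3, 0.25 * VN / 8)
  expect_equal(lay@chcRadius, 0)
  lay3 <- seedLayout(geom, fhcShare = 0.5)
  expect_equal(4 / 3 * pi * lay3@chcRadius^3, 0.125 * VN / 8)
  expect_equal(nrow(defaultSeedCoordinates()), 8)
})

test_that("seeded state honours the heterochromatin fraction and core structure", {
  cfg <- runConfig("two-component-conventional", meshDivisor = 6,
                   noiseOn = FALSE)
  st <- quietSeedState(cfg)
  g <- cfg@grid
  expect_length(st@phi, 8)
  vols <- compartmentVolumes(st, g)
  VN <- cfg@params@nuclearVolume
  # total seeded HC volume ~ 25% of VN within 10%
  hc <- sum(vols$v) + sum(vols$w)
  expect_equal(hc / VN, 0.25, tolerance = 0.10)
  expect_true(max(st@psi1 + st@psi2) <= 1 + 1e-6)
  # every territory contains one HC core at its center
  X <- cfg@layout@ctCenters
  h <- gridSpacing(g)
  # tanh cores with the family interface width (2*sqrt(2)*eps ~ 0.9 um)
  # plateau below 1 at these seed radii; assert dominance, not saturation
  for (i in seq_len(8)) {
    vox <- pmax(pmin(round(X[i, ] / h + 0.5), gridShape(g)), 1)
    expect_gt(st@phi[[i]][vox[1], vox[2], vox[3]], 0.85)
    expect_gt(st@psi1[vox[1], vox[2], vox[3]], 0.75)
  }
  # three-component preset: cHC core inside the fHC shell
  cfg3 <- runConfig("three-component", meshDivisor = 6, noiseOn = FALSE)
  st3 <- quietSeedState(cfg3)
  vox <- pmax(pmin(round(X[1, ] / gridSpacing(cfg3@grid) + 0.5),
                   gridShape(cfg3@grid)), 1)
  expect_gt(st3@psi2[vox[1], vox[2], vox[3]], 0.6)
  expect_lt(st3@psi1[vox[1], vox[2], vox[3]], 0.5)  # fHC is the shell
  # neighbouring seed tails may overlap by a few percent at most
  expect_true(max(st3@psi1 + st3@psi2) <= 1.05)
})

test_that("hcFraction = 0 seeds no heterochromatin", {
  cfg <- runConfig("two-component-conventional", meshDivisor = 8,
                   hcFraction = 0, noiseOn = FALSE)
  st <- quietSeedState(cfg)
  expect_true(all(st@psi1 == 0) && all(st@psi2 == 0))
})

test_that("a single centered territory reproduces the analytic sphere volume", {
  g <- simGrid(c(40L, 40L, 40L), extents = c(4, 4, 4))
  geom <- nucleusGeometry(semiaxes = c(1.8, 1.8, 1.8), center = c(2, 2, 2),
                          epsEta = 0.02)
  r <- 0.8  # spacing 0.1 = r/8
  lay <- seedLayout(geom, ctCenters = matrix(c(2, 2, 2), 1), ctRadius = r,
                    hcFraction = 0)
  # a sharp interface (width << r) so the smeared-profile volume reduces
  # to the analytic ball volume
  p <- modelParameters(nChromosomes = 1L, targetV = 1, targetv = 0,
                       targetw = 0, epsPhi = 0.05)
  st <- seedInitialState(g, geom, lay, p)
  V1 <- compartmentVolumes(st, g)$V
  expect_equal(V1, 4 / 3 * pi * r^3, tolerance = 0.05)
})

test_that("dynamics never mutates the nucleus indicator", {
  cfg <- runConfig("two-component-conventional", meshDivisor = 10,
                   nSteps = 3L, noiseOn = FALSE)
  st <- quietSeedState(cfg)
  out <- stepState(st, cfg@params, cfg@grid, cfg@integrator)
  expect_identical(out@eta, st@eta)
})
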