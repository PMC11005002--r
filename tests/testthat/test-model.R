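# model core: interpolation polynomial, bulk density, compartment
# volumes, free-energy breakdown, and the derivative/energy consistency
# that everything else rests on.

test_that("interpolation polynomial pins the bulk minima", {
  expect_equal(interpolationH(0), 0)
  expect_equal(interpolationH(1), 1)
  expect_equal(interpolationH(0.5), 0.5)  # 0.125 * (10 - 7.5 + 1.5)
  expect_equal(interpolationHPrime(0), 0)
  expect_equal(interpolationHPrime(1), 0)
  # numeric derivative agreement away from the endpoints
  x <- seq(-0.2, 1.2, by = 0.1)
  h <- 1e-6
  expect_equal(interpolationHPrime(x),
               (interpolationH(x + h) - interpolationH(x - h)) / (2 * h),
               tolerance = 1e-6)
})

test_that("bulk density is a non-negative multi-well with zeros only at pure phases", {
  g <- tinyGrid()
  st0 <- uniformState(g, N = 2, value = 0)
  expect_true(all(bulkDensity(st0) == 0))
  st1 <- uniformState(g, N = 2, value = 1)
  expect_true(all(abs(bulkDensity(st1)) < 1e-14))
  sth <- uniformState(g, N = 1, value = 0)
  sth@psi1[] <- 0.5
  expect_equal(unique(as.vector(bulkDensity(sth))), 0.015625)
  # property: non-negative and zero iff all fields in {0, 1}
  for (seed in 1:3) {
    st <- randState(g, seed = seed)
    bd <- bulkDensity(st)
    expect_true(all(bd >= 0))
    expect_true(all(bd > 0))  # random fields are never at a pure phase
  }
})

test_that("compartment volumes integrate the interpolated occupancy", {
  g <- simGrid(c(12L, 18L, 6L), extents = c(6, 9, 3))
  one <- array(1, dim = gridShape(g))
  zero <- array(0, dim = gridShape(g))
  st <- fieldState(phi = list(one), psi1 = zero, psi2 = zero, eta = zero)
  vols <- compartmentVolumes(st, g)
  expect_equal(vols$V, 162)           # h(1) = 1 times the 6 x 9 x 3 domain
  expect_equal(vols$v, 0)
  st@psi1[] <- 0.5
  expect_equal(compartmentVolumes(st, g)$v, 81)  # h(0.5) = 0.5
  st0 <- fieldState(phi = list(zero), psi1 = zero, psi2 = zero, eta = zero)
  v0 <- compartmentVolumes(st0, g)
  expect_equal(v0$V, 0); expect_equal(v0$v, 0); expect_equal(v0$w, 0)
  # v_i <= V_i and w_i <= V_i for fields within [0, 1]
  st2 <- randState(g, N = 2, seed = 4)
  v2 <- compartmentVolumes(st2, g)
  expect_true(all(v2$v <= v2$V + 1e-9))
  expect_true(all(v2$w <= v2$V + 1e-9))
})

test_that("free energy splits into consistent, sign-correct components", {
  g <- tinyGrid()
  st <- randState(g, N = 2, seed = 7)
  p <- modelParameters(nChromosomes = 2L, targetV = c(1, 2),
                       targetv = c(0.3, 0.2), targetw = c(0.1, 0.15),
                       betaPsi2 = 0.5, betaPsi12 = 4.5, gamma1 = 5,
                       gamma2 = 3)
  eb <- freeEnergy(st, p, g)
  comps <- energyComponents(eb)
  expect_equal(sum(comps), totalEnergy(eb))
  nonneg <- setdiff(names(comps), "adhesion")
  expect_true(all(comps[nonneg] >= 0))
  # switching a coefficient off removes its component exactly
  p0 <- p; p0@betaPhi <- 0
  expect_equal(energyComponents(freeEnergy(st, p0, g))[["ctExclusion"]], 0)
  p0 <- p; p0@gamma1 <- 0; p0@gamma2 <- 0
  expect_equal(energyComponents(freeEnergy(st, p0, g))[["adhesion"]], 0)
  p0 <- p; p0@betaPsi12 <- 0
  expect_equal(energyComponents(freeEnergy(st, p0, g))[["hcExclusion"]], 0)
  # all-zero fields with all constraints off: total is exactly zero
  z <- uniformState(g, N = 2, value = 0)
  expect_equal(totalEnergy(freeEnergy(z, paramsOff(2L,
    targetV = rep(0, 2), targetv = rep(0, 2), targetw = rep(0, 2)), g)), 0)
  expect_error(freeEnergy(uniformState(tinyGrid(c(4L, 4L, 4L),
    extents = c(1, 1, 1))), p, g), "shape")
})

test_that("adhesion energy is confined to the overlap of the eta and psi interfaces", {
  g <- simGrid(c(24L, 16L, 16L), extents = c(3, 2, 2))
  geom <- nucleusGeometry(semiaxes = c(1, 0.6, 0.6), center = c(1.5, 1, 1),
                          epsEta = 0.04)
  eta <- buildNucleusIndicator(g, geom)
  zero <- array(0, dim = gridShape(g))
  # psi1 fills the nucleus: its interface shell coincides with eta's
  psiIn <- 1 - eta
  p <- paramsOff(1L, gamma1 = 5)
  stIn <- fieldState(phi = list(zero), psi1 = psiIn, psi2 = zero, eta = eta)
  ebIn <- freeEnergy(stIn, p, g)
  expect_lt(energyComponents(ebIn)[["adhesion"]], 0)  # wetting is favorable
  # psi1 as a small central droplet far from the envelope: the interface
  # shells do not overlap, so the adhesion energy is (exponentially) zero
  psiC <- syntheticBallField(g, c(1.5, 1, 1), 0.15, width = 0.04)
  stC <- fieldState(phi = list(zero), psi1 = psiC, psi2 = zero, eta = eta)
  expect_lt(abs(energyComponents(freeEnergy(stC, p, g))[["adhesion"]]),
            1e-8)
  # and the variational adhesion force vanishes in the bulk (h'(0)=h'(1)=0)
  d <- functionalDerivatives(stIn, p, g)
  inner <- eta < 1e-6 & psiIn > 1 - 1e-6
  dNoAdh <- functionalDerivatives(stIn, paramsOff(1L), g)
  expect_equal(d$dpsi1[inner], dNoAdh$dpsi1[inner], tolerance = 1e-8)
})
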