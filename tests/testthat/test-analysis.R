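# droplet labeling, isosurface areas, sphericity, profiles, distance CDFs

test_that("sphericity evaluates its closed form and rejects bad input", {
  expect_equal(sphericity(4 * pi / 3, 4 * pi), 1)
  expect_equal(sphericity(1, 6), (pi / 6)^(1 / 3))
  expect_equal(sphericity(4 * pi / 3, 8 * pi), 0.5)
  expect_error(sphericity(0, 1), "positive")
  expect_error(sphericity(1, -2), "positive")
})

test_that("droplet labeling separates and merges balls correctly", {
  g <- simGrid(c(64L, 32L, 32L), spacing = 0.05)
  two <- pmax(syntheticBallField(g, c(0.8, 0.8, 0.8), 0.4),
              syntheticBallField(g, c(2.4, 0.8, 0.8), 0.4))
  expect_equal(dropletCount(labelDroplets(two, g)), 2L)
  merged <- pmax(syntheticBallField(g, c(1.2, 0.8, 0.8), 0.4),
                 syntheticBallField(g, c(1.7, 0.8, 0.8), 0.4))
  expect_equal(dropletCount(labelDroplets(merged, g)), 1L)
  empty <- array(0, dim = gridShape(g))
  expect_equal(dropletCount(labelDroplets(empty, g)), 0L)
  expect_error(labelDroplets(two, g, threshold = 1.2), "threshold")
})

test_that("a rasterized ball reproduces the analytic volume, area and sphericity", {
  g <- simGrid(rep(48L, 3), spacing = 1 / 16)  # spacing = r/16
  f <- syntheticBallField(g, rep(1.5, 3), 1)
  tb <- dropletTable(labelDroplets(f, g))
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$volume, 4 * pi / 3, tolerance = 0.03)
  expect_equal(tb$surface, 4 * pi, tolerance = 0.02)
  expect_gte(tb$sphericity, 0.97)
  expect_equal(c(tb$cx, tb$cy, tb$cz), rep(1.5, 3), tolerance = 1e-3)
})

test_that("a rasterized prolate spheroid matches its closed-form surface", {
  g <- simGrid(c(96L, 48L, 48L), spacing = 0.05)
  f <- syntheticEllipsoidField(g, c(2.4, 1.2, 1.2), c(1.5, 0.5, 0.5))
  tb <- dropletTable(labelDroplets(f, g))
  Vex <- 4 * pi / 3 * 1.5 * 0.25
  Sex <- prolateSpheroidArea(1.5, 0.5)
  expect_equal(tb$volume, Vex, tolerance = 0.03)
  expect_equal(tb$surface, Sex, tolerance = 0.02)
  expect_equal(tb$sphericity, pi^(1 / 3) * (6 * Vex)^(2 / 3) / Sex,
               tolerance = 0.01)
})

test_that("droplet count is non-increasing under dilation of the superlevel set", {
  g <- simGrid(c(64L, 32L, 32L), spacing = 0.05)
  f <- pmax(syntheticBallField(g, c(1.2, 0.8, 0.8), 0.35),
            syntheticBallField(g, c(2.1, 0.8, 0.8), 0.35),
            syntheticBallField(g, c(1.65, 1.2, 0.8), 0.2))
  n0 <- dropletCount(labelDroplets(f, g))
  expect_gte(n0, 2L)
  prev <- n0
  for (grow in c(0.1, 0.25)) {
    fd <- pmax(syntheticBallField(g, c(1.2, 0.8, 0.8), 0.35 + grow),
               syntheticBallField(g, c(2.1, 0.8, 0.8), 0.35 + grow),
               syntheticBallField(g, c(1.65, 1.2, 0.8), 0.2 + grow))
    n <- dropletCount(labelDroplets(fd, g))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("droplet ownership and spanning follow the dominant territory", {
  g <- simGrid(c(48L, 24L, 24L), spacing = 0.1)
  # midline at 2.45 sits exactly on a voxel center so the centroid voxel
  # sees both territories symmetrically
  phi1 <- syntheticBallField(g, c(1.45, 1.2, 1.2), 0.9, width = 0.15)
  phi2 <- syntheticBallField(g, c(3.45, 1.2, 1.2), 0.9, width = 0.15)
  inOne <- syntheticBallField(g, c(1.45, 1.2, 1.2), 0.35)
  ds1 <- labelDroplets(inOne, g, phi = list(phi1, phi2))
  expect_equal(dropletTable(ds1)$owner, "1")
  expect_equal(dropletTable(ds1)$nCTspanned, 1L)
  # droplet on the midline: shared ownership
  mid <- syntheticBallField(g, c(2.45, 1.2, 1.2), 0.45)
  dsm <- labelDroplets(mid, g, phi = list(phi1, phi2))
  expect_equal(dropletTable(dsm)$owner, "shared")
  expect_equal(dropletTable(dsm)$nCTspanned, 2L)
})

test_that("radial profiles respect constants, zeros, and shell geometry", {
  g <- simGrid(c(30L, 45L, 15L), extents = c(6, 9, 3))
  geom <- nucleusGeometry()
  eta <- buildNucleusIndicator(g, geom)
  const <- (1 - eta) * 0.7  # ~0.7 inside the nucleus
  pr <- radialProfile(const, g, geom, axis = "major", nBins = 8L,
                      cylinderRadius = 0.7)
  d <- as.data.frame(pr)
  inner <- d$density[d$distance < 3]
  expect_true(all(abs(inner - 0.7) < 0.05))
  zero <- array(0, dim = gridShape(g))
  prz <- radialProfile(zero, g, geom, axis = "minor", nBins = 8L,
                       cylinderRadius = 0.7)
  expect_true(all(as.data.frame(prz)$density == 0, na.rm = TRUE))
  # a shell hugging the envelope peaks in the outermost populated bins
  shell <- 4 * eta * (1 - eta)  # 1 on the envelope, ~0 in the bulk
  prs <- radialProfile(shell, g, geom, axis = "major", nBins = 8L,
                       cylinderRadius = 0.7)
  ds <- as.data.frame(prs)
  ok <- !is.na(ds$density)
  expect_equal(which.max(ds$density[ok]), sum(ok))  # outermost populated bin
  # mirrored field gives the identical profile (axis symmetry)
  mirrored <- const[rev(seq_len(30)), , ]
  prm <- radialProfile(mirrored, g, geom, axis = "major", nBins = 8L,
                       cylinderRadius = 0.7)
  expect_equal(prm@density, pr@density, tolerance = 1e-12)
})

test_that("centroid-distance CDF enumerates cross-chromosome pairs", {
  mkSet <- function(centers, owners) {
    tb <- data.frame(label = seq_along(owners), subtype = "fHC",
                     owner = owners, nVoxels = 10L, volume = 1,
                     surface = 5, sphericity = 0.9,
                     cx = centers[, 1], cy = centers[, 2],
                     cz = centers[, 3], nCTspanned = 1L)
    new("DropletSet", table = tb, labelArray = array(0L, dim = c(2, 2, 2)),
        threshold = 0.5, subtype = "fHC")
  }
  two <- mkSet(rbind(c(0, 0, 0), c(3, 4, 0)), c("1", "2"))
  cdf <- centroidDistanceCdf(two)
  expect_equal(cdf$distance, 5)
  expect_equal(cdf$cumfrac, 1)
  # three collinear equally spaced droplets on three chromosomes
  three <- mkSet(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)),
                 c("1", "2", "3"))
  cdf3 <- centroidDistanceCdf(three)
  expect_equal(cdf3$distance, c(2, 2, 4))
  expect_equal(cdf3$cumfrac, c(1, 2, 3) / 3)
  expect_true(all(diff(cdf3$cumfrac) >= 0))
  expect_equal(cdf3$cumfrac[length(cdf3$cumfrac)], 1)
  # all droplets on one chromosome: empty table with warning
  same <- mkSet(rbind(c(0, 0, 0), c(2, 0, 0)), c("1", "1"))
  expect_warning(cdfS <- centroidDistanceCdf(same), "pairs")
  expect_equal(nrow(cdfS), 0L)
  one <- mkSet(rbind(c(0, 0, 0)), "1")
  expect_warning(centroidDistanceCdf(one), "fewer than two")
})
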