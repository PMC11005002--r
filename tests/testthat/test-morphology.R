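# regime classification on constructed droplet configurations

mkDroplets <- function(centers, owners, nspan, volumes = NULL) {
  n <- length(owners)
  if (is.null(volumes)) volumes <- rep(1, n)
  tb <- data.frame(label = seq_len(n), subtype = "fHC", owner = owners,
                   nVoxels = 10L, volume = volumes, surface = 5,
                   sphericity = 0.9, cx = centers[, 1], cy = centers[, 2],
                   cz = centers[, 3], nCTspanned = as.integer(nspan))
  new("DropletSet", table = tb, labelArray = array(0L, dim = c(2, 2, 2)),
      threshold = 0.5, subtype = "fHC")
}

test_that("one droplet per territory with no spanning is disconnected-within-CT", {
  geom <- nucleusGeometry()
  X <- defaultSeedCoordinates()
  ds <- mkDroplets(X, as.character(1:8), rep(1L, 8))
  call <- classifyMorphology(ds, ctCount = 8, geom = geom)
  expect_equal(regime(call), "disconnected-within-CT")
  expect_equal(morphologyEvidence(call)$nSpanning, 0L)
})

test_that("few central fused droplets are connected-interior", {
  geom <- nucleusGeometry()
  ds <- mkDroplets(rbind(c(3, 4.2, 1.5), c(3.2, 4.9, 1.5)),
                   c("shared", "shared"), c(3L, 2L), volumes = c(6, 5))
  call <- classifyMorphology(ds, ctCount = 8, geom = geom)
  expect_equal(regime(call), "connected-interior")
  expect_gte(morphologyEvidence(call)$centralVolFrac, 0.5)
})

test_that("off-center spanning droplets are connected-across-boundaries", {
  geom <- nucleusGeometry()
  ds <- mkDroplets(rbind(c(3, 1.4, 1.5), c(3.1, 7.8, 1.5), c(4.9, 4.5, 1.5)),
                   c("shared", "shared", "shared"), c(2L, 2L, 2L))
  call <- classifyMorphology(ds, ctCount = 8, geom = geom)
  expect_equal(regime(call), "connected-across-boundaries")
})

test_that("degenerate states and missing assignments are handled", {
  geom <- nucleusGeometry()
  emptySet <- new("DropletSet",
                  table = dropletTable(labelDroplets(
                    array(0, dim = c(4, 4, 4)),
                    simGrid(c(4L, 4L, 4L), spacing = 0.5))),
                  labelArray = array(0L, dim = c(4, 4, 4)),
                  threshold = 0.5, subtype = "fHC")
  call <- classifyMorphology(emptySet, ctCount = 8, geom = geom)
  expect_true(is.na(regime(call)))
  expect_match(morphologyEvidence(call)$message, "no droplets")
  noPhi <- mkDroplets(rbind(c(3, 4.5, 1.5)), "1", NA_integer_)
  expect_error(classifyMorphology(noPhi, 8, geom), "territory assignment")
})
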