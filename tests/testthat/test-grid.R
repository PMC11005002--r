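test_that("grid construction enforces the shape * spacing == extents invariant", {
  g <- simGrid(c(24L, 36L, 12L), extents = c(6, 9, 3))
  expect_equal(gridSpacing(g), c(0.25, 0.25, 0.25))
  expect_equal(voxelVolume(g), 0.25^3)
  g2 <- simGrid(c(10L, 10L, 10L), spacing = 0.1)
  expect_equal(gridExtents(g2), c(1, 1, 1))
  expect_error(simGrid(c(10L, 10L, 10L)), "exactly one")
  expect_error(simGrid(c(10L, 0L, 10L), spacing = 0.1), "positive")
  expect_error(simGrid(c(4L, 4L, 4L), extents = c(1, 1, 1),
                       boundary = "reflecting"))
})

test_that("voxel-center coordinates use midpoint quadrature", {
  g <- tinyGrid(shape = c(4L, 2L, 2L), extents = c(1, 0.5, 0.5))
  cc <- axisCoords(g)
  expect_equal(cc$x, c(0.125, 0.375, 0.625, 0.875))
  expect_equal(cc$y, c(0.125, 0.375))
})
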