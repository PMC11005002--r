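# parameter sweeps: degenerate plans, reproducibility, consensus

test_that("a 1x1 sweep equals a single run plus classification", {
  base <- runConfig("two-component-conventional", meshDivisor = 10,
                    nSteps = 60L, noiseOn = FALSE, energyEvery = 60L)
  plan <- sweepPlan(base, sweep = list(betaPsi1 = 0.1), replicates = 1L,
                    seed = 5L)
  out <- suppressWarnings(runSweep(plan))
  expect_equal(nrow(out$results), 1L)
  # reproduce the same run by hand with the derived seed
  cfg <- base
  cfg@integrator@rngSeed <- out$results$seed[1]
  traj <- quietRun(cfg)
  fs <- finalState(traj)
  ds <- labelDroplets(fs@psi1, cfg@grid, subtype = "fHC", phi = fs@phi)
  call <- classifyMorphology(ds, 8, cfg@geometry)
  expect_equal(out$results$regime[1], regime(call))
  expect_equal(out$results$nDroplets[1], dropletCount(ds))
  e <- energySeries(traj)
  expect_equal(out$results$finalEnergy[1], e$total[nrow(e)])
})

test_that("sweeps are reproducible and form a consensus over replicates", {
  base <- runConfig("two-component-conventional", meshDivisor = 12,
                    nSteps = 30L, noiseOn = FALSE, energyEvery = 30L)
  plan <- sweepPlan(base, sweep = list(betaPsi1 = c(0.1, 4.5)),
                    replicates = 2L, seed = 3L)
  o1 <- suppressWarnings(runSweep(plan))
  o2 <- suppressWarnings(runSweep(plan))
  expect_equal(o1$results$regime, o2$results$regime)
  expect_equal(o1$results$finalEnergy, o2$results$finalEnergy)
  expect_equal(nrow(o1$results), 4L)
  expect_equal(nrow(o1$consensus), 2L)
  # noise-off replicates agree, so the consensus is never "mixed"
  expect_false(any(o1$consensus$consensusRegime == "mixed"))
  # distinct deterministic seeds per (point, replicate)
  expect_equal(anyDuplicated(o1$results$seed), 0L)
})

test_that("swept parameter names are validated", {
  base <- runConfig("two-component-conventional", meshDivisor = 12,
                    nSteps = 1L, noiseOn = FALSE)
  expect_error(sweepPlan(base, sweep = list(notAParam = 1:2)), "unknown")
  expect_error(sweepPlan(base, sweep = list(1:2)), "named")
})
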