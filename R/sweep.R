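#' @include config.R morphology.R
NULL

#' Define a parameter sweep
#'
#' @param base a [RunConfig-class] used for every run (typically built at
#'   reduced resolution via `runConfig(..., meshDivisor = ...)`).
#' @param sweep named list of numeric vectors; names must be
#'   [ModelParameters-class] slots (e.g. `betaPhi`, `betaPsi1`,
#'   `betaPsi12`). The Cartesian product defines the run set.
#' @param replicates replicate runs per grid point.
#' @param seed plan-level seed; every (point, replicate) derives a
#'   distinct deterministic RNG seed from it.
#' @return a [SweepPlan-class].
#' @export
sweepPlan <- function(base, sweep, replicates = 1L, seed = 1L) {
  new("SweepPlan", base = base, sweep = sweep,
      replicates = as.integer(replicates), seed = as.integer(seed))
}

# deterministic per-run seed, kept well below 2^31
.runSeed <- function(planSeed, point, rep) {
  (planSeed * 1000L + point * 97L + rep * 7L) %% 2147483647L
}

#' Run a parameter sweep and classify each endpoint morphology
#'
#' For every point of the sweep grid and every replicate: the initial
#' state is seeded, the dynamics run, heterochromatin droplets labeled,
#' and the morphology classified. Single-run failures are recorded
#' (regime `NA`, error message kept) and the sweep continues; if every
#' run fails the sweep errors.
#'
#' @param plan a [SweepPlan-class].
#' @param threshold droplet level-set threshold.
#' @return list with `results` (one row per point x replicate: swept
#'   values, replicate, seed, regime, droplet count/volume, final energy)
#'   and `consensus` (modal regime per point; ties give `"mixed"`).
#' @export
runSweep <- function(plan, threshold = 0.5) {
  grid <- expand.grid(plan@sweep, KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  nFail <- 0L
  for (p in seq_len(nrow(grid))) {
    for (r in seq_len(plan@replicates)) {
      cfg <- plan@base
      for (nm in names(grid)) slot(cfg@params, nm) <- grid[[nm]][p]
      validObject(cfg@params)
      cfg@integrator@rngSeed <- .runSeed(plan@seed, p, r)
      rec <- c(as.list(grid[p, , drop = FALSE]),
               list(point = p, replicate = r,
                    seed = cfg@integrator@rngSeed))
      res <- tryCatch({
        traj <- runFromConfig(cfg)
        fs <- finalState(traj)
        dsets <- list(labelDroplets(fs@psi1, cfg@grid,
                                    threshold = threshold,
                                    subtype = "fHC", phi = fs@phi))
        if (any(cfg@params@targetw > 0))
          dsets <- c(dsets, list(labelDroplets(fs@psi2, cfg@grid,
                                               threshold = threshold,
                                               subtype = "cHC",
                                               phi = fs@phi)))
        call <- classifyMorphology(dsets, cfg@params@nChromosomes,
                                   cfg@geometry)
        vols <- compartmentVolumes(fs, cfg@grid)
        e <- energySeries(traj)
        list(regime = regime(call),
             nDroplets = sum(vapply(dsets, dropletCount, integer(1))),
             hcVolume = sum(vols$v) + sum(vols$w),
             finalEnergy = e$total[nrow(e)], error = NA_character_)
      }, error = function(e) {
        list(regime = NA_character_, nDroplets = NA_integer_,
             hcVolume = NA_real_, finalEnergy = NA_real_,
             error = conditionMessage(e))
      })
      if (!is.na(res$error)) nFail <- nFail + 1L
      rows[[length(rows) + 1L]] <- as.data.frame(c(rec, res),
                                                 stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  if (nFail == nrow(results))
    stop("every sweep run failed; first error: ", results$error[1])
  consensus <- do.call(rbind, lapply(split(results, results$point),
    function(d) {
      tab <- table(d$regime[!is.na(d$regime)])
      reg <- if (!length(tab)) NA_character_
        else if (sum(tab == max(tab)) > 1L) "mixed"
        else names(which.max(tab))
      out <- d[1, names(plan@sweep), drop = FALSE]
      out$point <- d$point[1]
      out$consensusRegime <- reg
      out
    }))
  rownames(consensus) <- NULL
  list(results = results, consensus = consensus)
}
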