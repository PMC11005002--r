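#' @include model.R
NULL

#' Integrator configuration
#'
#' @param dt dimensionless time step; the reference value is 0.04.
#' @param nSteps number of steps.
#' @param scheme `"semi-implicit-spectral"` (default) or `"explicit-euler"`.
#'   The semi-implicit scheme treats the diffusion term implicitly in
#'   transform space (mirror-extension FFT under zero-flux boundaries,
#'   plain FFT under periodic ones) and the nonlinear terms explicitly
#'   with a stabilization shift, and is robust at dt = 0.04. The explicit
#'   scheme is retained for cross-checks and must respect
#'   dt <= C h^2 / (L eps^2) with C = 1/6 (three dimensions).
#' @param rngSeed integer seed for the noise stream.
#' @param snapshotEvery keep a snapshot every this many steps (0 = none).
#' @param energyEvery record the energy breakdown every this many steps.
#' @param noiseOn apply interfacial white noise to psi1, psi2 (never phi).
#' @param stabilization `NA` = automatic per-step Lipschitz bound;
#'   otherwise an explicit constant S >= 0.
#' @param maxHalvings retries with halved dt when a step goes non-finite.
#' @return an [IntegratorConfig-class].
#' @export
integratorConfig <- function(dt = 0.04, nSteps = 100L,
                             scheme = c("semi-implicit-spectral",
                                        "explicit-euler"),
                             rngSeed = 1L, snapshotEvery = 0L,
                             energyEvery = 1L, noiseOn = FALSE,
                             stabilization = NA_real_,
                             maxHalvings = 2L) {
  new("IntegratorConfig", dt = dt, nSteps = as.integer(nSteps),
      scheme = match.arg(scheme), rngSeed = as.integer(rngSeed),
      snapshotEvery = as.integer(snapshotEvery),
      energyEvery = as.integer(energyEvery),
      noiseOn = noiseOn, stabilization = as.numeric(stabilization),
      maxHalvings = as.integer(maxHalvings))
}

# White-noise increment for one psi field: independent Gaussians with
# variance A * dt / voxel_volume per voxel (discretized space-time white
# noise <zeta zeta'> = A delta(r - r') delta(t - t')).
.noiseIncrement <- function(shape, A, dt, vv) {
  array(stats::rnorm(prod(shape), sd = sqrt(A * dt / vv)), dim = shape)
}

# Stabilization constant per family: a sup-bound of the diagonal
# nonlinear Jacobian, sup|f''| + sup|h''| * sup|B| with the curvature
# suprema taken over the value range the fields actually attain this
# step (B is the coupling multiplier measured this step).
.autoStabilization <- function(lip, lo, hi) {
  .supWellCurv(lo, hi) + .supHCurv(lo, hi) * lip
}

# One time step of size dt. `solver` is the cached spectral factorization
# (NULL builds one on demand for the spectral scheme).
.stepCore <- function(state, params, grid, cfg, solver, dt) {
  explicit <- cfg@scheme == "explicit-euler"
  parts <- .derivParts(state, params, grid, needLap = explicit)
  vv <- voxelVolume(grid)

  advance <- function(u, nl, lap, L, eps2, Sfam) {
    if (L == 0) return(u)
    if (explicit) return(u - dt * L * (nl - eps2 * lap))
    S <- if (is.na(cfg@stabilization)) Sfam else cfg@stabilization
    a0 <- 1 + dt * L * S
    # solve (a0 - dt L eps2 Lap) u+ = a0 u - dt L nl(u)
    .spectralSolve(a0 * u - dt * L * nl, solver, a0, dt * L * eps2)
  }

  rphi <- range(vapply(state@phi, range, numeric(2)))
  Sphi <- .autoStabilization(parts$lip$phi, rphi[1], rphi[2])
  phi <- state@phi
  for (i in seq_along(phi))
    phi[[i]] <- advance(phi[[i]], parts$nlPhi[[i]], parts$lapPhi[[i]],
                        params@LPhi, params@epsPhi^2, Sphi)
  r1 <- range(state@psi1); r2 <- range(state@psi2)
  psi1 <- advance(state@psi1, parts$nlPsi1, parts$lapPsi1, params@LPsi1,
                  params@epsPsi1^2,
                  .autoStabilization(parts$lip$psi1, r1[1], r1[2]))
  psi2 <- advance(state@psi2, parts$nlPsi2, parts$lapPsi2, params@LPsi2,
                  params@epsPsi2^2,
                  .autoStabilization(parts$lip$psi2, r2[1], r2[2]))
  if (cfg@noiseOn) {
    if (params@noiseAmp[1] > 0)
      psi1 <- psi1 + .noiseIncrement(grid@shape, params@noiseAmp[1], dt, vv)
    if (params@noiseAmp[2] > 0)
      psi2 <- psi2 + .noiseIncrement(grid@shape, params@noiseAmp[2], dt, vv)
  }
  fieldState(phi = phi, psi1 = psi1, psi2 = psi2, eta = state@eta,
             time = state@time + dt)
}

.isFiniteState <- function(state) {
  all(vapply(state@phi, function(p) all(is.finite(p)), logical(1))) &&
    all(is.finite(state@psi1)) && all(is.finite(state@psi2))
}

#' Advance a nuclear state by one time step
#'
#' Advances every territory field by \eqn{-L_\varphi\,\delta F/\delta\varphi_i\,dt}
#' and the heterochromatin fields by
#' \eqn{-L_{\psi_j}\,\delta F/\delta\psi_j\,dt} plus (optionally) a white
#' noise increment of per-voxel standard deviation
#' \eqn{\sqrt{A_j\,dt/\Delta V}}. The nucleus indicator is never modified.
#'
#' @param state a [FieldState-class].
#' @param params a [ModelParameters-class].
#' @param grid a [SimGrid-class].
#' @param cfg an [IntegratorConfig-class]; one step of `cfg@dt` is taken.
#'   Noise (if on) consumes the current RNG stream: seed it with
#'   `set.seed()` for reproducibility, as [runSimulation()] does.
#' @return the advanced [FieldState-class].
#' @export
stepState <- function(state, params, grid, cfg = integratorConfig()) {
  solver <- if (cfg@scheme == "semi-implicit-spectral")
    .makeSpectralSolver(grid) else NULL
  out <- .stepCore(state, params, grid, cfg, solver, cfg@dt)
  if (!.isFiniteState(out))
    stop("integration blew up within a single step; reduce dt (",
         cfg@dt, ")")
  out
}

.energyRow <- function(step, time, eb) {
  comps <- as.list(energyComponents(eb))
  data.frame(step = step, time = time, comps, total = eb@total)
}

#' Run a simulation
#'
#' Integrates the stochastic Allen-Cahn dynamics for `cfg@nSteps` steps,
#' recording the energy breakdown every `cfg@energyEvery` steps and a
#' snapshot every `cfg@snapshotEvery` steps. With noise off the dynamics
#' is a gradient flow and the recorded total energy is non-increasing.
#' A step that produces non-finite values is retried with halved dt (up
#' to `cfg@maxHalvings` times) before an error naming the offending step
#' is raised. If `outputDir` is given, snapshots, the energy series, and
#' a fully resolved provenance manifest are written there (see
#' [writeSnapshot()]).
#'
#' @param state initial [FieldState-class].
#' @param params a [ModelParameters-class].
#' @param grid a [SimGrid-class].
#' @param cfg an [IntegratorConfig-class].
#' @param outputDir optional directory for snapshots and logs.
#' @return a [Trajectory-class].
#' @export
runSimulation <- function(state, params, grid, cfg = integratorConfig(),
                          outputDir = NULL) {
  set.seed(cfg@rngSeed)
  solver <- if (cfg@scheme == "semi-implicit-spectral")
    .makeSpectralSolver(grid) else NULL
  if (cfg@scheme == "explicit-euler") {
    eps2 <- max(params@epsPhi, params@epsPsi1, params@epsPsi2)^2
    L <- max(params@LPhi, params@LPsi1, params@LPsi2)
    bound <- min(grid@spacing)^2 / (6 * L * eps2)
    if (cfg@dt > bound)
      warning(sprintf(
        "explicit dt = %g exceeds the diffusion stability bound %g",
        cfg@dt, bound))
  }
  if (!is.null(outputDir)) dir.create(outputDir, recursive = TRUE,
                                      showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  initial <- state
  energies <- list(.energyRow(0L, state@time, freeEnergy(state, params, grid)))
  snaps <- list()
  halvings <- 0L
  for (step in seq_len(cfg@nSteps)) {
    nxt <- .stepCore(state, params, grid, cfg, solver, cfg@dt)
    if (!.isFiniteState(nxt)) {
      ok <- FALSE
      sub <- 2L
      for (try in seq_len(cfg@maxHalvings)) {
        halvings <- halvings + 1L
        cand <- state
        dts <- cfg@dt / sub
        good <- TRUE
        for (k in seq_len(sub)) {
          cand <- .stepCore(cand, params, grid, cfg, solver, dts)
          if (!.isFiniteState(cand)) { good <- FALSE; break }
        }
        if (good) { nxt <- cand; ok <- TRUE; break }
        sub <- sub * 2L
      }
      if (!ok)
        stop("integration blew up at step ", step,
             " (t = ", format(state@time), "); reduce dt below ",
             format(cfg@dt / sub))
    }
    state <- nxt
    if (step %% cfg@energyEvery == 0L || step == cfg@nSteps)
      energies[[length(energies) + 1L]] <-
        .energyRow(step, state@time, freeEnergy(state, params, grid))
    if (cfg@snapshotEvery > 0L && step %% cfg@snapshotEvery == 0L) {
      snaps[[length(snaps) + 1L]] <- state
      if (!is.null(outputDir))
        writeSnapshot(state, file.path(outputDir,
                        sprintf("snapshot_%06d.rds", step)), grid = grid)
    }
  }
  energies <- do.call(rbind, energies)
  diagnostics <- list(
    wallSeconds = proc.time()[["elapsed"]] - t0,
    steps = cfg@nSteps, dtHalvings = halvings,
    scheme = cfg@scheme, rngSeed = cfg@rngSeed)
  if (!is.null(outputDir)) {
    utils::write.csv(energies, file.path(outputDir, "energy.csv"),
                     row.names = FALSE)
  }
  new("Trajectory", initial = initial, final = state, snapshots = snaps,
      energies = energies, diagnostics = diagnostics)
}

#' @rdname trajectory-accessors
setMethod("finalState", "Trajectory", function(object) object@final)

#' @rdname trajectory-accessors
setMethod("initialState", "Trajectory", function(object) object@initial)

#' @rdname trajectory-accessors
setMethod("energySeries", "Trajectory", function(object) object@energies)

#' @rdname trajectory-accessors
setMethod("snapshots", "Trajectory", function(object) object@snapshots)

setMethod("show", "Trajectory", function(object) {
  e <- object@energies
  cat(sprintf(
    "Trajectory: %d steps (t = %.4g), %d snapshots, energy %.5g -> %.5g\n",
    object@diagnostics$steps, object@final@time, length(object@snapshots),
    e$total[1], e$total[nrow(e)]))
})
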