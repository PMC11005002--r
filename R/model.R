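#' @include numerics.R geometry.R
NULL

#' Volume interpolation polynomial h and its derivatives
#'
#' \eqn{h(x) = x^3(10 - 15x + 6x^2)} maps field values to occupancy
#' weights while preserving the bulk minima: h(0) = 0, h(1) = 1 and
#' h'(0) = h'(1) = 0, so volume and coupling terms exert no force in the
#' pure phases.
#'
#' @param x numeric scalar, vector or array.
#' @return same shape as `x`.
#' @examples
#' interpolationH(c(0, 0.5, 1))  # 0, 0.5, 1
#' @export
interpolationH <- function(x) x^3 * (10 - 15 * x + 6 * x^2)

#' @rdname interpolationH
#' @export
interpolationHPrime <- function(x) 30 * x^2 * (1 - x)^2

# sup |h''| on [0,1]; used by the stabilized integrator's Lipschitz bound
.hPrime2Max <- 10 * sqrt(3) / 3  # max of |60 x (1-x)(1-2x)| = 5.7735

# sup |h''| and sup |f''| over the value range [m, M] actually attained by
# a field (both grow without bound outside [0, 1], so the stabilization
# shift must track transient overshoot)
.supHCurv <- function(m, M) {
  h2 <- function(x) abs(60 * x - 180 * x^2 + 120 * x^3)
  mx <- max(h2(m), h2(M))
  if (m < 1 && M > 0) mx <- max(mx, .hPrime2Max)
  mx
}
.supWellCurv <- function(m, M) {
  f2 <- function(x) abs(3 * x^2 - 3 * x + 0.5)
  max(f2(m), f2(M), 0.5)
}

# quartic double well and its derivative
.doubleWell <- function(u) u^2 * (1 - u)^2 / 4
.doubleWellPrime <- function(u) u * (1 - u) * (1 - 2 * u) / 2

#' Multi-well bulk free-energy density
#'
#' Pointwise \eqn{\sum_i \varphi_i^2(1-\varphi_i)^2/4 +
#' \sum_{j=1,2} \psi_j^2(1-\psi_j)^2/4}: a quartic double well per field,
#' with minima at 0 and 1 stabilizing the two coexisting bulk phases.
#' Non-negative everywhere; zero exactly where every field is 0 or 1.
#'
#' @param state a [FieldState-class].
#' @return a 3D array with the grid's shape.
#' @export
bulkDensity <- function(state) {
  acc <- .doubleWell(state@psi1) + .doubleWell(state@psi2)
  for (p in state@phi) acc <- acc + .doubleWell(p)
  acc
}

#' Compartment volumes of territories and their heterochromatin content
#'
#' Midpoint-quadrature integrals
#' \eqn{V_i = \int h(\varphi_i)}, \eqn{v_i = \int h(\psi_1) h(\varphi_i)},
#' \eqn{w_i = \int h(\psi_2) h(\varphi_i)} in um^3. Volumes carry an
#' O(spacing) interface quadrature error.
#'
#' @param state a [FieldState-class].
#' @param grid a [SimGrid-class].
#' @return list with numeric(N) components `V`, `v`, `w`.
#' @export
compartmentVolumes <- function(state, grid) {
  vv <- voxelVolume(grid)
  h1 <- interpolationH(state@psi1)
  h2 <- interpolationH(state@psi2)
  N <- length(state@phi)
  V <- v <- w <- numeric(N)
  for (i in seq_len(N)) {
    hp <- interpolationH(state@phi[[i]])
    V[i] <- sum(hp) * vv
    v[i] <- sum(h1 * hp) * vv
    w[i] <- sum(h2 * hp) * vv
  }
  list(V = V, v = v, w = w)
}

#' Free energy of a nuclear state, split by term
#'
#' Evaluates every term of the Ginzburg-Landau bulk functional (gradient
#' energies, multi-well density, the four volume penalties) and the
#' interaction functional (envelope confinement, CT-CT exclusion, HC
#' subtype exclusion, HC-outside-CT penalty, lamina adhesion) by midpoint
#' quadrature, in kBT units. The gradient terms use forward differences,
#' whose exact discrete gradient is the compact Laplacian used by
#' [functionalDerivatives()].
#'
#' @param state a [FieldState-class].
#' @param params a [ModelParameters-class].
#' @param grid a [SimGrid-class].
#' @return an [EnergyBreakdown-class].
#' @export
freeEnergy <- function(state, params, grid) {
  if (!identical(dim(state@eta), as.integer(grid@shape)) &&
      !identical(dim(state@eta), grid@shape))
    stop("field shape does not match the grid")
  vv <- voxelVolume(grid)
  N <- length(state@phi)

  grad <- params@epsPsi1^2 / 2 * .gradSquaredIntegral(state@psi1, grid) +
          params@epsPsi2^2 / 2 * .gradSquaredIntegral(state@psi2, grid)
  for (p in state@phi)
    grad <- grad + params@epsPhi^2 / 2 * .gradSquaredIntegral(p, grid)

  bulk <- sum(bulkDensity(state)) * vv

  vols <- compartmentVolumes(state, grid)
  volPen <- c(
    a1 = params@a1 * (params@nuclearVolume - sum(vols$V))^2,
    a2 = params@a2 * sum((vols$V - params@targetV)^2),
    a3 = params@a3 * sum((vols$v - params@targetv)^2),
    a4 = params@a4 * sum((vols$w - params@targetw)^2))

  heta <- interpolationH(state@eta)
  envelope <- heta * (1 - heta)
  hphi <- lapply(state@phi, interpolationH)
  hphiSum <- Reduce(`+`, hphi, accumulate = FALSE)
  h1 <- interpolationH(state@psi1)
  h2 <- interpolationH(state@psi2)

  confinement <- params@beta0 * sum(envelope * hphiSum) * vv

  ctEx <- 0
  if (N > 1 && params@betaPhi > 0) {
    # ordered-pair sum: sum_{i != j} h_i h_j = (sum h)^2 - sum h^2
    sq <- Reduce(`+`, lapply(hphi, function(h) h^2))
    ctEx <- params@betaPhi * sum(hphiSum^2 - sq) * vv
  }

  hcEx <- params@betaPsi12 * sum(h1 * h2) * vv
  hcOut <- sum((1 - hphiSum) *
               (params@betaPsi1 * h1 + params@betaPsi2 * h2)) * vv

  adhesion <- 0
  if (params@gamma1 > 0 || params@gamma2 > 0) {
    adhesion <- params@gamma1 * .gradDotIntegral(heta, h1, grid) +
                params@gamma2 * .gradDotIntegral(heta, h2, grid)
  }

  total <- grad + bulk + sum(volPen) + confinement + ctEx + hcEx +
    hcOut + adhesion
  new("EnergyBreakdown", gradient = grad, bulk = bulk,
      volumePenalty = volPen, confinement = confinement,
      ctExclusion = ctEx, hcExclusion = hcEx, hcOutsideCt = hcOut,
      adhesion = adhesion, total = total)
}

# Nonlinear (non-diffusive) parts of the functional derivatives, the
# Laplacians, and the per-family Lipschitz data the stabilized integrator
# needs. dF/du = -eps^2 lap(u) + nl(u). Returns:
#   nlPhi : list of N arrays; nlPsi1, nlPsi2 : arrays
#   lapPhi : list of N arrays; lapPsi1, lapPsi2 : arrays (unscaled lap u)
#   lip   : list(phi, psi1, psi2) sup-bounds of the nonlinear Jacobian
.derivParts <- function(state, params, grid, needLap = TRUE) {
  vv <- voxelVolume(grid)
  N <- length(state@phi)
  heta <- interpolationH(state@eta)
  envelope <- heta * (1 - heta)
  hphi <- lapply(state@phi, interpolationH)
  hphiSum <- Reduce(`+`, hphi)
  h1 <- interpolationH(state@psi1)
  h2 <- interpolationH(state@psi2)
  vols <- compartmentVolumes(state, grid)
  fillDef <- params@nuclearVolume - sum(vols$V)

  nlPhi <- vector("list", N)
  lapPhi <- vector("list", N)
  lipPhi <- 0
  for (i in seq_len(N)) {
    # multiplier of h'(phi_i): all energy densities that h(phi_i) enters
    B <- (-2 * params@a1 * fillDef +
           2 * params@a2 * (vols$V[i] - params@targetV[i])) +
      2 * params@a3 * (vols$v[i] - params@targetv[i]) * h1 +
      2 * params@a4 * (vols$w[i] - params@targetw[i]) * h2 +
      params@beta0 * envelope +
      2 * params@betaPhi * (hphiSum - hphi[[i]]) -
      (params@betaPsi1 * h1 + params@betaPsi2 * h2)
    nlPhi[[i]] <- .doubleWellPrime(state@phi[[i]]) +
      interpolationHPrime(state@phi[[i]]) * B
    if (needLap) lapPhi[[i]] <- .laplacian(state@phi[[i]], grid)
    lipPhi <- max(lipPhi, max(abs(B)))
  }

  lapHeta <- NULL
  B1 <- 2 * params@a3 * {
    acc <- array(0, dim = dim(h1))
    for (i in seq_len(N))
      acc <- acc + (vols$v[i] - params@targetv[i]) * hphi[[i]]
    acc
  } + params@betaPsi12 * h2 + params@betaPsi1 * (1 - hphiSum)
  if (params@gamma1 > 0) {
    lapHeta <- .laplacian(heta, grid)
    B1 <- B1 - params@gamma1 * lapHeta
  }
  nlPsi1 <- .doubleWellPrime(state@psi1) +
    interpolationHPrime(state@psi1) * B1
  lapPsi1 <- if (needLap) .laplacian(state@psi1, grid) else NULL

  B2 <- 2 * params@a4 * {
    acc <- array(0, dim = dim(h2))
    for (i in seq_len(N))
      acc <- acc + (vols$w[i] - params@targetw[i]) * hphi[[i]]
    acc
  } + params@betaPsi12 * h1 + params@betaPsi2 * (1 - hphiSum)
  if (params@gamma2 > 0) {
    if (is.null(lapHeta)) lapHeta <- .laplacian(heta, grid)
    B2 <- B2 - params@gamma2 * lapHeta
  }
  nlPsi2 <- .doubleWellPrime(state@psi2) +
    interpolationHPrime(state@psi2) * B2
  lapPsi2 <- if (needLap) .laplacian(state@psi2, grid) else NULL

  list(nlPhi = nlPhi, nlPsi1 = nlPsi1, nlPsi2 = nlPsi2,
       lapPhi = lapPhi, lapPsi1 = lapPsi1, lapPsi2 = lapPsi2,
       lip = list(phi = lipPhi,
                  psi1 = max(abs(B1)), psi2 = max(abs(B2))))
}

#' Analytic functional derivatives of the discretized free energy
#'
#' Variational derivatives \eqn{\delta F/\delta\varphi_i},
#' \eqn{\delta F/\delta\psi_1}, \eqn{\delta F/\delta\psi_2} of the
#' discrete functional evaluated by [freeEnergy()]: the compact-Laplacian
#' diffusion term, the double-well slope, and chain-rule contributions
#' \eqn{h'(u)\times} (every interaction density and volume-penalty factor
#' multiplying \eqn{h(u)}), with the lamina adhesion entering as
#' \eqn{-\gamma_j h'(\psi_j)\nabla^2 h(\eta)}. Discretization is
#' adjoint-consistent with the energy, so single-voxel finite differences
#' of [freeEnergy()] reproduce these fields to near machine precision.
#'
#' @param state a [FieldState-class].
#' @param params a [ModelParameters-class].
#' @param grid a [SimGrid-class].
#' @return list with components `dphi` (list of N arrays), `dpsi1`, `dpsi2`.
#' @export
functionalDerivatives <- function(state, params, grid) {
  p <- .derivParts(state, params, grid)
  dphi <- vector("list", length(state@phi))
  for (i in seq_along(dphi))
    dphi[[i]] <- -params@epsPhi^2 * p$lapPhi[[i]] + p$nlPhi[[i]]
  list(dphi = dphi,
       dpsi1 = -params@epsPsi1^2 * p$lapPsi1 + p$nlPsi1,
       dpsi2 = -params@epsPsi2^2 * p$lapPsi2 + p$nlPsi2)
}
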