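#' @include AllClasses.R
NULL

#' Interface-width coefficient from a diffusion coefficient
#'
#' The gradient (interface-width) coefficient of each field family is tied
#' to its physical diffusion coefficient through \eqn{D = L\,\epsilon^2}.
#' In dimensionless form (characteristic length `l` in um, time `tau` in
#' seconds) \eqn{\tilde D = D\,\tau/l^2} and
#' \eqn{\epsilon = \sqrt{\tilde D / L}}.
#'
#' @param D diffusion coefficient in um^2/s.
#' @param L dimensionless mobility (default 1).
#' @param lengthScale characteristic length l in um (default 1).
#' @param timeScale characteristic time tau in seconds (default 0.005).
#' @return the dimensionless interface coefficient epsilon.
#' @examples
#' epsilonFromDiffusion(20)  # territory fields
#' epsilonFromDiffusion(12)  # heterochromatin fields
#' @export
epsilonFromDiffusion <- function(D, L = 1, lengthScale = 1,
                                 timeScale = 0.005) {
  if (D < 0 || L <= 0) stop("D must be >= 0 and L > 0")
  sqrt(D * timeScale / lengthScale^2 / L)
}

#' Model parameters with literature defaults
#'
#' Returns the full coefficient set of the free energy and dynamics. The
#' defaults are the reference parametrization of the Drosophila interphase
#' nucleus: N = 8 territories, volume-constraint strengths a1 = 0.16 and
#' a2 = a3 = a4 = 2, envelope confinement beta0 = 16.7, CT-CT exclusion
#' betaPhi = 40, HC-EC coupling betaPsi1 = 0.1, noise amplitudes
#' A1 = A2 = 5, equal mobilities L = 1, and interface coefficients derived
#' from the diffusion coefficients D_phi = 20 um^2/s and
#' D_psi = 12 um^2/s with l = 1 um, tau = 0.005 s. Target volumes default
#' to an equal split of the nuclear volume across territories with a 25%
#' heterochromatin fraction.
#'
#' @param preset one of `"two-component-conventional"` (cHC channel and
#'   adhesion off), `"two-component-adhesive"` (adds lamina adhesion
#'   gamma1 = 5), `"three-component"` (fHC + cHC with strong subtype
#'   exclusion betaPsi12 = 4.5 and the HC volume split equally).
#' @param nChromosomes number of territory fields N.
#' @param nuclearVolume nominal nuclear volume VN in um^3 (default the
#'   a = 2.5, b = 4, c = 1.2 um ellipsoid).
#' @param hcFraction heterochromatin volume fraction of VN (default 0.25).
#' @param ... named overrides for any [ModelParameters-class] slot.
#' @return a validated [ModelParameters-class].
#' @examples
#' p <- modelParameters()
#' p@betaPhi           # 40
#' sum(p@targetv) / p@nuclearVolume  # 0.25
#' @export
modelParameters <- function(preset = c("two-component-conventional",
                                       "two-component-adhesive",
                                       "three-component"),
                            nChromosomes = 8L,
                            nuclearVolume = 4 / 3 * pi * 2.5 * 4 * 1.2,
                            hcFraction = 0.25, ...) {
  preset <- match.arg(preset)
  N <- as.integer(nChromosomes)
  fhcShare <- if (preset == "three-component") 0.5 else 1
  vHC <- hcFraction * nuclearVolume / N
  def <- list(
    nChromosomes = N,
    epsPhi = epsilonFromDiffusion(20),
    epsPsi1 = epsilonFromDiffusion(12),
    epsPsi2 = epsilonFromDiffusion(12),
    LPhi = 1, LPsi1 = 1, LPsi2 = 1,
    a1 = 0.16, a2 = 2, a3 = 2, a4 = 2,
    beta0 = 16.7, betaPhi = 40,
    betaPsi1 = 0.1,
    betaPsi2 = if (preset == "three-component") 0.1 else 0,
    betaPsi12 = if (preset == "three-component") 4.5 else 0,
    gamma1 = if (preset == "two-component-adhesive") 5 else 0,
    gamma2 = 0,
    noiseAmp = c(5, 5),
    targetV = rep(nuclearVolume / N, N),
    targetv = rep(fhcShare * vHC, N),
    targetw = rep((1 - fhcShare) * vHC, N),
    nuclearVolume = nuclearVolume,
    lengthScale = 1, timeScale = 0.005
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(def))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  def[names(ov)] <- ov
  def$nChromosomes <- as.integer(def$nChromosomes)
  do.call(new, c(list("ModelParameters"), def))
}

setMethod("show", "ModelParameters", function(object) {
  cat(sprintf("ModelParameters: N = %d territories, VN = %.2f um^3\n",
              object@nChromosomes, object@nuclearVolume))
  cat(sprintf("  eps: phi %.3f, psi (%.3f, %.3f); L = (%g, %g, %g)\n",
              object@epsPhi, object@epsPsi1, object@epsPsi2,
              object@LPhi, object@LPsi1, object@LPsi2))
  cat(sprintf("  a = (%g, %g, %g, %g); beta0 = %g, betaPhi = %g\n",
              object@a1, object@a2, object@a3, object@a4,
              object@beta0, object@betaPhi))
  cat(sprintf("  betaPsi = (%g, %g), betaPsi12 = %g; gamma = (%g, %g); A = (%g, %g)\n",
              object@betaPsi1, object@betaPsi2, object@betaPsi12,
              object@gamma1, object@gamma2,
              object@noiseAmp[1], object@noiseAmp[2]))
})

#' @rdname totalEnergy
setMethod("totalEnergy", "EnergyBreakdown", function(object) object@total)

#' @rdname energyComponents
setMethod("energyComponents", "EnergyBreakdown", function(object) {
  c(gradient = object@gradient, bulk = object@bulk,
    object@volumePenalty,
    confinement = object@confinement, ctExclusion = object@ctExclusion,
    hcExclusion = object@hcExclusion, hcOutsideCt = object@hcOutsideCt,
    adhesion = object@adhesion)
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat("EnergyBreakdown (kBT):\n")
  comps <- energyComponents(object)
  for (nm in names(comps))
    cat(sprintf("  %-14s %.6g\n", nm, comps[[nm]]))
  cat(sprintf("  %-14s %.6g\n", "total", object@total))
})
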