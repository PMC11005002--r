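#' @include grid.R
NULL

#' Ellipsoidal nucleus geometry
#'
#' Defaults are the oblate interphase Drosophila nucleus: semiaxes
#' a = 2.5, b = 4, c = 1.2 um, giving an analytic volume
#' \eqn{(4/3)\pi abc = 50.27} um^3.
#'
#' @param semiaxes numeric(3): (a, b, c) along (x, y, z), in um.
#' @param center ellipsoid center in um; defaults to the domain center of
#'   the reference 6 x 9 x 3 um box.
#' @param epsEta envelope interface-width parameter in the normalized
#'   ellipsoidal coordinate (default 0.04; the tanh transition spans about
#'   \eqn{2\sqrt2\,\epsilon_\eta} in that coordinate, i.e. roughly 0.3 um
#'   along the minor axis).
#' @return a [NucleusGeometry-class].
#' @export
nucleusGeometry <- function(semiaxes = c(2.5, 4, 1.2),
                            center = c(3, 4.5, 1.5),
                            epsEta = 0.04) {
  new("NucleusGeometry", semiaxes = as.numeric(semiaxes),
      center = as.numeric(center), epsEta = epsEta)
}

#' @rdname nuclearVolume
setMethod("nuclearVolume", "NucleusGeometry", function(object)
  4 / 3 * pi * prod(object@semiaxes))

setMethod("show", "NucleusGeometry", function(object) {
  cat(sprintf(
    "NucleusGeometry: semiaxes (%.3g, %.3g, %.3g) um at (%.3g, %.3g, %.3g)\n",
    object@semiaxes[1], object@semiaxes[2], object@semiaxes[3],
    object@center[1], object@center[2], object@center[3]))
  cat(sprintf("  volume %.2f um^3, epsEta = %g\n",
              nuclearVolume(object), object@epsEta))
})

# Normalized ellipsoidal coordinate r_ell = sqrt(((x-x0)/a)^2 + ...) as a
# full 3D array; r_ell = 1 on the ellipsoid surface.
.ellipsoidalRadius <- function(grid, geom) {
  cc <- .coordArrays(grid)
  a <- geom@semiaxes; x0 <- geom@center
  sqrt(((cc$x - x0[1]) / a[1])^2 +
       ((cc$y - x0[2]) / a[2])^2 +
       ((cc$z - x0[3]) / a[3])^2)
}

#' Build the static nucleus indicator field
#'
#' The indicator is 0 inside the nucleus and 1 outside, with a smooth tanh
#' transition whose 1/2-isocontour is exactly the ellipsoid surface:
#' \deqn{\eta(r) = \tfrac12\left[1 + \tanh\frac{r_{ell}-1}{2\sqrt2\,\epsilon_\eta}\right],}
#' where \eqn{r_{ell}} is the normalized ellipsoidal coordinate. The shift
#' by 1 places the envelope on the surface (an unshifted profile would put
#' the 1/2 level at the nuclear center), and the inside-0/outside-1 sign
#' convention follows the indicator's role as an "outside" penalty carrier.
#' The confinement energy density \eqn{h(\eta)(1-h(\eta))h(\varphi_i)} is
#' symmetric under the sign choice; only the sign of the adhesion coupling
#' depends on it, and all terms here use this convention consistently.
#'
#' @param grid a [SimGrid-class].
#' @param geom a [NucleusGeometry-class]. The ellipsoid must fit inside the
#'   domain with at least one envelope-width of margin.
#' @return a 3D array eta with the grid's shape.
#' @export
buildNucleusIndicator <- function(grid, geom) {
  a <- geom@semiaxes; x0 <- geom@center
  margin <- 2 * sqrt(2) * geom@epsEta * a  # envelope width, per axis
  lo <- x0 - a - margin
  hi <- x0 + a + margin
  if (any(lo < 0) || any(hi > grid@extents))
    stop("ellipsoid (plus one envelope width) does not fit inside the domain")
  rell <- .ellipsoidalRadius(grid, geom)
  0.5 * (1 + tanh((rell - 1) / (2 * sqrt(2) * geom@epsEta)))
}

#' Reference chromosomal-territory seed coordinates
#'
#' The eight seed centers (um) of the reference Drosophila configuration,
#' one per chromosomal territory, inside the 6 x 9 x 3 um domain.
#'
#' @return an 8 x 3 matrix with columns x, y, z.
#' @export
defaultSeedCoordinates <- function() {
  m <- matrix(c(
    3,    1.2,  1.5,
    1.2,  2.9,  1.5,
    2.7,  3.25, 0.26,
    4.5,  2.5,  1.5,
    3.2,  5.4,  1.5,
    4.8,  6.0,  1.5,
    3.0,  8.2,  1.5,
    1.35, 6.1,  1.5), ncol = 3, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Seed layout for the initial condition
#'
#' Radii are solved from the prescribed volumes: the territory radius from
#' an equal split of the nuclear volume (\eqn{(4/3)\pi r^3 = V_N/N}) and
#' the heterochromatin core radii from the target heterochromatin fraction
#' (default 25% of VN, split between fHC and cHC by `fhcShare`). The cHC
#' core is a central sphere and fHC the concentric shell around it.
#'
#' @param geom a [NucleusGeometry-class] (supplies VN).
#' @param ctCenters N x 3 matrix of seed centers; default the reference
#'   eight coordinates.
#' @param hcFraction heterochromatin volume fraction of VN (default 0.25).
#' @param fhcShare fraction of heterochromatin volume given to fHC
#'   (1 for two-component models, 0.5 for the three-component preset).
#' @param ctRadius optional territory radius override (um).
#' @return a [SeedLayout-class].
#' @export
seedLayout <- function(geom = nucleusGeometry(),
                       ctCenters = defaultSeedCoordinates(),
                       hcFraction = 0.25, fhcShare = 1,
                       ctRadius = NULL) {
  N <- nrow(ctCenters)
  VN <- nuclearVolume(geom)
  if (is.null(ctRadius))
    ctRadius <- (3 * VN / N / (4 * pi))^(1 / 3)
  vHC <- hcFraction * VN / N          # total HC volume per territory
  wC <- (1 - fhcShare) * vHC          # cHC core volume
  chcRadius <- (3 * wC / (4 * pi))^(1 / 3)
  fhcRadius <- (3 * vHC / (4 * pi))^(1 / 3)  # outer radius of the HC ball
  new("SeedLayout", ctCenters = ctCenters, ctRadius = ctRadius,
      fhcRadius = fhcRadius, chcRadius = chcRadius,
      hcFraction = hcFraction, fhcShare = fhcShare)
}

#' Construct a FieldState
#'
#' @param phi list of territory field arrays.
#' @param psi1,psi2 heterochromatin field arrays (fHC, cHC).
#' @param eta nucleus indicator array.
#' @param time simulation time (dimensionless).
#' @return a validated [FieldState-class].
#' @export
fieldState <- function(phi, psi1, psi2, eta, time = 0) {
  new("FieldState", phi = phi, psi1 = psi1, psi2 = psi2, eta = eta,
      time = time)
}

setMethod("show", "FieldState", function(object) {
  d <- dim(object@eta)
  cat(sprintf("FieldState: %d territory fields + psi1/psi2 on %d x %d x %d, t = %.4g\n",
              length(object@phi), d[1], d[2], d[3], object@time))
})

# Smooth sphere profile: 1 inside radius R around center, tanh interface of
# family width eps, i.e. (1/2)[1 - tanh((|x - c| - R)/(2*sqrt(2) eps))].
.tanhBall <- function(cc, center, R, eps) {
  d <- sqrt((cc$x - center[1])^2 + (cc$y - center[2])^2 +
            (cc$z - center[3])^2)
  0.5 * (1 - tanh((d - R) / (2 * sqrt(2) * eps)))
}

# h-weighted volume of a tanh ball, 4 pi int h(profile(s)) s^2 ds. When the
# interface width is comparable to the radius this exceeds (4/3) pi R^3
# substantially, so seed radii must be solved against this integral.
.profileBallVolume <- function(R, eps) {
  w <- 2 * sqrt(2) * eps
  ds <- w / 40
  s <- seq(ds / 2, R + 8 * w, by = ds)
  4 * pi * sum(interpolationH(0.5 * (1 - tanh((s - R) / w))) * s^2) * ds
}

# invert .profileBallVolume for the radius producing a target volume
# h-weighted volume of the concentric shell pmax(outer - core, 0) used to
# seed fHC around a cHC core, and the outer radius meeting a target
.profileShellVolume <- function(Rout, Rcore, epsOut, epsCore) {
  wo <- 2 * sqrt(2) * epsOut
  wc <- 2 * sqrt(2) * epsCore
  ds <- min(wo, wc) / 40
  s <- seq(ds / 2, Rout + 8 * wo, by = ds)
  shell <- pmax(0.5 * (1 - tanh((s - Rout) / wo)) -
                0.5 * (1 - tanh((s - Rcore) / wc)), 0)
  4 * pi * sum(interpolationH(shell) * s^2) * ds
}

.solveShellRadius <- function(V, Rcore, epsOut, epsCore) {
  if (V <= 0) return(Rcore)
  hi <- Rcore + (3 * V / (4 * pi))^(1 / 3) + 1e-3
  while (.profileShellVolume(hi, Rcore, epsOut, epsCore) < V) hi <- hi * 1.5
  stats::uniroot(function(r) .profileShellVolume(r, Rcore, epsOut, epsCore) - V,
                 lower = max(Rcore, 1e-9) , upper = hi, tol = 1e-10)$root
}

.solveBallRadius <- function(V, eps) {
  if (V <= 0) return(0)
  sharp <- (3 * V / (4 * pi))^(1 / 3)
  if (.profileBallVolume(1e-9, eps) >= V) return(sharp)
  hi <- sharp + 1e-3
  while (.profileBallVolume(hi, eps) < V) hi <- hi * 1.5
  stats::uniroot(function(r) .profileBallVolume(r, eps) - V,
                 lower = 1e-9, upper = hi, tol = 1e-10)$root
}

#' Seed the initial nuclear state
#'
#' Each territory field is a tanh sphere (value ~ 1 inside) of radius
#' `layout@ctRadius` around its seed center; heterochromatin is seeded at
#' the center of every territory as a cHC sphere (radius `chcRadius`)
#' surrounded by a concentric fHC shell out to `fhcRadius`, so that
#' psi1 + psi2 <= 1 everywhere and the summed seed volumes match the
#' prescribed heterochromatin fraction. Construction is deterministic;
#' stochasticity enters only through the dynamics noise.
#'
#' @param grid a [SimGrid-class].
#' @param geom a [NucleusGeometry-class]; seed centers outside the
#'   ellipsoid draw a warning (the reference coordinate set contains one
#'   marginal case; confinement resolves it).
#' @param layout a [SeedLayout-class].
#' @param params a [ModelParameters-class] (supplies the interface widths).
#' @param overlapWarn warn if seed spheres overlap by more than this
#'   fraction of the territory radius (the dynamics resolves overlaps).
#' @return a [FieldState-class] at time 0.
#' @export
seedInitialState <- function(grid, geom, layout, params,
                             overlapWarn = 0.5) {
  X <- layout@ctCenters
  N <- nrow(X)
  if (N != params@nChromosomes)
    stop("layout has ", N, " seed centers but params expects ",
         params@nChromosomes)
  a <- geom@semiaxes; x0 <- geom@center
  rell <- sqrt(((X[, 1] - x0[1]) / a[1])^2 + ((X[, 2] - x0[2]) / a[2])^2 +
               ((X[, 3] - x0[3]) / a[3])^2)
  if (any(rell >= 1))
    # the reference coordinate set itself contains one center marginally
    # outside the ellipsoid; envelope confinement pulls it in, so this is
    # advisory rather than fatal
    warning("seed center(s) ", paste(which(rell >= 1), collapse = ", "),
            " lie outside the nucleus (normalized radius ",
            paste(sprintf("%.2f", rell[rell >= 1]), collapse = ", "),
            "); the confinement term will drive them inward")
  if (N > 1) {
    dd <- as.matrix(stats::dist(X))
    diag(dd) <- Inf
    if (min(dd) < (2 - overlapWarn) * layout@ctRadius)
      warning("territory seed spheres overlap substantially; ",
              "the dynamics will resolve the overlap")
  }
  cc <- .coordArrays(grid)
  phi <- vector("list", N)
  psi1 <- array(0, dim = grid@shape)
  psi2 <- array(0, dim = grid@shape)
  # The layout radii encode sharp-interface target volumes; solve the
  # radii of the actual tanh profiles (family interface widths) so the
  # h-weighted seed volumes meet those targets.
  rct <- .solveBallRadius(4 / 3 * pi * layout@ctRadius^3, params@epsPhi)
  rcore <- .solveBallRadius(4 / 3 * pi * layout@chcRadius^3, params@epsPsi2)
  rhc <- if (layout@chcRadius > 0) {
    # outer radius solved against the actual fHC shell integral
    .solveShellRadius(4 / 3 * pi * (layout@fhcRadius^3 - layout@chcRadius^3),
                      rcore, params@epsPsi1, params@epsPsi2)
  } else {
    .solveBallRadius(4 / 3 * pi * layout@fhcRadius^3, params@epsPsi1)
  }
  for (i in seq_len(N)) {
    phi[[i]] <- .tanhBall(cc, X[i, ], rct, params@epsPhi)
    if (layout@hcFraction > 0) {
      outer_ <- .tanhBall(cc, X[i, ], rhc, params@epsPsi1)
      if (layout@chcRadius > 0) {
        core <- .tanhBall(cc, X[i, ], rcore, params@epsPsi2)
        psi2 <- psi2 + core
        psi1 <- psi1 + pmax(outer_ - core, 0)
      } else {
        psi1 <- psi1 + outer_
      }
    }
  }
  eta <- buildNucleusIndicator(grid, geom)
  fieldState(phi = phi, psi1 = psi1, psi2 = psi2, eta = eta, time = 0)
}
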