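#' @include grid.R
NULL

# Regular-grid differential operators.
#
# The discrete free energy uses forward-difference gradient quadrature;
# its exact gradient with respect to the voxel values is the compact
# 7-point Laplacian with mirror (zero-flux) or periodic closure. Keeping
# the operators adjoint-consistent is what lets the analytic functional
# derivatives match brute-force finite differences of the energy to
# near machine precision.

# Index vectors for a +1 / -1 shift along one axis under each boundary mode.
.idxShift <- function(n, dir, boundary) {
  if (n == 1L) return(1L)
  if (dir > 0) {
    if (boundary == "periodic") c(2:n, 1L) else c(2:n, n)
  } else {
    if (boundary == "periodic") c(n, 1:(n - 1L)) else c(1L, 1:(n - 1L))
  }
}

# Shift an array by one voxel along an axis (1, 2 or 3).
.shift <- function(u, axis, dir, boundary) {
  d <- dim(u)
  i <- .idxShift(d[axis], dir, boundary)
  switch(axis,
         u[i, , , drop = FALSE],
         u[, i, , drop = FALSE],
         u[, , i, drop = FALSE])
}

# Compact 7-point Laplacian honouring the grid's boundary contract.
.laplacian <- function(u, grid) {
  h <- grid@spacing; b <- grid@boundary
  out <- array(0, dim = dim(u))
  for (ax in 1:3) {
    if (dim(u)[ax] == 1L) next
    out <- out + (.shift(u, ax, +1L, b) - 2 * u +
                  .shift(u, ax, -1L, b)) / h[ax]^2
  }
  out
}

# Forward-difference gradient energy sum((grad u)^2) * voxvol (no 1/2, no
# eps^2). For zero-flux boundaries the mirror ghost difference is zero, so
# faces at the top boundary drop out; for periodic the wrap face counts.
.gradSquaredIntegral <- function(u, grid) {
  h <- grid@spacing; b <- grid@boundary
  acc <- 0
  for (ax in 1:3) {
    n <- dim(u)[ax]
    if (n == 1L) next
    du <- (.shift(u, ax, +1L, b) - u) / h[ax]
    if (b == "zero-flux") {
      # drop the duplicated top face (difference is zero anyway)
      acc <- acc + sum(du^2)
    } else {
      acc <- acc + sum(du^2)
    }
  }
  acc * prod(h)
}

# Forward-difference dot-product integral sum(grad a . grad b) * voxvol,
# used by the adhesion energy.
.gradDotIntegral <- function(a, bfield, grid) {
  h <- grid@spacing; bnd <- grid@boundary
  acc <- 0
  for (ax in 1:3) {
    if (dim(a)[ax] == 1L) next
    da <- (.shift(a, ax, +1L, bnd) - a) / h[ax]
    db <- (.shift(bfield, ax, +1L, bnd) - bfield) / h[ax]
    acc <- acc + sum(da * db)
  }
  acc * prod(h)
}

# ---- spectral solve of (1 + c0) u - cL lap(u) = rhs -------------------
#
# For zero-flux boundaries the compact Neumann Laplacian is diagonalized
# by even (mirror) extension to a periodic grid of twice the size; for
# periodic boundaries the plain FFT applies. `.makeSpectralSolver` caches
# the eigenvalue array -lambda = k2 >= 0 of the (extended) grid.

.makeSpectralSolver <- function(grid) {
  s <- grid@shape; h <- grid@spacing
  periodic <- grid@boundary == "periodic"
  es <- if (periodic) s else ifelse(s > 1L, 2L * s, 1L)
  ax <- function(k) {
    n <- es[k]
    if (n == 1L) return(0)
    j <- 0:(n - 1)
    (2 - 2 * cos(2 * pi * j / n)) / h[k]^2
  }
  k1 <- ax(1); k2_ <- ax(2); k3 <- ax(3)
  k2 <- outer(outer(k1, k2_, `+`), k3, `+`)
  mirror <- lapply(1:3, function(k) {
    n <- s[k]
    if (periodic || n == 1L) seq_len(n) else c(seq_len(n), rev(seq_len(n)))
  })
  list(k2 = k2, mirror = mirror, shape = s, extShape = es,
       periodic = periodic, nExt = prod(es))
}

# Solve (a0 * I - cL * Lap) u = a0 * u - cL*Lap(u) = rhs for u,
# i.e. apply the multiplier a0 / (a0 + cL * k2) in transform space
# given rhs; a0 > 0, cL >= 0.
.spectralSolve <- function(rhs, solver, a0, cL) {
  m <- solver$mirror
  re <- rhs[m[[1]], m[[2]], m[[3]], drop = FALSE]
  dim(re) <- solver$extShape
  Rk <- stats::fft(re)
  Uk <- Rk / (a0 + cL * solver$k2)
  u <- Re(stats::fft(Uk, inverse = TRUE)) / solver$nExt
  u[seq_len(solver$shape[1]), seq_len(solver$shape[2]),
    seq_len(solver$shape[3]), drop = FALSE]
}
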