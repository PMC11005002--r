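#' @include grid.R
NULL

# Triangulated isosurface area by marching tetrahedra.
#
# Each grid cell (8 voxel centers as corners) is split into the six
# Freudenthal tetrahedra sharing the main diagonal; each tetrahedron is
# triangulated against the threshold level with edge crossings placed by
# linear interpolation. Vectorized over cells: per tetrahedron the 16
# sign configurations collapse to "one corner separated" (one triangle)
# and "two vs two" (a quad, two triangles).

# cube corners numbered 0..7 by bits (bx, by, bz); six tetrahedra along
# the 0-7 diagonal (Freudenthal/Kuhn decomposition)
.tetDecomposition <- matrix(c(
  0L, 1L, 3L, 7L,
  0L, 1L, 5L, 7L,
  0L, 2L, 3L, 7L,
  0L, 2L, 6L, 7L,
  0L, 4L, 5L, 7L,
  0L, 4L, 6L, 7L), ncol = 4, byrow = TRUE)

# Quad edge cycles for the two-vs-two cases, keyed by which pair of local
# tet vertices (1..4) is above threshold. Edges are local vertex pairs;
# consecutive edges in each cycle share a tetrahedron face, so the quad
# is planar-convex in the interpolation sense and splits cleanly into
# triangles (1,2,3) and (1,3,4) of the cycle.
.tetQuadCycle <- list(
  "12" = matrix(c(1L, 3L,  2L, 3L,  2L, 4L,  1L, 4L), ncol = 2, byrow = TRUE),
  "13" = matrix(c(1L, 2L,  2L, 3L,  3L, 4L,  1L, 4L), ncol = 2, byrow = TRUE),
  "14" = matrix(c(1L, 2L,  1L, 3L,  3L, 4L,  2L, 4L), ncol = 2, byrow = TRUE)
)

# area of triangles given three ncase x 3 coordinate matrices
.triArea <- function(P1, P2, P3) {
  u <- P2 - P1; v <- P3 - P1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Per-label triangulated isosurface areas of {field >= threshold}.
# labelArr: integer array (0 = background) assigning voxels to droplets;
# each active cell's area is credited to the largest label among its
# above-threshold corners. Returns a named numeric vector (names = label).
.isosurfaceAreaByLabel <- function(field, grid, threshold, labelArr) {
  s <- grid@shape; h <- grid@spacing
  if (any(s < 2L)) stop("isosurface extraction needs >= 2 voxels per axis")
  nc <- s - 1L
  corner <- function(a, bx, by, bz)
    a[(1:nc[1]) + bx, (1:nc[2]) + by, (1:nc[3]) + bz, drop = FALSE]
  vals <- list(
    corner(field, 0, 0, 0), corner(field, 1, 0, 0),
    corner(field, 0, 1, 0), corner(field, 1, 1, 0),
    corner(field, 0, 0, 1), corner(field, 1, 0, 1),
    corner(field, 0, 1, 1), corner(field, 1, 1, 1))
  above <- lapply(vals, function(v) v >= threshold)
  nAbove <- Reduce(`+`, above)
  act <- which(nAbove > 0 & nAbove < 8)          # cells crossed by surface
  if (!length(act)) return(numeric(0))

  # cell integer coordinates (0-based) of active cells
  ci <- arrayInd(act, .dim = nc)
  baseX <- (ci[, 1] - 0.5) * h[1]
  baseY <- (ci[, 2] - 0.5) * h[2]
  baseZ <- (ci[, 3] - 0.5) * h[3]
  cornerXYZ <- function(code) {
    cbind(baseX + bitwAnd(code, 1L) * h[1],
          baseY + bitwAnd(bitwShiftR(code, 1L), 1L) * h[2],
          baseZ + bitwAnd(bitwShiftR(code, 2L), 1L) * h[3])
  }
  V <- vapply(vals, function(v) v[act], numeric(length(act)))
  if (length(act) == 1L) V <- matrix(V, nrow = 1)

  # label of each active cell: max droplet label over its corners
  labs <- lapply(c(0:7), function(code) {
    la <- corner(labelArr, bitwAnd(code, 1L),
                 bitwAnd(bitwShiftR(code, 1L), 1L),
                 bitwAnd(bitwShiftR(code, 2L), 1L))
    la[act]
  })
  cellLab <- Reduce(pmax, labs)

  maxLab <- max(cellLab)
  areas <- numeric(maxLab)

  addTris <- function(P1, P2, P3, labsHere) {
    a <- .triArea(P1, P2, P3)
    tab <- rowsum(a, group = labsHere)
    idx <- as.integer(rownames(tab))
    keep <- idx > 0
    areas[idx[keep]] <<- areas[idx[keep]] + tab[keep, 1]
  }

  interp <- function(Pa, Pb, va, vb) {
    t <- (threshold - va) / (vb - va)
    Pa + t * (Pb - Pa)
  }

  for (tet in seq_len(nrow(.tetDecomposition))) {
    codes <- .tetDecomposition[tet, ]
    tv <- V[, codes + 1L, drop = FALSE]
    tb <- tv >= threshold
    cnt <- rowSums(tb)
    cross <- which(cnt > 0 & cnt < 4)
    if (!length(cross)) next
    tvc <- tv[cross, , drop = FALSE]
    tbc <- tb[cross, , drop = FALSE]
    cntc <- cnt[cross]
    labc <- cellLab[cross]
    P <- lapply(codes, function(code) cornerXYZ(code)[cross, , drop = FALSE])

    # single separated vertex (1 above or 1 below): one triangle
    for (v0 in 1:4) {
      sel <- which((cntc == 1 & tbc[, v0]) | (cntc == 3 & !tbc[, v0]))
      if (!length(sel)) next
      others <- setdiff(1:4, v0)
      Pa <- P[[v0]][sel, , drop = FALSE]
      va <- tvc[sel, v0]
      crossP <- lapply(others, function(vb)
        interp(Pa, P[[vb]][sel, , drop = FALSE], va, tvc[sel, vb]))
      addTris(crossP[[1]], crossP[[2]], crossP[[3]], labc[sel])
    }

    # two-vs-two: quad split into two triangles
    for (pair in names(.tetQuadCycle)) {
      v1 <- as.integer(substr(pair, 1, 1))
      v2 <- as.integer(substr(pair, 2, 2))
      sel <- which(cntc == 2 & (tbc[, v1] == tbc[, v2]) &
                     (tbc[, v1] != tbc[, setdiff(1:4, c(v1, v2))[1]]))
      if (!length(sel)) next
      cyc <- .tetQuadCycle[[pair]]
      Q <- lapply(1:4, function(k) {
        a <- cyc[k, 1]; b <- cyc[k, 2]
        interp(P[[a]][sel, , drop = FALSE], P[[b]][sel, , drop = FALSE],
               tvc[sel, a], tvc[sel, b])
      })
      addTris(Q[[1]], Q[[2]], Q[[3]], labc[sel])
      addTris(Q[[1]], Q[[3]], Q[[4]], labc[sel])
    }
  }
  names(areas) <- as.character(seq_len(maxLab))
  areas
}
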