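#' @include isosurface.R
NULL

#' Sphericity index
#'
#' \eqn{\Psi = \pi^{1/3}(6V)^{2/3}/S}: 1 for a ball, below 1 for every
#' other shape; scale-invariant.
#'
#' @param volume volume(s) in um^3, positive.
#' @param surface surface area(s) in um^2, positive.
#' @return sphericity value(s).
#' @examples
#' sphericity(4 * pi / 3, 4 * pi)  # exact ball: 1
#' sphericity(1, 6)                # unit cube: (pi/6)^(1/3)
#' @export
sphericity <- function(volume, surface) {
  if (any(volume <= 0) || any(surface <= 0))
    stop("sphericity needs positive volume and surface")
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface
}

# connected components (6-neighbourhood) of a logical mask; returns an
# integer array of labels (0 = background), labels ordered by first voxel
.labelComponents <- function(mask) {
  d <- dim(mask)
  idxAll <- which(mask)
  lab <- array(0L, dim = d)
  if (!length(idxAll)) return(lab)
  Lidx <- array(seq_len(prod(d)), dim = d)
  edges <- list()
  for (ax in 1:3) {
    n <- d[ax]
    if (n == 1L) next
    take <- function(a, r) switch(ax, a[r, , , drop = FALSE],
                                  a[, r, , drop = FALSE],
                                  a[, , r, drop = FALSE])
    adj <- take(mask, 1:(n - 1)) & take(mask, 2:n)
    if (!any(adj)) next
    edges[[length(edges) + 1L]] <-
      cbind(take(Lidx, 1:(n - 1))[adj], take(Lidx, 2:n)[adj])
  }
  m <- length(idxAll)
  if (length(edges)) {
    ee <- do.call(rbind, edges)
    v1 <- match(ee[, 1], idxAll)
    v2 <- match(ee[, 2], idxAll)
    g <- igraph::make_graph(rbind(v1, v2), n = m, directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_len(m)
  }
  # relabel so ids are 1..k in order of first appearance
  memb <- match(memb, unique(memb))
  lab[idxAll] <- memb
  lab
}

#' Label connected heterochromatin droplets and measure them
#'
#' Connected components (face adjacency, 6-neighbourhood) of the
#' superlevel set `field >= threshold`. Per droplet: volume as voxel
#' count x voxel volume, surface as the triangulated isosurface area at
#' the threshold level (marching tetrahedra; voxel-face counting would
#' bias sphericity low), field-weighted centroid, and sphericity. When
#' territory fields are supplied each droplet is assigned to the
#' chromosome whose \eqn{h(\varphi_i)} dominates at its centroid voxel
#' (`"shared"` when the top two are within `dominanceGap`), and the
#' number of distinct territories the droplet spans is recorded (a
#' territory counts as spanned when it dominates at least `spanMinFrac`
#' of the droplet's voxels).
#'
#' @param field scalar field (3D array).
#' @param grid a [SimGrid-class].
#' @param threshold level-set threshold in (0, 1); default 0.5, the
#'   interface convention used throughout.
#' @param subtype provenance label (`"fHC"`, `"cHC"`, `"HC"`).
#' @param phi optional list of territory fields for ownership calls.
#' @param dominanceGap h-value gap below which ownership is `"shared"`.
#' @param spanMinFrac voxel fraction for a territory to count as spanned.
#' @param minVoxels droplets smaller than this report `NA` surface and
#'   sphericity: below roughly five voxels across (the default, 125
#'   voxels) the triangulated isosurface is not meaningful and the
#'   sphericity index leaves its (0, 1] range. Volumes and centroids are
#'   still reported.
#' @return a [DropletSet-class]; empty superlevel set gives zero rows.
#' @export
labelDroplets <- function(field, grid, threshold = 0.5, subtype = "HC",
                          phi = NULL, dominanceGap = 0.1,
                          spanMinFrac = 0.1, minVoxels = 125L) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  mask <- field >= threshold
  lab <- .labelComponents(mask)
  k <- max(lab)
  empty <- data.frame(label = integer(), subtype = character(),
                      owner = character(), nVoxels = integer(),
                      volume = numeric(), surface = numeric(),
                      sphericity = numeric(), cx = numeric(),
                      cy = numeric(), cz = numeric(),
                      nCTspanned = integer())
  if (k == 0L)
    return(new("DropletSet", table = empty, labelArray = lab,
               threshold = threshold, subtype = subtype))

  vv <- voxelVolume(grid)
  idx <- which(mask)
  labs <- lab[idx]
  w <- field[idx]
  ai <- arrayInd(idx, .dim = dim(field))
  h <- grid@spacing
  xs <- (ai[, 1] - 0.5) * h[1]
  ys <- (ai[, 2] - 0.5) * h[2]
  zs <- (ai[, 3] - 0.5) * h[3]
  wsum <- rowsum(w, labs)[, 1]
  cx <- rowsum(w * xs, labs)[, 1] / wsum
  cy <- rowsum(w * ys, labs)[, 1] / wsum
  cz <- rowsum(w * zs, labs)[, 1] / wsum
  nvox <- tabulate(labs, nbins = k)
  vol <- nvox * vv
  surf <- .isosurfaceAreaByLabel(field, grid, threshold, lab)
  surf <- surf[as.character(seq_len(k))]
  surf[is.na(surf) | surf <= 0 | nvox < minVoxels] <- NA_real_
  psi <- pi^(1 / 3) * (6 * vol)^(2 / 3) / surf

  owner <- rep(NA_character_, k)
  nspan <- rep(NA_integer_, k)
  if (!is.null(phi) && length(phi)) {
    hphiAt <- function(vidx)
      vapply(phi, function(p) interpolationH(p[vidx]), numeric(length(vidx)))
    # dominant territory per droplet voxel
    hv <- hphiAt(idx)
    if (is.null(dim(hv))) hv <- matrix(hv, nrow = length(idx))
    domEach <- max.col(hv, ties.method = "first")
    for (j in seq_len(k)) {
      sel <- labs == j
      frac <- tabulate(domEach[sel], nbins = length(phi)) / sum(sel)
      nspan[j] <- sum(frac >= spanMinFrac)
      # ownership at the centroid voxel
      cvox <- c(pmin(pmax(round(cx[j] / h[1] + 0.5), 1), dim(field)[1]),
                pmin(pmax(round(cy[j] / h[2] + 0.5), 1), dim(field)[2]),
                pmin(pmax(round(cz[j] / h[3] + 0.5), 1), dim(field)[3]))
      hc <- vapply(phi, function(p)
        interpolationH(p[cvox[1], cvox[2], cvox[3]]), numeric(1))
      o <- order(hc, decreasing = TRUE)
      owner[j] <- if (length(hc) > 1 && hc[o[1]] - hc[o[2]] < dominanceGap)
        "shared" else as.character(o[1])
    }
  }

  tb <- data.frame(label = seq_len(k), subtype = subtype, owner = owner,
                   nVoxels = nvox, volume = vol, surface = unname(surf),
                   sphericity = unname(psi), cx = unname(cx),
                   cy = unname(cy), cz = unname(cz), nCTspanned = nspan)
  new("DropletSet", table = tb, labelArray = lab, threshold = threshold,
      subtype = subtype)
}

#' @rdname droplet-accessors
setMethod("dropletTable", "DropletSet", function(object) object@table)

#' @rdname droplet-accessors
setMethod("dropletCount", "DropletSet", function(object) nrow(object@table))

setMethod("show", "DropletSet", function(object) {
  tb <- object@table
  cat(sprintf("DropletSet (%s): %d droplet(s) at threshold %.2g\n",
              object@subtype, nrow(tb), object@threshold))
  if (nrow(tb))
    cat(sprintf("  volumes %.3g-%.3g um^3, sphericity %.3g-%.3g\n",
                min(tb$volume), max(tb$volume),
                min(tb$sphericity, na.rm = TRUE),
                max(tb$sphericity, na.rm = TRUE)))
})

#' Cumulative distribution of cross-chromosome centroid distances
#'
#' All pairwise Euclidean distances between droplet centroids whose
#' owning chromosomes differ (the same-subtype, j != i pairing), sorted
#' into an empirical CDF. Droplets with `"shared"` or unknown ownership
#' are excluded from the pairing.
#'
#' @param droplets a [DropletSet-class] whose table carries owners.
#' @return data.frame with columns `distance` (um, sorted) and `cumfrac`;
#'   zero rows (with a warning) when fewer than two ownable droplets
#'   exist.
#' @export
centroidDistanceCdf <- function(droplets) {
  tb <- dropletTable(droplets)
  tb <- tb[!is.na(tb$owner) & tb$owner != "shared", , drop = FALSE]
  emptyCdf <- data.frame(distance = numeric(), cumfrac = numeric())
  if (nrow(tb) < 2) {
    warning("fewer than two owned droplets; empty distance table")
    return(emptyCdf)
  }
  pairs <- utils::combn(nrow(tb), 2)
  keep <- tb$owner[pairs[1, ]] != tb$owner[pairs[2, ]]
  if (!any(keep)) {
    warning("no cross-chromosome droplet pairs; empty distance table")
    return(emptyCdf)
  }
  p1 <- pairs[1, keep]; p2 <- pairs[2, keep]
  d <- sqrt((tb$cx[p1] - tb$cx[p2])^2 + (tb$cy[p1] - tb$cy[p2])^2 +
            (tb$cz[p1] - tb$cz[p2])^2)
  d <- sort(d)
  data.frame(distance = d, cumfrac = seq_along(d) / length(d))
}
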