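#' @include droplets.R geometry.R
NULL

#' Classify the morphological regime of a nuclear architecture
#'
#' Applies a reproducible decision rule to the droplet census of a final
#' state, producing one of the three regimes seen across the
#' (CT-exclusion, chromatin-type coupling) phase diagram:
#'
#' * `"disconnected-within-CT"`: at least as many droplets as
#'   territories, none spanning several territories — heterochromatin
#'   droplets confined within individual chromosomes.
#' * `"connected-interior"`: fused droplets (fewer than territories, or
#'   spanning ones) whose volume is concentrated near the nuclear
#'   center — at least `centralVolFrac` of the droplet volume has its
#'   centroid within `interiorRadius` of the center in normalized
#'   ellipsoidal coordinates.
#' * `"connected-across-boundaries"`: fused droplets sitting across
#'   territory boundaries away from the center.
#'
#' The thresholds are configurable; the regimes themselves are defined
#' qualitatively, so the defaults (interior = inner 50% of each semiaxis,
#' central volume majority) are stated here to make calls reproducible.
#'
#' @param droplets a [DropletSet-class] or list of them (one per
#'   heterochromatin subtype); tables must carry ownership/spanning
#'   columns, i.e. [labelDroplets()] must have been given `phi`.
#' @param ctCount number of chromosomal territories N.
#' @param geom a [NucleusGeometry-class].
#' @param interiorRadius normalized ellipsoidal radius bounding the
#'   "interior" (default 0.5).
#' @param centralVolFrac volume fraction that must be interior for a
#'   connected-interior call (default 0.5).
#' @return a [MorphologyCall-class]; a state with no droplets gives
#'   regime `NA` with a diagnostic message in the evidence.
#' @export
classifyMorphology <- function(droplets, ctCount, geom,
                               interiorRadius = 0.5,
                               centralVolFrac = 0.5) {
  if (is(droplets, "DropletSet")) droplets <- list(droplets)
  tb <- do.call(rbind, lapply(droplets, dropletTable))
  if (is.null(tb) || !nrow(tb))
    return(new("MorphologyCall", regime = NA_character_,
               evidence = list(message = "no droplets found",
                               nDroplets = 0L)))
  if (all(is.na(tb$nCTspanned)))
    stop("droplets carry no territory assignment; ",
         "run labelDroplets() with phi fields")
  a <- geom@semiaxes; x0 <- geom@center
  re <- sqrt(((tb$cx - x0[1]) / a[1])^2 + ((tb$cy - x0[2]) / a[2])^2 +
             ((tb$cz - x0[3]) / a[3])^2)
  nDrop <- nrow(tb)
  nSpanning <- sum(tb$nCTspanned >= 2L, na.rm = TRUE)
  centralFrac <- sum(tb$volume[re <= interiorRadius]) / sum(tb$volume)
  regime <- if (nDrop >= ctCount && nSpanning == 0L) {
    "disconnected-within-CT"
  } else if (centralFrac >= centralVolFrac) {
    "connected-interior"
  } else {
    "connected-across-boundaries"
  }
  new("MorphologyCall", regime = regime, evidence = list(
    nDroplets = nDrop, nSpanning = nSpanning,
    centralVolFrac = centralFrac, meanCentroidRadius = mean(re),
    interiorRadius = interiorRadius, ctCount = ctCount))
}

#' @rdname morphology-accessors
setMethod("regime", "MorphologyCall", function(object) object@regime)

#' @rdname morphology-accessors
setMethod("morphologyEvidence", "MorphologyCall",
          function(object) object@evidence)

setMethod("show", "MorphologyCall", function(object) {
  ev <- object@evidence
  cat(sprintf("MorphologyCall: %s\n", object@regime))
  if (!is.null(ev$nDroplets))
    cat(sprintf("  %d droplet(s), %s spanning, central volume fraction %.2f\n",
                ev$nDroplets,
                if (is.null(ev$nSpanning)) "?" else ev$nSpanning,
                if (is.null(ev$centralVolFrac)) NA else ev$centralVolFrac))
})
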