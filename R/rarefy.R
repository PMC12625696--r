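## Rarefaction: subsampling count profiles without replacement to a fixed
## depth. Only genuine read counts can be rarefied; relative-abundance
## profiles are refused rather than fabricating pseudo-counts.

#' Subsampling depth from a fraction of total reads
#'
#' `depth = round(total * fraction)` (half-up), floored at 1 read. The
#' fraction is interpreted per sample.
#'
#' @param total total read count of the sample (>= 1).
#' @param fraction proportion in (0, 1\].
#' @return integer depth.
#' @examples
#' depthFromFraction(2e7, 5e-5)  # 1000
#' @export
depthFromFraction <- function(total, fraction) {
  stopifnot(length(total) == 1L, length(fraction) == 1L)
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    dataError("fraction must lie in (0, 1]")
  if (!is.finite(total) || total < 1)
    dataError("total must be a positive read count")
  max(1L, as.integer(roundHalfUp(total * fraction)))
}

#' Rarefy a count profile to a fixed depth
#'
#' Draws `depth` reads without replacement (multivariate hypergeometric), so
#' the output total equals `depth` exactly and each taxon's expected
#' proportion equals its input proportion. Fully deterministic given `seed`.
#'
#' @param profile a [CountProfile-class].
#' @param depth target depth, `1 <= depth <= total`.
#' @param seed integer seed (required: rarefaction is a stochastic step and
#'   must be reproducible).
#' @return a [CountProfile-class] over the same taxa (zero counts retained)
#'   with total exactly `depth`.
#' @export
rarefyCounts <- function(profile, depth, seed) {
  stopifnot(is(profile, "CountProfile"), length(depth) == 1L)
  counts <- profile@counts
  total <- sum(counts)
  if (depth < 1 || depth > total)
    dataError("depth must lie in [1, ", total, "], got ", depth)
  depth <- as.integer(depth)
  if (depth == total) return(profile)
  sub <- withSeed(seed, {
    idx <- sample.int(total, depth)
    # read index r belongs to taxon k iff cumsum[k-1] < r <= cumsum[k]
    bins <- findInterval(idx, c(0, cumsum(counts)), left.open = TRUE)
    tabulate(bins, nbins = length(counts))
  })
  CountProfile(stats::setNames(sub, names(counts)), rank = profile@rank)
}

#' Measure the effect of rarefaction on the key reporting measures
#'
#' Computes the four key measures from count-bearing replicates before and
#' after rarefaction through the identical pathway (convert to percent
#' compositions, average, score against the reference), and reports the
#' per-measure change.
#'
#' @param reps a [ReplicateSet-class] of [CountProfile-class] replicates.
#' @param reference the ground-truth [Composition-class].
#' @param depth fixed target depth applied to every replicate, or `NULL` to
#'   use `fraction`/`minSample`.
#' @param fraction per-sample fraction of total reads (see
#'   [depthFromFraction()]).
#' @param minSample when `TRUE`, rarefy every replicate to the smallest
#'   replicate total.
#' @param seed integer seed; replicate `i` uses `seed + i - 1` so draws are
#'   independent but reproducible.
#' @param detectionThreshold forwarded to [computeKeyMeasures()].
#' @return list with `before` and `after` ([KeyMeasures-class]) and `delta`
#'   (named numeric, after minus before).
#' @export
rarefactionEffect <- function(reps, reference, depth = NULL, fraction = NULL,
                              minSample = FALSE, seed = 1,
                              detectionThreshold = 0) {
  stopifnot(is(reps, "ReplicateSet"), is(reference, "Composition"))
  profs <- reps@replicates
  if (!all(vapply(profs, is, logical(1), "CountProfile")))
    dataError("rarefaction requires count profiles; relative-abundance ",
              "profiles cannot be rarefied")
  totals <- vapply(profs, function(p) sum(p@counts), numeric(1))
  depths <- if (!is.null(depth)) {
    rep(as.integer(depth), length(profs))
  } else if (!is.null(fraction)) {
    vapply(totals, depthFromFraction, integer(1), fraction = fraction)
  } else if (minSample) {
    rep(as.integer(min(totals)), length(profs))
  } else {
    dataError("specify one of depth, fraction or minSample")
  }
  score <- function(comps) {
    avg <- averageReplicates(ReplicateSet(comps, reps@datasetId,
                                          reps@reagentId))
    computeKeyMeasures(avg, reference,
                       detectionThreshold = detectionThreshold)
  }
  before <- score(lapply(profs, asComposition))
  after <- score(lapply(seq_along(profs), function(i)
    asComposition(rarefyCounts(profs[[i]], depths[i], seed = seed + i - 1))))
  delta <- c(sensitivity = after@sensitivity - before@sensitivity,
             fpra = after@fpra - before@fpra,
             diversity = after@diversity - before@diversity,
             similarity = after@similarity - before@similarity)
  list(before = before, after = after, delta = delta, depths = depths)
}
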