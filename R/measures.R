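## The four key reporting measures, and the transformations applied to a
## profile before they are computed: exclusion of unassigned mass,
## replicate averaging, and 16S gene copy-number adjustment.

#' Exclude unassigned mass and renormalize
#'
#' Reads not assigned at the profiled rank must not dilute the reporting
#' measures: categories matching the unassigned keyword list (case-insensitive)
#' are removed and the remaining abundances rescaled to sum to 100. The
#' removed percent of the original mass is recorded in the result's
#' `unassignedPct` for bookkeeping.
#'
#' @param x a named numeric vector of non-negative abundances (any scale) or
#'   a [Composition-class].
#' @param rank rank of the profile (used when `x` is a bare vector).
#' @param keywords labels treated as unassigned (default `"unclassified"`,
#'   `"unassigned"`, `"uncultured"`; empty labels always count).
#' @return a [Composition-class] summing to 100.
#' @examples
#' excludeUnassigned(c(A = 40, B = 40, unassigned = 20), rank = "species")
#' @export
excludeUnassigned <- function(x, rank = c("species", "genus"),
                              keywords = c("unclassified", "unassigned",
                                           "uncultured")) {
  if (is(x, "Composition")) {
    rank <- x@rank
    x <- x@abundance
  } else {
    rank <- match.arg(rank)
  }
  if (any(!is.finite(x)) || any(x < 0))
    dataError("abundances must be finite and non-negative")
  un <- isUnassignedLabel(names(x), keywords)
  total <- sum(x)
  assigned <- x[!un]
  if (!length(assigned) || sum(assigned) <= 0)
    dataError("all abundance mass is unassigned; nothing to score")
  removed <- if (total > 0) 100 * sum(x[un]) / total else 0
  Composition(assigned, rank = rank, unassignedPct = removed)
}

#' Average replicate compositions
#'
#' Per-taxon arithmetic mean across the replicates of a
#' [ReplicateSet-class]; a taxon absent from a replicate contributes zero
#' there. Because each replicate sums to 100, so does the mean. Averaging is
#' applied before measure computation, not the other way around.
#'
#' @param reps a [ReplicateSet-class] of [Composition-class] replicates.
#' @return a [Composition-class]; its `unassignedPct` is the mean of the
#'   replicates' values.
#' @export
averageReplicates <- function(reps) {
  stopifnot(is(reps, "ReplicateSet"))
  comps <- reps@replicates
  if (!all(vapply(comps, is, logical(1), "Composition")))
    dataError("averageReplicates requires Composition replicates; ",
              "convert counts with asComposition() first")
  allTaxa <- unique(unlist(lapply(comps, function(cc) names(cc@abundance))))
  m <- vapply(comps, function(cc) {
    v <- stats::setNames(numeric(length(allTaxa)), allTaxa)
    v[names(cc@abundance)] <- cc@abundance
    v
  }, numeric(length(allTaxa)))
  mean_ab <- if (is.null(dim(m))) m else rowMeans(m)
  Composition(stats::setNames(mean_ab, allTaxa), rank = comps[[1L]]@rank,
              unassignedPct = mean(vapply(comps, function(cc) cc@unassignedPct,
                                          numeric(1))),
              normalize = FALSE)
}

#' Compute the four key reporting measures
#'
#' Given an observed composition and the reference (ground-truth)
#' composition at the same rank:
#' \describe{
#'   \item{sensitivity}{`100 * |TP| / |reference|`, where TP are reference
#'     taxa observed above `detectionThreshold`.}
#'   \item{FPRA}{summed observed abundance of taxa (above the threshold) not
#'     present in the reference; the observed vector sums to 100 so this is
#'     already a percentage.}
#'   \item{diversity}{observed richness `|TP| + |FP|`.}
#'   \item{similarity}{`100 * (1 - sum|x_obs - x_ref| / sum(x_obs + x_ref))`
#'     over the union of taxa, i.e. 100 x (1 - Bray-Curtis dissimilarity);
#'     absent taxa contribute 0, never a pseudocount.}
#' }
#' Taxon identity is decided on case-folded canonical labels. All four values
#' are returned at full precision; display rounding belongs to reporting
#' (see [applyDisplayRounding()]).
#'
#' @param observed,reference [Composition-class] objects at the same rank.
#' @param detectionThreshold percent abundance strictly above which a taxon
#'   counts as detected (default 0: any positive abundance).
#' @param gcn optional copy-number table (named numeric); when supplied, the
#'   copy-number-adjusted similarity is additionally computed via
#'   [gcnAdjust()] and stored in the `similarityGcn` slot.
#' @param gcnMissingPolicy forwarded to [gcnAdjust()].
#' @return a [KeyMeasures-class] object.
#' @examples
#' ref <- Composition(c(A = 50, B = 50), rank = "species")
#' obs <- Composition(c(A = 40, B = 40, C = 20), rank = "species")
#' computeKeyMeasures(obs, ref)  # sensitivity 100, FPRA 20, diversity 3,
#'                               # similarity 80
#' @export
computeKeyMeasures <- function(observed, reference, detectionThreshold = 0,
                               gcn = NULL,
                               gcnMissingPolicy = c("error", "default_one")) {
  stopifnot(is(observed, "Composition"), is(reference, "Composition"))
  if (length(reference@abundance) < 1L)
    dataError("reference composition is empty")
  if (observed@rank != reference@rank)
    dataError("observed (", observed@rank, ") and reference (",
              reference@rank, ") ranks differ")
  if (detectionThreshold < 0 || detectionThreshold >= 100)
    dataError("detectionThreshold must lie in [0, 100)")

  obs <- observed@abundance
  ref <- reference@abundance
  okey <- taxonKey(names(obs))
  rkey <- taxonKey(names(ref))

  detected <- okey[obs > detectionThreshold]
  nTP <- sum(rkey %in% detected)
  fpMask <- obs > detectionThreshold & !(okey %in% rkey)
  nFP <- sum(fpMask)
  sensitivity <- 100 * nTP / length(ref)
  fpra <- sum(obs[fpMask])

  new("KeyMeasures",
      sensitivity = sensitivity, fpra = fpra,
      diversity = as.numeric(nTP + nFP),
      similarity = brayCurtisSimilarity(obs, ref),
      similarityGcn = if (is.null(gcn)) NA_real_ else
        brayCurtisSimilarity(gcnAdjust(observed, gcn,
                                       match.arg(gcnMissingPolicy))@abundance,
                             ref),
      nTruePositive = as.integer(nTP), nFalsePositive = as.integer(nFP),
      referenceRichness = length(ref), rank = observed@rank,
      detectionThreshold = detectionThreshold)
}

# 100 * (1 - Bray-Curtis dissimilarity) on named percent vectors, matched on
# case-folded keys over the union of taxa.
brayCurtisSimilarity <- function(x, y) {
  keys <- union(taxonKey(names(x)), taxonKey(names(y)))
  xv <- yv <- stats::setNames(numeric(length(keys)), keys)
  xv[taxonKey(names(x))] <- xv[taxonKey(names(x))] + x
  yv[taxonKey(names(y))] <- yv[taxonKey(names(y))] + y
  denom <- sum(xv + yv)
  if (denom <= 0) return(100)
  100 * (1 - sum(abs(xv - yv)) / denom)
}

#' Adjust a genus-level composition for 16S gene copy number
#'
#' Marker-gene read proportions over-represent genera carrying many 16S rRNA
#' gene copies. Dividing each genus's abundance by its copy number and
#' renormalizing converts gene-copy proportions toward cell proportions.
#'
#' @param observed a genus-rank [Composition-class].
#' @param gcn named numeric vector of copy numbers (> 0), keyed by canonical
#'   genus (see [readGcnTable()]).
#' @param missingPolicy `"error"` rejects when a genus lacks a copy number,
#'   naming it; `"default_one"` substitutes 1 with a warning.
#' @return the adjusted [Composition-class] (sums to 100).
#' @examples
#' x <- Composition(c(A = 50, B = 50), rank = "genus")
#' gcnAdjust(x, c(A = 1, B = 4))  # A 80, B 20
#' @export
gcnAdjust <- function(observed, gcn, missingPolicy = c("error", "default_one")) {
  missingPolicy <- match.arg(missingPolicy)
  stopifnot(is(observed, "Composition"))
  if (observed@rank != "genus")
    dataError("copy-number adjustment applies to genus-rank compositions")
  if (any(!is.finite(gcn)) || any(gcn <= 0))
    dataError("copy numbers must be positive and finite")
  hit <- match(taxonKey(names(observed@abundance)), taxonKey(names(gcn)))
  copies <- unname(gcn[hit])
  if (anyNA(copies)) {
    missing <- names(observed@abundance)[is.na(copies)]
    if (missingPolicy == "error")
      dataError("no 16S copy number for: ", paste(missing, collapse = ", "))
    warning("no 16S copy number for ", paste(missing, collapse = ", "),
            "; using 1", call. = FALSE)
    copies[is.na(copies)] <- 1
  }
  Composition(observed@abundance / copies, rank = "genus",
              unassignedPct = observed@unassignedPct)
}

#' Apply the display-rounding policy to measure values
#'
#' Reporting convention inferred from the precision at which multi-lab
#' cohort tables are printed: sensitivity and similarity to the nearest whole
#' percent, FPRA to two decimals, diversity an exact integer. Rounding is
#' half-up ([roundHalfUp()]) and is applied only at output and before
#' threshold comparison -- never inside the measure computations.
#'
#' @param x a [KeyMeasures-class], or a data.frame with measure columns
#'   (`sensitivity`, `fpra`, `diversity`, `similarity`, optionally
#'   `similarity_gcn`).
#' @return object of the same shape with rounded values.
#' @export
applyDisplayRounding <- function(x) {
  if (is(x, "KeyMeasures")) {
    x@sensitivity <- roundHalfUp(x@sensitivity)
    x@fpra <- roundHalfUp(x@fpra, 2)
    x@diversity <- roundHalfUp(x@diversity)
    x@similarity <- roundHalfUp(x@similarity)
    if (!is.na(x@similarityGcn)) x@similarityGcn <- roundHalfUp(x@similarityGcn)
    return(x)
  }
  stopifnot(is.data.frame(x))
  for (col in intersect(c("sensitivity", "similarity", "diversity",
                          "similarity_gcn"), names(x)))
    x[[col]] <- roundHalfUp(x[[col]])
  if ("fpra" %in% names(x)) x$fpra <- roundHalfUp(x$fpra, 2)
  x
}
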