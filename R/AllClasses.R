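#' @import methods
NULL

.RANKS <- c("species", "genus")

#' Composition: a relative-abundance vector over named taxa
#'
#' A `Composition` holds relative abundances (percent, summing to 100) over
#' canonical taxon labels at a single rank (species or genus). The percent
#' mass that was removed as unassigned during renormalization is kept as
#' bookkeeping in `unassignedPct`.
#'
#' @slot abundance named numeric vector of percent abundances (sums to 100).
#' @slot rank `"species"` or `"genus"`.
#' @slot unassignedPct percent of the original mass that was unassigned and
#'   excluded before renormalization.
#' @seealso [Composition()], [excludeUnassigned()], [computeKeyMeasures()]
#' @export
setClass("Composition",
  representation(abundance = "numeric", rank = "character",
                 unassignedPct = "numeric"),
  prototype(unassignedPct = 0))

setValidity("Composition", function(object) {
  a <- object@abundance
  msg <- character()
  if (length(a) < 1L) msg <- c(msg, "composition must contain at least one taxon")
  if (is.null(names(a)) || any(!nzchar(names(a))))
    msg <- c(msg, "all abundances must be named")
  if (anyDuplicated(tolower(names(a))))
    msg <- c(msg, "duplicate taxon labels after case folding")
  if (any(!is.finite(a)) || any(a < 0))
    msg <- c(msg, "abundances must be finite and non-negative")
  if (length(a) >= 1L && abs(sum(a) - 100) > 1e-6)
    msg <- c(msg, sprintf("abundances must sum to 100 (got %.9g)", sum(a)))
  if (length(object@rank) != 1L || !object@rank %in% .RANKS)
    msg <- c(msg, "rank must be 'species' or 'genus'")
  if (length(object@unassignedPct) != 1L || object@unassignedPct < 0 ||
      object@unassignedPct > 100)
    msg <- c(msg, "unassignedPct must be a single value in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Construct a Composition
#'
#' @param abundance named numeric vector of non-negative abundances on any
#'   scale (percent, fractions, arbitrary positive weights); scaled to sum
#'   to 100 unless `normalize = FALSE`.
#' @param rank `"species"` or `"genus"`.
#' @param unassignedPct bookkeeping value, see [excludeUnassigned()].
#' @param normalize scale abundances to sum to 100 (default `TRUE`).
#' @return a [Composition-class] object.
#' @examples
#' Composition(c("Bacteroides fragilis" = 3, "Escherichia coli" = 1),
#'             rank = "species")
#' @export
Composition <- function(abundance, rank = c("species", "genus"),
                        unassignedPct = 0, normalize = TRUE) {
  rank <- match.arg(rank)
  if (normalize) {
    tot <- sum(abundance)
    if (!is.finite(tot) || tot <= 0)
      dataError("cannot normalize a composition with non-positive total abundance")
    abundance <- abundance / tot * 100
  }
  new("Composition", abundance = abundance, rank = rank,
      unassignedPct = unassignedPct)
}

#' CountProfile: integer read counts per taxon
#'
#' Count-bearing profiles are the inputs to rarefaction; converting to a
#' [Composition-class] divides by the total and scales to percent.
#'
#' @slot counts named numeric vector of non-negative whole numbers.
#' @slot rank `"species"` or `"genus"`.
#' @export
setClass("CountProfile",
  representation(counts = "numeric", rank = "character"))

setValidity("CountProfile", function(object) {
  k <- object@counts
  msg <- character()
  if (is.null(names(k)) || any(!nzchar(names(k))))
    msg <- c(msg, "all counts must be named")
  if (any(!is.finite(k)) || any(k < 0) || any(abs(k - round(k)) > 1e-9))
    msg <- c(msg, "counts must be finite non-negative whole numbers")
  if (sum(k) < 1) msg <- c(msg, "total count must be at least 1")
  if (length(object@rank) != 1L || !object@rank %in% .RANKS)
    msg <- c(msg, "rank must be 'species' or 'genus'")
  if (length(msg)) msg else TRUE
})

#' Construct a CountProfile
#' @param counts named numeric vector of non-negative whole read counts.
#' @param rank `"species"` or `"genus"`.
#' @return a [CountProfile-class] object.
#' @export
CountProfile <- function(counts, rank = c("species", "genus")) {
  new("CountProfile", counts = counts, rank = match.arg(rank))
}

#' ReplicateSet: technical replicates of one data set x reagent
#'
#' @slot datasetId identifier of the data set (e.g. a lab/run label).
#' @slot reagentId identifier of the reference reagent profiled.
#' @slot replicates list of [Composition-class] (or [CountProfile-class])
#'   objects, all at the same rank.
#' @export
setClass("ReplicateSet",
  representation(datasetId = "character", reagentId = "character",
                 replicates = "list"))

setValidity("ReplicateSet", function(object) {
  reps <- object@replicates
  msg <- character()
  if (length(reps) < 1L) msg <- c(msg, "at least one replicate is required")
  cls <- vapply(reps, function(r) class(r)[1L], character(1))
  if (!all(cls %in% c("Composition", "CountProfile")))
    msg <- c(msg, "replicates must be Composition or CountProfile objects")
  else {
    if (length(unique(cls)) > 1L)
      msg <- c(msg, "replicates must all be of the same class")
    rks <- vapply(reps, function(r) r@rank, character(1))
    if (length(unique(rks)) > 1L)
      msg <- c(msg, "replicates must share a single rank")
  }
  if (length(object@datasetId) != 1L || length(object@reagentId) != 1L)
    msg <- c(msg, "datasetId and reagentId must be single strings")
  if (length(msg)) msg else TRUE
})

#' Construct a ReplicateSet
#' @param replicates list of [Composition-class] or [CountProfile-class]
#'   objects at a common rank.
#' @param datasetId,reagentId identifying labels.
#' @return a [ReplicateSet-class] object.
#' @export
ReplicateSet <- function(replicates, datasetId = "dataset", reagentId = "RR") {
  new("ReplicateSet", datasetId = datasetId, reagentId = reagentId,
      replicates = replicates)
}

#' KeyMeasures: the four key reporting measures
#'
#' Sensitivity (percent of reference taxa detected), FPRA (summed percent
#' abundance of false-positive taxa), diversity (observed richness, true plus
#' false positives) and similarity (100 x (1 - Bray-Curtis dissimilarity)).
#' Values are stored at full precision; display rounding is applied only when
#' reporting (see [applyDisplayRounding()]).
#'
#' @slot sensitivity,fpra,similarity percent values in \[0, 100\].
#' @slot diversity observed richness (count).
#' @slot similarityGcn copy-number-adjusted similarity, `NA` unless computed.
#' @slot nTruePositive,nFalsePositive,referenceRichness integer bookkeeping.
#' @slot rank rank at which the measures were computed.
#' @slot detectionThreshold abundance floor used for detection calls.
#' @export
setClass("KeyMeasures",
  representation(sensitivity = "numeric", fpra = "numeric",
                 diversity = "numeric", similarity = "numeric",
                 similarityGcn = "numeric",
                 nTruePositive = "integer", nFalsePositive = "integer",
                 referenceRichness = "integer", rank = "character",
                 detectionThreshold = "numeric"),
  prototype(similarityGcn = NA_real_, detectionThreshold = 0))

setValidity("KeyMeasures", function(object) {
  msg <- character()
  pct <- c(sensitivity = object@sensitivity, fpra = object@fpra,
           similarity = object@similarity)
  if (any(!is.finite(pct)) || any(pct < -1e-9) || any(pct > 100 + 1e-9))
    msg <- c(msg, "sensitivity, FPRA and similarity must lie in [0, 100]")
  if (object@diversity < object@nTruePositive)
    msg <- c(msg, "diversity cannot be below the true-positive count")
  if (length(msg)) msg else TRUE
})

#' MqcThresholds: minimum quality criteria for one reagent
#'
#' Pass thresholds per measure: a data set passes when its display-rounded
#' sensitivity >= `minSensitivity`, FPRA <= `maxFpra`, diversity within
#' `diversityRange` (inclusive), and similarity >= `minSimilarity` (and, when
#' present, copy-number-adjusted similarity >= `minSimilarityGcn`).
#'
#' @slot reagent reagent identifier.
#' @slot minSensitivity,minSimilarity,minSimilarityGcn percent floors
#'   (`minSimilarityGcn` is `NA` when not calibrated).
#' @slot maxFpra percent ceiling.
#' @slot diversityRange inclusive integer range `c(lo, hi)`.
#' @export
setClass("MqcThresholds",
  representation(reagent = "character", minSensitivity = "numeric",
                 maxFpra = "numeric", diversityRange = "numeric",
                 minSimilarity = "numeric", minSimilarityGcn = "numeric"),
  prototype(minSimilarityGcn = NA_real_))

setValidity("MqcThresholds", function(object) {
  msg <- character()
  if (length(object@diversityRange) != 2L ||
      object@diversityRange[1L] > object@diversityRange[2L])
    msg <- c(msg, "diversityRange must be c(lo, hi) with lo <= hi")
  num <- c(object@minSensitivity, object@maxFpra, object@minSimilarity)
  if (any(!is.finite(num))) msg <- c(msg, "thresholds must be finite")
  if (length(msg)) msg else TRUE
})

#' CohortTable: per-data-set key measures for a cohort of laboratories
#'
#' Holds the long-format table of key reporting measures (one row per
#' data set x reagent), the ground-truth richness per reagent, and any
#' `Actual`/`MQC` rows of the source table as metadata (excluded from
#' calibration input).
#'
#' @slot data data.frame with columns `dataset`, `reagent`, `sensitivity`,
#'   `fpra`, `diversity`, `similarity` and optionally `similarity_gcn`.
#' @slot reagents character vector of reagent identifiers.
#' @slot rank rank of the underlying profiles.
#' @slot trueRichness named numeric, ground-truth richness per reagent
#'   (`NA` when unknown).
#' @slot actual data.frame of the `Actual` row(s) in long format (may be
#'   empty).
#' @slot printedMqc data.frame of the `MQC` row as printed (character cells;
#'   may be empty) -- metadata only, never used for calibration.
#' @export
setClass("CohortTable",
  representation(data = "data.frame", reagents = "character",
                 rank = "character", trueRichness = "numeric",
                 actual = "data.frame", printedMqc = "data.frame"))

setValidity("CohortTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("dataset", "reagent", "sensitivity", "fpra", "diversity",
            "similarity")
  if (!all(need %in% names(d)))
    msg <- c(msg, paste("data must contain columns:",
                        paste(setdiff(need, names(d)), collapse = ", ")))
  else if (length(unique(d$dataset)) < 2L)
    msg <- c(msg, "calibration requires at least 2 data sets")
  if (!all(object@reagents %in% d$reagent))
    msg <- c(msg, "every listed reagent must appear in the data")
  if (length(object@rank) != 1L || !object@rank %in% .RANKS)
    msg <- c(msg, "rank must be 'species' or 'genus'")
  if (length(msg)) msg else TRUE
})

#' LabErrorModel: error model for simulated laboratory observations
#'
#' Parameters of the generative model used by
#' [simulateObservedReplicates()]: each reference taxon is dropped
#' independently with probability `dropoutRate` (optionally weighted toward
#' low-abundance taxa), `Poisson(fpRate)` false-positive taxa are added
#' carrying `fpMass` percent of the total abundance, and surviving abundances
#' are jittered with multiplicative log-normal noise of coefficient of
#' variation `noiseCv`.
#'
#' @slot dropoutRate probability in \[0, 1\].
#' @slot fpRate expected number of false-positive taxa (>= 0).
#' @slot fpMass percent of total abundance given to false positives, \[0, 100).
#' @slot noiseCv coefficient of variation of the log-normal jitter (>= 0).
#' @slot seed integer seed; the simulation is fully determined by it.
#' @slot depthAware when `TRUE`, dropout probability is skewed toward
#'   low-abundance taxa (rank-weighted), emulating shallow sequencing.
#' @slot fpScope `"sister"` (false positives named as novel species within
#'   reference genera) or `"alien"` (novel genera).
#' @export
setClass("LabErrorModel",
  representation(dropoutRate = "numeric", fpRate = "numeric",
                 fpMass = "numeric", noiseCv = "numeric", seed = "numeric",
                 depthAware = "logical", fpScope = "character"),
  prototype(dropoutRate = 0, fpRate = 0, fpMass = 0, noiseCv = 0,
            depthAware = FALSE, fpScope = "sister"))

setValidity("LabErrorModel", function(object) {
  msg <- character()
  if (object@dropoutRate < 0 || object@dropoutRate > 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1]")
  if (object@fpRate < 0) msg <- c(msg, "fpRate must be non-negative")
  if (object@fpMass < 0 || object@fpMass >= 100)
    msg <- c(msg, "fpMass must lie in [0, 100)")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be non-negative")
  if (length(object@seed) != 1L || !is.finite(object@seed))
    msg <- c(msg, "seed must be a single finite number")
  if (!object@fpScope %in% c("sister", "alien"))
    msg <- c(msg, "fpScope must be 'sister' or 'alien'")
  if (length(msg)) msg else TRUE
})

#' Construct a LabErrorModel
#' @param dropoutRate,fpRate,fpMass,noiseCv,seed,depthAware,fpScope see
#'   [LabErrorModel-class].
#' @return a [LabErrorModel-class] object.
#' @examples
#' labErrorModel(dropoutRate = 0.25, fpMass = 5, seed = 1)
#' @export
labErrorModel <- function(dropoutRate = 0, fpRate = 0, fpMass = 0,
                          noiseCv = 0, seed = 1, depthAware = FALSE,
                          fpScope = c("sister", "alien")) {
  new("LabErrorModel", dropoutRate = dropoutRate, fpRate = fpRate,
      fpMass = fpMass, noiseCv = noiseCv, seed = seed,
      depthAware = depthAware, fpScope = match.arg(fpScope))
}

## ---- accessors ------------------------------------------------------------

#' Accessors for package classes
#'
#' `abundances()` returns the named percent vector of a [Composition-class];
#' `readCounts()` the named count vector of a [CountProfile-class];
#' `taxRank()` the rank of either; `taxa()` the taxon labels;
#' `unassignedPct()` the excluded unassigned mass; `replicates()` the
#' replicate list of a [ReplicateSet-class]; `measuresTable()` the long
#' data.frame of a [CohortTable-class]; `reagents()` its reagent ids;
#' `trueRichness()` its ground-truth richness per reagent.
#'
#' @param x an object of the appropriate class.
#' @return see description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setMethod("abundances", "Composition", function(x) x@abundance)

#' @rdname accessors
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))
#' @rdname accessors
#' @export
setMethod("readCounts", "CountProfile", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("taxRank", function(x) standardGeneric("taxRank"))
#' @rdname accessors
#' @export
setMethod("taxRank", "Composition", function(x) x@rank)
#' @rdname accessors
#' @export
setMethod("taxRank", "CountProfile", function(x) x@rank)
#' @rdname accessors
#' @export
setMethod("taxRank", "CohortTable", function(x) x@rank)

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setMethod("taxa", "Composition", function(x) names(x@abundance))
#' @rdname accessors
#' @export
setMethod("taxa", "CountProfile", function(x) names(x@counts))

#' @rdname accessors
#' @export
setGeneric("unassignedPct", function(x) standardGeneric("unassignedPct"))
#' @rdname accessors
#' @export
setMethod("unassignedPct", "Composition", function(x) x@unassignedPct)

#' @rdname accessors
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))
#' @rdname accessors
#' @export
setMethod("replicates", "ReplicateSet", function(x) x@replicates)

#' @rdname accessors
#' @export
setGeneric("measuresTable", function(x) standardGeneric("measuresTable"))
#' @rdname accessors
#' @export
setMethod("measuresTable", "CohortTable", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("reagents", function(x) standardGeneric("reagents"))
#' @rdname accessors
#' @export
setMethod("reagents", "CohortTable", function(x) x@reagents)

#' @rdname accessors
#' @export
setGeneric("trueRichness", function(x) standardGeneric("trueRichness"))
#' @rdname accessors
#' @export
setMethod("trueRichness", "CohortTable", function(x) x@trueRichness)

## ---- show methods ---------------------------------------------------------

setMethod("show", "Composition", function(object) {
  a <- sort(object@abundance, decreasing = TRUE)
  cat(sprintf("Composition (%s rank): %d taxa, unassigned excluded %.2f%%\n",
              object@rank, length(a), object@unassignedPct))
  head <- utils::head(a, 5L)
  for (i in seq_along(head))
    cat(sprintf("  %-40s %8.3f%%\n", names(head)[i], head[i]))
  if (length(a) > 5L) cat(sprintf("  ... and %d more taxa\n", length(a) - 5L))
})

setMethod("show", "CountProfile", function(object) {
  cat(sprintf("CountProfile (%s rank): %d taxa, %s reads\n", object@rank,
              length(object@counts), format(sum(object@counts), big.mark = ",")))
})

setMethod("show", "ReplicateSet", function(object) {
  cat(sprintf("ReplicateSet '%s' x '%s': %d replicate(s) [%s, %s rank]\n",
              object@datasetId, object@reagentId, length(object@replicates),
              class(object@replicates[[1L]]), object@replicates[[1L]]@rank))
})

setMethod("show", "KeyMeasures", function(object) {
  cat("Key reporting measures",
      sprintf("(%s rank, detection threshold %g%%):\n", object@rank,
              object@detectionThreshold))
  cat(sprintf("  sensitivity: %6.2f%%  (%d/%d reference taxa detected)\n",
              object@sensitivity, object@nTruePositive,
              object@referenceRichness))
  cat(sprintf("  FPRA:        %6.2f%%  (%d false-positive taxa)\n",
              object@fpra, object@nFalsePositive))
  cat(sprintf("  diversity:   %6d\n", as.integer(object@diversity)))
  cat(sprintf("  similarity:  %6.2f%%\n", object@similarity))
  if (!is.na(object@similarityGcn))
    cat(sprintf("  similarity (copy-number adjusted): %6.2f%%\n",
                object@similarityGcn))
})

setMethod("show", "MqcThresholds", function(object) {
  dr <- object@diversityRange
  div <- if (dr[1L] == dr[2L]) sprintf("%d", as.integer(dr[1L])) else
    sprintf("%d-%d", as.integer(dr[1L]), as.integer(dr[2L]))
  cat(sprintf("Minimum quality criteria [%s]:\n", object@reagent))
  cat(sprintf("  sensitivity >= %g%%, FPRA <= %.2f%%, diversity %s, similarity >= %g%%\n",
              object@minSensitivity, object@maxFpra, div, object@minSimilarity))
  if (!is.na(object@minSimilarityGcn))
    cat(sprintf("  copy-number-adjusted similarity >= %g%%\n",
                object@minSimilarityGcn))
})

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable (%s rank): %d data sets x %d reagent(s) [%s]\n",
              object@rank, length(unique(object@data$dataset)),
              length(object@reagents),
              paste(object@reagents, collapse = ", ")))
})

setMethod("show", "LabErrorModel", function(object) {
  cat(sprintf(paste0("LabErrorModel: dropout %.3g, fpRate %.3g, fpMass %.3g%%, ",
                     "noiseCv %.3g, seed %d%s, FP scope '%s'\n"),
              object@dropoutRate, object@fpRate, object@fpMass, object@noiseCv,
              as.integer(object@seed),
              if (object@depthAware) ", depth-aware dropout" else "",
              object@fpScope))
})

## ---- coercions ------------------------------------------------------------

#' Convert a CountProfile to a Composition
#' @param profile a [CountProfile-class].
#' @return a [Composition-class] with abundances `counts / total * 100`.
#' @export
asComposition <- function(profile) {
  stopifnot(is(profile, "CountProfile"))
  k <- profile@counts[profile@counts > 0]
  Composition(k, rank = profile@rank)
}

#' @export
#' @describeIn KeyMeasures-class one-row data.frame of the four measures.
#' @param x a `KeyMeasures` object.
#' @param row.names,optional,... ignored (S3 compatibility).
as.data.frame.KeyMeasures <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(sensitivity = x@sensitivity, fpra = x@fpra,
             diversity = x@diversity, similarity = x@similarity,
             similarity_gcn = x@similarityGcn)
}
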