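## Deriving Minimum Quality Criteria (MQC) from a cohort of per-data-set
## measures, assessing data sets against them, and cohort summary statistics.
##
## The calibration rule: across the cohort's data sets (Actual/MQC rows
## excluded), the lower quartile is the pass floor for sensitivity, diversity
## and similarity -- measures where higher is better -- and the upper
## quartile is the ceiling for FPRA, where lower is better. Quartiles use the
## Hyndman-Fan type-7 definition; thresholds are display-rounded half-up and
## comparisons are inclusive. The diversity ceiling is additionally capped at
## the ground-truth richness: observing more taxa than exist in the reagent
## is never rewarded.

#' Hyndman-Fan type-7 quantile
#'
#' Linear interpolation between order statistics at position
#' `h = (n - 1) p + 1`: the value is
#' `x_(floor(h)) + (h - floor(h)) (x_(ceil(h)) - x_(floor(h)))` on the sorted
#' sample. `p = 0` gives the minimum, `p = 1` the maximum, and the result is
#' monotone non-decreasing in `p`.
#'
#' @param values numeric vector (n >= 1, finite).
#' @param p probability / probabilities in \[0, 1\].
#' @return numeric vector of quantiles, one per element of `p`.
#' @examples
#' quantileHF7(c(1, 2, 3, 4), 0.5)  # 2.5
#' @export
quantileHF7 <- function(values, p) {
  if (!length(values)) dataError("cannot take a quantile of an empty vector")
  if (any(!is.finite(values))) dataError("quantile input must be finite")
  stopifnot(all(p >= 0 & p <= 1))
  s <- sort(values)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[pmin(lo + 1, n)] - s[lo])
}

#' Derive minimum quality criteria from a cohort
#'
#' For one reagent of a [CohortTable-class]: the pass floor for sensitivity
#' and similarity is the half-up-rounded (whole percent) lower quartile of
#' the cohort's values; the FPRA ceiling is the upper quartile rounded to two
#' decimals; the diversity range runs from the rounded lower quartile to the
#' rounded upper quartile capped at the ground-truth richness (collapsing to
#' a single value when the bounds meet). When the cohort carries a
#' copy-number-adjusted similarity column, its lower-quartile floor is
#' derived the same way.
#'
#' @param cohort a [CohortTable-class] (Actual/MQC rows already excluded by
#'   [readCohortTable()]).
#' @param reagent reagent identifier present in the cohort.
#' @param trueRichness optional override of the cohort's stored ground-truth
#'   richness for this reagent; when neither is available the diversity
#'   ceiling is the uncapped upper quartile.
#' @return an [MqcThresholds-class].
#' @export
deriveMqc <- function(cohort, reagent, trueRichness = NULL) {
  stopifnot(is(cohort, "CohortTable"))
  if (!reagent %in% cohort@reagents)
    dataError("unknown reagent '", reagent, "'; cohort has: ",
              paste(cohort@reagents, collapse = ", "))
  d <- cohort@data[cohort@data$reagent == reagent, ]
  richness <- if (!is.null(trueRichness)) trueRichness else
    unname(cohort@trueRichness[reagent])

  lo <- roundHalfUp(quantileHF7(d$diversity, 0.25))
  hi <- roundHalfUp(quantileHF7(d$diversity, 0.75))
  if (!is.null(richness) && is.finite(richness)) hi <- min(hi, richness)
  lo <- min(lo, hi)

  gcnFloor <- NA_real_
  if ("similarity_gcn" %in% names(d) && !anyNA(d$similarity_gcn))
    gcnFloor <- roundHalfUp(quantileHF7(d$similarity_gcn, 0.25))

  new("MqcThresholds", reagent = reagent,
      minSensitivity = roundHalfUp(quantileHF7(d$sensitivity, 0.25)),
      maxFpra = roundHalfUp(quantileHF7(d$fpra, 0.75), 2),
      diversityRange = c(lo, hi),
      minSimilarity = roundHalfUp(quantileHF7(d$similarity, 0.25)),
      minSimilarityGcn = gcnFloor)
}

#' Assess key measures against minimum quality criteria
#'
#' Display rounding is applied to the measures first (thresholds are printed
#' at display precision, so assessment happens on the same scale), then every
#' comparison is inclusive: sensitivity >= floor, FPRA <= ceiling, diversity
#' within the range, similarity >= floor. A value exactly at its threshold
#' passes.
#'
#' @param m a [KeyMeasures-class], or a named numeric vector / one-row
#'   data.frame with elements `sensitivity`, `fpra`, `diversity`,
#'   `similarity` and optionally `similarity_gcn`.
#' @param thresholds an [MqcThresholds-class].
#' @return named list with `flags` (named logical vector per measure; a
#'   `similarity_gcn` flag is present only when both the measure and its
#'   threshold exist) and `passAll` (conjunction of all flags).
#' @export
assessAgainstMqc <- function(m, thresholds) {
  stopifnot(is(thresholds, "MqcThresholds"))
  if (is(m, "KeyMeasures")) {
    m <- as.data.frame(m)
  } else if (!is.data.frame(m)) {
    m <- as.data.frame(as.list(m))
  }
  m <- applyDisplayRounding(m)
  flags <- c(
    sensitivity = m$sensitivity >= thresholds@minSensitivity,
    fpra = m$fpra <= thresholds@maxFpra,
    diversity = m$diversity >= thresholds@diversityRange[1L] &&
      m$diversity <= thresholds@diversityRange[2L],
    similarity = m$similarity >= thresholds@minSimilarity)
  if (!is.na(thresholds@minSimilarityGcn) &&
      !is.null(m$similarity_gcn) && !is.na(m$similarity_gcn))
    flags <- c(flags,
               similarity_gcn = m$similarity_gcn >= thresholds@minSimilarityGcn)
  list(flags = flags, passAll = all(flags))
}

#' Assess every data set of a cohort
#'
#' Applies [assessAgainstMqc()] to each data set x reagent row. Thresholds
#' are derived from the cohort itself unless supplied.
#'
#' @param cohort a [CohortTable-class].
#' @param thresholds optional named list of [MqcThresholds-class] objects,
#'   one per reagent (default: [deriveMqc()] per reagent).
#' @return data.frame with one row per data set x reagent: the measures,
#'   `pass_<measure>` flags and `pass_all`.
#' @export
assessCohort <- function(cohort, thresholds = NULL) {
  stopifnot(is(cohort, "CohortTable"))
  if (is.null(thresholds)) {
    thresholds <- lapply(cohort@reagents, function(r) deriveMqc(cohort, r))
    names(thresholds) <- cohort@reagents
  }
  d <- cohort@data
  res <- lapply(seq_len(nrow(d)), function(i) {
    a <- assessAgainstMqc(d[i, ], thresholds[[d$reagent[i]]])
    flags <- as.list(a$flags)
    names(flags) <- paste0("pass_", names(flags))
    cbind(d[i, ], as.data.frame(flags), pass_all = a$passAll)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Data sets passing every criterion for every reagent
#'
#' @param assessment output of [assessCohort()].
#' @return character vector of dataset identifiers whose rows have
#'   `pass_all` true for all reagents.
#' @export
passingDatasets <- function(assessment) {
  ok <- tapply(assessment$pass_all, assessment$dataset, all)
  names(ok)[ok]
}

#' Cohort summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation (SD/mean; reported as `NA` when the mean is zero) of each
#' measure, per reagent.
#'
#' @param cohort a [CohortTable-class] with at least two data sets.
#' @return data.frame with columns `reagent`, `measure`, `n`, `mean`, `sd`,
#'   `cv`.
#' @export
cohortSummary <- function(cohort) {
  stopifnot(is(cohort, "CohortTable"))
  d <- cohort@data
  measures <- intersect(.MEASURE_NAMES, names(d))
  rows <- list()
  for (rg in cohort@reagents) {
    for (m in measures) {
      v <- d[[m]][d$reagent == rg]
      v <- v[!is.na(v)]
      if (length(v) < 2L)
        dataError("summary requires >= 2 data sets per reagent")
      mu <- mean(v)
      sdev <- stats::sd(v)
      rows[[length(rows) + 1L]] <- data.frame(
        reagent = rg, measure = m, n = length(v), mean = mu, sd = sdev,
        cv = if (mu == 0) NA_real_ else sdev / mu)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a measure between two reagents (Mann-Whitney U)
#'
#' Two-sided unpaired Mann-Whitney U test using the normal approximation
#' with tie correction (no continuity correction). When every value across
#' both groups is tied the location shift is degenerate and p = 1 is
#' returned.
#'
#' @param cohort a [CohortTable-class] with exactly the two reagents to
#'   compare (or use `reagentPair` to pick two).
#' @param measure measure column to compare.
#' @param reagentPair length-2 character vector of reagent ids (default: the
#'   cohort's first two).
#' @return list with `U` (the U statistic of the first reagent's group),
#'   `p.value`, and the group sizes.
#' @export
compareReagents <- function(cohort, measure = c("sensitivity", "fpra",
                                                "diversity", "similarity",
                                                "similarity_gcn"),
                            reagentPair = NULL) {
  stopifnot(is(cohort, "CohortTable"))
  measure <- match.arg(measure)
  if (is.null(reagentPair)) reagentPair <- cohort@reagents[1:2]
  if (length(reagentPair) != 2L || !all(reagentPair %in% cohort@reagents))
    dataError("reagentPair must name two reagents present in the cohort")
  if (!measure %in% names(cohort@data))
    dataError("measure '", measure, "' not present in this cohort")
  x <- cohort@data[[measure]][cohort@data$reagent == reagentPair[1L]]
  y <- cohort@data[[measure]][cohort@data$reagent == reagentPair[2L]]
  if (length(x) < 3L || length(y) < 3L)
    dataError("need at least 3 observations per reagent")
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p.value = 1,
                n = c(length(x), length(y))))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = FALSE))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # zero tie-corrected variance
  list(U = unname(wt$statistic), p.value = p, n = c(length(x), length(y)))
}
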