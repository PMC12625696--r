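## Packaged multi-laboratory cohort fixtures: the per-data-set key reporting
## measures of an international collaborative study of two gut-microbiome DNA
## reference reagents ("HiLo", strain abundances spanning three orders of
## magnitude, and "Mix", even). The shotgun cohort (19 data sets, species
## rank, truth richness 19) and the 16S amplicon cohort (23 data sets, genus
## rank, truth richness 16, with copy-number-adjusted similarity) are shipped
## as plain TSVs; parallel 0/1 masks record which printed cells met the
## published criteria, for cross-validation of the assessment logic.

#' Path to a packaged data file
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return file path (or vector of file names).
#' @export
taxprofileQCFile <- function(file = NULL) {
  dir <- system.file("extdata", package = "taxprofileQC", mustWork = TRUE)
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) dataError("no packaged file '", file, "'")
  path
}

#' Packaged multi-lab cohort tables
#'
#' `cohortFixture("shotgun")` returns the shotgun-sequencing cohort
#' (19 data sets, species rank); `cohortFixture("amplicon")` the 16S rRNA
#' gene amplicon cohort (23 data sets, genus rank, including the
#' copy-number-adjusted similarity column). Both carry the `Actual` row
#' (hence the ground-truth richness) and the published criteria row as
#' metadata.
#'
#' @param which `"shotgun"` or `"amplicon"`.
#' @return a [CohortTable-class].
#' @examples
#' cohortFixture("shotgun")
#' @export
cohortFixture <- function(which = c("shotgun", "amplicon")) {
  which <- match.arg(which)
  readCohortTable(taxprofileQCFile(paste0(which, "_cohort.tsv")),
                  rank = if (which == "shotgun") "species" else "genus")
}

#' Published pass/fail marks for the packaged cohorts
#'
#' The 0/1 mask of which cells of the packaged cohort tables were marked as
#' meeting the published minimum quality criteria, in the same long layout
#' as [measuresTable()].
#'
#' @param which `"shotgun"` or `"amplicon"`.
#' @return data.frame with columns `dataset`, `reagent`, and one logical
#'   column per measure.
#' @export
boldFixture <- function(which = c("shotgun", "amplicon")) {
  which <- match.arg(which)
  ct <- readCohortTable(taxprofileQCFile(paste0(which, "_cohort_bold.tsv")),
                        rank = if (which == "shotgun") "species" else "genus")
  d <- ct@data
  for (m in intersect(.MEASURE_NAMES, names(d))) d[[m]] <- d[[m]] == 1
  d
}
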