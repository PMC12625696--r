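## Readers/writers for the tabular formats the tool touches. All files are
## tab-delimited UTF-8 with "." as decimal separator. Three profile dialects
## are understood:
##   plain     two columns (taxon, abundance) or taxon + one column per sample
##   metaphlan merged clade tables: pipe-delimited lineages, one column per
##             sample; only rows terminal at the requested rank are kept so
##             ancestor rows are not double counted
##   qiime     semicolon-delimited taxonomy strings plus abundance column(s);
##             rows without an assignment at the requested rank feed the
##             unassigned category

.readTsv <- function(path, header) {
  if (!file.exists(path)) dataError("file not found: ", path)
  force(header)
  utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#",
                    colClasses = "character", blank.lines.skip = TRUE)
}

# does the first data line look like a header? (any non-first cell that is
# not interpretable as a number)
.hasHeader <- function(path) {
  if (!file.exists(path)) dataError("file not found: ", path)
  ln <- readLines(path, n = 50L, warn = FALSE)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) dataError("file is empty: ", path)
  cells <- strsplit(ln[1L], "\t", fixed = TRUE)[[1L]]
  if (length(cells) < 2L) dataError("expected at least two tab-separated columns")
  suppressWarnings(any(is.na(as.numeric(cells[-1L]))))
}

.numericOrDie <- function(x, rowLabels, column) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1L]
    dataError("non-numeric abundance '", x[bad], "' at row '",
              rowLabels[bad], "', column '", column, "'")
  }
  v
}

#' Parse a taxonomic profile table
#'
#' Reads one or more samples from a profile table in one of three dialects
#' (see the `dialect` argument). Labels are canonicalized at the requested
#' rank, duplicate taxa are summed, and unassigned categories are excluded
#' with renormalization. The scale of each sample is autodetected: abundances
#' summing to about 1 are treated as fractions (scaled x100), to about 100 as
#' percent, and anything else as raw read counts -- count samples are
#' returned as [CountProfile-class] objects (eligible for rarefaction; the
#' unassigned rows are dropped from the counts) instead of
#' [Composition-class].
#'
#' @param path path to a TSV file.
#' @param dialect `"plain"`, `"metaphlan"` or `"qiime"`.
#' @param rank rank to extract (`"species"` or `"genus"`).
#' @param aliases optional alias map (see [readAliasTable()]).
#' @param keywords unassigned keyword list (see [excludeUnassigned()]).
#' @return named list of [Composition-class] / [CountProfile-class] objects,
#'   one per sample column.
#' @export
readProfileTable <- function(path, dialect = c("plain", "metaphlan", "qiime"),
                             rank = c("species", "genus"), aliases = NULL,
                             keywords = c("unclassified", "unassigned",
                                          "uncultured")) {
  dialect <- match.arg(dialect)
  rank <- match.arg(rank)
  header <- .hasHeader(path)
  tab <- .readTsv(path, header = header)
  if (ncol(tab) < 2L)
    dataError("profile table needs a taxon column plus >= 1 abundance column")
  rawNames <- tab[[1L]]
  sampleIds <- if (header) colnames(tab)[-1L] else
    if (ncol(tab) == 2L) tools::file_path_sans_ext(basename(path)) else
      paste0("sample", seq_len(ncol(tab) - 1L))

  keep <- rep(TRUE, nrow(tab))
  if (dialect == "metaphlan") {
    last <- vapply(strsplit(rawNames, "|", fixed = TRUE),
                   function(f) f[length(f)], character(1))
    keep <- startsWith(last, .RANK_PREFIX[[rank]])
    if (!any(keep))
      dataError("no rows terminal at rank '", rank, "' in MetaPhlAn table; ",
                "merged tables repeat every rank -- check the requested rank")
  }
  tab <- tab[keep, , drop = FALSE]
  rawNames <- rawNames[keep]
  if (!nrow(tab))
    dataError("no usable rows at rank '", rank, "' in ", path)

  canon <- vapply(rawNames, .canonicalizeOrNA, character(1), rank = rank,
                  USE.NAMES = FALSE)
  if (dialect == "plain" && anyNA(canon))
    dataError("empty taxon label at row ",
              paste(which(is.na(canon)), collapse = ", "), " of ", path)
  if (!is.null(aliases) && length(aliases)) {
    hit <- match(tolower(canon), tolower(names(aliases)))
    canon[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  unassigned <- is.na(canon) | isUnassignedLabel(ifelse(is.na(canon), "", canon),
                                                 keywords)
  if (all(unassigned))
    dataError("no rows assigned at rank '", rank, "' in ", path,
              if (dialect == "qiime")
                " (all taxonomy strings stop above the requested rank?)" else "")

  out <- vector("list", length(sampleIds))
  names(out) <- sampleIds
  for (j in seq_along(sampleIds)) {
    v <- .numericOrDie(tab[[j + 1L]], rawNames, colnames(tab)[j + 1L])
    if (any(v < 0))
      dataError("negative abundance at row '",
                rawNames[which(v < 0)[1L]], "' in sample '", sampleIds[j], "'")
    lab <- ifelse(unassigned, "unassigned", canon)
    agg <- vapply(split(v, factor(lab, levels = unique(lab))), sum, numeric(1))
    total <- sum(agg)
    if (total <= 0)
      dataError("sample '", sampleIds[j], "' has zero total abundance")
    out[[j]] <- if (total >= 0.9 && total <= 1.1) {
      excludeUnassigned(agg * 100, rank = rank, keywords = keywords)
    } else if (total >= 90 && total <= 110) {
      excludeUnassigned(agg, rank = rank, keywords = keywords)
    } else {
      k <- agg[!isUnassignedLabel(names(agg), keywords)]
      k <- k[k > 0]
      if (!length(k)) dataError("sample '", sampleIds[j],
                                "' has no assigned counts")
      CountProfile(round(k), rank = rank)
    }
  }
  out
}

#' Parse a reference (ground-truth) composition
#'
#' Two-column TSV (taxon, expected relative abundance). Abundances must be
#' strictly positive and are renormalized to sum to 100 (fractions summing to
#' 1 are therefore accepted). Duplicate taxa after canonicalization make the
#' ground truth ambiguous and are rejected.
#'
#' @param path path to the TSV file.
#' @param rank rank of the reference (`"species"` or `"genus"`).
#' @param aliases optional alias map (see [readAliasTable()]).
#' @return a [Composition-class]; its length is the reference richness.
#' @export
readReferenceComposition <- function(path, rank = c("species", "genus"),
                                     aliases = NULL) {
  rank <- match.arg(rank)
  tab <- .readTsv(path, header = .hasHeader(path))
  if (ncol(tab) != 2L)
    dataError("reference composition must have exactly two columns")
  canon <- canonicalizeName(tab[[1L]], rank, aliases = aliases)
  v <- .numericOrDie(tab[[2L]], tab[[1L]], colnames(tab)[2L])
  if (any(v <= 0))
    dataError("reference abundances must be strictly positive (offending: '",
              tab[[1L]][which(v <= 0)[1L]], "')")
  if (anyDuplicated(taxonKey(canon))) {
    dup <- canon[duplicated(taxonKey(canon))][1L]
    dataError("duplicate reference taxon after canonicalization: '", dup,
              "' -- the ground truth is ambiguous")
  }
  Composition(stats::setNames(v, canon), rank = rank)
}

#' Parse a 16S gene copy-number table
#'
#' Two-column TSV (taxon, copy number). Copy numbers must be strictly
#' positive; duplicate taxa are rejected.
#'
#' @param path path to the TSV file.
#' @param rank rank of the taxa (default genus, the rank at which
#'   copy-number adjustment operates).
#' @return named numeric vector keyed by canonical label.
#' @export
readGcnTable <- function(path, rank = "genus") {
  tab <- .readTsv(path, header = .hasHeader(path))
  if (!nrow(tab)) dataError("copy-number table is empty: ", path)
  if (ncol(tab) != 2L)
    dataError("copy-number table must have exactly two columns")
  canon <- canonicalizeName(tab[[1L]], rank)
  v <- .numericOrDie(tab[[2L]], tab[[1L]], colnames(tab)[2L])
  if (any(v <= 0))
    dataError("copy numbers must be strictly positive (offending: '",
              tab[[1L]][which(v <= 0)[1L]], "')")
  if (anyDuplicated(taxonKey(canon)))
    dataError("duplicate taxon in copy-number table: '",
              canon[duplicated(taxonKey(canon))][1L], "'")
  stats::setNames(v, canon)
}

.MEASURE_NAMES <- c("sensitivity", "fpra", "diversity", "similarity",
                    "similarity_gcn")

#' Parse a cohort table of per-data-set key measures
#'
#' Two layouts are accepted:
#' \itemize{
#'   \item wide: first column `dataset`, remaining headers
#'     `measure.reagent` (e.g. `sensitivity.HiLo`); one row per data set.
#'   \item long: columns `dataset`, `reagent`, then one column per measure
#'     (the layout written by [writeMeasuresReport()]).
#' }
#' Rows labelled `Actual` or `MQC` (case-insensitive) are excluded from the
#' calibration data but retained as metadata; the `Actual` row's diversity
#' provides the ground-truth richness per reagent.
#'
#' @param path path to the TSV file.
#' @param rank rank the measures were computed at (metadata).
#' @return a [CohortTable-class].
#' @export
readCohortTable <- function(path, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  tab <- .readTsv(path, header = TRUE)
  if (ncol(tab) < 2L || !nrow(tab))
    dataError("cohort table needs a dataset column plus measure columns")
  names(tab)[1L] <- "dataset"
  long <- "reagent" %in% names(tab)

  if (long) {
    reagentOf <- tab$reagent
    measureCols <- intersect(.MEASURE_NAMES, names(tab))
  } else {
    cols <- names(tab)[-1L]
    parts <- strsplit(cols, ".", fixed = TRUE)
    ok <- lengths(parts) == 2L & vapply(parts, `[`, character(1), 1L) %in%
      .MEASURE_NAMES
    if (!any(ok))
      dataError("no 'measure.reagent' columns found; expected headers like ",
                "'sensitivity.HiLo'")
    cols <- cols[ok]
    measures <- vapply(parts[ok], `[`, character(1), 1L)
    reags <- vapply(parts[ok], `[`, character(1), 2L)
  }

  label <- tolower(trimws(tab$dataset))
  isActual <- label == "actual"
  isMqc <- label == "mqc"
  dataRows <- which(!isActual & !isMqc)
  if (!length(dataRows))
    dataError("cohort table contains no data-set rows (only Actual/MQC)")

  toLong <- function(rows, numeric = TRUE) {
    if (!length(rows)) return(data.frame())
    if (long) {
      d <- tab[rows, c("dataset", "reagent", measureCols)]
      if (numeric)
        for (mc in measureCols)
          d[[mc]] <- .numericOrDie(d[[mc]], d$dataset, mc)
      rownames(d) <- NULL
      return(d)
    }
    pieces <- lapply(unique(reags), function(rg) {
      d <- data.frame(dataset = tab$dataset[rows], reagent = rg,
                      stringsAsFactors = FALSE)
      for (m in unique(measures[reags == rg])) {
        cell <- tab[rows, cols[measures == m & reags == rg][1L]]
        d[[m]] <- if (numeric) .numericOrDie(cell, d$dataset, m) else cell
      }
      d
    })
    do.call(rbind, pieces)
  }

  data <- toLong(dataRows)
  need <- setdiff(c("sensitivity", "fpra", "diversity", "similarity"),
                  names(data))
  if (length(need))
    dataError("cohort table is missing measure column(s): ",
              paste(need, collapse = ", "))
  actual <- toLong(which(isActual))
  printedMqc <- toLong(which(isMqc), numeric = FALSE)
  reagentIds <- unique(data$reagent)

  richness <- stats::setNames(rep(NA_real_, length(reagentIds)), reagentIds)
  if (nrow(actual))
    richness[actual$reagent] <- actual$diversity

  new("CohortTable", data = data, reagents = reagentIds, rank = rank,
      trueRichness = richness, actual = actual, printedMqc = printedMqc)
}

#' Write a measures/assessment report
#'
#' Writes one row per data set x reagent with the four measures (display
#' rounding applied once: sensitivity/similarity whole percent, FPRA two
#' decimals, diversity integer) plus any `pass_*` flag columns. The layout is
#' the long cohort layout, so [readCohortTable()] on the output recovers the
#' numeric payload exactly.
#'
#' @param rows data.frame with columns `dataset`, `reagent`, the measures and
#'   optional flags.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMeasuresReport <- function(rows, path) {
  if (!is.data.frame(rows) || !nrow(rows))
    dataError("nothing to report: empty measures table")
  need <- c("dataset", "reagent", "sensitivity", "fpra", "diversity",
            "similarity")
  if (!all(need %in% names(rows)))
    dataError("measures report needs columns: ",
              paste(setdiff(need, names(rows)), collapse = ", "))
  rows <- applyDisplayRounding(rows)
  ok <- tryCatch({
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    dataError("cannot write report to '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Write a composition or count profile as a plain two-column TSV
#'
#' @param x a [Composition-class] or [CountProfile-class].
#' @param path output file path.
#' @param comments optional character vector written as `#` header lines
#'   (used by the CLI to log seeds and parameters).
#' @return `path`, invisibly.
#' @export
writeProfile <- function(x, path, comments = character()) {
  v <- if (is(x, "Composition")) x@abundance else readCounts(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines("taxon\tabundance", con)
  writeLines(paste(names(v), format(v, trim = TRUE, scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}
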