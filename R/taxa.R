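## Taxon naming, canonicalization and rank handling.
##
## Pipelines emit the same organism under many spellings: MetaPhlAn-style
## "s__Lactobacillus_gasseri", QIIME-style "d__Bacteria;...;g__Lactobacillus",
## bracketed provisional genera "[Ruminococcus] gauvreauii". Scoring against a
## ground truth needs one identity rule, and continual reclassification of
## species (e.g. Lactobacillus gasseri vs the now-distinct Lactobacillus
## paragasseri) means naive string matching silently mis-scores. Canonical
## labels plus an optional user alias table are the answer here; no taxonomy
## database is consulted.

.RANK_PREFIX <- c(species = "s__", genus = "g__")

# default keywords marking unassigned mass, matched case-insensitively
.UNASSIGNED_KEYWORDS <- c("unclassified", "unassigned", "uncultured")

#' Canonicalize a taxon label
#'
#' Normalizes a raw label as read from a profile table: rank prefixes
#' (`s__`, `g__`) and lineage heads (pipe- or semicolon-delimited) are
#' stripped, underscores become spaces, square brackets are removed and
#' internal whitespace is collapsed. Case is preserved for display; equality
#' between labels is defined on the case-folded canonical form (see
#' [taxonKey()]). The operation is idempotent.
#'
#' For a full lineage string, the field carrying the requested rank's prefix
#' is used when present; otherwise the last non-empty field is taken.
#'
#' @param raw character vector of labels.
#' @param rank rank the labels are interpreted at.
#' @param aliases optional named character vector mapping old canonical names
#'   to replacements (as loaded by [readAliasTable()]); matching is
#'   case-insensitive.
#' @return character vector of canonical labels.
#' @examples
#' canonicalizeName("s__Lactobacillus_gasseri", "species")
#' canonicalizeName("[Ruminococcus] gauvreauii", "species")
#' canonicalizeName("k__Bacteria|g__Collinsella|s__Collinsella_aerofaciens",
#'                  "species")
#' @export
canonicalizeName <- function(raw, rank = c("species", "genus"),
                             aliases = NULL) {
  rank <- match.arg(rank)
  stopifnot(is.character(raw))
  out <- vapply(raw, function(x) .canonicalizeOne(x, rank), character(1),
                USE.NAMES = FALSE)
  if (!is.null(aliases) && length(aliases)) {
    hit <- match(tolower(out), tolower(names(aliases)))
    out[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  out
}

.canonicalizeOne <- function(x, rank) {
  lab <- .canonicalizeOrNA(x, rank)
  if (is.na(lab))
    dataError("taxon label '", x,
              "' is empty (or lacks a ", rank, " field) after normalization")
  lab
}

# Like .canonicalizeOne but returns NA_character_ when the label carries no
# information at the requested rank (empty label, empty rank field, or a
# prefixed lineage that stops above the requested rank). Parsers route NA to
# the unassigned category.
.canonicalizeOrNA <- function(x, rank) {
  if (is.na(x) || !nzchar(trimws(x))) return(NA_character_)
  lab <- x
  if (grepl("[|;]", lab)) {
    fields <- trimws(strsplit(lab, "[|;]")[[1L]])
    pref <- .RANK_PREFIX[[rank]]
    at <- grep(paste0("^", pref), fields)
    if (length(at)) {
      lab <- fields[at[length(at)]]
    } else if (any(grepl("^[a-zA-Z]__", fields))) {
      # a prefixed lineage without the requested rank's field carries no
      # assignment at that rank
      return(NA_character_)
    } else {
      fields <- fields[nzchar(fields)]
      if (!length(fields)) return(NA_character_)
      lab <- fields[length(fields)]
    }
  }
  lab <- sub("^[a-zA-Z]__", "", lab)
  lab <- gsub("_", " ", lab, fixed = TRUE)
  lab <- gsub("\\[|\\]", "", lab)
  lab <- gsub("\\s+", " ", trimws(lab))
  if (!nzchar(lab)) NA_character_ else lab
}

#' Case-folded identity key for canonical labels
#'
#' Two labels denote the same taxon iff their keys are identical.
#'
#' @param x character vector of canonical labels.
#' @return character vector of lower-cased keys.
#' @export
taxonKey <- function(x) tolower(x)

# genus of a species binomial = first whitespace token
genusOf <- function(species) sub("\\s.*$", "", species)

#' Aggregate a composition to a coarser rank
#'
#' Species-level abundances sharing a genus (first token of the binomial) are
#' summed; total abundance is conserved. Genus-level profiles cannot be
#' disaggregated to species.
#'
#' @param composition a [Composition-class].
#' @param target `"species"` or `"genus"`.
#' @return a [Composition-class] at `target` rank.
#' @examples
#' x <- Composition(c("Lactobacillus gasseri" = 3,
#'                    "Lactobacillus paragasseri" = 2,
#'                    "Bacteroides fragilis" = 95), rank = "species")
#' aggregateToRank(x, "genus")
#' @export
aggregateToRank <- function(composition, target = c("species", "genus")) {
  target <- match.arg(target)
  stopifnot(is(composition, "Composition"))
  if (composition@rank == target) return(composition)
  if (composition@rank == "genus" && target == "species")
    dataError("a genus-level composition cannot be disaggregated to species")
  a <- composition@abundance
  g <- genusOf(names(a))
  summed <- vapply(split(a, factor(g, levels = unique(g))), sum, numeric(1))
  Composition(summed, rank = target,
              unassignedPct = composition@unassignedPct, normalize = FALSE)
}

#' Read a taxon alias table
#'
#' A headerless two-column TSV (`raw_name`, `canonical_name`) mapping known
#' synonyms -- typically reclassified species -- onto the names used by the
#' reference composition. Both columns are canonicalized on load.
#'
#' @param path path to the TSV file.
#' @param rank rank at which the labels are interpreted.
#' @return named character vector (`old canonical` -> `new canonical`).
#' @export
readAliasTable <- function(path, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) != 2L)
    dataError("alias file must have exactly two tab-separated columns")
  from <- canonicalizeName(tab[[1L]], rank)
  to <- canonicalizeName(tab[[2L]], rank)
  if (anyDuplicated(tolower(from)))
    dataError("duplicate source names in alias file")
  stats::setNames(to, from)
}

# is a canonical label an unassigned placeholder?
isUnassignedLabel <- function(x, keywords = .UNASSIGNED_KEYWORDS) {
  !nzchar(x) | tolower(x) %in% tolower(keywords)
}
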