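## Synthetic mock communities and simulated laboratory observations.
##
## The generator plays two roles: it reconstructs the structure of the two
## reference-reagent designs (an even pool and a "HiLo" pool whose strain
## abundances span orders of magnitude), and it emulates what profiling
## pipelines actually report against such a truth -- taxa dropping out,
## false positives appearing (typically as close relatives of reagent taxa),
## and multiplicative abundance noise. Everything is driven by a single seed.

# Curated default panel: 20 strains, 19 species (the first species is carried
# by two strains), 16 genera -- the structural fingerprint of a 20-strain
# gut-community reagent that collapses to 19 species and 16 genera.
.DEFAULT_PANEL <- c(
  "Escherichia coli",
  "Bacteroides fragilis",
  "Bacteroides thetaiotaomicron",
  "Bacteroides vulgatus",
  "Lactobacillus gasseri",
  "Lactobacillus paragasseri",
  "Akkermansia muciniphila",
  "Faecalibacterium prausnitzii",
  "Bifidobacterium adolescentis",
  "Collinsella aerofaciens",
  "Ruminococcus gauvreauii",
  "Alistipes finegoldii",
  "Prevotella copri",
  "Roseburia intestinalis",
  "Blautia obeum",
  "Enterococcus faecalis",
  "Eubacterium rectale",
  "Parabacteroides distasonis",
  "Veillonella parvula")

#' Construct a synthetic reference (ground-truth) composition
#'
#' Builds a mock-community truth of `nStrains` strains. In `even` mode every
#' strain contributes equally; in `hilo` mode strains are assigned
#' round-robin to `tiers` abundance tiers spaced log-uniformly so the
#' most/least abundant strain ratio is exactly `10^spreadOrders`.
#' `duplicateSpecies` pairs of strains share a species name, so species
#' richness is `nStrains - duplicateSpecies` (with the default panel of 20
#' strains: 19 species collapsing to 16 genera). The result is normalized to
#' percent; at `rank = "genus"` the species are aggregated.
#'
#' @param nStrains number of strains (>= 2).
#' @param mode `"even"` or `"hilo"`.
#' @param spreadOrders orders of magnitude between the most and least
#'   abundant strain in `hilo` mode (> 0; default 3).
#' @param rank output rank.
#' @param duplicateSpecies number of species carried by two strains
#'   (< `nStrains`; default 1).
#' @param tiers number of abundance tiers in `hilo` mode (>= 2).
#' @return a [Composition-class].
#' @examples
#' makeReference(4, "even")               # four species at 25% each
#' makeReference(20, "hilo", rank = "genus")
#' @export
makeReference <- function(nStrains = 20L, mode = c("even", "hilo"),
                          spreadOrders = 3, rank = c("species", "genus"),
                          duplicateSpecies = 1L, tiers = 4L) {
  mode <- match.arg(mode)
  rank <- match.arg(rank)
  if (nStrains < 2L) dataError("nStrains must be at least 2")
  if (duplicateSpecies < 0L || duplicateSpecies >= nStrains)
    dataError("duplicateSpecies must be non-negative and below nStrains")
  if (mode == "hilo") {
    if (spreadOrders <= 0)
      dataError("spreadOrders must be positive in hilo mode")
    if (tiers < 2L) dataError("hilo mode needs at least 2 tiers")
    if (nStrains < tiers)
      dataError("hilo mode needs at least as many strains as tiers")
  }

  nSpecies <- nStrains - duplicateSpecies
  pool <- .DEFAULT_PANEL
  if (nSpecies > length(pool))
    pool <- c(pool, sprintf("Simulibacter species%d",
                            seq_len(nSpecies - length(pool))))
  species <- pool[seq_len(nSpecies)]
  # strains: each species once, then second strains of the first species
  strains <- c(species, species[seq_len(duplicateSpecies)])

  w <- if (mode == "even") rep(1, nStrains) else {
    tier <- ((seq_len(nStrains) - 1L) %% tiers) + 1L
    10^(-spreadOrders * (tier - 1L) / (tiers - 1L))
  }
  ab <- vapply(split(w, factor(strains, levels = species)), sum, numeric(1))
  out <- Composition(ab, rank = "species")
  if (rank == "genus") out <- aggregateToRank(out, "genus") else out
}

#' Simulate observed replicate profiles of a reference composition
#'
#' Emulates what a sequencing + profiling pipeline reports for each of
#' `nReplicates` technical replicates of the reagent, under a
#' [LabErrorModel-class]:
#' \enumerate{
#'   \item each reference taxon is independently dropped with probability
#'     `dropoutRate`; with `depthAware = TRUE` the per-taxon probability is
#'     proportional to the inverse abundance rank (least abundant taxa drop
#'     most readily, as at shallow sequencing depth), scaled so the mean
#'     equals `dropoutRate` and capped at 1. If everything drops, the most
#'     abundant taxon is retained so the replicate is scorable.
#'   \item survivors are jittered by multiplicative log-normal noise of
#'     unit mean and coefficient of variation `noiseCv`.
#'   \item `Poisson(fpRate)` false-positive taxa are added (at least one
#'     whenever `fpMass > 0`), named as novel sister species within the
#'     reference genera (`fpScope = "sister"`), or as alien genera
#'     (`fpScope = "alien"`, and always at genus rank where a novel species
#'     of a reference genus would not be a false positive).
#'   \item survivors are renormalized to `100 - fpMass` percent and the
#'     false-positive mass `fpMass` is split uniformly, so each replicate
#'     sums to 100 and carries exactly `fpMass` percent false-positive
#'     abundance.
#' }
#' The whole set is a deterministic function of `model@seed`.
#'
#' @param reference the ground-truth [Composition-class].
#' @param model a [LabErrorModel-class].
#' @param nReplicates number of replicates (default 5, the usual number of
#'   vials profiled per reagent).
#' @param datasetId,reagentId labels for the returned set.
#' @return a [ReplicateSet-class] of [Composition-class] replicates.
#' @examples
#' ref <- makeReference(20, "even")
#' sim <- simulateObservedReplicates(ref, labErrorModel(seed = 1))
#' computeKeyMeasures(averageReplicates(sim), ref)  # perfect recovery
#' @export
simulateObservedReplicates <- function(reference, model, nReplicates = 5L,
                                       datasetId = "simulated",
                                       reagentId = "RR") {
  stopifnot(is(reference, "Composition"), is(model, "LabErrorModel"))
  validObject(model)
  if (nReplicates < 1L) dataError("nReplicates must be at least 1")
  a <- reference@abundance
  if (!length(a)) dataError("reference composition is empty")

  pDrop <- rep(model@dropoutRate, length(a))
  if (model@depthAware && model@dropoutRate > 0) {
    # inverse abundance-rank weighting: rank 1 = least abundant
    r <- rank(a, ties.method = "first")
    wts <- 1 / r
    pDrop <- pmin(1, model@dropoutRate * wts / mean(wts))
  }
  sigma <- if (model@noiseCv > 0) sqrt(log(1 + model@noiseCv^2)) else 0
  useSister <- model@fpScope == "sister" && reference@rank == "species"
  refGenera <- unique(genusOf(names(a)))

  reps <- withSeed(model@seed, lapply(seq_len(nReplicates), function(i) {
    keep <- stats::runif(length(a)) >= pDrop
    if (!any(keep)) keep[which.max(a)] <- TRUE
    obs <- a[keep]
    if (sigma > 0)
      obs <- obs * stats::rlnorm(length(obs), meanlog = -sigma^2 / 2,
                                 sdlog = sigma)
    nFP <- stats::rpois(1L, model@fpRate)
    if (model@fpMass > 0) nFP <- max(1L, nFP)
    if (nFP > 0L && model@fpMass > 0) {
      fpNames <- if (useSister) {
        paste(sample(refGenera, nFP, replace = TRUE),
              sprintf("fictus%d", seq_len(nFP)))
      } else {
        sprintf(if (reference@rank == "species") "Novelgenus%d fictus"
                else "Novelgenus%d", seq_len(nFP))
      }
      obs <- obs / sum(obs) * (100 - model@fpMass)
      obs <- c(obs, stats::setNames(rep(model@fpMass / nFP, nFP), fpNames))
      Composition(obs, rank = reference@rank, normalize = FALSE)
    } else {
      Composition(obs, rank = reference@rank)
    }
  }))
  ReplicateSet(reps, datasetId = datasetId, reagentId = reagentId)
}
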