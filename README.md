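# taxprofileQC

Benchmarking taxonomic profiles against mock-community reference reagents.

Microbiome profiling pipelines disagree — platform, primers, classifier and
database all bias the reported composition. Profiling a reference reagent
(a DNA mock community of known composition) makes that bias measurable.
taxprofileQC is for labs and pipeline developers who run such reagents: it
scores a reported profile against the ground truth, calibrates pass/fail
quality criteria from a multi-laboratory cohort, and ships a synthetic
mock-community simulator so the whole pipeline is testable without any
sequencing data.

## The reporting system

For an observed percent composition `x_obs` and ground truth `x_ref` at one
rank (species for shotgun, genus for 16S amplicon data), after excluding
unassigned reads and averaging technical replicates:

* **sensitivity** `= 100 |TP| / R` — percentage of the `R` reference taxa
  detected;
* **FPRA** `= Σ_{i∉ref} x_obs,i` — false-positive relative abundance;
* **diversity** `= |TP| + |FP|` — observed richness;
* **similarity** `= 100 (1 − Σ|x_obs − x_ref| / Σ(x_obs + x_ref))`
  — 100 × (1 − Bray-Curtis dissimilarity), equal to `Σ min(x_obs, x_ref)`
  when both vectors sum to 100.

Minimum quality criteria (MQC) are calibrated from a cohort of data sets as
quartiles of these measures (Hyndman–Fan 7, half-up display rounding,
inclusive comparison): lower quartile as the floor for sensitivity,
diversity and similarity, upper quartile as the FPRA ceiling, with the
diversity ceiling capped at the true richness. 16S profiles can additionally
be adjusted for rRNA gene copy number, and count profiles rarefied without
replacement.

## Worked example

```r
library(taxprofileQC)

ref <- makeReference(20, "hilo")   # 20 strains, 19 species, 16 genera,
                                   # abundances spanning 3 orders of magnitude
sim <- simulateObservedReplicates(
  ref, labErrorModel(dropoutRate = 0.15, fpRate = 3, fpMass = 4,
                     noiseCv = 0.3, seed = 42, depthAware = TRUE))
computeKeyMeasures(averageReplicates(sim), ref)
#> Key reporting measures (species rank, detection threshold 0%):
#>   sensitivity: 100.00%  (19/19 reference taxa detected)
#>   FPRA:          4.00%  (12 false-positive taxa)
#>   diversity:       31
#>   similarity:   92.81%
```

Every reference taxon was recovered in at least one of the five averaged
replicates (hence sensitivity 100 despite 15% per-replicate dropout); the
false positives carry exactly the simulated 4% mass; diversity counts the
19 true positives plus 12 spurious taxa; similarity is the overlapping
abundance between the averaged profile and the truth.

Calibrating criteria from the packaged shotgun cohort (19 labs × 2
reagents) and assessing it:

```r
shotgun <- cohortFixture("shotgun")
deriveMqc(shotgun, "HiLo")
#> Minimum quality criteria [HiLo]:
#>   sensitivity >= 68%, FPRA <= 0.53%, diversity 13-19, similarity >= 75%
passingDatasets(assessCohort(shotgun))
#> [1] "Lab 10"        "Lab 13"        "Lab 15-NS2000" "Lab 18"
#> [5] "Lab 22"        "Lab 24"        "Lab 8"
```

Seven of the nineteen shotgun data sets meet every criterion for both
reagents. A command-line wrapper with `measures`, `mqc`, `simulate`,
`rarefy` and `fixtures` subcommands is installed at
`system.file("cli", "taxprofileQC", package = "taxprofileQC")`.

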