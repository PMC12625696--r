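test_that("excludeUnassigned removes unassigned mass and renormalizes", {
  x <- excludeUnassigned(c(A = 40, B = 40, unassigned = 20), rank = "species")
  expect_equal(abundances(x), c(A = 50, B = 50))
  expect_equal(unassignedPct(x), 20)
  # no unassigned mass: unchanged
  y <- excludeUnassigned(c(A = 60, B = 40), rank = "species")
  expect_equal(abundances(y), c(A = 60, B = 40))
  expect_equal(unassignedPct(y), 0)
  # keyword matching is case-insensitive and configurable
  z <- excludeUnassigned(c(A = 50, UNCLASSIFIED = 50), rank = "genus")
  expect_equal(abundances(z), c(A = 100))
  expect_error(excludeUnassigned(c(unassigned = 100), rank = "species"),
               "all abundance mass is unassigned")
})

test_that("averageReplicates takes per-taxon means with absences as zero", {
  a <- Composition(c(A = 50, B = 50), rank = "species")
  b <- Composition(c(A = 40, B = 50, C = 10), rank = "species")
  fiveSame <- ReplicateSet(rep(list(a), 5))
  expect_equal(abundances(averageReplicates(fiveSame)), abundances(a))

  # a taxon at 10% in one of five replicates averages to 2%
  withC <- ReplicateSet(c(rep(list(a), 4),
                          list(Composition(c(A = 45, B = 45, C = 10),
                                           rank = "species"))))
  expect_equal(abundances(averageReplicates(withC))[["C"]], 2)

  # replicate sets of any size >= 1 are accepted and sum to 100
  for (k in 1:5) {
    rs <- ReplicateSet(rep(list(a, b), length.out = k))
    expect_lt(abs(sum(abundances(averageReplicates(rs))) - 100), 1e-9)
  }
  # mixed ranks are rejected at construction
  expect_error(ReplicateSet(list(a, aggregateToRank(b, "genus"))), "rank")
})

test_that("computeKeyMeasures matches the worked example and edge cases", {
  ref <- Composition(c(A = 50, B = 50), rank = "species")
  obs <- Composition(c(A = 40, B = 40, C = 20), rank = "species")
  km <- computeKeyMeasures(obs, ref)
  expect_equal(km@sensitivity, 100)
  expect_equal(km@fpra, 20)
  expect_equal(km@diversity, 3)
  expect_equal(km@similarity, 80)

  # observed == reference: perfect scores at the reference richness
  ref19 <- makeReference(20, "even")
  perfect <- computeKeyMeasures(ref19, ref19)
  expect_equal(perfect@sensitivity, 100)
  expect_equal(perfect@fpra, 0)
  expect_equal(perfect@diversity, 19)
  expect_equal(perfect@similarity, 100)

  # disjoint supports: nothing recovered
  alien <- Composition(c(X = 60, Y = 40), rank = "species")
  none <- computeKeyMeasures(alien, ref)
  expect_equal(none@sensitivity, 0)
  expect_equal(none@fpra, 100)
  expect_equal(none@similarity, 0)

  expect_error(computeKeyMeasures(aggregateToRank(obs, "genus"), ref),
               "ranks differ")
})

test_that("taxon matching in scoring is case-folded", {
  ref <- Composition(c("Escherichia coli" = 100), rank = "species")
  obs <- Composition(c("ESCHERICHIA COLI" = 100), rank = "species")
  km <- computeKeyMeasures(obs, ref)
  expect_equal(km@sensitivity, 100)
  expect_equal(km@similarity, 100)
})

test_that("similarity equals the sum-of-minima overlap oracle and is metric-sane", {
  set.seed(97)
  for (i in 1:50) {
    n <- sample(2:25, 1)
    x <- randomComposition(n)
    # y shares a random subset of x's taxa
    yNames <- c(sample(taxa(x), sample(n, 1)),
                paste0("Other sp", seq_len(sample(5, 1))))
    y <- Composition(setNames(runif(length(yNames)), yNames),
                     rank = "species")
    sxy <- computeKeyMeasures(x, y)@similarity
    expect_equal(sxy, overlapSimilarity(abundances(x), abundances(y)),
                 tolerance = 1e-9)
    # symmetry, identity, bounds
    expect_equal(sxy, computeKeyMeasures(y, x)@similarity, tolerance = 1e-9)
    expect_true(sxy >= 0 && sxy <= 100)
    expect_equal(computeKeyMeasures(x, x)@similarity, 100)
  }
})

test_that("similarity agrees with an independent Bray-Curtis routine", {
  skip_if_not_installed("vegan")
  set.seed(13)
  for (i in 1:25) {
    x <- randomComposition(sample(3:20, 1))
    y <- randomComposition(sample(3:20, 1))
    keys <- union(taxa(x), taxa(y))
    m <- rbind(ifelse(keys %in% taxa(x), abundances(x)[keys], 0),
               ifelse(keys %in% taxa(y), abundances(y)[keys], 0))
    m[is.na(m)] <- 0
    expect_equal(computeKeyMeasures(x, y)@similarity,
                 100 * (1 - as.numeric(vegan::vegdist(m, method = "bray"))),
                 tolerance = 1e-9)
  }
})

test_that("FPRA complements the observed reference mass and diversity decomposes", {
  set.seed(7)
  for (i in 1:25) {
    ref <- randomComposition(sample(3:15, 1))
    obsNames <- c(sample(taxa(ref), sample(length(taxa(ref)), 1)),
                  paste0("FalsePos sp", seq_len(sample(6, 1))))
    obs <- Composition(setNames(runif(length(obsNames)), obsNames),
                       rank = "species")
    km <- computeKeyMeasures(obs, ref)
    refMass <- sum(abundances(obs)[taxa(obs) %in% taxa(ref)])
    expect_equal(km@fpra + refMass, 100, tolerance = 1e-9)
    expect_identical(as.integer(km@diversity),
                     km@nTruePositive + km@nFalsePositive)
    expect_equal(round(km@sensitivity * km@referenceRichness / 100) +
                   km@nFalsePositive, km@diversity)
  }
})

test_that("detection threshold turns low-abundance taxa into non-detections", {
  ref <- Composition(c(A = 50, B = 50), rank = "species")
  obs <- Composition(c(A = 99.5, B = 0.3, C = 0.2), rank = "species")
  km0 <- computeKeyMeasures(obs, ref)
  km1 <- computeKeyMeasures(obs, ref, detectionThreshold = 0.5)
  expect_equal(km0@sensitivity, 100)
  expect_equal(km0@diversity, 3)
  expect_equal(km1@sensitivity, 50)  # B falls below the floor
  expect_equal(km1@diversity, 1)
  expect_equal(km1@fpra, 0)          # C is no longer a detected FP
})

test_that("gcnAdjust divides by copy number and renormalizes", {
  x <- Composition(c(A = 50, B = 50), rank = "genus")
  adj <- gcnAdjust(x, c(A = 1, B = 4))
  expect_equal(abundances(adj), c(A = 80, B = 20))
  # constant copy numbers leave the composition unchanged
  same <- gcnAdjust(x, c(A = 7, B = 7))
  expect_equal(abundances(same), abundances(x), tolerance = 1e-9)
  # missing-policy behaviour
  expect_error(gcnAdjust(x, c(A = 1), "error"), "B")
  expect_warning(def <- gcnAdjust(x, c(A = 1), "default_one"), "using 1")
  expect_equal(abundances(def), abundances(gcnAdjust(x, c(A = 1, B = 1))))
  # species-rank profiles are refused
  sp <- Composition(c("A b" = 100), rank = "species")
  expect_error(gcnAdjust(sp, c("A b" = 2)), "genus")
})

test_that("display rounding is half-up at the documented precision", {
  expect_equal(roundHalfUp(74.5), 75)
  expect_equal(roundHalfUp(1.285, 2), 1.29)
  expect_equal(roundHalfUp(4.085, 2), 4.09)
  expect_equal(roundHalfUp(60.5), 61)
  expect_equal(roundHalfUp(-1.5), -2)
  km <- new("KeyMeasures", sensitivity = 94.5, fpra = 0.535, diversity = 16,
            similarity = 54.49, nTruePositive = 15L, nFalsePositive = 1L,
            referenceRichness = 16L, rank = "genus")
  r <- applyDisplayRounding(km)
  expect_equal(r@sensitivity, 95)
  expect_equal(r@fpra, 0.54)
  expect_equal(r@similarity, 54)
})
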