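test_that("quantileHF7 matches the hand-computable cases", {
  expect_equal(quantileHF7(c(1, 2, 3, 4), 0.5), 2.5)
  expect_equal(quantileHF7(c(5, 1, 9), 0), 1)
  expect_equal(quantileHF7(c(5, 1, 9), 1), 9)
  expect_equal(quantileHF7(7, 0.37), 7)  # n = 1
  # the upper quartile of the packaged shotgun HiLo FPRA column underlies
  # the published 0.53 criterion
  d <- measuresTable(cohortFixture("shotgun"))
  expect_equal(quantileHF7(d$fpra[d$reagent == "HiLo"], 0.75), 0.53)
  expect_error(quantileHF7(numeric(), 0.5), "empty")
  expect_error(quantileHF7(c(1, Inf), 0.5), "finite")
})

test_that("quantileHF7 agrees with a brute-force implementation on random vectors", {
  set.seed(2024)
  for (i in 1:1000) {
    x <- rnorm(sample(1:40, 1), sd = 10)
    p <- runif(1)
    expect_lt(abs(quantileHF7(x, p) - bruteQuantile7(x, p)), 1e-12)
  }
  # and with the reference interpolation in stats::quantile (type 7)
  set.seed(3)
  for (i in 1:50) {
    x <- runif(sample(2:30, 1)) * 100
    p <- runif(3)
    expect_equal(quantileHF7(x, p), unname(stats::quantile(x, p, type = 7)),
                 tolerance = 1e-12)
  }
  # monotone in p
  x <- rnorm(17)
  ps <- sort(runif(25))
  expect_true(all(diff(quantileHF7(x, ps)) >= -1e-12))
})

test_that("deriveMqc reproduces the published shotgun criteria", {
  sg <- cohortFixture("shotgun")
  hilo <- deriveMqc(sg, "HiLo")
  expect_equal(hilo@minSensitivity, 68)
  expect_equal(hilo@maxFpra, 0.53)
  expect_equal(hilo@diversityRange, c(13, 19))
  expect_equal(hilo@minSimilarity, 75)
  mix <- deriveMqc(sg, "Mix")
  expect_equal(mix@minSensitivity, 95)
  expect_equal(mix@maxFpra, 1.29)
  expect_equal(mix@diversityRange, c(18, 19))  # UQ capped at truth richness
  expect_equal(mix@minSimilarity, 72)
  expect_error(deriveMqc(sg, "nope"), "unknown reagent")
})

test_that("deriveMqc reproduces the published 16S criteria including GCN columns", {
  am <- cohortFixture("amplicon")
  hilo <- deriveMqc(am, "HiLo")
  expect_equal(hilo@minSensitivity, 94)
  expect_equal(hilo@maxFpra, 0.50)
  expect_equal(hilo@diversityRange, c(16, 16))  # cap collapses the range
  expect_equal(hilo@minSimilarity, 55)
  expect_equal(hilo@minSimilarityGcn, 54)
  mix <- deriveMqc(am, "Mix")
  expect_equal(mix@minSensitivity, 94)
  expect_equal(mix@maxFpra, 4.09)
  expect_equal(mix@diversityRange, c(16, 16))
  expect_equal(mix@minSimilarity, 68)
  expect_equal(mix@minSimilarityGcn, 61)
})

test_that("a constant cohort calibrates to its own values", {
  p <- writeTempTsv(c(
    "dataset\tsensitivity.R\tfpra.R\tdiversity.R\tsimilarity.R",
    "d1\t90\t1.5\t17\t80", "d2\t90\t1.5\t17\t80", "d3\t90\t1.5\t17\t80"))
  t <- deriveMqc(readCohortTable(p), "R")
  expect_equal(t@minSensitivity, 90)
  expect_equal(t@maxFpra, 1.5)
  expect_equal(t@diversityRange, c(17, 17))
  expect_equal(t@minSimilarity, 80)
})

test_that("assessment is inclusive at the thresholds", {
  t <- new("MqcThresholds", reagent = "R", minSensitivity = 68,
           maxFpra = 0.53, diversityRange = c(13, 19), minSimilarity = 75)
  atBound <- c(sensitivity = 68, fpra = 0.53, diversity = 19, similarity = 75)
  expect_true(assessAgainstMqc(atBound, t)$passAll)
  # rounding happens before comparison: 67.5 rounds up to the floor
  expect_true(assessAgainstMqc(c(sensitivity = 67.5, fpra = 0.534,
                                 diversity = 13, similarity = 74.5),
                               t)$passAll)
  just <- assessAgainstMqc(c(sensitivity = 67.4, fpra = 0.54,
                             diversity = 12, similarity = 74.4), t)
  expect_false(any(just$flags))
})

test_that("per-cell pass flags reproduce the published marks on both cohorts", {
  for (which in c("shotgun", "amplicon")) {
    cohort <- cohortFixture(which)
    ass <- assessCohort(cohort)
    bold <- boldFixture(which)
    key <- function(d) paste(d$dataset, d$reagent)
    ass <- ass[match(key(bold), key(ass)), ]
    for (m in intersect(c("sensitivity", "fpra", "diversity", "similarity",
                          "similarity_gcn"), names(bold)))
      expect_identical(ass[[paste0("pass_", m)]], bold[[m]],
                       label = paste(which, m))
  }
})

test_that("known passing labs pass everything for both reagents", {
  sg <- assessCohort(cohortFixture("shotgun"))
  expect_setequal(passingDatasets(sg),
                  c("Lab 8", "Lab 10", "Lab 13", "Lab 15-NS2000", "Lab 18",
                    "Lab 22", "Lab 24"))
  am <- assessCohort(cohortFixture("amplicon"))
  expect_setequal(passingDatasets(am),
                  c("Lab 8-R", "Lab 13", "Lab 14", "Lab 23"))
})

test_that("weakening any threshold never fails a previously passing data set", {
  sg <- cohortFixture("shotgun")
  base <- deriveMqc(sg, "HiLo")
  weaker <- new("MqcThresholds", reagent = "HiLo",
                minSensitivity = base@minSensitivity - 5,
                maxFpra = base@maxFpra + 1,
                diversityRange = base@diversityRange + c(-2, 3),
                minSimilarity = base@minSimilarity - 10)
  d <- measuresTable(sg)
  d <- d[d$reagent == "HiLo", ]
  for (i in seq_len(nrow(d))) {
    before <- assessAgainstMqc(d[i, ], base)
    after <- assessAgainstMqc(d[i, ], weaker)
    expect_true(all(after$flags[before$flags]), label = d$dataset[i])
  }
})

test_that("cohortSummary computes mean, SD and CV with the n-1 convention", {
  p <- writeTempTsv(c(
    "dataset\tsensitivity.R\tfpra.R\tdiversity.R\tsimilarity.R",
    "d1\t10\t0\t5\t50", "d2\t20\t0\t5\t60", "d3\t30\t0\t5\t70"))
  s <- cohortSummary(readCohortTable(p))
  sens <- s[s$measure == "sensitivity", ]
  expect_equal(sens$mean, 20)
  expect_equal(sens$sd, 10)
  expect_equal(sens$cv, 0.5)
  expect_equal(s$cv[s$measure == "diversity"], 0)   # constant column
  expect_true(is.na(s$cv[s$measure == "fpra"]))     # zero mean
  # shotgun profiles vary more than 16S ones on the packaged cohorts
  cvOf <- function(w, m) {
    s <- cohortSummary(cohortFixture(w))
    mean(s$cv[s$measure == m], na.rm = TRUE)
  }
  expect_gt(cvOf("shotgun", "similarity"), cvOf("amplicon", "similarity"))
})

test_that("compareReagents is a two-sided Mann-Whitney with sane edge cases", {
  p <- writeTempTsv(c(
    "dataset\tsensitivity.A\tfpra.A\tdiversity.A\tsimilarity.A\tsensitivity.B\tfpra.B\tdiversity.B\tsimilarity.B",
    "d1\t1\t0\t1\t1\t10\t0\t1\t1",
    "d2\t2\t0\t1\t1\t11\t0\t1\t1",
    "d3\t3\t0\t1\t1\t12\t0\t1\t1"))
  ct <- readCohortTable(p)
  r <- compareReagents(ct, "sensitivity")
  expect_equal(r$U, bruteU(c(1, 2, 3), c(10, 11, 12)))  # = 0
  expect_lt(r$p.value, 0.1)
  # identical columns: no location shift
  expect_equal(compareReagents(ct, "diversity")$p.value, 1)
  # U statistic matches brute-force enumeration, including with ties
  set.seed(5)
  for (i in 1:10) {
    x <- sample(0:5, 8, replace = TRUE)
    y <- sample(0:5, 6, replace = TRUE)
    rows <- data.frame(dataset = paste0("d", c(seq_along(x), seq_along(y))),
                       reagent = rep(c("A", "B"), c(length(x), length(y))),
                       sensitivity = c(x, y), fpra = 0, diversity = 1,
                       similarity = 1)
    f <- withr::local_tempfile(fileext = ".tsv")
    utils::write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_equal(compareReagents(readCohortTable(f), "sensitivity")$U,
                 bruteU(x, y))
  }
  # the packaged shotgun sensitivity columns differ between reagents
  sg <- cohortFixture("shotgun")
  expect_lt(compareReagents(sg, "sensitivity")$p.value, 0.05)
})
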