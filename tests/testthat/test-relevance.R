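# Eigenvalue-based relevance labelling and preprocessing.

test_that("doubling-time bound arithmetic", {
  expect_equal(eigenvalueBoundFromDoublingTime(21, 3), -60 * 3 / 21)
  expect_equal(eigenvalueBoundFromDoublingTime(21, 3), -60 / 7, tolerance = 1e-12)
  expect_equal(eigenvalueBoundFromDoublingTime(60, 3), -3)
  expect_equal(eigenvalueBoundFromDoublingTime(60, 1), -1)
  expect_error(eigenvalueBoundFromDoublingTime(-5), "> 0")
  # the operational integer bound rounds -60/7
  expect_equal(ECOLI_RELEVANCE_BOUND, round(eigenvalueBoundFromDoublingTime(21, 3)))
})

test_that("stability report: max real part, stability flag and tau", {
  r1 <- stabilityReport(c(-60, -200))
  expect_true(r1@stable)
  expect_equal(r1@tau, 1)               # 60/60 min
  r2 <- stabilityReport(c(-9, -50))
  expect_equal(r2@tau, 60 / 9)          # about 6.67 min, under ~7 min
  r3 <- stabilityReport(c(0.1, -50))
  expect_false(r3@stable)
  expect_true(is.na(r3@tau))
  expect_error(stabilityReport(complex(0)), "empty")
})

test_that("relevance labelling uses a strict negative bound", {
  mk <- function(maxReal) stabilityReport(c(maxReal, -50))
  expect_identical(labelRelevance(mk(-12.3), bound = -9), "relevant")
  expect_identical(labelRelevance(mk(-5), bound = -9), "irrelevant")
  expect_identical(labelRelevance(mk(-9), bound = -9), "irrelevant")  # boundary
  expect_error(labelRelevance(mk(-12), bound = 2), "negative")
})

test_that("relevance is monotone in the eigenvalue real part", {
  bound <- -9
  reals <- seq(-30, 5, by = 0.5)
  labels <- vapply(reals, function(m)
    labelRelevance(stabilityReport(c(m, -100)), bound), character(1))
  # once irrelevant (too slow), more negative never flips back
  firstIrrelevant <- match("irrelevant", labels)
  expect_true(all(labels[seq_len(firstIrrelevant - 1)] == "relevant"))
  expect_true(all(labels[firstIrrelevant:length(labels)] == "irrelevant"))
})

test_that("table labelling partitions rows and is idempotent", {
  labelled <- labelTable(toyA@network, toyTableA, toyA@ref)
  lab <- relevanceLabels(labelled)
  expect_identical(length(lab), nrow(parameterValues(toyTableA)))
  expect_true(all(lab %in% c(0L, 1L)))
  expect_equal(sum(lab == 1L) + sum(lab == 0L), length(lab))
  expect_equal(attr(labelled, "incidence"), mean(lab == 1L))
  again <- labelTable(toyA@network, labelled, toyA@ref)
  expect_identical(relevanceLabels(again), lab)
})

test_that("an all-fast table labels with incidence one", {
  # stable-fast rows: scaled-up Vmax speeds up all modes
  vals <- parameterValues(toyTableA)[1:5, , drop = FALSE]
  vcols <- startsWith(colnames(vals), "VMAX__")
  vals[, vcols] <- vals[, vcols] * 50
  fast <- labelTable(toyA@network, ParameterTable(vals), toyA@ref)
  expect_equal(attr(fast, "incidence"), 1)
})

test_that("preprocessing drops Vmax, log-transforms and splits 9:1", {
  labelled <- labelTable(toyA@network, toyTableA, toyA@ref)
  ds <- preprocessDataset(labelled, seed = 2)
  feats <- datasetFeatures(ds)
  expect_identical(ncol(feats), length(kmNames(toyA@network)))
  expect_false(any(startsWith(colnames(feats), "VMAX__")))
  # natural log is lossless on the Km block
  kmCols <- colnames(feats)
  expect_equal(exp(feats), parameterValues(labelled)[, kmCols],
               tolerance = 1e-15)
  n <- nrow(feats)
  expect_identical(length(trainIndices(ds)), as.integer(round(n * 0.9)))
  expect_identical(sort(c(trainIndices(ds), testIndices(ds))), seq_len(n))
})

test_that("the 9:1 split of 80,000 rows yields 72,000 training rows", {
  vals <- matrix(exp(rnorm(80000 * 2)), 80000, 2,
                 dimnames = list(NULL, c("KM__r__a", "KM__r__b")))
  tab <- ParameterTable(vals, label = rep(c(0L, 1L), 40000))
  ds <- preprocessDataset(tab, splitRatio = c(9, 1), seed = 1)
  expect_identical(length(trainIndices(ds)), 72000L)
  expect_identical(length(testIndices(ds)), 8000L)
})

test_that("split shuffling is seeded and label-agnostic", {
  labelled <- labelTable(toyA@network, toyTableA, toyA@ref)
  d1 <- preprocessDataset(labelled, seed = 7)
  d2 <- preprocessDataset(labelled, seed = 7)
  d3 <- preprocessDataset(labelled, seed = 8)
  expect_identical(trainIndices(d1), trainIndices(d2))
  expect_false(identical(trainIndices(d1), trainIndices(d3)))
})
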