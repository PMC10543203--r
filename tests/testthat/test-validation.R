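# KL divergence, Spearman correlation, PCA, ranking and stratification.

test_that("KL divergence of identical histograms is zero", {
  edges <- seq(0, 1, by = 0.25)
  P <- binHistogram(runif(100), edges)
  expect_equal(klDivergence(P, P), 0)
})

test_that("KL divergence matches the direct sum on a two-bin example", {
  p <- c(0.5, 0.5); q <- c(0.25, 0.75)
  expect_equal(klDivergence(p, q),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-14)
})

test_that("KL divergence is nonnegative for random histogram pairs", {
  set.seed(99)
  for (i in 1:1000) {
    k <- sample(2:12, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    q <- rgamma(k, 1); q <- q / sum(q)
    expect_gte(klDivergence(p, q), 0)
  }
})

test_that("KL divergence refuses mismatched bin edges", {
  P <- binHistogram(runif(50), seq(0, 1, by = 0.5))
  Q <- binHistogram(runif(50), seq(0, 1, by = 0.25))
  expect_error(klDivergence(P, Q), "share")
  expect_error(klDivergence(c(0.5, 0.5), c(1)), "equal length")
})

test_that("per-feature KL is zero against itself and flags shifted columns", {
  set.seed(3)
  A <- matrix(rnorm(500 * 4), 500, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  self <- featureKl(A, A)
  expect_equal(unname(self$perFeature), rep(0, 4))
  expect_equal(self$aggregate, 0)
  B <- A
  B[, "f3"] <- B[, "f3"] + 5
  kl <- featureKl(A, B)
  expect_identical(names(which.max(kl$perFeature)), "f3")
  # distributional: row order of either table is irrelevant
  expect_equal(featureKl(A[sample(500), ], B)$perFeature, kl$perFeature)
  # constant feature degenerates to a single bin, divergence zero
  C1 <- matrix(1, 10, 1, dimnames = list(NULL, "c"))
  expect_equal(unname(featureKl(C1, C1)$perFeature), 0)
})

test_that("Spearman correlation handles the exact and reversed cases", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearmanRho(x, x), 1)
  expect_equal(spearmanRho(x, -x), -1)
  expect_warning(rho <- spearmanRho(x, rep(1, 6)), "rank variance")
  expect_true(is.na(rho))
  expect_error(spearmanRho(1:3, 1:4), "equal length")
})

test_that("Spearman matches the rank-then-Pearson oracle with ties", {
  set.seed(17)
  for (i in 1:20) {
    x <- sample(1:10, 50, replace = TRUE)  # heavy ties
    y <- rnorm(50) + 0.3 * x
    oracle <- cor(rank(x), rank(y))
    expect_equal(spearmanRho(x, y), oracle, tolerance = 1e-12)
    expect_equal(spearmanRho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("trajectory PCA returns ordered variance fractions", {
  set.seed(8)
  trajs <- lapply(1:5, function(i) {
    t <- seq(0, 1, length.out = 20)
    cbind(time = t, x = sin(t * i) + rnorm(20, 0, 0.01),
          y = cos(t * i), z = rnorm(20, 0, 0.05))
  })
  pc <- pcaTrajectories(trajs)
  vf <- pc$varianceFraction
  expect_true(all(diff(vf) <= 1e-12))
  expect_lte(sum(vf), 1 + 1e-8)
  expect_identical(length(pc$projected), 5L)
})

test_that("collinear trajectories collapse onto the first component", {
  trajs <- lapply(1:3, function(i) {
    s <- seq(0, i, length.out = 10)
    cbind(time = seq_along(s), x = s, y = 2 * s, z = -s)
  })
  pc <- pcaTrajectories(trajs)
  expect_equal(pc$varianceFraction[1], 1, tolerance = 1e-10)
  expect_error(pcaTrajectories(trajs[1]), "at least 2")
})

test_that("parameter ranking puts a planted shifted feature first", {
  set.seed(21)
  nm <- paste0("KM__r__", letters[1:6])
  rel <- matrix(rnorm(300 * 6), 300, 6, dimnames = list(NULL, nm))
  irr <- matrix(rnorm(300 * 6), 300, 6, dimnames = list(NULL, nm))
  irr[, 4] <- irr[, 4] + 4  # the planted discriminating parameter
  rk <- rankParametersByKl(rel, irr, topK = 3)
  expect_identical(rk$feature[1], nm[4])
  expect_true(all(diff(rk$kl) <= 0))
  # identical tables: all scores zero
  rk0 <- rankParametersByKl(rel, rel)
  expect_equal(rk0$kl, rep(0, 6))
  # column order only relabels, never rescores
  perm <- c(4, 1, 6, 2, 3, 5)
  rkP <- rankParametersByKl(rel[, perm], irr[, perm])
  rkFull <- rankParametersByKl(rel, irr)
  expect_identical(rkP$feature[1], rkFull$feature[1])
  expect_equal(sort(rkP$kl), sort(rkFull$kl), tolerance = 1e-12)
})

test_that("stratification bins equally and exposes a planted monotone trend", {
  # deterministic rows: all saturations at 1/2 except the influential
  # Km of the export reaction, swept over a grid
  full <- c(toyA@ref@concentrations, toyA@ref@boundaryConcentrations)
  nm <- kmNames(toyA@network)
  metIds <- vapply(strsplit(sub("^KM__", "", nm), "__", fixed = TRUE),
                   `[[`, character(1), 2L)
  kmBase <- setNames(full[metIds], nm)
  buildSwept <- function(feature, grid) {
    rows <- t(vapply(grid, function(g) {
      km <- kmBase; km[feature] <- g
      vmax <- vapply(reactionIds(toyA@network), function(r)
        vmaxFromFlux(toyA@network, r, km, toyA@ref), numeric(1))
      c(km, setNames(vmax, vmaxNames(toyA@network)))
    }, numeric(length(nm) + 9)))
    ParameterTable(rows)
  }
  grid <- exp(seq(log(0.02), log(8), length.out = 60))
  tabInf <- buildSwept("KM__out__F", grid)
  st <- stratifyByParameter(tabInf, "KM__out__F", nBins = 6,
                            network = toyA@network, ref = toyA@ref)
  expect_equal(unique(st$n), 10)           # equal-count bins
  expect_equal(spearmanRho(st$meanValue, st$meanMaxEig), -1)  # faster as Km grows
  # a sloppy parameter shows no comparable trend
  tabSloppy <- buildSwept("KM__shunt__D", grid)
  stS <- stratifyByParameter(tabSloppy, "KM__shunt__D", nBins = 6,
                             network = toyA@network, ref = toyA@ref)
  expect_lt(diff(range(stS$meanMaxEig)), 0.1 * diff(range(st$meanMaxEig)))
  expect_error(stratifyByParameter(tabInf, "KM__out__F", nBins = 50,
                                   network = toyA@network, ref = toyA@ref),
               "insufficient")
})
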