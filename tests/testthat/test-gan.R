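# Conditional GAN construction, training bookkeeping, generation and
# checkpointing. Full learning benchmarks live in the acceptance suite; here
# training runs are kept tiny.

cfgSmall <- GanConfig(nFeatures = 18L, latentDim = 16L, batchSize = 64L,
                      epochs = 6L, checkpointEvery = 3L, evalSamples = 40L,
                      seed = 5L)

test_that("generator and discriminator have the published architecture", {
  set.seed(1); gen <- buildGenerator(cfgSmall)
  set.seed(1); gen2 <- buildGenerator(cfgSmall)
  expect_identical(hiddenWidths(gen), c(128L, 256L, 512L))
  expect_identical(gen$layers, gen2$layers)  # same seed, same init
  dis <- buildDiscriminator(cfgSmall)
  expect_identical(hiddenWidths(dis), c(32L, 64L, 128L))
  # generator output shape b x nFeatures
  z <- matrix(rnorm(7 * 16), 7, 16)
  oh <- kinforge:::.oneHot(rep(1L, 7), 2L)
  out <- kinforge:::.nnForward(list(layers = gen$layers), cbind(z, oh))$out
  expect_identical(dim(out), c(7L, 18L))
  # discriminator emits one probability per row for real and fake alike
  dOut <- kinforge:::.nnForward(list(layers = dis$layers),
                                cbind(matrix(rnorm(7 * 18), 7, 18), oh))$out
  expect_identical(dim(dOut), c(7L, 1L))
  expect_true(all(kinforge:::.sigmoid(dOut) >= 0 & kinforge:::.sigmoid(dOut) <= 1))
})

test_that("short training fills history and evaluates at checkpoints", {
  bundle <- trainGan(toyDatasetA, cfgSmall,
                     labeller = makeRelevanceLabeller(toyA@network, toyA@ref))
  h <- trainingHistory(bundle)
  expect_identical(nrow(h), 6L)
  expect_true(all(is.finite(h$genLoss)))
  expect_true(all(is.finite(h$disAccuracy)))
  expect_identical(which(!is.na(h$evalIncidence)), c(3L, 6L))
  expect_true(all(h$evalKl[!is.na(h$evalKl)] >= 0))
})

test_that("generated tables are positive, reproducible and steady-state-exact", {
  bundle <- trainGan(toyDatasetA, cfgSmall, labeller = NULL)
  tab <- generateParameterTable(bundle, 12, "relevant", seed = 3,
                                network = toyA@network, ref = toyA@ref)
  vals <- parameterValues(tab)
  expect_identical(nrow(vals), 12L)
  expect_true(all(vals[, kmNames(toyA@network)] > 0))
  tol <- 1e-6 * max(abs(toyA@ref@fluxes))
  for (i in 1:12) {
    rhs <- massBalanceRhs(toyA@network, parameterSetFromRow(tab, i),
                          toyA@ref@concentrations, toyA@ref)
    expect_lt(max(abs(rhs)), tol)
  }
  tabSame <- generateParameterTable(bundle, 12, "relevant", seed = 3,
                                    network = toyA@network, ref = toyA@ref)
  expect_identical(vals, parameterValues(tabSame))
  tabOther <- generateParameterTable(bundle, 12, "relevant", seed = 4,
                                     network = toyA@network, ref = toyA@ref)
  expect_false(identical(vals, parameterValues(tabOther)))
})

test_that("checkpoint save -> load -> generate is bit-reproducible", {
  bundle <- trainGan(toyDatasetA, cfgSmall, labeller = NULL)
  dir <- withr::local_tempdir()
  saveGanBundle(bundle, dir)
  expect_true(file.exists(file.path(dir, "bundle.rds")))
  expect_true(file.exists(file.path(dir, "history.csv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- loadGanBundle(dir)
  t1 <- generateParameterTable(bundle, 10, "relevant", seed = 11,
                               network = toyA@network, ref = toyA@ref)
  t2 <- generateParameterTable(back, 10, "relevant", seed = 11,
                               network = toyA@network, ref = toyA@ref)
  expect_identical(parameterValues(t1), parameterValues(t2))
})

test_that("failed-training detection follows the 200-epoch accuracy rule", {
  h <- data.frame(disAccuracy = rep(0.95, 250))
  expect_true(detectFailedTraining(h))
  h$disAccuracy[200] <- 0.85  # one dip inside the window breaks 'consistently'
  expect_false(detectFailedTraining(h))
  expect_warning(res <- detectFailedTraining(data.frame(disAccuracy = rep(0.95, 100))),
                 "undecided")
  expect_false(res)
})

test_that("irrelevant populations can be harvested by rejection or direct label", {
  bundle <- trainGan(toyDatasetA, cfgSmall, labeller = NULL)
  labeller <- makeRelevanceLabeller(toyA@network, toyA@ref)
  rej <- generateIrrelevantPopulation(bundle, 15, labeller, mode = "rejection",
                                      seed = 2, network = toyA@network,
                                      ref = toyA@ref, batch = 100L)
  expect_identical(nrow(parameterValues(rej)), 15L)
  expect_true(all(relevanceLabels(rej) == 0L))
  # by construction: relabelling the harvested rows confirms irrelevance
  relab <- labelTable(toyA@network, rej, toyA@ref)
  expect_true(all(relevanceLabels(relab) == 0L))
  dir <- generateIrrelevantPopulation(bundle, 8, labeller, mode = "direct",
                                      seed = 2, network = toyA@network,
                                      ref = toyA@ref)
  expect_identical(nrow(parameterValues(dir)), 8L)
})
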