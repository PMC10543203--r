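# Conditional GAN over ln-Km feature vectors. The generator maps Gaussian
# latent noise + a one-hot class label to a feature vector; the discriminator
# scores (features, label) pairs as real or generated. Training alternates
# one discriminator and one generator Adam step per minibatch with binary
# cross-entropy loss. Every few epochs the generator is asked for
# relevant-conditioned samples, which are labelled by Jacobian eigenvalues;
# the snapshot with the highest incidence of relevant models is retained.

#' Build the generator network
#'
#' Fully connected stack: input = latent noise concatenated with the one-hot
#' class label; three hidden layers of 128, 256 and 512 units, each with
#' batch normalization, ReLU and dropout 0.5; linear output of
#' \code{nFeatures} ln-Km values.
#'
#' @param config a \linkS4class{GanConfig}.
#' @return a network list (layers + architecture metadata).
#' @export
buildGenerator <- function(config) {
  inDim <- config@latentDim + config@nClasses
  widths <- c(128L, 256L, 512L)
  layers <- list()
  prev <- inDim
  for (w in widths) {
    layers <- c(layers, list(.denseLayer(prev, w), .batchnormLayer(w),
                             .actLayer("relu"), .dropoutLayer(0.5)))
    prev <- w
  }
  layers <- c(layers, list(.denseLayer(prev, config@nFeatures)))
  list(layers = layers, kind = "generator", hidden = widths,
       latentDim = config@latentDim, nClasses = config@nClasses,
       nFeatures = config@nFeatures)
}

#' Build the discriminator network
#'
#' Fully connected stack: input = feature vector concatenated with the
#' one-hot class label; three hidden layers of 32, 64 and 128 units, each
#' with leaky-ReLU (slope 0.2) and dropout 0.5; single logit output (the
#' real-vs-generated probability after a sigmoid).
#'
#' @param config a \linkS4class{GanConfig}.
#' @return a network list.
#' @export
buildDiscriminator <- function(config) {
  inDim <- config@nFeatures + config@nClasses
  widths <- c(32L, 64L, 128L)
  layers <- list()
  prev <- inDim
  for (w in widths) {
    layers <- c(layers, list(.denseLayer(prev, w), .actLayer("lrelu"),
                             .dropoutLayer(0.5)))
    prev <- w
  }
  layers <- c(layers, list(.denseLayer(prev, 1L)))
  list(layers = layers, kind = "discriminator", hidden = widths,
       nClasses = config@nClasses, nFeatures = config@nFeatures)
}

#' Hidden-layer widths of a network
#' @param net a network list from \code{\link{buildGenerator}} or
#'   \code{\link{buildDiscriminator}}.
#' @return integer vector of dense hidden-layer widths.
#' @export
hiddenWidths <- function(net) net$hidden

.generatorForward <- function(gen, z, onehot, training) {
  .nnForward(list(layers = gen$layers), cbind(z, onehot), training = training)
}

# Generate a feature matrix from a generator (inference mode: running-stat
# batchnorm, no dropout). Caller controls the RNG.
.generateFeatures <- function(gen, n, classLabel, featureNames) {
  z <- matrix(stats::rnorm(n * gen$latentDim), n, gen$latentDim)
  oh <- .oneHot(rep(as.integer(classLabel), n), gen$nClasses)
  out <- .nnForward(list(layers = gen$layers), cbind(z, oh), training = FALSE)$out
  colnames(out) <- featureNames
  out
}

#' Train a conditional GAN on a labelled dataset
#'
#' Alternating adversarial training (one discriminator step, one generator
#' step per minibatch) with binary cross-entropy loss and Adam. Every
#' \code{checkpointEvery} epochs the generator produces \code{evalSamples}
#' relevant-conditioned sets; these are labelled by \code{labeller} and
#' compared to the relevant training rows by mean per-feature KL divergence.
#' The generator snapshot with the highest evaluation incidence is retained
#' as the best checkpoint. A NaN loss aborts training and returns the last
#' good state.
#'
#' @param dataset a \linkS4class{LabelledDataset}; only its training split is
#'   used for the adversarial game.
#' @param config a \linkS4class{GanConfig}.
#' @param labeller function(features) -> 0/1 labels, e.g. from
#'   \code{\link{makeRelevanceLabeller}}; NULL disables evaluation (the final
#'   generator becomes the best checkpoint).
#' @param initGenerator optional generator network to start from (used by
#'   transfer learning); weights are copied, the discriminator is always
#'   freshly initialized.
#' @param verbose print a progress line at each evaluation.
#' @return a \linkS4class{GanBundle}.
#' @export
trainGan <- function(dataset, config, labeller = NULL, initGenerator = NULL,
                     verbose = FALSE) {
  set.seed(config@seed)
  X <- dataset@features[dataset@trainIdx, , drop = FALSE]
  y <- dataset@labels[dataset@trainIdx]
  if (nrow(X) == 0L) stop("empty training split")
  relFeats <- X[y == 1L, , drop = FALSE]
  classFreq <- tabulate(y + 1L, nbins = config@nClasses)
  classFreq <- classFreq / sum(classFreq)

  gen <- if (is.null(initGenerator)) buildGenerator(config) else initGenerator
  dis <- buildDiscriminator(config)
  optG <- .adamInit(gen)
  optD <- .adamInit(dis)
  tG <- 0L; tD <- 0L

  nTrain <- nrow(X)
  bs <- min(config@batchSize, nTrain)
  history <- data.frame(epoch = seq_len(config@epochs), genLoss = NA_real_,
                        disLoss = NA_real_, disAccuracy = NA_real_,
                        evalIncidence = NA_real_, evalKl = NA_real_)
  best <- list(incidence = -Inf, generator = gen, epoch = NA_integer_)

  sampleLabels <- function(n) sample.int(config@nClasses, n, replace = TRUE,
                                         prob = classFreq) - 1L
  aborted <- FALSE
  for (epoch in seq_len(config@epochs)) {
    perm <- sample.int(nTrain)
    nBatch <- max(1L, floor(nTrain / bs))
    eG <- eD <- eAcc <- 0
    for (b in seq_len(nBatch)) {
      idx <- perm[((b - 1L) * bs + 1L):(b * bs)]
      realX <- X[idx, , drop = FALSE]
      realOh <- .oneHot(y[idx], config@nClasses)

      # discriminator step (generator frozen)
      fakeLab <- sampleLabels(bs)
      z <- matrix(stats::rnorm(bs * gen$latentDim), bs, gen$latentDim)
      gFwd <- .generatorForward(gen, z, .oneHot(fakeLab, config@nClasses), TRUE)
      gen$layers <- gFwd$net$layers  # BN running stats updated
      fakeX <- gFwd$out
      dIn <- rbind(cbind(realX, realOh),
                   cbind(fakeX, .oneHot(fakeLab, config@nClasses)))
      targets <- matrix(c(rep(1, bs), rep(0, bs)), ncol = 1)
      dFwd <- .nnForward(list(layers = dis$layers), dIn, training = TRUE)
      lossD <- .bceLogits(dFwd$out, targets)
      bwd <- .nnBackward(list(layers = dis$layers), dFwd$caches, lossD$dLogit)
      tD <- tD + 1L
      stepD <- .adamStep(list(layers = dis$layers), optD, bwd$grads,
                         config@learningRate, config@beta1, config@beta2, tD)
      dis$layers <- stepD$net$layers
      optD <- stepD$state
      acc <- mean((.sigmoid(dFwd$out) > 0.5) == targets)

      # generator step (discriminator frozen)
      fakeLab <- sampleLabels(bs)
      z <- matrix(stats::rnorm(bs * gen$latentDim), bs, gen$latentDim)
      oh <- .oneHot(fakeLab, config@nClasses)
      gFwd <- .generatorForward(gen, z, oh, TRUE)
      gen$layers <- gFwd$net$layers
      dFwd <- .nnForward(list(layers = dis$layers), cbind(gFwd$out, oh),
                         training = TRUE)
      lossG <- .bceLogits(dFwd$out, matrix(1, bs, 1))
      dBwd <- .nnBackward(list(layers = dis$layers), dFwd$caches, lossG$dLogit)
      dFeat <- dBwd$dX[, seq_len(config@nFeatures), drop = FALSE]
      gBwd <- .nnBackward(list(layers = gen$layers), gFwd$caches, dFeat)
      tG <- tG + 1L
      stepG <- .adamStep(list(layers = gen$layers), optG, gBwd$grads,
                         config@learningRate, config@beta1, config@beta2, tG)
      gen$layers <- stepG$net$layers
      optG <- stepG$state

      if (!is.finite(lossD$loss) || !is.finite(lossG$loss)) {
        warning("NaN loss at epoch ", epoch, "; aborting with last good checkpoint")
        aborted <- TRUE
        break
      }
      eG <- eG + lossG$loss; eD <- eD + lossD$loss; eAcc <- eAcc + acc
    }
    if (aborted) { history <- history[seq_len(epoch - 1L), , drop = FALSE]; break }
    history$genLoss[epoch] <- eG / nBatch
    history$disLoss[epoch] <- eD / nBatch
    history$disAccuracy[epoch] <- eAcc / nBatch

    if (!is.null(labeller) && epoch %% config@checkpointEvery == 0L) {
      feats <- .generateFeatures(gen, config@evalSamples, 1L,
                                 dataset@featureNames)
      labs <- labeller(feats)
      inc <- mean(labs == 1L)
      kl <- if (nrow(relFeats) > 1L)
        featureKl(feats, relFeats)$aggregate else NA_real_
      history$evalIncidence[epoch] <- inc
      history$evalKl[epoch] <- kl
      if (inc > best$incidence)
        best <- list(incidence = inc, generator = gen, epoch = epoch)
      if (verbose)
        message(sprintf("epoch %d: D acc %.2f, incidence %.3f, KL %.3f",
                        epoch, history$disAccuracy[epoch], inc, kl))
    }
  }
  if (!is.finite(best$incidence)) best$generator <- gen
  new("GanBundle", generator = gen, discriminator = dis,
      bestGenerator = best$generator, history = history, config = config,
      featureNames = dataset@featureNames)
}

#' Detect a failed adversarial training run
#'
#' Training has failed when the discriminator accuracy is consistently above
#' 90% over the last 200 epochs (the discriminator has overpowered the
#' generator). Histories shorter than 200 epochs are undecided and return
#' FALSE with a warning.
#'
#' @param history data.frame with a \code{disAccuracy} column (as in
#'   \code{\link{trainingHistory}}).
#' @param window number of trailing epochs examined (default 200).
#' @param threshold accuracy threshold (default 0.9).
#' @return logical(1).
#' @export
detectFailedTraining <- function(history, window = 200L, threshold = 0.9) {
  acc <- history$disAccuracy
  if (length(acc) < window) {
    warning("history shorter than ", window, " epochs; failure undecided")
    return(FALSE)
  }
  all(utils::tail(acc, window) > threshold)
}

#' Generate a ParameterTable from a trained bundle
#'
#' Samples latent noise, conditions on the requested class, emits ln-Km
#' features from the best generator checkpoint, exponentiates them and
#' reattaches Vmax from the reference fluxes so every generated set is
#' steady-state-exact. Fixed seed gives a bit-identical table.
#'
#' @param bundle a trained \linkS4class{GanBundle}.
#' @param n number of sets.
#' @param classLabel \code{"relevant"} or \code{"irrelevant"} (condition).
#' @param seed integer RNG seed.
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param ref a \linkS4class{ReferenceState}.
#' @param useBest use the best checkpoint (default) or the final generator.
#' @return an unlabelled \linkS4class{ParameterTable}; the raw feature matrix
#'   is attached as attribute \code{"features"}.
#' @export
generateParameterTable <- function(bundle, n, classLabel = c("relevant", "irrelevant"),
                                   seed = 1L, network, ref, useBest = TRUE) {
  classLabel <- match.arg(classLabel)
  gen <- if (useBest) bundle@bestGenerator else bundle@generator
  set.seed(as.integer(seed))
  feats <- .generateFeatures(gen, n, if (classLabel == "relevant") 1L else 0L,
                             bundle@featureNames)
  tab <- parameterTableFromFeatures(feats, network, ref)
  attr(tab, "features") <- feats
  tab
}

#' Harvest an irrelevant-labelled population from a trained generator
#'
#' Mode \code{"rejection"} (default) keeps the irrelevant by-products of
#' relevant-conditioned generation — the preferred route, since these rows
#' carry the parameters that actually determine instability. Mode
#' \code{"direct"} conditions the generator on the irrelevant class label.
#'
#' @param bundle a trained \linkS4class{GanBundle}.
#' @param n rows to return.
#' @param labeller function(features) -> 0/1 labels.
#' @param mode \code{"rejection"} or \code{"direct"}.
#' @param seed RNG seed.
#' @param network,ref model context for Vmax reattachment.
#' @param batch generation batch size per attempt.
#' @param maxBatches attempt cap for rejection mode; exceeded -> error (the
#'   generator's incidence of irrelevant by-products is too low).
#' @return a \linkS4class{ParameterTable} with labels filled (all 0 in
#'   rejection mode).
#' @export
generateIrrelevantPopulation <- function(bundle, n, labeller,
                                         mode = c("rejection", "direct"),
                                         seed = 1L, network, ref,
                                         batch = 500L, maxBatches = 200L) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  gen <- bundle@bestGenerator
  if (mode == "direct") {
    feats <- .generateFeatures(gen, n, 0L, bundle@featureNames)
    tab <- parameterTableFromFeatures(feats, network, ref)
    return(ParameterTable(tab@values, label = labeller(feats)))
  }
  kept <- NULL
  for (b in seq_len(maxBatches)) {
    feats <- .generateFeatures(gen, batch, 1L, bundle@featureNames)
    labs <- labeller(feats)
    hit <- feats[labs == 0L, , drop = FALSE]
    kept <- rbind(kept, hit)
    if (nrow(kept) >= n) {
      kept <- kept[seq_len(n), , drop = FALSE]
      tab <- parameterTableFromFeatures(kept, network, ref)
      return(ParameterTable(tab@values, label = rep(0L, n)))
    }
  }
  stop("rejection mode exhausted ", maxBatches, " batches; incidence of ",
       "irrelevant by-products too low (", nrow(kept), "/", n, " collected)")
}

#' Save a GanBundle to disk
#'
#' Checkpoint directory layout: \code{bundle.rds} (weights, history, config)
#' plus \code{history.csv} and a \code{config.json} snapshot for inspection.
#'
#' @param bundle a \linkS4class{GanBundle}.
#' @param dir checkpoint directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
saveGanBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(bundle, file.path(dir, "bundle.rds"))
  utils::write.csv(bundle@history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  cfg <- bundle@config
  jsonlite::write_json(
    list(latentDim = cfg@latentDim, nFeatures = cfg@nFeatures,
         nClasses = cfg@nClasses, learningRate = cfg@learningRate,
         beta1 = cfg@beta1, beta2 = cfg@beta2, batchSize = cfg@batchSize,
         epochs = cfg@epochs, checkpointEvery = cfg@checkpointEvery,
         evalSamples = cfg@evalSamples, seed = cfg@seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a GanBundle saved by \code{\link{saveGanBundle}}
#'
#' @param dir checkpoint directory.
#' @return a \linkS4class{GanBundle}.
#' @export
loadGanBundle <- function(dir) readRDS(file.path(dir, "bundle.rds"))
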