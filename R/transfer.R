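# Transfer learning across physiologies: a generator trained on one
# flux-direction physiology has already learned the network structure and
# mechanism nonlinearities; re-training it inside a fresh adversarial game
# with a few target-physiology samples and a randomly initialized
# discriminator adapts it at a fraction of the data and epochs that training
# from scratch needs.

#' Batch size rule for small training sets
#'
#' The size-to-batch map used in the low-data regime: training-set sizes
#' 10, 50, 100, 500, 1000 use batches of 2, 5, 10, 20, 50. Other sizes
#' interpolate as \code{max(2, min(50, n \%/\% 20))}.
#'
#' @param n training-set size.
#' @return integer batch size.
#' @export
transferBatchSize <- function(n) {
  map <- c(`10` = 2L, `50` = 5L, `100` = 10L, `500` = 20L, `1000` = 50L)
  key <- as.character(n)
  if (key %in% names(map)) return(unname(map[key]))
  max(2L, min(50L, n %/% 20L))
}

#' Learning-rate rule for small training sets
#'
#' 0.001 for 500 samples or more, 0.0002 below.
#'
#' @param n training-set size.
#' @return numeric learning rate.
#' @export
transferLearningRate <- function(n) if (n >= 500) 1e-3 else 2e-4

#' GAN configuration for a small (transfer or scratch) training run
#'
#' Applies the size-dependent batch-size and learning-rate rules.
#'
#' @param nFeatures feature dimension.
#' @param n training-set size (drives the rules).
#' @param epochs training epochs (default 300).
#' @param seed RNG seed.
#' @param evalSamples generated sets per evaluation checkpoint (default 300).
#' @param latentDim latent dimension (must match a source generator when
#'   transferring; default 64).
#' @return a \linkS4class{GanConfig}.
#' @export
smallDataGanConfig <- function(nFeatures, n, epochs = 300L, seed = 1L,
                               evalSamples = 300L, latentDim = 64L) {
  GanConfig(nFeatures = nFeatures, latentDim = latentDim,
            learningRate = transferLearningRate(n),
            batchSize = transferBatchSize(n), epochs = epochs,
            evalSamples = evalSamples, seed = seed)
}

#' Subsample a LabelledDataset for low-data experiments
#'
#' Draws \code{n} rows (seeded, without replacement) and returns them as a
#' dataset whose training split is everything (no held-out rows: at n = 10
#' every sample counts).
#'
#' @param dataset a \linkS4class{LabelledDataset}.
#' @param n rows to keep.
#' @param seed RNG seed.
#' @return a \linkS4class{LabelledDataset} with \code{n} rows.
#' @export
subsetDataset <- function(dataset, n, seed = 1L) {
  if (n > nrow(dataset@features)) stop("n exceeds dataset size")
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(dataset@features), n)
  new("LabelledDataset", features = dataset@features[idx, , drop = FALSE],
      labels = dataset@labels[idx], featureNames = dataset@featureNames,
      trainIdx = seq_len(n), testIdx = integer())
}

#' Transfer-train a generator onto a target physiology
#'
#' Initializes the generator from the source bundle's best checkpoint,
#' pairs it with a freshly (randomly) initialized discriminator, and runs
#' the adversarial game on the small target dataset with the size-dependent
#' batch-size/learning-rate rules. Each of \code{repeats} runs starts from
#' bit-identical source generator weights with a re-seeded discriminator;
#' the run with the highest best-checkpoint incidence is reported.
#'
#' @param sourceBundle trained \linkS4class{GanBundle} for the source
#'   physiology.
#' @param targetData small \linkS4class{LabelledDataset} from the target
#'   physiology.
#' @param labeller function(features) -> 0/1 labels for the target physiology.
#' @param epochs training epochs (default 300).
#' @param repeats training repeats with fresh discriminator seeds (default 1).
#' @param seed base RNG seed; repeat r uses \code{seed + r - 1}.
#' @param evalSamples generated sets per evaluation (default 300).
#' @param verbose print evaluation lines.
#' @return list with \code{bundle} (best repeat), \code{bestIncidence},
#'   \code{repeatIncidences} (numeric per repeat).
#' @export
transferTrain <- function(sourceBundle, targetData, labeller, epochs = 300L,
                          repeats = 1L, seed = 1L, evalSamples = 300L,
                          verbose = FALSE) {
  n <- length(targetData@trainIdx)
  if (n < 2L) stop("target training split needs at least 2 rows")
  init <- sourceBundle@bestGenerator
  bestBundle <- NULL
  bestInc <- -Inf
  incidences <- numeric(repeats)
  for (r in seq_len(repeats)) {
    cfg <- smallDataGanConfig(
      nFeatures = ncol(targetData@features), n = n, epochs = epochs,
      seed = as.integer(seed + r - 1L), evalSamples = evalSamples,
      latentDim = init$latentDim)
    bundle <- trainGan(targetData, cfg, labeller = labeller,
                       initGenerator = init, verbose = verbose)
    inc <- bundle@history$evalIncidence
    incidences[r] <- if (all(is.na(inc))) NA_real_ else max(inc, na.rm = TRUE)
    if (is.null(bestBundle) || isTRUE(incidences[r] > bestInc)) {
      bestBundle <- bundle
      bestInc <- incidences[r]
    }
  }
  list(bundle = bestBundle, bestIncidence = bestInc,
       repeatIncidences = incidences)
}

#' Incidence grid over source physiologies, targets and data sizes
#'
#' For every (source bundle, target dataset, size) combination, subsamples
#' the target data, transfer-trains with \code{repeats} discriminator seeds
#' and records the best incidence attained. Individual failures are recorded
#' as NA; the grid always completes.
#'
#' @param sourceBundles named list of trained \linkS4class{GanBundle}s.
#' @param targets named list of \linkS4class{LabelledDataset}s.
#' @param labellers named list of labellers aligned with \code{targets}.
#' @param sizes integer vector of target-data sizes.
#' @param repeats training repeats per cell.
#' @param epochs epochs per training (default 300).
#' @param seed base seed.
#' @param evalSamples generated sets per evaluation.
#' @return data.frame with columns \code{source}, \code{target}, \code{size},
#'   \code{bestIncidence}.
#' @export
transferGrid <- function(sourceBundles, targets, labellers, sizes,
                         repeats = 1L, epochs = 300L, seed = 1L,
                         evalSamples = 300L) {
  cells <- expand.grid(source = names(sourceBundles), target = names(targets),
                       size = sizes, stringsAsFactors = FALSE)
  cells$bestIncidence <- NA_real_
  for (i in seq_len(nrow(cells))) {
    src <- cells$source[i]; tgt <- cells$target[i]; n <- cells$size[i]
    res <- try({
      sub <- subsetDataset(targets[[tgt]], n, seed = seed + i)
      transferTrain(sourceBundles[[src]], sub, labellers[[tgt]],
                    epochs = epochs, repeats = repeats, seed = seed + i,
                    evalSamples = evalSamples)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      message("grid cell ", src, "->", tgt, " n=", n, " failed: ",
              attr(res, "condition")$message)
    } else cells$bestIncidence[i] <- res$bestIncidence
  }
  cells
}
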