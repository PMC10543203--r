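#' Construct a MetabolicNetwork
#'
#' @param metabolites data.frame with columns \code{id} and \code{internal},
#'   or a character vector of internal metabolite ids.
#' @param reactions list of reactions; each a list with \code{id},
#'   \code{stoich} (named numeric; negative = consumed, positive = produced),
#'   \code{reversible} (default FALSE) and \code{mechanism} (default
#'   \code{"convenience"}).
#' @return A validated \linkS4class{MetabolicNetwork}.
#' @examples
#' net <- MetabolicNetwork(
#'   metabolites = data.frame(id = c("A", "B"), internal = c(TRUE, TRUE)),
#'   reactions = list(list(id = "r1", stoich = c(A = -1, B = 1))))
#' @export
MetabolicNetwork <- function(metabolites, reactions) {
  if (is.character(metabolites))
    metabolites <- data.frame(id = metabolites, internal = TRUE)
  metabolites$id <- as.character(metabolites$id)
  reactions <- lapply(reactions, function(rx) {
    if (is.null(rx$reversible)) rx$reversible <- FALSE
    if (is.null(rx$mechanism)) rx$mechanism <- "convenience"
    rx
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  new("MetabolicNetwork", metabolites = metabolites, reactions = reactions)
}

#' Construct a ReferenceState
#'
#' @param concentrations named numeric, internal metabolite concentrations (mM).
#' @param boundaryConcentrations named numeric, clamped boundary
#'   concentrations (mM); may be empty.
#' @param fluxes named numeric, signed reference fluxes per reaction.
#' @param keq named numeric, equilibrium constants per reaction.
#' @param doublingTime numeric(1), doubling time in minutes.
#' @return A validated \linkS4class{ReferenceState}.
#' @export
ReferenceState <- function(concentrations, boundaryConcentrations = numeric(),
                           fluxes, keq, doublingTime) {
  new("ReferenceState", concentrations = concentrations,
      boundaryConcentrations = boundaryConcentrations,
      fluxes = fluxes, keq = keq, doublingTime = as.numeric(doublingTime))
}

#' Construct a ParameterSet
#'
#' @param km named numeric, \code{KM__<reaction>__<metabolite>} (mM).
#' @param vmax named numeric, \code{VMAX__<reaction>}.
#' @return A validated \linkS4class{ParameterSet}.
#' @export
ParameterSet <- function(km, vmax) new("ParameterSet", km = km, vmax = vmax)

#' Construct a ParameterTable
#'
#' @param values numeric matrix with \code{KM__}/\code{VMAX__} column names.
#' @param label optional 0/1 labels (NA = unlabelled).
#' @return A \linkS4class{ParameterTable}.
#' @export
ParameterTable <- function(values, label = rep(NA_integer_, nrow(values))) {
  new("ParameterTable", values = values, label = as.integer(label))
}

#' Construct a GanConfig
#'
#' Defaults follow the reference architecture: Adam with learning rate 2e-4,
#' three-layer generator/discriminator stacks, evaluation of 300
#' relevant-conditioned samples every 10 epochs.
#'
#' @param nFeatures number of ln-Km features.
#' @param latentDim latent noise dimension (default 64).
#' @param nClasses number of condition classes (default 2).
#' @param learningRate Adam step size (default 0.0002).
#' @param beta1,beta2 Adam moment decays (defaults 0.5, 0.999).
#' @param batchSize minibatch size (default 128).
#' @param epochs training epochs (default 300).
#' @param checkpointEvery epochs between generator evaluations (default 10).
#' @param evalSamples generated sets per evaluation (default 300).
#' @param seed master RNG seed (default 1).
#' @return A validated \linkS4class{GanConfig}.
#' @export
GanConfig <- function(nFeatures, latentDim = 64L, nClasses = 2L,
                      learningRate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                      batchSize = 128L, epochs = 300L,
                      checkpointEvery = 10L, evalSamples = 300L, seed = 1L) {
  new("GanConfig", latentDim = as.integer(latentDim),
      nFeatures = as.integer(nFeatures), nClasses = as.integer(nClasses),
      learningRate = learningRate, beta1 = beta1, beta2 = beta2,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      checkpointEvery = as.integer(checkpointEvery),
      evalSamples = as.integer(evalSamples), seed = as.integer(seed))
}

# ---- accessors ----

#' @describeIn MetabolicNetwork-accessors metabolite ids
#' @export
metaboliteIds <- function(network) network@metabolites$id

#' Accessors for MetabolicNetwork
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @name MetabolicNetwork-accessors
#' @return character vectors of ids, or the reaction list.
NULL

#' @describeIn MetabolicNetwork-accessors ids of internal (ODE-state) metabolites
#' @export
internalMetabolites <- function(network)
  network@metabolites$id[network@metabolites$internal]

#' @describeIn MetabolicNetwork-accessors ids of clamped boundary metabolites
#' @export
boundaryMetabolites <- function(network)
  network@metabolites$id[!network@metabolites$internal]

#' @describeIn MetabolicNetwork-accessors reaction ids
#' @export
reactionIds <- function(network)
  vapply(network@reactions, `[[`, character(1), "id")

#' @describeIn MetabolicNetwork-accessors the reaction list
#' @export
reactions <- function(network) network@reactions

#' Stoichiometric matrix over internal metabolites
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @return integer-valued matrix, internal metabolites x reactions.
#' @export
stoichiometryMatrix <- function(network) {
  mets <- internalMetabolites(network)
  rxns <- reactionIds(network)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (rx in network@reactions) {
    st <- rx$stoich
    keep <- intersect(names(st), mets)
    S[keep, rx$id] <- st[keep]
  }
  S
}

#' Parameter values of a ParameterTable
#' @param x a \linkS4class{ParameterTable}.
#' @return the numeric value matrix.
#' @export
parameterValues <- function(x) x@values

#' Relevance labels of a ParameterTable
#' @param x a \linkS4class{ParameterTable}.
#' @return integer 0/1/NA vector.
#' @export
relevanceLabels <- function(x) x@label

#' Km column names demanded by a network's mechanisms
#'
#' One Michaelis constant per (reaction, participating metabolite) pair.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @return character vector \code{KM__<reaction>__<metabolite>}.
#' @export
kmNames <- function(network) {
  unlist(lapply(network@reactions, function(rx)
    paste0("KM__", rx$id, "__", names(rx$stoich))), use.names = FALSE)
}

#' Vmax column names of a network
#' @param network a \linkS4class{MetabolicNetwork}.
#' @return character vector \code{VMAX__<reaction>}.
#' @export
vmaxNames <- function(network) paste0("VMAX__", reactionIds(network))

#' Extract one ParameterSet from a ParameterTable row
#'
#' @param table a \linkS4class{ParameterTable}.
#' @param i row index.
#' @return a \linkS4class{ParameterSet}.
#' @export
parameterSetFromRow <- function(table, i) {
  v <- table@values[i, ]
  ParameterSet(km = v[startsWith(names(v), "KM__")],
               vmax = v[startsWith(names(v), "VMAX__")])
}

#' Training features of a LabelledDataset
#' @param x a \linkS4class{LabelledDataset}.
#' @return numeric matrix of ln-Km features.
#' @export
datasetFeatures <- function(x) x@features

#' Class labels of a LabelledDataset
#' @param x a \linkS4class{LabelledDataset}.
#' @return integer 0/1 vector.
#' @export
datasetLabels <- function(x) x@labels

#' Training-split row indices of a LabelledDataset
#' @param x a \linkS4class{LabelledDataset}.
#' @return integer indices.
#' @export
trainIndices <- function(x) x@trainIdx

#' Test-split row indices of a LabelledDataset
#' @param x a \linkS4class{LabelledDataset}.
#' @return integer indices.
#' @export
testIndices <- function(x) x@testIdx

#' Per-epoch training history of a GanBundle
#' @param bundle a \linkS4class{GanBundle}.
#' @return data.frame with one row per trained epoch.
#' @export
trainingHistory <- function(bundle) bundle@history

# ---- show methods ----

setMethod("show", "MetabolicNetwork", function(object) {
  cat(sprintf("MetabolicNetwork: %d metabolites (%d internal), %d reactions\n",
              nrow(object@metabolites), sum(object@metabolites$internal),
              length(object@reactions)))
  rev <- vapply(object@reactions, `[[`, logical(1), "reversible")
  cat(sprintf("  reversible reactions: %d\n", sum(rev)))
})

setMethod("show", "ReferenceState", function(object) {
  cat(sprintf(
    "ReferenceState: %d internal + %d boundary metabolites, %d fluxes, Td = %.3g min\n",
    length(object@concentrations), length(object@boundaryConcentrations),
    length(object@fluxes), object@doublingTime))
})

setMethod("show", "ParameterTable", function(object) {
  lab <- object@label
  cat(sprintf("ParameterTable: %d sets x %d parameters", nrow(object@values),
              ncol(object@values)))
  if (all(is.na(lab))) cat(" (unlabelled)\n")
  else cat(sprintf(" | incidence of relevant: %.3f\n", mean(lab == 1L, na.rm = TRUE)))
})

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport: max Re(lambda) = %.4g 1/h, %s",
              object@maxReal, if (object@stable) "stable" else "UNSTABLE"))
  if (object@stable) cat(sprintf(", tau = %.3g min", object@tau))
  cat("\n")
})

setMethod("show", "LabelledDataset", function(object) {
  cat(sprintf(
    "LabelledDataset: %d sets x %d features | incidence %.3f | split %d/%d\n",
    nrow(object@features), ncol(object@features), mean(object@labels == 1L),
    length(object@trainIdx), length(object@testIdx)))
})

setMethod("show", "GanBundle", function(object) {
  h <- object@history
  cat(sprintf("GanBundle: %d features, %d trained epochs", object@config@nFeatures,
              nrow(h)))
  inc <- h$evalIncidence[!is.na(h$evalIncidence)]
  if (length(inc)) cat(sprintf(", best eval incidence %.3f", max(inc)))
  cat("\n")
})

setMethod("show", "ToyPhysiology", function(object) {
  cat(sprintf("ToyPhysiology '%s':\n", object@physiologyId))
  show(object@network)
  show(object@ref)
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport:\n")
  cat(sprintf("  incidence of relevant models: %.3f\n", object@incidence))
  cat(sprintf("  aggregate KL vs reference table: %.4g nats\n", object@aggregateKl))
  if (!is.na(object@returnFraction))
    cat(sprintf("  perturbation return fraction: %.3f\n", object@returnFraction))
  if (length(object@tauDistribution))
    cat(sprintf("  dominant tau (min): median %.3g\n",
                stats::median(object@tauDistribution)))
})
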