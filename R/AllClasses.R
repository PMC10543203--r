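#' @import methods
NULL

#' MetabolicNetwork: stoichiometry, reversibilities and reactant roles
#'
#' An S4 container for a (small- to medium-scale) metabolic network. Metabolites
#' are split into internal species, whose mass balances become ODE states, and
#' boundary species, which are clamped to fixed concentrations. Each reaction
#' carries a signed integer stoichiometry over declared metabolites, a
#' reversibility flag and a kinetic mechanism tag (currently convenience
#' kinetics for any stoichiometry).
#'
#' @slot metabolites data.frame with columns \code{id} (character) and
#'   \code{internal} (logical).
#' @slot reactions named list; each element has \code{id}, \code{stoich}
#'   (named numeric, negative = substrate, positive = product),
#'   \code{reversible} (logical) and \code{mechanism} (character).
#'
#' @export
setClass("MetabolicNetwork",
  representation(metabolites = "data.frame", reactions = "list"))

setValidity("MetabolicNetwork", function(object) {
  msg <- character()
  met <- object@metabolites
  if (!all(c("id", "internal") %in% names(met)))
    msg <- c(msg, "metabolites must have columns 'id' and 'internal'")
  else {
    if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
    if (!any(met$internal)) msg <- c(msg, "need at least one internal metabolite")
    for (rx in object@reactions) {
      if (!all(c("id", "stoich", "reversible", "mechanism") %in% names(rx))) {
        msg <- c(msg, "each reaction needs id, stoich, reversible, mechanism")
        break
      }
      if (length(rx$stoich) == 0L || any(rx$stoich == 0))
        msg <- c(msg, sprintf("reaction '%s': stoichiometric coefficients must be nonzero", rx$id))
      unknown <- setdiff(names(rx$stoich), met$id)
      if (length(unknown))
        msg <- c(msg, sprintf("reaction '%s' references undeclared metabolites: %s",
                              rx$id, paste(unknown, collapse = ", ")))
    }
    ids <- vapply(object@reactions, `[[`, character(1), "id")
    if (anyDuplicated(ids)) msg <- c(msg, "duplicated reaction ids")
  }
  if (length(msg)) msg else TRUE
})

#' ReferenceState: thermodynamically consistent reference steady state
#'
#' Holds the steady-state operating point a sampled kinetic model must
#' reproduce: internal and boundary metabolite concentrations (mM), net
#' reaction fluxes (mmol gDW^-1 h^-1), equilibrium constants and the
#' organism's doubling time (min). Validity enforces strict positivity;
#' steady-state closure and thermodynamic sign consistency are checked
#' against a network with \code{\link{checkReferenceState}}.
#'
#' @slot concentrations named numeric, internal metabolites (mM), > 0.
#' @slot boundaryConcentrations named numeric, boundary metabolites (mM), > 0.
#' @slot fluxes named numeric, one signed flux per reaction.
#' @slot keq named numeric, one equilibrium constant per reaction (> 0,
#'   \code{Inf} allowed for practically irreversible steps).
#' @slot doublingTime numeric(1), minutes, > 0.
#'
#' @export
setClass("ReferenceState",
  representation(concentrations = "numeric",
                 boundaryConcentrations = "numeric",
                 fluxes = "numeric",
                 keq = "numeric",
                 doublingTime = "numeric"))

setValidity("ReferenceState", function(object) {
  msg <- character()
  if (any(object@concentrations <= 0) || is.null(names(object@concentrations)))
    msg <- c(msg, "concentrations must be named and strictly positive")
  if (length(object@boundaryConcentrations) &&
      (any(object@boundaryConcentrations <= 0) || is.null(names(object@boundaryConcentrations))))
    msg <- c(msg, "boundaryConcentrations must be named and strictly positive")
  if (is.null(names(object@fluxes))) msg <- c(msg, "fluxes must be named by reaction")
  if (any(object@keq <= 0) || is.null(names(object@keq)))
    msg <- c(msg, "keq must be named and strictly positive")
  if (length(object@doublingTime) != 1L || object@doublingTime <= 0)
    msg <- c(msg, "doublingTime must be a single positive number (minutes)")
  if (length(msg)) msg else TRUE
})

#' ParameterSet: kinetic parameters of one model
#'
#' Michaelis constants (mM) for every (reaction, metabolite) pair demanded by
#' the reaction mechanisms, and one maximal velocity per reaction. Km entries
#' are named \code{KM__<reaction>__<metabolite>}, Vmax entries
#' \code{VMAX__<reaction>}.
#'
#' @slot km named numeric, strictly positive.
#' @slot vmax named numeric, strictly positive.
#'
#' @export
setClass("ParameterSet", representation(km = "numeric", vmax = "numeric"))

setValidity("ParameterSet", function(object) {
  msg <- character()
  if (length(object@km) == 0L || any(object@km <= 0) || is.null(names(object@km)))
    msg <- c(msg, "km must be named and strictly positive")
  if (any(object@vmax <= 0) || (length(object@vmax) && is.null(names(object@vmax))))
    msg <- c(msg, "vmax must be named and strictly positive")
  if (length(msg)) msg else TRUE
})

#' ParameterTable: a population of kinetic parameter sets
#'
#' Wide table, one row per kinetic model. Columns follow the
#' \code{KM__<reaction>__<metabolite>} / \code{VMAX__<reaction>} naming of
#' \linkS4class{ParameterSet}. An optional per-row relevance label (1 =
#' biologically relevant, 0 = irrelevant, NA = unlabelled) travels with the
#' table.
#'
#' @slot values numeric matrix, rows = models, columns = parameters.
#' @slot label integer vector (0/1/NA), length = number of rows.
#'
#' @export
setClass("ParameterTable",
  representation(values = "matrix", label = "integer"))

setValidity("ParameterTable", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
  if (is.null(colnames(object@values))) msg <- c(msg, "values must have column names")
  if (length(object@label) != nrow(object@values))
    msg <- c(msg, "label length must equal row count")
  bad <- object@label[!is.na(object@label)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' StabilityReport: linear-stability summary of one kinetic model
#'
#' Eigenvalues (h^-1) of the Jacobian at the reference state, the largest
#' real part, a local-stability flag and, for stable models, the dominant
#' time constant tau = 60/|max Re(lambda)| in minutes (the slowest relaxation
#' timescale of the linearized system).
#'
#' @slot eigenvalues complex vector (h^-1).
#' @slot maxReal numeric(1) (h^-1).
#' @slot stable logical(1).
#' @slot tau numeric(1), minutes; NA when unstable.
#'
#' @export
setClass("StabilityReport",
  representation(eigenvalues = "complex", maxReal = "numeric",
                 stable = "logical", tau = "numeric"))

setValidity("StabilityReport", function(object) {
  msg <- character()
  if (length(object@eigenvalues) == 0L) msg <- c(msg, "eigenvalues must be nonempty")
  if (!identical(object@stable, all(Re(object@eigenvalues) < 0)))
    msg <- c(msg, "stable flag inconsistent with eigenvalue real parts")
  if (!object@stable && !is.na(object@tau))
    msg <- c(msg, "tau must be NA for unstable models")
  if (length(msg)) msg else TRUE
})

#' LabelledDataset: preprocessed features for adversarial training
#'
#' Natural-log Michaelis constants (Vmax columns dropped: they are
#' back-calculable from Km and the reference state) with 0/1 relevance
#' labels and a train/test split.
#'
#' @slot features numeric matrix, n_sets x n_features (ln Km).
#' @slot labels integer vector of 0/1.
#' @slot featureNames character, column manifest.
#' @slot trainIdx,testIdx integer row indices, disjoint, exhaustive.
#'
#' @export
setClass("LabelledDataset",
  representation(features = "matrix", labels = "integer",
                 featureNames = "character",
                 trainIdx = "integer", testIdx = "integer"))

setValidity("LabelledDataset", function(object) {
  msg <- character()
  if (!all(is.finite(object@features))) msg <- c(msg, "features must be finite")
  if (length(object@labels) != nrow(object@features))
    msg <- c(msg, "labels length must equal feature rows")
  if (!all(object@labels %in% c(0L, 1L))) msg <- c(msg, "labels must be 0/1")
  if (length(object@featureNames) != ncol(object@features))
    msg <- c(msg, "featureNames length must equal feature columns")
  idx <- c(object@trainIdx, object@testIdx)
  if (length(idx) != nrow(object@features) || anyDuplicated(idx) ||
      !setequal(idx, seq_len(nrow(object@features))))
    msg <- c(msg, "train/test split must be disjoint and exhaustive")
  if (length(msg)) msg else TRUE
})

#' GanConfig: hyperparameters of the conditional GAN
#'
#' @slot latentDim integer, dimension of the Gaussian latent noise.
#' @slot nFeatures integer, feature-space dimension (number of ln-Km columns).
#' @slot nClasses integer, number of condition classes (2: relevant/irrelevant).
#' @slot learningRate numeric, Adam step size (default 2e-4).
#' @slot beta1,beta2 numeric, Adam moment decays.
#' @slot batchSize integer.
#' @slot epochs integer.
#' @slot checkpointEvery integer, epochs between generator evaluations.
#' @slot evalSamples integer, relevant-conditioned sets generated per evaluation.
#' @slot seed integer, master seed for weight init, shuffling and noise.
#'
#' @export
setClass("GanConfig",
  representation(latentDim = "integer", nFeatures = "integer",
                 nClasses = "integer", learningRate = "numeric",
                 beta1 = "numeric", beta2 = "numeric",
                 batchSize = "integer", epochs = "integer",
                 checkpointEvery = "integer", evalSamples = "integer",
                 seed = "integer"))

setValidity("GanConfig", function(object) {
  msg <- character()
  cnt <- c(latentDim = object@latentDim, nFeatures = object@nFeatures,
           nClasses = object@nClasses, batchSize = object@batchSize,
           epochs = object@epochs, checkpointEvery = object@checkpointEvery,
           evalSamples = object@evalSamples)
  if (any(cnt < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' GanBundle: trained generator/discriminator pair with training history
#'
#' @slot generator,discriminator network weight lists (see
#'   \code{\link{buildGenerator}}).
#' @slot bestGenerator snapshot of the generator at the best evaluation
#'   checkpoint (highest incidence of relevant models).
#' @slot history data.frame, one row per epoch: generator loss, discriminator
#'   loss, discriminator accuracy, and (at checkpoint epochs) eval incidence
#'   and eval KL divergence.
#' @slot config the \linkS4class{GanConfig} used.
#' @slot featureNames character, feature column manifest for generation.
#'
#' @export
setClass("GanBundle",
  representation(generator = "list", discriminator = "list",
                 bestGenerator = "list", history = "data.frame",
                 config = "GanConfig", featureNames = "character"))

#' ToyPhysiology: packaged toy network + reference state
#'
#' A small branched pathway (6 internal metabolites, 9 reactions, one
#' reversible shunt whose flux direction defines the physiology) with a
#' steady, thermodynamically consistent reference state, for end-to-end
#' testing without any external model download.
#'
#' @slot network a \linkS4class{MetabolicNetwork}.
#' @slot ref a \linkS4class{ReferenceState}.
#' @slot physiologyId character, e.g. \code{"A"} (shunt forward) or
#'   \code{"B"} (shunt reversed).
#'
#' @export
setClass("ToyPhysiology",
  representation(network = "MetabolicNetwork", ref = "ReferenceState",
                 physiologyId = "character"))

#' ValidationReport: statistical and dynamical validation summary
#'
#' @slot incidence numeric in [0,1], fraction of relevant models.
#' @slot perFeatureKl named numeric, per-feature KL divergence (nats).
#' @slot aggregateKl numeric(1), mean of per-feature KLs.
#' @slot tauDistribution numeric, dominant time constants (min) of stable models.
#' @slot returnFraction numeric in [0,1] (NA if perturbation analysis skipped).
#' @slot pcaVariance numeric, nonincreasing explained-variance fractions.
#' @slot rankings character, features ordered by relevance-discriminating KL.
#'
#' @export
setClass("ValidationReport",
  representation(incidence = "numeric", perFeatureKl = "numeric",
                 aggregateKl = "numeric", tauDistribution = "numeric",
                 returnFraction = "numeric", pcaVariance = "numeric",
                 rankings = "character"))

setValidity("ValidationReport", function(object) {
  msg <- character()
  if (length(object@pcaVariance) && (is.unsorted(rev(object@pcaVariance)) ||
      sum(object@pcaVariance) > 1 + 1e-8))
    msg <- c(msg, "pcaVariance must be nonincreasing and sum to <= 1")
  if (length(object@incidence) == 1L && !is.na(object@incidence) &&
      (object@incidence < 0 || object@incidence > 1))
    msg <- c(msg, "incidence must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
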