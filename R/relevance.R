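# Biological relevance from linear stability: a parameter set is relevant
# when all Jacobian eigenvalue real parts lie strictly below a negative
# bound derived from the doubling time, i.e. the model is locally stable
# and its slowest relaxation is fast enough for perturbations to settle
# before the next cell division.

#' Eigenvalue bound implied by a doubling time
#'
#' All characteristic response times must be \code{speedFactor} times faster
#' than the doubling time, giving the upper bound
#' \eqn{-60 \cdot speedFactor / T_d} (1/h) on eigenvalue real parts. For the
#' 21-min doubling time of aerobically grown E. coli with speed factor 3 this
#' is -60/7 (about -8.57 1/h), operationalized in labelling pipelines as the
#' rounded integer bound -9.
#'
#' @param doublingTime doubling time in minutes, > 0.
#' @param speedFactor how many times faster than the doubling time responses
#'   must be (>= 1, default 3).
#' @return negative bound in 1/h.
#' @export
eigenvalueBoundFromDoublingTime <- function(doublingTime, speedFactor = 3) {
  if (doublingTime <= 0) stop("doublingTime must be > 0")
  if (speedFactor < 1) stop("speedFactor must be >= 1")
  -60 * speedFactor / doublingTime
}

#' Operational relevance bound for the reference E. coli physiology
#'
#' The rounded integer form (-9 1/h) of the -60/7 bound; the exact bound is
#' available from \code{\link{eigenvalueBoundFromDoublingTime}}.
#' @export
ECOLI_RELEVANCE_BOUND <- -9

#' Summarize the linear stability of a model from its eigenvalues
#'
#' @param eigs nonempty complex (or numeric) eigenvalue vector, 1/h.
#' @return a \linkS4class{StabilityReport}; the dominant time constant is
#'   \eqn{\tau = 60/|\max Re(\lambda)|} minutes, defined only for stable
#'   models.
#' @export
stabilityReport <- function(eigs) {
  if (length(eigs) == 0L) stop("empty eigenvalue list")
  eigs <- as.complex(eigs)
  maxReal <- max(Re(eigs))
  stable <- maxReal < 0
  new("StabilityReport", eigenvalues = eigs, maxReal = maxReal,
      stable = stable, tau = if (stable) 60 / abs(maxReal) else NA_real_)
}

#' Label one stability report as biologically relevant or not
#'
#' Relevant iff the largest eigenvalue real part lies strictly below the
#' (negative) bound — i.e. stable and fast enough. A model exactly at the
#' bound is irrelevant (strict inequality).
#'
#' @param report a \linkS4class{StabilityReport}.
#' @param bound negative bound in 1/h (default the operational -9).
#' @return \code{"relevant"} or \code{"irrelevant"}.
#' @export
labelRelevance <- function(report, bound = ECOLI_RELEVANCE_BOUND) {
  if (bound >= 0) stop("bound must be negative")
  if (report@maxReal < bound) "relevant" else "irrelevant"
}

#' Stability report of one parameter set at the reference state
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param params a \linkS4class{ParameterSet}.
#' @param ref a \linkS4class{ReferenceState}.
#' @return a \linkS4class{StabilityReport}.
#' @export
modelStability <- function(network, params, ref) {
  J <- jacobianMatrix(network, params, ref@concentrations, ref)
  stabilityReport(eigen(J, only.values = TRUE)$values)
}

#' Label every row of a ParameterTable by Jacobian eigenvalues
#'
#' Rows whose rate evaluation fails are labelled irrelevant and logged.
#' Relabelling is idempotent.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param table a \linkS4class{ParameterTable}.
#' @param ref a \linkS4class{ReferenceState}.
#' @param bound negative relevance bound in 1/h; defaults to the bound
#'   derived from the reference state's doubling time with speed factor 3.
#' @return the table with its \code{label} slot filled; the achieved
#'   incidence (fraction relevant) is attached as attribute
#'   \code{"incidence"}.
#' @export
labelTable <- function(network, table, ref,
                       bound = eigenvalueBoundFromDoublingTime(ref@doublingTime)) {
  n <- nrow(table@values)
  lab <- integer(n)
  for (i in seq_len(n)) {
    rep_i <- try(modelStability(network, parameterSetFromRow(table, i), ref),
                 silent = TRUE)
    if (inherits(rep_i, "try-error")) {
      message("row ", i, ": rate evaluation failed; labelled irrelevant")
      lab[i] <- 0L
    } else {
      lab[i] <- as.integer(labelRelevance(rep_i, bound) == "relevant")
    }
  }
  out <- ParameterTable(table@values, label = lab)
  attr(out, "incidence") <- mean(lab == 1L)
  out
}

#' Labeller closure for generated Km feature matrices
#'
#' Returns a function mapping an ln-Km feature matrix (columns named
#' \code{KM__...}) to 0/1 relevance labels: Km values are recovered by
#' exponentiation, Vmax is reattached from the reference fluxes, and each
#' model's Jacobian eigenvalues are compared against the bound. Used to
#' monitor generator quality during adversarial training.
#'
#' @inheritParams labelTable
#' @return function(features) -> integer 0/1 vector.
#' @export
makeRelevanceLabeller <- function(network, ref,
                                  bound = eigenvalueBoundFromDoublingTime(ref@doublingTime)) {
  force(network); force(ref); force(bound)
  function(features) {
    tab <- parameterTableFromFeatures(features, network, ref)
    labelled <- suppressMessages(labelTable(network, tab, ref, bound))
    labelled@label
  }
}

#' Rebuild a full ParameterTable from ln-Km features
#'
#' Exponentiates the features and reattaches Vmax through
#' \code{\link{vmaxFromFlux}}, making every row steady-state-exact. Rows
#' whose Vmax reattachment fails (thermodynamically impossible Km draws do
#' not occur by construction, but generated features are unconstrained) get
#' NA Vmax and are labelled irrelevant downstream.
#'
#' @param features numeric matrix of ln-Km values, columns \code{KM__...}.
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param ref a \linkS4class{ReferenceState}.
#' @return a \linkS4class{ParameterTable}.
#' @export
parameterTableFromFeatures <- function(features, network, ref) {
  kmCols <- kmNames(network)
  km <- exp(features[, kmCols, drop = FALSE])
  rids <- reactionIds(network)
  vm <- matrix(NA_real_, nrow(km), length(rids),
               dimnames = list(NULL, vmaxNames(network)))
  for (i in seq_len(nrow(km))) {
    row <- km[i, ]
    v <- try(vapply(rids, function(r) vmaxFromFlux(network, r, row, ref),
                    numeric(1)), silent = TRUE)
    if (!inherits(v, "try-error")) vm[i, ] <- v
  }
  ParameterTable(cbind(km, vm))
}

#' Preprocess a labelled table into GAN training features
#'
#' Drops the Vmax columns (they are back-calculable from Km and the
#' reference state), applies the natural-log transform (the parameters span
#' several orders of magnitude) and splits rows into training and test sets
#' by a seeded shuffle at the given ratio.
#'
#' @param table a labelled \linkS4class{ParameterTable}.
#' @param splitRatio length-2 numeric, train:test ratio (default \code{c(9,1)}).
#' @param seed shuffle seed.
#' @return a \linkS4class{LabelledDataset}.
#' @export
preprocessDataset <- function(table, splitRatio = c(9, 1), seed = 1L) {
  if (all(is.na(table@label))) stop("table must be labelled first")
  kmCols <- colnames(table@values)[startsWith(colnames(table@values), "KM__")]
  vals <- table@values[, kmCols, drop = FALSE]
  if (any(vals <= 0)) stop("transform error: nonpositive parameter values")
  feats <- log(vals)
  n <- nrow(feats)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  nTrain <- round(n * splitRatio[1] / sum(splitRatio))
  new("LabelledDataset", features = feats, labels = as.integer(table@label),
      featureNames = kmCols,
      trainIdx = sort(perm[seq_len(nTrain)]),
      testIdx = sort(perm[setdiff(seq_len(n), seq_len(nTrain))]))
}
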