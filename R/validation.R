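# Statistical and dynamical validation of generated model populations:
# histogram KL divergence against the training distribution (mode-collapse
# monitor), rank correlation, perturbation-return robustness, PCA of
# trajectories, and per-parameter relevance diagnostics.

#' Build a normalized histogram on given bin edges
#'
#' @param x numeric sample.
#' @param edges increasing bin-edge vector covering \code{x}.
#' @return list with \code{edges} and \code{masses} (summing to 1).
#' @export
binHistogram <- function(x, edges) {
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be increasing")
  counts <- graphics::hist(x, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  list(edges = edges, masses = counts / sum(counts))
}

#' Kullback-Leibler divergence between two binned distributions
#'
#' \eqn{D_{KL}(P\|Q) = \sum_x P(x) \log(P(x)/Q(x))} in nats, computed over
#' shared bins; zero when the distributions agree binwise. Q masses are
#' floored at \code{eps} wherever P carries mass, keeping the sum finite for
#' empirical histograms with empty Q bins.
#'
#' @param P,Q histograms from \code{\link{binHistogram}} with identical edges,
#'   or bare mass vectors of equal length.
#' @param eps mass floor for Q (default 1e-10).
#' @return nonnegative divergence in nats.
#' @export
klDivergence <- function(P, Q, eps = 1e-10) {
  if (is.list(P)) {
    if (!is.list(Q) || !isTRUE(all.equal(P$edges, Q$edges)))
      stop("histograms must share bin edges")
    p <- P$masses; q <- Q$masses
  } else {
    p <- P; q <- Q
    if (length(p) != length(q)) stop("mass vectors must have equal length")
  }
  pos <- p > 0
  q <- pmax(q, eps)
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Per-feature KL divergence between two feature tables
#'
#' For each shared column, both samples are binned on \code{nBins} equal-width
#' bins spanning their pooled range, and \eqn{D_{KL}(A\|B)} is computed; the
#' aggregate is the mean over features. A constant pooled feature gets a
#' single bin and divergence zero.
#'
#' @param tableA,tableB numeric matrices with identical column names (A plays
#'   the role of P, B of Q).
#' @param nBins bins per feature (default 50).
#' @param eps mass floor (default 1e-10).
#' @return list with \code{perFeature} (named numeric) and \code{aggregate}.
#' @export
featureKl <- function(tableA, tableB, nBins = 50L, eps = 1e-10) {
  if (!identical(colnames(tableA), colnames(tableB)))
    stop("feature columns must match")
  per <- vapply(colnames(tableA), function(cn) {
    a <- tableA[, cn]; b <- tableB[, cn]
    lo <- min(a, b); hi <- max(a, b)
    if (hi - lo <= 0) return(0)
    edges <- seq(lo, hi, length.out = nBins + 1L)
    edges[length(edges)] <- hi + (hi - lo) * 1e-9  # right-open top bin
    klDivergence(binHistogram(a, edges), binHistogram(b, edges), eps = eps)
  }, numeric(1))
  list(perFeature = per, aggregate = mean(per))
}

#' Spearman rank correlation
#'
#' Rank both variables (mean ranks on ties) and take the Pearson correlation
#' of the ranks: \eqn{\rho = cov(R(X), R(Y)) / (\sigma_{R(X)} \sigma_{R(Y)})}.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1]; NA with a warning when either variable has
#'   zero rank variance.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance; Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cov(rx, ry) / (stats::sd(rx) * stats::sd(ry))
}

#' Perturbation-return analysis of a model population
#'
#' For each of \code{nModels} sampled rows and each repeat, every internal
#' concentration is multiplied by an independent random factor (log-uniform
#' on \code{factorRange}), the ODEs are integrated to the doubling time, and
#' the trial counts as returned when the final state lies within 1% of the
#' reference in relative L2 norm:
#' \eqn{\|X(T_d) - X_{ref}\|_2 < 0.01 \|X_{ref}\|_2}. Diverged integrations
#' count as not returned.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param table a \linkS4class{ParameterTable}.
#' @param ref a \linkS4class{ReferenceState}.
#' @param nModels rows sampled from the table (without replacement).
#' @param repeats perturbation repeats per model (default 10).
#' @param factorRange multiplicative perturbation range (default c(0.5, 2)).
#' @param seed RNG seed.
#' @param returnTol relative L2 tolerance for "returned" (default 0.01).
#' @param keepTrajectories retain the integrated trajectories (memory!).
#' @return list with \code{returnFraction}, \code{returned} (logical matrix
#'   models x repeats) and optionally \code{trajectories}.
#' @export
perturbationTest <- function(network, table, ref, nModels = 10L, repeats = 10L,
                             factorRange = c(0.5, 2), seed = 1L,
                             returnTol = 0.01, keepTrajectories = FALSE) {
  if (nrow(table@values) < nModels) stop("table has fewer rows than nModels")
  set.seed(as.integer(seed))
  rows <- sample.int(nrow(table@values), nModels)
  ints <- internalMetabolites(network)
  xref <- ref@concentrations[ints]
  refNorm <- sqrt(sum(xref^2))
  returned <- matrix(NA, nModels, repeats)
  trajs <- if (keepTrajectories) vector("list", nModels * repeats) else NULL
  for (m in seq_len(nModels)) {
    params <- parameterSetFromRow(table, rows[m])
    for (r in seq_len(repeats)) {
      f <- exp(stats::runif(length(xref), log(factorRange[1]), log(factorRange[2])))
      x0 <- xref * f
      tr <- simulateTrajectory(network, params, x0, horizon = ref@doublingTime,
                               nPoints = 40L, ref = ref)
      if (keepTrajectories) trajs[[(m - 1L) * repeats + r]] <- tr
      if (attr(tr, "diverged")) { returned[m, r] <- FALSE; next }
      xEnd <- tr[nrow(tr), ints]
      returned[m, r] <- sqrt(sum((xEnd - xref)^2)) < returnTol * refNorm
    }
  }
  out <- list(returnFraction = mean(returned), returned = returned)
  if (keepTrajectories) out$trajectories <- trajs
  out
}

#' PCA of a set of concentration trajectories
#'
#' Stacks all time points of all trajectories as observations (one column per
#' internal metabolite) and performs principal component analysis, giving
#' the low-dimensional view in which perturbed trajectories can be plotted
#' flowing back to the reference state.
#'
#' @param trajectories list of trajectory matrices from
#'   \code{\link{simulateTrajectory}} (first column \code{time}).
#' @return list with \code{varianceFraction} (nonincreasing, sums to 1),
#'   \code{rotation}, \code{center} and \code{projected} (list of projected
#'   paths, same order as input).
#' @export
pcaTrajectories <- function(trajectories) {
  if (length(trajectories) < 2L) stop("need at least 2 trajectories")
  states <- lapply(trajectories, function(tr) tr[, -1, drop = FALSE])
  stacked <- do.call(rbind, states)
  if (all(apply(stacked, 2, stats::sd) == 0))
    stop("degenerate trajectories: all states constant")
  pc <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(varianceFraction = vf, rotation = pc$rotation, center = pc$center,
       projected = lapply(states, function(s)
         sweep(s, 2, pc$center) %*% pc$rotation))
}

#' Rank parameters by how strongly they separate relevant from irrelevant
#'
#' Per-feature KL divergence of the relevant population against the
#' irrelevant one, in descending order: the top-ranked parameters are the
#' ones whose distributions differ most between the two classes, the rest
#' are sloppy.
#'
#' @param relevant,irrelevant numeric feature matrices with identical columns.
#' @param topK how many features to return (default all).
#' @param nBins histogram bins (default 50).
#' @return data.frame with \code{feature} and \code{kl}, sorted descending.
#' @export
rankParametersByKl <- function(relevant, irrelevant, topK = ncol(relevant),
                               nBins = 50L) {
  kl <- featureKl(relevant, irrelevant, nBins = nBins)$perFeature
  ord <- order(kl, decreasing = TRUE)
  utils::head(data.frame(feature = names(kl)[ord], kl = unname(kl[ord]),
                         row.names = NULL), topK)
}

#' Stratify a relevant population by one parameter and summarize stability
#'
#' Splits the rows into \code{nBins} equal-count bins by the value of one
#' parameter and reports, per bin, the distribution and mean of the largest
#' Jacobian-eigenvalue real part — exposing monotone dependence of the
#' system's dynamics on that parameter (or its absence, for sloppy ones).
#'
#' @param table a \linkS4class{ParameterTable} (relevant-labelled rows are
#'   used when labels are present, otherwise all rows).
#' @param feature a \code{KM__} column name to stratify on.
#' @param nBins number of equal-count bins (>= 2, default 10).
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param ref a \linkS4class{ReferenceState}.
#' @return data.frame with per-bin \code{lo}, \code{hi}, \code{meanValue},
#'   \code{meanMaxEig}, \code{n}; the per-row eigenvalues are attached as
#'   attribute \code{"maxEig"} with attribute \code{"bin"}.
#' @export
stratifyByParameter <- function(table, feature, nBins = 10L, network, ref) {
  if (nBins < 2L) stop("nBins must be >= 2")
  vals <- table@values
  if (!all(is.na(table@label))) vals <- vals[table@label == 1L, , drop = FALSE]
  if (nrow(vals) < 2L * nBins)
    stop("insufficient rows per bin: ", nrow(vals), " rows for ", nBins, " bins")
  x <- vals[, feature]
  maxEig <- vapply(seq_len(nrow(vals)), function(i) {
    v <- vals[i, ]
    ps <- ParameterSet(km = v[startsWith(names(v), "KM__")],
                       vmax = v[startsWith(names(v), "VMAX__")])
    modelStability(network, ps, ref)@maxReal
  }, numeric(1))
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1L))
  bin <- cut(x, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, lo = min(x[sel]), hi = max(x[sel]),
               meanValue = mean(x[sel]), meanMaxEig = mean(maxEig[sel]),
               n = sum(sel))
  }))
  attr(maxEig, "bin") <- bin
  attr(out, "maxEig") <- maxEig
  out
}

#' Full validation report for a generated population
#'
#' Computes incidence (after labelling), per-feature and aggregate KL against
#' a reference table, the dominant-time-constant distribution of stable
#' models, optionally the perturbation-return fraction, and the
#' class-separating parameter ranking when an irrelevant population is
#' supplied.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param ref a \linkS4class{ReferenceState}.
#' @param table generated \linkS4class{ParameterTable}.
#' @param referenceFeatures ln-Km matrix of the training population the
#'   generated one is compared against.
#' @param bound relevance bound (1/h).
#' @param perturb logical: run the perturbation-return analysis.
#' @param nModels,repeats,seed perturbation settings.
#' @return a \linkS4class{ValidationReport}.
#' @export
validatePopulation <- function(network, ref, table, referenceFeatures,
                               bound = eigenvalueBoundFromDoublingTime(ref@doublingTime),
                               perturb = FALSE, nModels = 10L, repeats = 10L,
                               seed = 1L) {
  labelled <- suppressMessages(labelTable(network, table, ref, bound))
  kmCols <- colnames(table@values)[startsWith(colnames(table@values), "KM__")]
  feats <- log(table@values[, kmCols, drop = FALSE])
  kl <- featureKl(feats, referenceFeatures[, kmCols, drop = FALSE])
  taus <- vapply(which(labelled@label == 1L), function(i) {
    modelStability(network, parameterSetFromRow(labelled, i), ref)@tau
  }, numeric(1))
  rf <- NA_real_
  if (perturb) {
    rel <- ParameterTable(labelled@values[labelled@label == 1L, , drop = FALSE])
    rf <- perturbationTest(network, rel, ref,
                           nModels = min(nModels, nrow(rel@values)),
                           repeats = repeats, seed = seed)$returnFraction
  }
  rk <- character()
  if (any(labelled@label == 0L) && any(labelled@label == 1L)) {
    relF <- feats[labelled@label == 1L, , drop = FALSE]
    irrF <- feats[labelled@label == 0L, , drop = FALSE]
    rk <- rankParametersByKl(relF, irrF)$feature
  }
  new("ValidationReport", incidence = attr(labelled, "incidence"),
      perFeatureKl = kl$perFeature, aggregateKl = kl$aggregate,
      tauDistribution = taus, returnFraction = rf,
      pcaVariance = numeric(), rankings = rk)
}

#' Serialize a ValidationReport to JSON
#'
#' @param report a \linkS4class{ValidationReport}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeValidationReport <- function(report, path) {
  jsonlite::write_json(list(
    incidence = report@incidence,
    aggregateKl = report@aggregateKl,
    perFeatureKl = as.list(report@perFeatureKl),
    tauDistributionMin = report@tauDistribution,
    returnFraction = report@returnFraction,
    pcaVariance = report@pcaVariance,
    rankings = report@rankings), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
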