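# Convenience kinetics: reversible Michaelis-Menten generalized to arbitrary
# stoichiometry, Haldane-constrained through the equilibrium constant:
#   v = Vmax * prod_s u_s^a_s * (1 - Gamma/Keq) / (Ds + Dp - 1)
# with u_m = c_m / Km, Ds = prod_s sum_{k=0..a} u_s^k, Dp analogous over
# products, Gamma the mass-action ratio. The denominator is positive for
# positive concentrations, so the rate sign is the sign of the drive term.

.geomSum <- function(u, a) {
  s <- 1
  p <- 1
  for (k in seq_len(a)) { p <- p * u; s <- s + p }
  s
}

.geomSumD <- function(u, a) {  # d/du sum_{k=0..a} u^k
  s <- 0
  p <- 1
  for (k in seq_len(a)) { s <- s + k * p; p <- p * u }
  s
}

# Rate and (optionally) its gradient wrt each participating concentration.
# km: named by metabolite (this reaction only); conc covers all participants.
.rateCore <- function(stoich, km, vmax, keq, conc, grad = FALSE) {
  mets <- names(stoich)
  cm <- conc[mets]
  if (anyNA(cm)) stop("missing concentration for: ",
                      paste(mets[is.na(cm)], collapse = ", "))
  if (any(cm <= 0)) stop("nonpositive concentration in rate evaluation")
  k <- km[mets]
  if (anyNA(k)) stop("parameterization error: missing K_M for ",
                     paste(mets[is.na(k)], collapse = ", "))
  a <- abs(stoich)
  isSub <- stoich < 0
  u <- cm / k

  A <- prod(u[isSub]^a[isSub])
  Gamma <- prod(cm[!isSub]^a[!isSub]) / prod(cm[isSub]^a[isSub])
  Tdrive <- if (is.finite(keq)) 1 - Gamma / keq else 1
  gs <- mapply(.geomSum, u, a)
  Ds <- prod(gs[isSub])
  Dp <- prod(gs[!isSub])
  D <- Ds + Dp - 1
  v <- vmax * A * Tdrive / D
  if (!grad) return(v)

  gd <- mapply(.geomSumD, u, a)
  dv <- numeric(length(mets))
  names(dv) <- mets
  for (i in seq_along(mets)) {
    if (isSub[i]) {
      dA <- A * a[i] / cm[i]
      dT <- if (is.finite(keq)) Gamma * a[i] / (cm[i] * keq) else 0
      dD <- Ds / gs[i] * gd[i] / k[i]
    } else {
      dA <- 0
      dT <- if (is.finite(keq)) -Gamma * a[i] / (cm[i] * keq) else 0
      dD <- Dp / gs[i] * gd[i] / k[i]
    }
    dv[i] <- vmax * ((dA * Tdrive + A * dT) / D - A * Tdrive * dD / D^2)
  }
  list(rate = v, grad = dv)
}

.kmForReaction <- function(params, rx) {
  nm <- paste0("KM__", rx$id, "__", names(rx$stoich))
  km <- params@km[nm]
  names(km) <- names(rx$stoich)
  km
}

#' Net rate of one reaction under convenience kinetics
#'
#' Evaluates the reversible Michaelis-Menten-type (convenience-kinetics) rate:
#' Vmax times substrate saturation terms, times the thermodynamic drive
#' \eqn{1 - \Gamma/K_{eq}} where \eqn{\Gamma} is the mass-action ratio. The
#' rate is zero exactly at equilibrium and carries the sign of the drive term.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param reaction reaction id.
#' @param params a \linkS4class{ParameterSet} covering the reaction.
#' @param conc named concentration vector (mM) covering all participating
#'   metabolites (internal and boundary); strictly positive.
#' @param keq equilibrium constant of the reaction (default taken from
#'   \code{ref} if supplied); \code{Inf} means no thermodynamic back-pressure.
#' @param ref optional \linkS4class{ReferenceState} supplying \code{keq}.
#' @return signed numeric flux.
#' @export
reactionRate <- function(network, reaction, params, conc, keq = NULL, ref = NULL) {
  rx <- network@reactions[[reaction]]
  if (is.null(rx)) stop("unknown reaction: ", reaction)
  if (is.null(keq)) {
    if (is.null(ref)) stop("supply keq or ref")
    keq <- ref@keq[[reaction]]
  }
  vmax <- params@vmax[[paste0("VMAX__", reaction)]]
  if (is.null(vmax) || is.na(vmax)) stop("parameterization error: missing V_max for ", reaction)
  .rateCore(rx$stoich, .kmForReaction(params, rx), vmax, keq, conc)
}

.allRates <- function(network, params, conc, keq, grad = FALSE) {
  lapply(network@reactions, function(rx) {
    vmax <- params@vmax[[paste0("VMAX__", rx$id)]]
    .rateCore(rx$stoich, .kmForReaction(params, rx), vmax, keq[[rx$id]], conc,
              grad = grad)
  })
}

#' Mass-balance right-hand side of the kinetic ODE system
#'
#' Entry i is \eqn{\sum_j n_{ij} v_j} over reactions; boundary metabolites
#' enter the rates as clamped concentrations but are never state variables.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param params a \linkS4class{ParameterSet}.
#' @param conc named concentrations of the internal metabolites (mM).
#' @param ref a \linkS4class{ReferenceState} (supplies equilibrium constants
#'   and boundary concentrations).
#' @return named derivative vector (mM/h), one entry per internal metabolite.
#' @export
massBalanceRhs <- function(network, params, conc, ref) {
  ints <- internalMetabolites(network)
  if (length(conc) != length(ints))
    stop("shape error: conc must have one entry per internal metabolite")
  if (is.null(names(conc))) names(conc) <- ints
  full <- c(conc, ref@boundaryConcentrations)
  rates <- unlist(.allRates(network, params, full, ref@keq), use.names = FALSE)
  drop(stoichiometryMatrix(network) %*% rates)
}

#' Jacobian of the mass balances with respect to internal concentrations
#'
#' Analytic derivatives of the convenience-kinetics rates assembled through
#' the stoichiometric matrix: \code{J[i,k] = d rhs_i / d conc_k}.
#'
#' @inheritParams massBalanceRhs
#' @return square numeric matrix (1/h), internal metabolites on both axes.
#' @export
jacobianMatrix <- function(network, params, conc, ref) {
  ints <- internalMetabolites(network)
  if (is.null(names(conc))) names(conc) <- ints
  full <- c(conc, ref@boundaryConcentrations)
  S <- stoichiometryMatrix(network)
  res <- .allRates(network, params, full, ref@keq, grad = TRUE)
  J <- matrix(0, length(ints), length(ints), dimnames = list(ints, ints))
  for (j in seq_along(res)) {
    g <- res[[j]]$grad
    keep <- intersect(names(g), ints)
    if (length(keep))
      J[, keep] <- J[, keep] + S[, j] %o% g[keep]
  }
  J
}

#' Integrate the kinetic ODE system
#'
#' Stiff-capable integration (lsoda, rtol 1e-6, atol 1e-9). A trajectory is
#' flagged as diverged when any state becomes nonfinite or exceeds 1e6 times
#' its reference value, or when the integrator fails before the horizon.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param params a \linkS4class{ParameterSet}.
#' @param x0 named positive initial internal concentrations (mM).
#' @param horizon integration horizon in minutes.
#' @param nPoints number of output time points (including t = 0).
#' @param ref a \linkS4class{ReferenceState}.
#' @return matrix with a \code{time} column (minutes) and one column per
#'   internal metabolite; attribute \code{diverged} (logical).
#' @export
simulateTrajectory <- function(network, params, x0, horizon, nPoints = 50L, ref) {
  if (horizon < 0) stop("horizon must be >= 0")
  if (any(x0 <= 0)) stop("x0 must be strictly positive")
  ints <- internalMetabolites(network)
  if (is.null(names(x0))) names(x0) <- ints
  x0 <- x0[ints]
  if (horizon == 0) {
    out <- matrix(c(0, x0), nrow = 1, dimnames = list(NULL, c("time", ints)))
    attr(out, "diverged") <- FALSE
    return(out)
  }
  timesH <- seq(0, horizon / 60, length.out = max(2L, as.integer(nPoints)))
  refScale <- ref@concentrations[ints]
  deriv <- function(t, y, parms) {
    if (any(!is.finite(y)) || any(y > 1e6 * refScale))
      return(list(rep(0, length(y))))
    y <- pmax(y, .Machine$double.xmin)
    names(y) <- ints
    list(massBalanceRhs(network, params, y, ref))
  }
  out <- try(suppressWarnings(
    deSolve::lsoda(y = x0, times = timesH, func = deriv, parms = NULL,
                   rtol = 1e-6, atol = 1e-9)), silent = TRUE)
  if (inherits(out, "try-error")) {
    traj <- matrix(c(0, x0), nrow = 1, dimnames = list(NULL, c("time", ints)))
    attr(traj, "diverged") <- TRUE
    return(traj)
  }
  traj <- unclass(out)
  colnames(traj)[1] <- "time"
  traj[, "time"] <- traj[, "time"] * 60
  states <- traj[, ints, drop = FALSE]
  diverged <- nrow(traj) < length(timesH) || any(!is.finite(states)) ||
    any(sweep(states, 2, 1e6 * refScale, ">"))
  attr(traj, "diverged") <- diverged
  traj
}

#' Check a reference state for steady-state closure and thermodynamic sign
#' consistency
#'
#' Verifies that (1) the net production of every internal metabolite under the
#' reference fluxes is zero and (2) for each reaction with nonzero flux and
#' finite equilibrium constant, the flux direction agrees with the sign of
#' the thermodynamic drive \eqn{1 - \Gamma/K_{eq}} at the reference
#' concentrations.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param ref a \linkS4class{ReferenceState}.
#' @param tol tolerance on the steady-state closure.
#' @return TRUE invisibly; stops with a message otherwise.
#' @export
checkReferenceState <- function(network, ref, tol = 1e-9) {
  S <- stoichiometryMatrix(network)
  v <- ref@fluxes[colnames(S)]
  net <- drop(S %*% v)
  if (max(abs(net)) > tol * max(1, max(abs(v))))
    stop("reference fluxes are not at steady state (max imbalance ",
         format(max(abs(net))), ")")
  full <- c(ref@concentrations, ref@boundaryConcentrations)
  for (rx in network@reactions) {
    flux <- ref@fluxes[[rx$id]]
    keq <- ref@keq[[rx$id]]
    if (flux == 0 || !is.finite(keq)) next
    st <- rx$stoich
    cm <- full[names(st)]
    Gamma <- prod(cm[st > 0]^st[st > 0]) / prod(cm[st < 0]^(-st[st < 0]))
    if (sign(1 - Gamma / keq) != sign(flux))
      stop("thermodynamic inconsistency at reaction ", rx$id,
           ": flux sign disagrees with 1 - Gamma/Keq")
  }
  invisible(TRUE)
}
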