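# Saturation-space Monte Carlo sampling: instead of sampling Michaelis
# constants directly (unbounded, spanning decades), sample the enzyme
# saturation sigma = (S/Km)/(1 + S/Km) in (0,1) and back-calculate Km from
# the known reference concentration. Vmax then follows from the reference
# flux, so every sampled model reproduces the reference steady state by
# construction.

.SIGMA_EPS <- 0.01  # saturations drawn uniformly on (eps, 1-eps)

#' Sample enzyme saturations for every Km of a network
#'
#' One saturation per (reaction, participating metabolite) pair, drawn
#' uniformly on (0.01, 0.99) — bounded away from 0 and 1 where the
#' back-calculated Km degenerates.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param seed optional integer seed (reproducible draws).
#' @return named numeric vector of saturations, names as in
#'   \code{\link{kmNames}} with \code{SIGMA__} prefix semantics preserved via
#'   the KM name (the pair is the same).
#' @export
sampleSaturations <- function(network, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nm <- kmNames(network)
  sig <- stats::runif(length(nm), .SIGMA_EPS, 1 - .SIGMA_EPS)
  names(sig) <- nm
  sig
}

#' Back-calculate a Michaelis constant from an enzyme saturation
#'
#' Inverts \eqn{\sigma = (S/K_M)/(1 + S/K_M)}: \eqn{K_M = S (1-\sigma)/\sigma}.
#'
#' @param sigma saturation(s) in the open interval (0,1).
#' @param s metabolite concentration(s), mM, > 0.
#' @return Km in mM (vectorized).
#' @export
kmFromSaturation <- function(sigma, s) {
  if (any(sigma <= 0 | sigma >= 1)) stop("sigma must lie strictly in (0,1)")
  if (any(s <= 0)) stop("concentration must be > 0")
  s * (1 - sigma) / sigma
}

#' Enzyme saturation implied by a Michaelis constant
#'
#' @param km Michaelis constant(s), mM, > 0.
#' @param s concentration(s), mM, > 0.
#' @return saturation in (0,1) (vectorized).
#' @export
saturationFromKm <- function(km, s) {
  if (any(km <= 0) || any(s <= 0)) stop("km and s must be > 0")
  (s / km) / (1 + s / km)
}

#' Maximal velocity that reproduces the reference flux
#'
#' With Km fixed, the convenience-kinetics rate is linear in Vmax; the unique
#' Vmax reproducing the reference flux is \eqn{v_j} divided by the rate
#' evaluated with unit Vmax at the reference state.
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param reaction reaction id.
#' @param km named numeric of \code{KM__} values covering the reaction.
#' @param ref a \linkS4class{ReferenceState}.
#' @return positive Vmax.
#' @export
vmaxFromFlux <- function(network, reaction, km, ref) {
  rx <- network@reactions[[reaction]]
  if (is.null(rx)) stop("unknown reaction: ", reaction)
  flux <- ref@fluxes[[reaction]]
  if (is.null(flux) || flux == 0)
    stop("degenerate reaction ", reaction, ": reference flux is zero, V_max undefined")
  full <- c(ref@concentrations, ref@boundaryConcentrations)
  nm <- paste0("KM__", reaction, "__", names(rx$stoich))
  kmr <- km[nm]
  names(kmr) <- names(rx$stoich)
  unit <- .rateCore(rx$stoich, kmr, 1, ref@keq[[reaction]], full)
  if (sign(unit) != sign(flux))
    stop("thermodynamic consistency error at reaction ", reaction,
         ": unit-V_max rate sign disagrees with the reference flux")
  flux / unit
}

#' Build one complete ParameterSet from a saturation sample
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param ref a \linkS4class{ReferenceState}.
#' @param sigma named saturations as returned by
#'   \code{\link{sampleSaturations}}.
#' @return a \linkS4class{ParameterSet} that reproduces the reference fluxes.
#' @export
parameterSetFromSaturations <- function(network, ref, sigma) {
  full <- c(ref@concentrations, ref@boundaryConcentrations)
  # names are KM__<rxn>__<met>; ids themselves contain no "__"
  parts <- strsplit(sub("^KM__", "", names(sigma)), "__", fixed = TRUE)
  metIds <- vapply(parts, `[[`, character(1), 2L)
  km <- kmFromSaturation(sigma, full[metIds])
  names(km) <- names(sigma)
  vmax <- vapply(reactionIds(network), function(r)
    vmaxFromFlux(network, r, km, ref), numeric(1))
  names(vmax) <- paste0("VMAX__", reactionIds(network))
  ParameterSet(km = km, vmax = vmax)
}

#' Generate a training table of steady-state-exact parameter sets
#'
#' Monte Carlo sampling in saturation space followed by back-calculation of
#' Km and Vmax, so each of the n sampled models reproduces the reference
#' steady state exactly. Draws that fail thermodynamic consistency are
#' logged and resampled (with a consistent reference state this does not
#' occur).
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param ref a \linkS4class{ReferenceState}.
#' @param n number of parameter sets (>= 1).
#' @param seed integer RNG seed.
#' @return an unlabelled \linkS4class{ParameterTable} with
#'   \code{KM__}/\code{VMAX__} columns.
#' @export
generateTrainingSet <- function(network, ref, n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  cols <- c(kmNames(network), vmaxNames(network))
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  nm <- kmNames(network)
  parts <- strsplit(sub("^KM__", "", nm), "__", fixed = TRUE)
  metIds <- vapply(parts, `[[`, character(1), 2L)
  full <- c(ref@concentrations, ref@boundaryConcentrations)
  sFull <- full[metIds]
  rids <- reactionIds(network)
  filled <- 0L
  attempts <- 0L
  while (filled < n) {
    attempts <- attempts + 1L
    if (attempts > 20L * n) stop("too many rejected draws; reference state inconsistent?")
    sig <- stats::runif(length(nm), .SIGMA_EPS, 1 - .SIGMA_EPS)
    km <- sFull * (1 - sig) / sig
    names(km) <- nm
    vmax <- try(vapply(rids, function(r) vmaxFromFlux(network, r, km, ref),
                       numeric(1)), silent = TRUE)
    if (inherits(vmax, "try-error")) {
      message("resampling draw ", attempts, ": ", attr(vmax, "condition")$message)
      next
    }
    filled <- filled + 1L
    out[filled, ] <- c(km, vmax)
  }
  ParameterTable(out)
}
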