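# Packaged toy physiologies: a branched uptake pathway with one reversible
# shunt. The two physiologies share the network and differ in the shunt's
# flux direction (with consistent Keq and downstream flux-magnitude
# adjustments), emulating flux-direction-defined physiological states of a
# real network at a scale where labelling thousands of sets takes seconds.
#
#   Sx -> A -> B -> C --> E -> F -> Px
#              \-> D --/
#   shunt: C <-> D (forward in physiology "A", reverse in "B")

.toyDoublingTime <- 50  # minutes; calibrated so saturation-sampled incidence
                        # falls mid-band between relevant and irrelevant

#' Build a packaged toy physiology
#'
#' Deterministic toy network (6 internal metabolites, 9 reactions, one
#' reversible shunt) plus a steady, thermodynamically consistent reference
#' state. Physiologies \code{"A"} and \code{"B"} differ in exactly one
#' reference flux sign (the C<->D shunt) with consistent equilibrium-constant
#' and flux-magnitude adjustments.
#'
#' @param physiologyId \code{"A"} (shunt C->D) or \code{"B"} (shunt D->C).
#' @param seed accepted for interface symmetry; the fixture is fully
#'   deterministic and ignores it.
#' @return a \linkS4class{ToyPhysiology}.
#' @export
buildToyPhysiology <- function(physiologyId = c("A", "B"), seed = 1L) {
  physiologyId <- match.arg(physiologyId)
  mets <- data.frame(
    id = c("A", "B", "C", "D", "E", "F", "Sx", "Px"),
    internal = c(rep(TRUE, 6), FALSE, FALSE))
  rxns <- list(
    list(id = "upt",   stoich = c(Sx = -1, A = 1)),
    list(id = "ab",    stoich = c(A = -1, B = 1)),
    list(id = "bc",    stoich = c(B = -1, C = 1)),
    list(id = "bd",    stoich = c(B = -1, D = 1)),
    list(id = "shunt", stoich = c(C = -1, D = 1), reversible = TRUE),
    list(id = "ce",    stoich = c(C = -1, E = 1)),
    list(id = "de",    stoich = c(D = -1, E = 1)),
    list(id = "ef",    stoich = c(E = -1, F = 1)),
    list(id = "out",   stoich = c(F = -1, Px = 1)))
  network <- MetabolicNetwork(mets, rxns)

  conc <- c(A = 2, B = 1.5, C = 1, D = 0.8, E = 0.6, F = 0.4)
  bconc <- c(Sx = 10, Px = 0.1)
  if (physiologyId == "A") {
    fluxes <- c(upt = 30, ab = 30, bc = 20, bd = 10, shunt = 5,
                ce = 15, de = 15, ef = 30, out = 30)
    keqShunt <- 2       # Gamma = D/C = 0.8 < Keq: forward drive
  } else {
    fluxes <- c(upt = 30, ab = 30, bc = 20, bd = 10, shunt = -5,
                ce = 25, de = 5, ef = 30, out = 30)
    keqShunt <- 0.4     # Gamma = 0.8 > Keq: reverse drive
  }
  keq <- c(upt = 10, ab = 5, bc = 4, bd = 4, shunt = keqShunt,
           ce = 3, de = 3, ef = 3, out = 5)
  ref <- ReferenceState(concentrations = conc, boundaryConcentrations = bconc,
                        fluxes = fluxes, keq = keq,
                        doublingTime = .toyDoublingTime)
  checkReferenceState(network, ref)
  new("ToyPhysiology", network = network, ref = ref,
      physiologyId = physiologyId)
}

#' Saturation-sample, label and preprocess a toy dataset
#'
#' Runs the full data-preparation pipeline on a toy physiology: Monte Carlo
#' saturation sampling, eigenvalue labelling at the bound implied by the
#' toy's doubling time, natural-log transform and a seeded 9:1 train/test
#' split. The fixture is calibrated so the incidence of relevant labels
#' falls in [0.3, 0.7]; a draw outside the band stops with an error asking
#' for re-calibration rather than silently returning a degenerate dataset.
#'
#' @param physiology a \linkS4class{ToyPhysiology}.
#' @param n number of parameter sets (>= 10).
#' @param seed RNG seed for sampling and the split.
#' @param splitRatio train:test ratio (default \code{c(9, 1)}).
#' @return a \linkS4class{LabelledDataset}; the labelled
#'   \linkS4class{ParameterTable} is attached as attribute \code{"table"}
#'   and the incidence as attribute \code{"incidence"}.
#' @export
makeLabelledDataset <- function(physiology, n, seed = 1L, splitRatio = c(9, 1)) {
  stopifnot(n >= 10)
  network <- physiology@network
  ref <- physiology@ref
  tab <- generateTrainingSet(network, ref, n, seed = seed)
  labelled <- labelTable(network, tab, ref)
  inc <- attr(labelled, "incidence")
  if (inc < 0.3 || inc > 0.7)
    stop(sprintf(paste0("fixture calibration failure: incidence %.3f outside ",
                        "[0.3, 0.7]; re-tune the toy doubling time"), inc))
  ds <- preprocessDataset(labelled, splitRatio = splitRatio, seed = seed)
  attr(ds, "table") <- labelled
  attr(ds, "incidence") <- inc
  ds
}
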