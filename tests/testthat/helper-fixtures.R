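# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; no data files.

toyA <- buildToyPhysiology("A")
toyB <- buildToyPhysiology("B")

# A mid-sized labelled dataset for data-pipeline and GAN tests.
toyDatasetA <- makeLabelledDataset(toyA, 400, seed = 101)
toyTableA <- attr(toyDatasetA, "table")

# One steady-state-exact parameter set on physiology A.
toyParamsA <- parameterSetFromSaturations(
  toyA@network, toyA@ref, sampleSaturations(toyA@network, seed = 77))

# Micro-networks for closed-form checks ------------------------------------

# Single-substrate sink A -> (nothing), effectively first order when Km >> A.
linearDecayModel <- function(k = 1, km = 1e6) {
  net <- MetabolicNetwork(
    data.frame(id = "A", internal = TRUE),
    list(list(id = "deg", stoich = c(A = -1))))
  ref <- ReferenceState(concentrations = c(A = 1), fluxes = c(deg = k),
                        keq = c(deg = Inf), doublingTime = 60)
  params <- ParameterSet(km = c(KM__deg__A = km),
                         vmax = c(VMAX__deg = k * (km + 1)))
  list(net = net, ref = ref, params = params, k = k)
}

# Two-metabolite interconversion cycle: total A + B is conserved.
cycleModel <- function() {
  net <- MetabolicNetwork(
    data.frame(id = c("A", "B"), internal = c(TRUE, TRUE)),
    list(list(id = "fwd", stoich = c(A = -1, B = 1), reversible = TRUE),
         list(id = "rev", stoich = c(B = -1, A = 1))))
  ref <- ReferenceState(concentrations = c(A = 1.2, B = 0.7),
                        fluxes = c(fwd = 1, rev = 1),
                        keq = c(fwd = 2, rev = 3), doublingTime = 60)
  params <- ParameterSet(
    km = c(KM__fwd__A = 0.9, KM__fwd__B = 1.4, KM__rev__B = 0.5,
           KM__rev__A = 2.1),
    vmax = c(VMAX__fwd = 3, VMAX__rev = 2.5))
  list(net = net, ref = ref, params = params)
}

# Bimolecular reversible reaction A + B <-> C for the symbolic-expansion
# oracle.
bimolecularModel <- function() {
  net <- MetabolicNetwork(
    data.frame(id = c("A", "B", "C"), internal = c(TRUE, TRUE, TRUE)),
    list(list(id = "rx", stoich = c(A = -1, B = -1, C = 1), reversible = TRUE)))
  params <- ParameterSet(
    km = c(KM__rx__A = 0.8, KM__rx__B = 2.5, KM__rx__C = 1.1),
    vmax = c(VMAX__rx = 4))
  list(net = net, params = params)
}

# Cheap labeller stub (no kinetics): relevant iff mean feature < cutoff.
# Used where only bookkeeping, not biology, is under test.
stubLabeller <- function(cutoff = 0) {
  function(features) as.integer(rowMeans(features) < cutoff)
}
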