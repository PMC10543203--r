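# Convenience-kinetics rate law, mass balances, Jacobian and integration.

test_that("single-substrate rate is half-maximal at S = Km", {
  net <- MetabolicNetwork(
    data.frame(id = "S", internal = TRUE),
    list(list(id = "r", stoich = c(S = -1))))
  params <- ParameterSet(km = c(KM__r__S = 1.5), vmax = c(VMAX__r = 2))
  expect_equal(reactionRate(net, "r", params, c(S = 1.5), keq = Inf), 1)
})

test_that("rate vanishes exactly at equilibrium and follows the drive sign", {
  bm <- bimolecularModel()
  # pick C so that Gamma = C/(A*B) equals Keq exactly
  A <- 1.3; B <- 0.6; keq <- 2.5
  conc <- c(A = A, B = B, C = keq * A * B)
  expect_equal(reactionRate(bm$net, "rx", bm$params, conc, keq = keq), 0)
  concFwd <- c(A = A, B = B, C = 0.5 * keq * A * B)
  concRev <- c(A = A, B = B, C = 2 * keq * A * B)
  expect_gt(reactionRate(bm$net, "rx", bm$params, concFwd, keq = keq), 0)
  expect_lt(reactionRate(bm$net, "rx", bm$params, concRev, keq = keq), 0)
})

test_that("bimolecular reversible rate matches the hand-expanded formula", {
  bm <- bimolecularModel()
  conc <- c(A = 1.7, B = 0.45, C = 0.9)
  keq <- 3.2
  # independent expansion of the convenience-kinetics rate law
  uA <- conc["A"] / 0.8; uB <- conc["B"] / 2.5; uC <- conc["C"] / 1.1
  gamma <- conc["C"] / (conc["A"] * conc["B"])
  expected <- unname(4 * uA * uB * (1 - gamma / keq) /
                       ((1 + uA) * (1 + uB) + (1 + uC) - 1))
  expect_equal(reactionRate(bm$net, "rx", bm$params, conc, keq = keq),
               expected, tolerance = 1e-12)
})

test_that("rate evaluation rejects bad inputs", {
  bm <- bimolecularModel()
  badParams <- ParameterSet(km = c(KM__rx__A = 0.8, KM__rx__C = 1.1),
                            vmax = c(VMAX__rx = 4))
  expect_error(reactionRate(bm$net, "rx", badParams,
                            c(A = 1, B = 1, C = 1), keq = 2),
               "parameterization error")
  expect_error(reactionRate(bm$net, "rx", bm$params,
                            c(A = 1, B = -0.1, C = 1), keq = 2),
               "nonpositive")
})

test_that("mass balance of a pure sink is minus its rate", {
  lm <- linearDecayModel(k = 2)
  rhs <- massBalanceRhs(lm$net, lm$params, c(A = 1), lm$ref)
  # near-linear regime: rate ~ k * A
  expect_equal(unname(rhs["A"]), -2, tolerance = 1e-5)
})

test_that("conserved interconversion cycle has zero net mass", {
  cm <- cycleModel()
  for (conc in list(c(A = 1.2, B = 0.7), c(A = 0.3, B = 2.4))) {
    rhs <- massBalanceRhs(cm$net, cm$params, conc, cm$ref)
    expect_equal(unname(sum(rhs)), 0, tolerance = 1e-14)
  }
})

test_that("rhs dimension mismatch is a shape error", {
  cm <- cycleModel()
  expect_error(massBalanceRhs(cm$net, cm$params, c(A = 1), cm$ref), "shape")
})

test_that("sampled parameter sets are steady-state-exact at the reference", {
  rhs <- massBalanceRhs(toyA@network, toyParamsA, toyA@ref@concentrations,
                        toyA@ref)
  expect_lt(max(abs(rhs)), 1e-6 * max(abs(toyA@ref@fluxes)))
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(5)
  fdJacobian <- function(net, params, conc, ref, h = 1e-6) {
    n <- length(conc)
    J <- matrix(0, n, n)
    for (k in seq_len(n)) {
      up <- conc; dn <- conc
      up[k] <- up[k] * (1 + h); dn[k] <- dn[k] * (1 - h)
      J[, k] <- (massBalanceRhs(net, params, up, ref) -
                   massBalanceRhs(net, params, dn, ref)) / (up[k] - dn[k])
    }
    J
  }
  for (i in 1:5) {
    conc <- toyA@ref@concentrations * exp(runif(6, -1, 1))
    J <- jacobianMatrix(toyA@network, toyParamsA, conc, toyA@ref)
    fd <- fdJacobian(toyA@network, toyParamsA, conc, toyA@ref)
    expect_lt(max(abs(J - fd)) / max(abs(J)), 1e-6)
  }
})

test_that("near-linear degradation has Jacobian approximately [-k]", {
  lm <- linearDecayModel(k = 3)
  J <- jacobianMatrix(lm$net, lm$params, c(A = 1), lm$ref)
  expect_equal(unname(J[1, 1]), -3, tolerance = 1e-4)
})

test_that("permuting metabolite declaration order permutes Jacobian rows/cols", {
  net2 <- MetabolicNetwork(
    toyA@network@metabolites[c(3, 1, 5, 2, 6, 4, 7, 8), ],
    unname(toyA@network@reactions))
  J1 <- jacobianMatrix(toyA@network, toyParamsA, toyA@ref@concentrations, toyA@ref)
  J2 <- jacobianMatrix(net2, toyParamsA, toyA@ref@concentrations, toyA@ref)
  expect_equal(J2[rownames(J1), colnames(J1)], J1)
})

test_that("first-order decay integrates to the closed form", {
  lm <- linearDecayModel(k = 1)
  traj <- simulateTrajectory(lm$net, lm$params, c(A = 1), horizon = 60,
                             nPoints = 11L, ref = lm$ref)
  expect_false(attr(traj, "diverged"))
  expect_equal(unname(traj[1, "A"]), 1)
  expect_equal(unname(traj[11, "A"]), exp(-1), tolerance = 1e-4)
})

test_that("zero horizon returns the initial state only", {
  lm <- linearDecayModel()
  traj <- simulateTrajectory(lm$net, lm$params, c(A = 2), horizon = 0,
                             ref = lm$ref)
  expect_identical(nrow(traj), 1L)
  expect_equal(unname(traj[1, "A"]), 2)
})

test_that("trajectories started at the reference stay there", {
  traj <- simulateTrajectory(toyA@network, toyParamsA,
                             toyA@ref@concentrations, horizon = 100,
                             nPoints = 25L, ref = toyA@ref)
  expect_false(attr(traj, "diverged"))
  drift <- sweep(traj[, -1, drop = FALSE], 2, toyA@ref@concentrations, "-")
  expect_lt(max(abs(drift)), 1e-6)
})

test_that("reference states are steady and thermodynamically consistent", {
  expect_true(checkReferenceState(toyA@network, toyA@ref))
  badRef <- toyA@ref
  badRef@fluxes["shunt"] <- -badRef@fluxes["shunt"]  # breaks closure
  expect_error(checkReferenceState(toyA@network, badRef), "steady state")
})
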