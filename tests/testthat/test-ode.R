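# ODE model representation, RHS evaluation, protocol simulation,
# settling time.

# independent oracle for the nuclear phospho-p53 balance, written directly
# from the rate law (not via the package's term machinery)
p53pnBalanceOracle <- function(st, p) {
  (p[["pa1"]] +
     p[["pa2"]] * st[["ATMan"]] / (st[["ATMan"]] + p[["pm1"]]) +
     p[["pa3"]] * st[["CHK2pn"]] / (st[["CHK2pn"]] + p[["pm2"]])) * st[["p53n"]] -
    p[["pc1"]] * st[["p53pn"]] * st[["WIP1n"]] -
    (p[["pd4"]] + p[["pd5"]] * st[["MDM2pn"]]^2) * st[["p53pn"]]
}

test_that("model validation catches undeclared symbols and unused parameters", {
  expect_error(ODEModel("x", c(p = 1),
    list(list(target = "x", sign = -1, rate = "p * y", name = "bad"))),
    "undeclared symbol")
  expect_error(ODEModel("x", c(p = 1, q = 2),
    list(list(target = "x", sign = -1, rate = "p * x", name = "decay"))),
    "appear in no rate term")
  expect_error(ODEModel("x", c(p = 1),
    list(list(target = "y", sign = -1, rate = "p * x", name = "decay"))),
    "not a declared species")
})

test_that("evaluateRHS is the signed sum of term rates", {
  mod <- reducedFixtureModel()
  p <- modelParameters(mod)
  # all-symbols-one state: hand-computable balance
  st <- setNames(rep(1, 6), speciesNames(mod))
  d <- evaluateRHS(mod, st, 0)
  expect_equal(d[["p53pn"]],
               (p[["pa1"]] + p[["pa2"]] / (1 + p[["pm1"]]) +
                  p[["pa3"]] / (1 + p[["pm2"]])) -
                 p[["pc1"]] - (p[["pd4"]] + p[["pd5"]]))
  # zero state with zero basal production gives zero derivative
  zeroPars <- p
  zeroPars[c("ps1", "batm", "bchk2", "bwip1", "bmdm2")] <- 0
  d0 <- evaluateRHS(mod, setNames(rep(0, 6), speciesNames(mod)), 0,
                    parameters = zeroPars)
  expect_true(all(d0 == 0))
  # Michaelis-Menten saturation: huge ATMan makes the ATM term ~ pa2 * p53n
  stSat <- st
  stSat[["ATMan"]] <- 1e9
  dSat <- evaluateRHS(mod, stSat, 0)
  stNo <- st
  stNo[["ATMan"]] <- 0
  dNo <- evaluateRHS(mod, stNo, 0)
  expect_equal(dSat[["p53pn"]] - dNo[["p53pn"]], p[["pa2"]],
               tolerance = 1e-8)
  expect_error(evaluateRHS(mod, c(st[-1], p53n = NaN)),
               class = "petrisig_analysis_error")
})

test_that("fixture RHS matches the independent rate-law oracle", {
  mod <- reducedFixtureModel()
  p <- modelParameters(mod)
  withr::with_seed(1, {
    for (i in 1:100) {
      st <- setNames(runif(6, 0, 3), speciesNames(mod))
      d <- evaluateRHS(mod, st, 0)
      expected <- p53pnBalanceOracle(st, p)
      expect_equal(d[["p53pn"]], expected, tolerance = 1e-12)
    }
  })
})

test_that("fixture structure: six species, low resting damage signals", {
  mod <- reducedFixtureModel()
  expect_identical(length(speciesNames(mod)), 6L)
  st <- initialState(mod)
  p <- modelParameters(mod)
  expect_equal(st[["ATMan"]], p[["batm"]] / p[["gatm"]])
  expect_equal(st[["CHK2pn"]], p[["bchk2"]] / p[["gchk2"]])
  expect_lt(st[["ATMan"]], 0.05)
  expect_lt(st[["CHK2pn"]], 0.05)
  # each balance parameter appears only in the terms it belongs to
  termsFor <- function(par) {
    vapply(modelTerms(mod), function(tm)
      par %in% all.vars(str2lang(tm$rate)), TRUE)
  }
  expect_identical(sum(termsFor("pd5")), 1L)     # Mdm2-dependent degradation
  expect_identical(sum(termsFor("pc1")), 2L)     # inactivation + its mirror
  expect_identical(sum(termsFor("pa2")), 2L)     # ATM activation + mirror
})

test_that("simulation from equilibrium stays flat; IR pulse gives a transient", {
  mod <- reducedFixtureModel()
  quiet <- simulationProtocol(phase1 = 4, phase2 = 1, phase3 = 8,
                              tnf = 0, ir = 0, step = 0.25)
  traj <- simulateProtocol(mod, quiet)
  v <- trajectoryValues(traj)
  expect_lt(max(abs(sweep(v, 2, v[1, ]))), 1e-5)
  # 4 Gy pulse: p53pn rises during/after stimulation, then relaxes back
  pulse <- simulationProtocol(phase1 = 24, phase2 = 1, phase3 = 120,
                              tnf = 10, ir = 4, step = 0.25)
  trajP <- simulateProtocol(mod, pulse)
  vp <- trajectoryValues(trajP)
  tp <- trajectoryTime(trajP)
  rest <- vp[max(which(tp <= 24)), "p53pn"]
  expect_gt(max(vp[tp > 24 & tp < 40, "p53pn"]), rest * 1.5)
  expect_equal(vp[length(tp), "p53pn"], rest, tolerance = 1e-3)
  expect_true(all(vp >= 0))
})

test_that("pure decay reproduces the closed form within solver tolerance", {
  mod <- pureDecay(p = 0.7, x0 = 2)
  prot <- shortProtocol(phase1 = 1, phase2 = 1, phase3 = 6, step = 0.1)
  traj <- suppressWarnings(simulateProtocol(mod, prot))
  tt <- trajectoryTime(traj)
  expect_equal(trajectoryValues(traj)[, "x"], 2 * exp(-0.7 * tt),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("equilibrium warning fires when phase 1 is too short", {
  mod <- pureDecay(p = 0.2, x0 = 1)
  expect_warning(
    simulateProtocol(mod, simulationProtocol(phase1 = 1, phase2 = 1,
                                             phase3 = 2, step = 0.25)),
    "not at equilibrium")
})

test_that("halving solver tolerances barely changes the fixture trajectory", {
  mod <- reducedFixtureModel()
  prot <- simulationProtocol(phase1 = 24, phase2 = 1, phase3 = 48,
                             ir = 4, step = 0.5)
  a <- trajectoryValues(simulateProtocol(mod, prot))
  b <- trajectoryValues(simulateProtocol(mod, prot, rtol = 5e-7, atol = 5e-10))
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-3)
})

test_that("settling time matches the exponential closed form", {
  # constant trajectory settles immediately
  mod <- linearProductionDecay(2, 1)
  prot <- shortProtocol(step = 0.1)
  traj <- simulateProtocol(mod, prot)
  expect_equal(settlingTime(traj, "x"), 0)
  # decay toward zero with the band on the initial amplitude:
  # t* = ln(1/band)/p
  p <- 0.9
  dec <- pureDecay(p = p, x0 = 1)
  prot2 <- simulationProtocol(phase1 = 0.5, phase2 = 0.5, phase3 = 20,
                              tnf = 0, ir = 0, step = 0.01)
  trajD <- suppressWarnings(simulateProtocol(dec, prot2))
  x1 <- trajectoryValues(trajD)[which.min(abs(trajectoryTime(trajD) - 1)), "x"]
  st <- settlingTime(trajD, "x", band = 0.05, reference = x1)
  expect_equal(st, log(1 / 0.05) / p, tolerance = 0.02)
  # an oscillation that never converges returns NA
  osc <- new("Trajectory",
             time = seq(0, 30, by = 0.1),
             values = matrix(sin(seq(0, 30, by = 0.1)),
                             dimnames = list(NULL, "x"), ncol = 1),
             phaseEnds = c(5, 6, 30))
  expect_true(is.na(settlingTime(osc, "x")))
})

test_that("YAML model configs round-trip through readODEModel", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "species: [x, z]",
    "inputs: [IR]",
    "parameters: {a: 1.5, b: 0.5}",
    "initial: {x: 3, z: 0}",
    "terms:",
    "  - {target: x, sign: 1, rate: a + IR, name: production}",
    "  - {target: x, sign: -1, rate: b * x, name: decay}",
    "  - {target: z, sign: 1, rate: b * x, name: transfer}"), path)
  mod <- readODEModel(path)
  expect_identical(speciesNames(mod), c("x", "z"))
  expect_equal(initialState(mod), c(x = 3, z = 0))
  d <- evaluateRHS(mod, c(x = 2, z = 0), 0, inputs = c(IR = 2))
  expect_equal(unname(d), c(1.5 + 2 - 1, 1))
  suppressWarnings(
    expect_error(readODEModel(withr::local_tempfile(fileext = ".yaml")),
                 class = "petrisig_input_error"))
})
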