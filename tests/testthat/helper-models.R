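# Shared builders for tests: tiny ODE models and invariant-set helpers.

# production/decay model dx/dt = a - b x, initialized at its steady state
linearProductionDecay <- function(a, b) {
  a <- as.numeric(a)[1]
  b <- as.numeric(b)[1]
  ODEModel(
    species = "x", parameters = c(a = a, b = b),
    terms = list(
      list(target = "x", sign = 1, rate = "a", name = "production"),
      list(target = "x", sign = -1, rate = "b * x", name = "decay")),
    initial = c(x = a / b))
}

# pure decay dx/dt = -p x from x0 (closed form x0 * exp(-p t))
pureDecay <- function(p = 0.5, x0 = 1) {
  ODEModel(
    species = "x", parameters = c(p = p),
    terms = list(list(target = "x", sign = -1, rate = "p * x",
                      name = "first-order decay")),
    initial = c(x = x0))
}

# short protocol for desk-scale ODE tests (no stimuli unless asked)
shortProtocol <- function(phase1 = 6, phase2 = 1, phase3 = 10,
                          tnf = 0, ir = 0, step = 0.25) {
  simulationProtocol(phase1, phase2, phase3, tnf = tnf, ir = ir, step = step)
}

# set equality of two invariant sets: same kind, same rows up to order
expectSameInvariants <- function(a, b) {
  expect_identical(invariantKind(a), invariantKind(b))
  va <- invariantVectors(a)
  vb <- invariantVectors(b)
  expect_identical(sort(colnames(va)), sort(colnames(vb)))
  vb <- vb[, colnames(va), drop = FALSE]
  keyOf <- function(m) sort(apply(m, 1, paste, collapse = " "))
  expect_identical(keyOf(va), keyOf(vb))
}
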