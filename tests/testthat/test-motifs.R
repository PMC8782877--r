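# Translation motifs and the p53 fragment fixture.

emptyNet <- function() {
  PetriNet(character(), character(),
           data.frame(source = character(), target = character()))
}

test_that("each motif builder adds exactly one primary transition", {
  net <- emptyNet()
  steps <- list(
    function(n) addSynthesisSource(n, "pA", "source of A"),
    function(n) addSpontaneousConversion(n, "pA", "pB", "conversion"),
    function(n) addDegradation(n, "pB", "degradation of B"),
    function(n) addInhibitionDrain(n, "t2", "pI", "inhibition of conversion")
  )
  for (f in steps) {
    before <- length(transitions(net))
    net <- f(net)
    expect_identical(length(transitions(net)), before + 1L)
    expect_true(validObject(net))
  }
  # catalyzed with pool adds primary + pool
  n2 <- addCatalyzedConversion(emptyNet(), "pS", "pC", "pP", "catalysis",
                               withPool = TRUE)
  expect_identical(length(transitions(n2)), 2L)
  # two successive calls create two distinct transitions
  n3 <- addSpontaneousConversion(emptyNet(), "pA", "pB", "x")
  n3 <- addSpontaneousConversion(n3, "pA", "pB", "y")
  expect_identical(anyDuplicated(transitions(n3)), 0L)
})

test_that("spontaneous conversion conserves tokens over {substrate, product}", {
  net <- addSpontaneousConversion(emptyNet(), "pA", "pB", "conversion")
  pInv <- invariantVectors(minimalPInvariants(net))
  expect_identical(unname(pInv), matrix(c(1, 1), 1, 2))
})

test_that("catalyzed conversion wiring and pool behaviour", {
  plain <- addCatalyzedConversion(emptyNet(), "pS", "pC", "pP", "cat")
  a <- arcs(plain)
  expect_setequal(a$source[a$target == "t1"], c("pS", "pC"))
  expect_identical(a$target[a$source == "t1"], "pP")
  pooled <- addCatalyzedConversion(emptyNet(), "pS", "pC", "pP", "cat",
                                   withPool = TRUE)
  expect_identical(nrow(arcs(pooled)) - nrow(arcs(plain)), 1L)
  # without a pool, catalyst + product is conserved (the catalyst is locked
  # into the product's budget); the pool source breaks that conservation so
  # no p-invariant of the pooled net touches the catalyst
  pinvPlain <- supports(minimalPInvariants(plain))
  expect_true(any(vapply(pinvPlain, function(s)
    setequal(s, c("pC", "pP")), TRUE)))
  pinvPooled <- supports(minimalPInvariants(pooled))
  expect_false(any(vapply(pinvPooled, function(s) "pC" %in% s, TRUE)))
})

test_that("inactivation mirrors activation with reversed arc direction", {
  act <- addCatalyzedConversion(emptyNet(), "pA", "pE", "pB", "act")
  inact <- addInactivation(emptyNet(), "pB", "pE", "pA", "inact")
  aAct <- arcs(act)
  aInact <- arcs(inact)
  expect_true("pA" %in% aAct$source[aAct$target == "t1"])
  expect_true("pA" %in% aInact$target[aInact$source == "t1"])
  # activation + inactivation + agent pools close a t-invariant
  net <- addCatalyzedConversion(emptyNet(), "pA", "pKin", "pB", "act",
                                withPool = TRUE)
  net <- addInactivation(net, "pB", "pPhos", "pA", "inact", withPool = TRUE)
  iv <- supports(minimalTInvariants(net))
  expect_true(any(vapply(iv, function(s)
    all(c("t1", "t3") %in% s), TRUE)))  # t1 = activation, t3 = inactivation
})

test_that("degradation closes coverage of a synthesis/conversion chain", {
  chain <- addSynthesisSource(emptyNet(), "pA", "source")
  chain <- addSpontaneousConversion(chain, "pA", "pB", "conversion")
  expect_false(isCovered(chain)$covered)
  full <- addDegradation(chain, "pB", "degradation")
  expect_true(isCovered(full)$covered)
  # mediated degradation consumes the mediator too
  med <- addDegradation(emptyNet(), "pX", "mediated deg", mediator = "pM")
  a <- arcs(med)
  expect_setequal(a$source, c("pX", "pM"))
  expect_identical(nrow(a[a$source == "t1", , drop = FALSE]), 0L)
})

test_that("synthesis source joins an invariant only once a sink exists", {
  src <- addSynthesisSource(emptyNet(), "pA", "source")
  expect_identical(length(minimalTInvariants(src)), 0L)
  pair <- addDegradation(src, "pA", "sink")
  expect_identical(unname(invariantVectors(minimalTInvariants(pair))),
                   matrix(c(1, 1), 1, 2))
})

test_that("inhibition drain takes the inhibited transition's pre-places", {
  net <- addSpontaneousConversion(emptyNet(), "pA", "pB", "conversion")
  net <- addInhibitionDrain(net, "t1", "pI", "inhibition")
  a <- arcs(net)
  expect_setequal(a$source[a$target == "t2"], c("pA", "pI"))
  expect_identical(sum(a$source == "t2"), 0L)
  # in a covered chain, the drain's significance cannot exceed the
  # inhibited conversion's
  chain <- addSynthesisSource(emptyNet(), "pA", "source")
  chain <- addSpontaneousConversion(chain, "pA", "pB", "conversion")
  chain <- addDegradation(chain, "pB", "deg")
  chain <- addInhibitionDrain(chain, "t2", "pI", "inhib")
  chain <- addSynthesisSource(chain, "pI", "source of inhibitor")
  tab <- significanceTable(
    transitionSignificance(minimalTInvariants(chain), chain))
  sOf <- function(id) tab$significance_pct[tab$transition_id == id]
  expect_lte(sOf("t4"), sOf("t2"))
})

test_that("reaction-list assembly reproduces builder calls", {
  reactions <- data.frame(
    kind = c("synthesis_source", "spontaneous_conversion", "degradation"),
    name = c("source of A", "conversion", "degradation of B"),
    product = c("pA", "pB", NA),
    substrate = c(NA, "pA", NA),
    target = c(NA, NA, "pB"),
    stringsAsFactors = FALSE)
  net <- buildNetFromReactionList(reactions)
  expect_identical(length(transitions(net)), 3L)
  expect_true(isCovered(net)$covered)
})

test_that("p53 fragment has the announced structure and coverage", {
  frag <- buildP53Fragment()
  expect_identical(length(places(frag)), 6L)
  expect_identical(length(transitions(frag)), 11L)
  # six rate-term transitions + synthesis + four pools
  expect_setequal(
    transitions(frag),
    c("t_p53_syn", "t_act_spont", "t_act_atm", "t_pool_atm",
      "t_act_chk2", "t_pool_chk2", "t_inact_wip1", "t_pool_wip1",
      "t_deg_spont", "t_deg_mdm2", "t_pool_mdm2"))
  expect_true(isCovered(frag)$covered)
  # marking: 1 token per source-fed place
  expect_identical(sum(marking(frag)), 5)
  expect_identical(marking(frag)[["p53pn"]], 0)
})

test_that("knocking the Mdm2 degradation branch keeps the rest covered", {
  frag <- buildP53Fragment()
  iv <- minimalTInvariants(frag)
  res <- knockout(iv, c("t_deg_mdm2", "t_pool_mdm2"))
  remaining <- removeTransitions(frag, c("t_deg_mdm2", "t_pool_mdm2"))
  cov <- isCovered(remaining, minimalTInvariants(remaining))
  expect_true(cov$covered)
  expect_lt(excludedPct(res), 100)
})
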