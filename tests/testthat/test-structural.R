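# Significance, knockout and subset-search analyses.

test_that("significance percentages follow S = f*100/s with half-up rounding", {
  frag <- buildP53Fragment()
  iv <- minimalTInvariants(frag)
  rep <- transitionSignificance(iv, frag)
  tab <- significanceTable(rep)
  expect_setequal(tab$transition_id, transitions(frag))
  s <- length(iv)
  f <- colSums(invariantVectors(iv) > 0)
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$t_inv_count[i], unname(f[tab$transition_id[i]]))
    expect_equal(tab$significance_pct[i],
                 petrisig:::roundHalfUp(f[[tab$transition_id[i]]] * 100 / s, 2))
  }
  # sorted by S desc then id; boundary rows behave
  expect_true(all(diff(tab$significance_pct) <= 0))
  # a transition in every support has S = 100
  oneInv <- minimalTInvariants(cycleNet(3))
  allS <- significanceTable(transitionSignificance(oneInv))$significance_pct
  expect_identical(allS, c(100, 100, 100))
})

test_that("double-counting identity: sum f = sum of support sizes", {
  iv <- minimalTInvariants(buildP53Fragment())
  f <- colSums(invariantVectors(iv) > 0)
  expect_equal(sum(f), sum(lengths(supports(iv))))
})

test_that("significance of an empty invariant set is an analysis error", {
  empty <- invariantSetFromSupports(list(), ids = c("t1", "t2"))
  expect_error(transitionSignificance(empty), class = "petrisig_analysis_error")
})

test_that("knockout exclusion follows E = (b - a)*100/b", {
  fam <- invariantSetFromSupports(
    c(lapply(1:25, function(i) c("tA", paste0("u", i))),
      lapply(26:100, function(i) c("tB", paste0("u", i)))),
    ids = c("tA", "tB", paste0("u", 1:100)))
  res <- knockout(fam, "tB")
  expect_equal(res@before, 100)
  expect_equal(res@after, 25)
  expect_equal(excludedPct(res), 75)
  # knocking any transition of the 3-cycle kills its single invariant
  res2 <- knockout(minimalTInvariants(cycleNet(3)), "t2")
  expect_equal(excludedPct(res2), 100)
  expect_identical(length(survivingInvariants(res2)), 0L)
  expect_error(knockout(fam, "nope"), "unknown transition")
})

test_that("knockout by filtering equals knockout by recompute", {
  for (seed in 1:25) {
    gen <- randomInvariantNet(nCycles = 2, cycleLengths = c(3, 4),
                              nChains = 2, nShared = seed %% 3, seed = seed)
    net <- gen$net
    iv <- minimalTInvariants(net)
    if (length(iv) == 0) next
    knocked <- withr::with_seed(seed,
      sample(transitions(net), min(2, length(transitions(net)))))
    filtered <- survivingInvariants(knockout(iv, knocked))
    recomputed <- minimalTInvariants(removeTransitions(net, knocked))
    vf <- invariantVectors(filtered)[, setdiff(colnames(invariantVectors(filtered)),
                                               knocked), drop = FALSE]
    expectSameInvariants(
      petrisig:::.makeInvariantSet(vf, "t", colnames(vf)),
      recomputed)
  }
})

test_that("knockout E is monotone in the knocked set", {
  frag <- buildP53Fragment()
  iv <- minimalTInvariants(frag)
  tr <- transitions(frag)
  for (seed in 1:10) {
    sets <- withr::with_seed(seed, {
      small <- sample(tr, 2)
      list(small = small, big = union(small, sample(tr, 2)))
    })
    expect_gte(excludedPct(knockout(iv, sets$big)),
               excludedPct(knockout(iv, sets$small)))
  }
})

test_that("joint-containment search finds exactly the maximal frequent sets", {
  supp <- list(c("t1", "t2"), c("t1", "t2", "t3"), c("t1", "t2", "t4"),
               c("t3"))
  res <- significantSubsetSearch(supp, threshold = 0.7, mode = "joint")
  expect_identical(res$set, "t1,t2")
  expect_equal(res$frequency, 0.75)

  # universal transition: {t1} alone at threshold 0.8
  supp2 <- list(c("t1", "t2"), c("t1", "t3"), c("t1", "t2", "t3"))
  res2 <- significantSubsetSearch(supp2, threshold = 0.8, mode = "joint")
  expect_identical(res2$set, "t1")
  expect_equal(res2$frequency, 1)

  expect_error(significantSubsetSearch(supp, threshold = 1.5),
               class = "petrisig_input_error")
})

test_that("joint frequency is bounded by members' individual frequencies", {
  fam <- randomSupportFamily(40, 8, planted = c("t1", "t2"),
                             frequency = 0.85, seed = 3)
  mat <- invariantVectors(fam)
  jf <- petrisig:::.jointFrequency(mat, c("t1", "t2"))
  expect_equal(jf, 0.85)
  for (t in c("t1", "t2")) {
    expect_lte(jf, petrisig:::.jointFrequency(mat, t))
  }
  # returned joint-mode sets satisfy the threshold, no frequent strict superset
  res <- significantSubsetSearch(fam, threshold = 0.8, mode = "joint",
                                 maxSetSize = 4)
  expect_true(all(res$frequency >= 0.8))
  expect_true(any(vapply(strsplit(res$set, ","), function(s)
    all(c("t1", "t2") %in% s), TRUE)))
})

test_that("planted frequent sets are recovered iff above threshold", {
  fam <- randomSupportFamily(50, 6, planted = c("t2", "t5"),
                             frequency = 0.9, seed = 9)
  res <- significantSubsetSearch(fam, threshold = 0.8, mode = "joint",
                                 maxSetSize = 4)
  expect_true(any(vapply(strsplit(res$set, ","), function(s)
    all(c("t2", "t5") %in% s), TRUE)))
  low <- randomSupportFamily(50, 6, planted = c("t2", "t5"),
                             frequency = 0.5, seed = 9)
  resLow <- significantSubsetSearch(low, threshold = 0.8, mode = "joint",
                                    maxSetSize = 4)
  expect_false(any(vapply(strsplit(resLow$set, ","), function(s)
    all(c("t2", "t5") %in% s), TRUE)))
})

test_that("union-knockout mode grows E monotonically up to the cap", {
  frag <- buildP53Fragment()
  iv <- minimalTInvariants(frag)
  res <- significantSubsetSearch(iv, mode = "union", maxSetSize = 3)
  res <- res[order(res$size), ]
  expect_true(all(diff(res$excluded_pct) >= 0))
  expect_equal(max(res$excluded_pct), 100)
  # seeding forces the initial set into every reported set
  res2 <- significantSubsetSearch(iv, mode = "union", maxSetSize = 3,
                                  initial = "t_p53_syn")
  expect_true(all(vapply(strsplit(res2$set, ","), function(s)
    "t_p53_syn" %in% s, TRUE)))
})

test_that("significance and knockout reports serialize to CSV/JSON", {
  frag <- buildP53Fragment()
  iv <- minimalTInvariants(frag)
  rep <- transitionSignificance(iv, frag)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeSignificance(rep, csv, header = "test run")
  back <- read.csv(csv, comment.char = "#")
  expect_identical(names(back),
                   c("transition_id", "name", "t_inv_count", "significance_pct"))
  expect_equal(back$significance_pct, significanceTable(rep)$significance_pct)
  js <- withr::local_tempfile(fileext = ".json")
  writeKnockout(knockout(iv, "t_p53_syn"), js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$excluded_pct,
               excludedPct(knockout(iv, "t_p53_syn")))
})
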