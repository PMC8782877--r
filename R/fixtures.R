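# Synthetic nets with analytically known invariant structure, the
# brute-force invariant oracle, and support-family generators.

#' Elementary example nets
#'
#' `cycleNet(k)` builds the k-cycle p1 -> t1 -> p2 -> ... -> tk -> p1
#' (exactly one t-invariant, all ones, and one p-invariant). `chainNet()`
#' builds the source/sink chain t_in -> p -> t_out (one t-invariant (1,1),
#' no p-invariant). `diamondNet()` builds the diamond
#' p1 -> {t1, t2} -> p2, p2 -> t3 -> p1 with the two minimal t-invariants
#' (1,0,1) and (0,1,1).
#'
#' @param k cycle length (>= 2 for distinct arcs; k = 1 allowed).
#' @param prefix id prefix so several copies can live in one net.
#' @return a [PetriNet-class].
#' @export
cycleNet <- function(k = 3, prefix = "") {
  p <- paste0(prefix, "p", seq_len(k))
  tr <- paste0(prefix, "t", seq_len(k))
  arcsDf <- rbind(
    data.frame(source = p, target = tr),
    data.frame(source = tr, target = c(p[-1], p[1]))
  )
  PetriNet(p, tr, arcsDf,
           marking = stats::setNames(c(1, rep(0, k - 1)), p))
}

#' @rdname cycleNet
#' @export
chainNet <- function(prefix = "") {
  p <- paste0(prefix, "p1")
  tr <- paste0(prefix, c("t_in", "t_out"))
  PetriNet(p, tr, data.frame(source = c(tr[1], p), target = c(p, tr[2])))
}

#' @rdname cycleNet
#' @export
diamondNet <- function(prefix = "") {
  p <- paste0(prefix, c("p1", "p2"))
  tr <- paste0(prefix, c("t1", "t2", "t3"))
  PetriNet(p, tr, data.frame(
    source = c(p[1], p[1], tr[1], tr[2], p[2], tr[3]),
    target = c(tr[1], tr[2], p[2], p[2], tr[3], p[1])))
}

#' Random net with known minimal t-invariant count
#'
#' Composes disjoint cycles and source/sink chains, optionally glued by
#' identifying transitions across components. When disjoint
#' (`nShared = 0`) the number of minimal t-invariants is exactly
#' `nCycles + nChains` (one per component). Gluing changes the count; the
#' brute-force oracle then supplies the expected set.
#'
#' @param nCycles number of cycle components.
#' @param cycleLengths integer vector (recycled) of cycle lengths.
#' @param nChains number of source/sink chain components.
#' @param nShared number of cross-component transition identifications.
#' @param seed integer seed.
#' @return list with `net` (a [PetriNet-class]) and `expectedCount`
#'   (exact count for disjoint composition, otherwise `NA`).
#' @export
randomInvariantNet <- function(nCycles = 2, cycleLengths = c(3, 4),
                               nChains = 1, nShared = 0, seed = 1) {
  withLocalSeed(seed, {
    comps <- list()
    lens <- rep(cycleLengths, length.out = max(nCycles, 1))
    for (i in seq_len(nCycles)) {
      comps[[length(comps) + 1]] <- cycleNet(lens[i], prefix = paste0("c", i, "_"))
    }
    for (i in seq_len(nChains)) {
      comps[[length(comps) + 1]] <- chainNet(prefix = paste0("h", i, "_"))
    }
    if (!length(comps)) stopInput("at least one component required")
    net <- Reduce(disjointUnion, comps)
    glued <- 0L
    while (glued < nShared) {
      tr <- net@transitions
      if (length(tr) < 2) break
      pick <- sample(tr, 2)
      a <- net@arcs
      a$source[a$source == pick[2]] <- pick[1]
      a$target[a$target == pick[2]] <- pick[1]
      keep <- setdiff(tr, pick[2])
      net <- suppressWarnings(
        PetriNet(net@places, keep, a, marking = net@marking,
                 placeNames = net@placeNames,
                 transitionNames = net@transitionNames[keep]))
      glued <- glued + 1L
    }
    list(net = net,
         expectedCount = if (nShared == 0) nCycles + nChains else NA_integer_)
  })
}

#' Brute-force t-invariant oracle
#'
#' Exhaustively enumerates all nonnegative integer vectors with entries at
#' most `bound` satisfying A x = 0, then reduces them to the gcd-canonical
#' minimal-support set. Complete for nets whose minimal invariants have
#' entries within the bound; intended as an independent oracle for the
#' elimination engine on small nets.
#'
#' @param net a [PetriNet-class].
#' @param bound entry bound (default 3, sufficient for the generated test
#'   nets whose weights are 1).
#' @return an [InvariantSet-class] of kind `"t"`.
#' @export
bruteForceTInvariants <- function(net, bound = 3) {
  A <- incidenceMatrix(net)
  m <- ncol(A)
  nVec <- (bound + 1)^m
  if (m * nVec > 1e7) {
    stopInput("enumeration guard exceeded: m * (bound+1)^m = ",
              format(m * nVec, scientific = TRUE))
  }
  grid <- as.matrix(expand.grid(rep(list(0:bound), m)))[-1, , drop = FALSE]
  res <- A %*% t(grid)
  sol <- grid[colSums(res != 0) == 0, , drop = FALSE]
  if (nrow(sol) == 0) {
    return(.makeInvariantSet(matrix(0, 0, m, dimnames = list(NULL, colnames(A))),
                             "t", colnames(A), netId = "oracle"))
  }
  X <- .canonicalizeInvariants(sol)
  .makeInvariantSet(X, "t", colnames(A), netId = "oracle")
}

#' Random support family with a planted frequent set
#'
#' Generates a family of t-invariant supports over `tNames` in which a
#' chosen transition set occurs at a prescribed joint frequency; used to
#' test the significant-subset search. All supports are distinct size-wise
#' antichain members (every support gets a unique private transition).
#'
#' @param nInvariants number of supports to generate (>= 1).
#' @param nTransitions number of shared (non-private) transitions.
#' @param planted character vector of planted transition ids (subset of the
#'   shared transitions `t1..tn`).
#' @param frequency target joint frequency of the planted set.
#' @param seed integer seed.
#' @return an [InvariantSet-class] of kind `"t"` over the shared plus
#'   private transitions.
#' @export
randomSupportFamily <- function(nInvariants, nTransitions,
                                planted = character(), frequency = 0.9,
                                seed = 1) {
  if (nInvariants < 1) stopInput("nInvariants must be >= 1")
  shared <- paste0("t", seq_len(nTransitions))
  unknown <- setdiff(planted, shared)
  if (length(unknown)) {
    stopInput("planted ids outside t1..t", nTransitions, ": ",
              paste(unknown, collapse = ", "))
  }
  withLocalSeed(seed, {
    nWith <- round(frequency * nInvariants)
    others <- setdiff(shared, planted)
    supp <- vector("list", nInvariants)
    for (i in seq_len(nInvariants)) {
      extras <- if (length(others)) {
        others[stats::runif(length(others)) < 0.3]
      } else character()
      base <- if (i <= nWith) c(planted, extras) else extras
      # drop one planted member for the complement so the joint frequency
      # is exactly nWith / nInvariants
      if (i > nWith && length(planted)) {
        base <- c(planted[-1], extras)
      }
      supp[[i]] <- unique(c(base, paste0("u", i)))  # private id -> antichain
    }
    ids <- c(shared, paste0("u", seq_len(nInvariants)))
    invariantSetFromSupports(supp, ids, kind = "t", netId = "synthetic")
  })
}
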