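#' @import methods
NULL

#' Classical place/transition Petri net
#'
#' A classical Petri net: a weighted bipartite directed graph whose vertices
#' are places (passive components, e.g. molecular species) and transitions
#' (active components, e.g. reactions), together with an initial marking
#' (token counts on places). Arcs connect a place to a transition or a
#' transition to a place and carry positive integer weights.
#'
#' @slot places character vector of place ids (ordered).
#' @slot transitions character vector of transition ids (ordered).
#' @slot placeNames named character vector of display names (names = place ids).
#' @slot transitionNames named character vector of display names
#'   (names = transition ids).
#' @slot arcs data.frame with columns `source`, `target` (ids) and `weight`
#'   (positive integer). Parallel arcs in the same direction are stored summed.
#' @slot marking named numeric vector of nonnegative integer token counts,
#'   one per place.
#'
#' @seealso [PetriNet()] for the user-facing constructor,
#'   [incidenceMatrix()], [minimalTInvariants()].
#' @exportClass PetriNet
setClass("PetriNet",
  representation(
    places = "character",
    transitions = "character",
    placeNames = "character",
    transitionNames = "character",
    arcs = "data.frame",
    marking = "numeric"
  )
)

setValidity("PetriNet", function(object) {
  msg <- character()
  p <- object@places
  tr <- object@transitions
  ids <- c(p, tr)
  if (anyDuplicated(ids)) {
    msg <- c(msg, paste0("duplicated node ids: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  a <- object@arcs
  if (!all(c("source", "target", "weight") %in% names(a))) {
    msg <- c(msg, "arcs must have columns source, target, weight")
  } else if (nrow(a) > 0) {
    unknown <- setdiff(unique(c(a$source, a$target)), ids)
    if (length(unknown)) {
      msg <- c(msg, paste0("arc endpoint refers to unknown id: ",
                           paste(unknown, collapse = ", ")))
    } else {
      p2t <- a$source %in% p & a$target %in% tr
      t2p <- a$source %in% tr & a$target %in% p
      if (!all(p2t | t2p)) {
        bad <- which(!(p2t | t2p))[1]
        msg <- c(msg, paste0("arc ", a$source[bad], " -> ", a$target[bad],
                             " is not bipartite (place<->transition)"))
      }
    }
    if (any(a$weight < 1) || any(a$weight != round(a$weight))) {
      msg <- c(msg, "arc weights must be positive integers")
    }
  }
  if (length(object@marking) != length(p) ||
      !identical(sort(names(object@marking)), sort(p))) {
    msg <- c(msg, "marking must be named by exactly the place ids")
  } else if (any(object@marking < 0) ||
             any(object@marking != round(object@marking))) {
    msg <- c(msg, "marking must be nonnegative integers")
  }
  if (!identical(sort(names(object@placeNames)), sort(p)) ||
      !identical(sort(names(object@transitionNames)), sort(tr))) {
    msg <- c(msg, "display names must be named by the node ids")
  }
  if (length(msg)) msg else TRUE
})

#' Set of minimal semi-positive invariants
#'
#' Holds the minimal-support, gcd-canonical semi-positive t-invariants
#' (solutions of A x = 0) or p-invariants (solutions of y A = 0) of a Petri
#' net. Supports form an antichain (no support strictly contains another) and
#' the set is stored in a deterministic lexicographic-by-support order.
#'
#' @slot kind `"t"` or `"p"`.
#' @slot vectors integer-valued numeric matrix, one invariant per row; columns
#'   are named by the net's transition ids (t-kind) or place ids (p-kind).
#' @slot netId provenance tag naming the source net.
#'
#' @seealso [minimalTInvariants()], [supports()], [knockout()].
#' @exportClass InvariantSet
setClass("InvariantSet",
  representation(
    kind = "character",
    vectors = "matrix",
    netId = "character"
  )
)

setValidity("InvariantSet", function(object) {
  msg <- character()
  if (!object@kind %in% c("t", "p")) msg <- c(msg, "kind must be 't' or 'p'")
  v <- object@vectors
  if (is.null(colnames(v))) msg <- c(msg, "vectors must have column names (ids)")
  if (nrow(v) > 0) {
    if (any(v < 0) || any(v != round(v))) {
      msg <- c(msg, "invariant entries must be nonnegative integers")
    }
    if (any(rowSums(v) == 0)) msg <- c(msg, "zero vector is not an invariant")
    g <- apply(v, 1, vecGCD)
    if (any(g != 1)) msg <- c(msg, "invariants must be gcd-normalized")
    supp <- v > 0
    n <- nrow(v)
    if (n > 1) {
      key <- apply(supp, 1, function(s) paste(which(s), collapse = ","))
      if (anyDuplicated(key)) msg <- c(msg, "supports must be pairwise distinct")
      # antichain check
      cont <- supp %*% t(!supp)  # cont[i,j] = #(i's support outside j's)
      sz <- rowSums(supp)
      for (i in seq_len(n)) {
        strict <- which(cont[, i] == 0 & sz < sz[i])
        if (length(strict)) {
          msg <- c(msg, "support minimality violated")
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Transition significance report
#'
#' Table-style result of the significance analysis: for every transition of a
#' net, the number `f` of t-invariant supports containing it and the
#' percentage significance S = f * 100 / s (s = total number of t-invariants),
#' rounded half-up to two decimals and sorted by decreasing S.
#'
#' @slot table data.frame with columns `transition_id`, `name`, `t_inv_count`,
#'   `significance_pct`.
#' @slot nInvariants total number of t-invariants (s).
#'
#' @seealso [transitionSignificance()], [writeSignificance()].
#' @exportClass SignificanceReport
setClass("SignificanceReport",
  representation(table = "data.frame", nInvariants = "numeric")
)

#' Knockout analysis result
#'
#' Result of knocking out a set of transitions: the surviving t-invariants
#' (those whose support is disjoint from the knocked set) and the exclusion
#' percentage E = (tinv_b - tinv_a) * 100 / tinv_b.
#'
#' @slot knocked character vector of knocked transition ids.
#' @slot before,after invariant counts before/after the knockout.
#' @slot excluded percentage E of excluded invariants (half-up, 2 decimals).
#' @slot surviving the surviving [InvariantSet-class].
#'
#' @seealso [knockout()], [significantSubsetSearch()].
#' @exportClass KnockoutResult
setClass("KnockoutResult",
  representation(
    knocked = "character",
    before = "numeric",
    after = "numeric",
    excluded = "numeric",
    surviving = "InvariantSet"
  )
)

#' ODE pathway model as named additive rate terms
#'
#' A system of ordinary differential equations in which each species'
#' derivative is a signed sum of named rate terms (elementary processes).
#' Rate expressions may reference species, parameters and named time-dependent
#' inputs (e.g. `TNF`, `IR`).
#'
#' @slot species ordered character vector of species names.
#' @slot parameters named numeric vector of (positive) kinetic parameters.
#' @slot terms list; each element a list with fields `target` (species),
#'   `sign` (+1/-1), `rate` (character, an R arithmetic expression) and
#'   `name` (human-readable process name).
#' @slot inputs character vector of input signal names.
#' @slot initial named numeric vector of initial species values.
#'
#' @seealso [ODEModel()], [evaluateRHS()], [simulateProtocol()],
#'   [reducedFixtureModel()].
#' @exportClass ODEModel
setClass("ODEModel",
  representation(
    species = "character",
    parameters = "numeric",
    terms = "list",
    inputs = "character",
    initial = "numeric"
  )
)

setValidity("ODEModel", function(object) {
  msg <- character()
  sp <- object@species
  pars <- names(object@parameters)
  known <- c(sp, pars, object@inputs, "t", "pi")
  used <- character()
  for (tm in object@terms) {
    if (!all(c("target", "sign", "rate", "name") %in% names(tm))) {
      msg <- c(msg, "each term needs target, sign, rate, name")
      next
    }
    if (!tm$target %in% sp) {
      msg <- c(msg, paste0("term target not a declared species: ", tm$target))
    }
    if (!tm$sign %in% c(-1, 1)) msg <- c(msg, "term sign must be +1 or -1")
    vars <- all.vars(str2lang(tm$rate))
    bad <- setdiff(vars, known)
    if (length(bad)) {
      msg <- c(msg, paste0("undeclared symbol(s) in rate '", tm$rate, "': ",
                           paste(bad, collapse = ", ")))
    }
    used <- union(used, vars)
  }
  unusedPars <- setdiff(pars, used)
  if (length(unusedPars)) {
    msg <- c(msg, paste0("parameter(s) appear in no rate term: ",
                         paste(unusedPars, collapse = ", ")))
  }
  if (length(object@initial) &&
      !identical(sort(names(object@initial)), sort(sp))) {
    msg <- c(msg, "initial state must be named by exactly the species")
  }
  if (length(msg)) msg else TRUE
})

#' Three-phase stimulation protocol
#'
#' The simulation protocol used throughout: an equilibration phase with no
#' stimuli, a stimulation phase with constant TNF and a 1-h ionizing-radiation
#' pulse delivering a total dose, and a recovery phase with TNF still present.
#'
#' @slot phase1,phase2,phase3 phase durations in hours (defaults 24, 1, 240).
#' @slot tnf TNF level (ng/ml) during phases 2-3.
#' @slot ir total IR dose (Gy) delivered uniformly over phase 2.
#' @slot step output sampling step (hours).
#'
#' @seealso [simulationProtocol()], [simulateProtocol()].
#' @exportClass SimulationProtocol
setClass("SimulationProtocol",
  representation(
    phase1 = "numeric", phase2 = "numeric", phase3 = "numeric",
    tnf = "numeric", ir = "numeric", step = "numeric"
  )
)

setValidity("SimulationProtocol", function(object) {
  msg <- character()
  if (any(c(object@phase1, object@phase2, object@phase3) <= 0)) {
    msg <- c(msg, "phase durations must be positive")
  }
  if (object@ir < 0) msg <- c(msg, "ir dose must be nonnegative")
  if (object@step <= 0) msg <- c(msg, "sampling step must be positive")
  if (length(msg)) msg else TRUE
})

#' Simulated trajectory
#'
#' Time courses of all model species over the three protocol phases.
#'
#' @slot time numeric vector of time points (hours), strictly increasing.
#' @slot values matrix time x species (columns named by species).
#' @slot phaseEnds numeric length-3 vector of phase end times.
#'
#' @seealso [simulateProtocol()], [settlingTime()].
#' @exportClass Trajectory
setClass("Trajectory",
  representation(time = "numeric", values = "matrix", phaseEnds = "numeric")
)

#' OAT sensitivity configuration
#'
#' Settings for one-at-a-time randomized parameter perturbation: each analyzed
#' parameter is perturbed uniformly within +/- `delta` of its nominal value,
#' `nRuns` times, with a reproducible stream keyed on (seed, parameter, run).
#'
#' @slot nRuns number of perturbed simulations per parameter (default 1000).
#' @slot delta perturbation halfwidth as a fraction of nominal (default 0.30).
#' @slot seed integer seed.
#' @slot indexType `"l1"` (normalized L1 deviation from the nominal trajectory,
#'   default) or `"dispersion"` (time-averaged inter-run dispersion).
#' @slot epsilon small constant guarding the normalization denominator.
#' @slot maxFailFrac maximum tolerated fraction of failed integrations.
#'
#' @seealso [oatConfig()], [oatSample()], [perVariableIndex()].
#' @exportClass OATConfig
setClass("OATConfig",
  representation(
    nRuns = "numeric", delta = "numeric", seed = "numeric",
    indexType = "character", epsilon = "numeric", maxFailFrac = "numeric"
  )
)

setValidity("OATConfig", function(object) {
  msg <- character()
  if (object@nRuns < 2) msg <- c(msg, "nRuns must be >= 2")
  if (object@delta <= 0 || object@delta >= 1) msg <- c(msg, "delta must be in (0,1)")
  if (!object@indexType %in% c("l1", "dispersion")) {
    msg <- c(msg, "indexType must be 'l1' or 'dispersion'")
  }
  if (length(msg)) msg else TRUE
})

#' OAT sensitivity analysis result
#'
#' Per-(parameter, variable) sensitivity indices, per-variable parameter
#' rankings, and the combined ranking: columns are max-normalized per
#' variable, the combined index is the arithmetic row mean, and parameters
#' are ranked by decreasing combined index (ties by id).
#'
#' @slot indices parameter x variable matrix of raw nonnegative indices.
#' @slot normalized the per-variable max-normalized index matrix.
#' @slot combined named numeric vector of combined indices.
#' @slot ranking character vector of parameter ids, most sensitive first.
#' @slot perVariableRankings list (by variable) of parameter-id rankings.
#' @slot config the [OATConfig-class] used.
#'
#' @seealso [sensitivityAnalysis()], [combinedRanking()].
#' @exportClass SensitivityResult
setClass("SensitivityResult",
  representation(
    indices = "matrix",
    normalized = "matrix",
    combined = "numeric",
    ranking = "character",
    perVariableRankings = "list",
    config = "OATConfig"
  )
)
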