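#' Construct a classical Petri net
#'
#' @param places character vector of place ids.
#' @param transitions character vector of transition ids.
#' @param arcs data.frame with columns `source`, `target` and optionally
#'   `weight` (default 1). Each arc must connect a place and a transition.
#'   Duplicate same-direction arcs are summed into one weighted arc with a
#'   warning.
#' @param marking named numeric vector of initial token counts; unnamed places
#'   default to 0.
#' @param placeNames,transitionNames optional named character vectors of
#'   display names; ids are used where omitted.
#' @return a [PetriNet-class].
#' @examples
#' net <- PetriNet(
#'   places = c("p1", "p2"),
#'   transitions = "t1",
#'   arcs = data.frame(source = c("p1", "t1"), target = c("t1", "p2"))
#' )
#' incidenceMatrix(net)
#' @export
PetriNet <- function(places, transitions, arcs,
                     marking = NULL, placeNames = NULL, transitionNames = NULL) {
  places <- as.character(places)
  transitions <- as.character(transitions)
  if (is.null(arcs)) arcs <- data.frame(source = character(), target = character())
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (!"weight" %in% names(arcs)) arcs$weight <- rep(1, nrow(arcs))
  arcs$weight[is.na(arcs$weight)] <- 1
  arcs <- arcs[, c("source", "target", "weight")]
  arcs$source <- as.character(arcs$source)
  arcs$target <- as.character(arcs$target)
  arcs$weight <- as.numeric(arcs$weight)
  if (nrow(arcs)) {
    key <- paste(arcs$source, arcs$target, sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate parallel arcs summed into single weighted arcs")
      w <- tapply(arcs$weight, key, sum)
      parts <- strsplit(names(w), "\r", fixed = TRUE)
      arcs <- data.frame(
        source = vapply(parts, `[`, "", 1L),
        target = vapply(parts, `[`, "", 2L),
        weight = as.numeric(w),
        stringsAsFactors = FALSE
      )
    }
    rownames(arcs) <- NULL
  }
  m <- stats::setNames(rep(0, length(places)), places)
  if (!is.null(marking) && length(marking)) {
    unknown <- setdiff(names(marking), places)
    if (length(unknown)) {
      stopInput("marking refers to unknown place(s): ",
                paste(unknown, collapse = ", "))
    }
    m[names(marking)] <- as.numeric(marking)
  }
  pn <- stats::setNames(places, places)
  if (!is.null(placeNames)) pn[names(placeNames)] <- placeNames
  tn <- stats::setNames(transitions, transitions)
  if (!is.null(transitionNames)) tn[names(transitionNames)] <- transitionNames
  new("PetriNet",
      places = places, transitions = transitions,
      placeNames = pn, transitionNames = tn,
      arcs = arcs, marking = m)
}

#' @rdname PetriNet
#' @export
setMethod("places", "PetriNet", function(x) x@places)

#' @rdname PetriNet
#' @export
setMethod("transitions", "PetriNet", function(x) x@transitions)

#' @rdname PetriNet
#' @export
setMethod("arcs", "PetriNet", function(x) x@arcs)

#' @rdname PetriNet
#' @export
setMethod("marking", "PetriNet", function(x) x@marking)

#' @rdname PetriNet
#' @export
setMethod("placeNames", "PetriNet", function(x) x@placeNames)

#' @rdname PetriNet
#' @export
setMethod("transitionNames", "PetriNet", function(x) x@transitionNames)

setMethod("show", "PetriNet", function(object) {
  cat("PetriNet with", length(object@places), "places,",
      length(object@transitions), "transitions,",
      nrow(object@arcs), "arcs\n")
  cat("  places:     ", paste(utils::head(object@places, 8), collapse = ", "),
      if (length(object@places) > 8) ", ..." else "", "\n", sep = "")
  cat("  transitions:", paste(utils::head(object@transitions, 8), collapse = ", "),
      if (length(object@transitions) > 8) ", ..." else "", "\n", sep = "")
  cat("  tokens:", sum(object@marking), "\n")
})

#' @rdname incidenceMatrix
#' @export
setMethod("incidenceMatrix", "PetriNet", function(x) {
  p <- x@places
  tr <- x@transitions
  A <- matrix(0, nrow = length(p), ncol = length(tr),
              dimnames = list(p, tr))
  a <- x@arcs
  if (nrow(a)) {
    unknown <- setdiff(unique(c(a$source, a$target)), c(p, tr))
    if (length(unknown)) {
      stopInput("dangling arc endpoint: ", paste(unknown, collapse = ", "))
    }
    for (k in seq_len(nrow(a))) {
      s <- a$source[k]; tg <- a$target[k]; w <- a$weight[k]
      if (s %in% p) {
        A[s, tg] <- A[s, tg] - w      # place -> transition consumes
      } else {
        A[tg, s] <- A[tg, s] + w      # transition -> place produces
      }
    }
  }
  A
})

#' Delete transitions from a net
#'
#' Removes the given transitions and all their arcs. Used as the
#' recompute route of the knockout analysis: the minimal t-invariants of the
#' reduced net equal the filtered invariants of the full net.
#'
#' @param net a [PetriNet-class].
#' @param ids transition ids to remove.
#' @return a [PetriNet-class].
#' @export
removeTransitions <- function(net, ids) {
  unknown <- setdiff(ids, net@transitions)
  if (length(unknown)) {
    stopInput("unknown transition(s): ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(net@transitions, ids)
  a <- net@arcs
  a <- a[!(a$source %in% ids | a$target %in% ids), , drop = FALSE]
  PetriNet(net@places, keep, a, marking = net@marking,
           placeNames = net@placeNames,
           transitionNames = net@transitionNames[keep])
}

#' Disjoint union of two Petri nets
#'
#' Node ids must not overlap; the minimal invariant set of the union is the
#' union of the parts' invariant sets.
#'
#' @param net1,net2 [PetriNet-class] objects with disjoint id sets.
#' @return a [PetriNet-class].
#' @export
disjointUnion <- function(net1, net2) {
  overlap <- intersect(c(net1@places, net1@transitions),
                       c(net2@places, net2@transitions))
  if (length(overlap)) {
    stopInput("nets share ids: ", paste(overlap, collapse = ", "))
  }
  PetriNet(c(net1@places, net2@places),
           c(net1@transitions, net2@transitions),
           rbind(net1@arcs, net2@arcs),
           marking = c(net1@marking, net2@marking),
           placeNames = c(net1@placeNames, net2@placeNames),
           transitionNames = c(net1@transitionNames, net2@transitionNames))
}

#' Permute the place ordering of a net
#'
#' Reorders the place list (and marking) without changing the structure;
#' invariant computation results are independent of this ordering.
#'
#' @param net a [PetriNet-class].
#' @param perm integer permutation of `seq_along(places(net))`.
#' @return a [PetriNet-class].
#' @export
permutePlaces <- function(net, perm) {
  p <- net@places[perm]
  PetriNet(p, net@transitions, net@arcs,
           marking = net@marking[p],
           placeNames = net@placeNames[p],
           transitionNames = net@transitionNames)
}
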