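# Minimal semi-positive invariant engine.
#
# Farkas-style (Fourier-Motzkin) place-by-place elimination on the table
# [A^T | I_m]: for the current place column, rows with opposite signs are
# combined pairwise into rows that annihilate the column, rows still nonzero
# in the column are discarded, and rows whose support (over the identity part)
# strictly contains another row's support are pruned after every step.
# All arithmetic is exact integer arithmetic on doubles with an overflow
# guard (see utils.R); every combined row is divided by the gcd of its
# entries immediately.

# deduplicate identical rows, then drop rows whose id-part support strictly
# contains another row's support
.pruneRows <- function(Tmat, idCols) {
  if (nrow(Tmat) <= 1) return(Tmat)
  key <- apply(Tmat, 1, paste, collapse = " ")
  Tmat <- Tmat[!duplicated(key), , drop = FALSE]
  n <- nrow(Tmat)
  if (n <= 1) return(Tmat)
  S <- (Tmat[, idCols, drop = FALSE] > 0) * 1
  sz <- rowSums(S)
  outside <- S %*% t(1 - S)   # outside[i,j] = |supp_i \ supp_j|
  drop <- logical(n)
  for (j in seq_len(n)) {
    if (any(outside[, j] == 0 & sz < sz[j])) drop[j] <- TRUE
  }
  Tmat[!drop, , drop = FALSE]
}

# minimal semipositive solutions of A %*% x == 0, one per row
.minimalSemiflows <- function(A) {
  n <- nrow(A)
  m <- ncol(A)
  if (m == 0L) return(matrix(0, nrow = 0, ncol = 0))
  Tmat <- cbind(t(A), diag(m))
  idCols <- n + seq_len(m)
  remaining <- seq_len(n)
  while (length(remaining)) {
    nz <- colSums(Tmat[, remaining, drop = FALSE] != 0)
    cIdx <- remaining[which.min(nz)]      # fewest nonzero rows first
    col <- Tmat[, cIdx]
    zero <- Tmat[col == 0, , drop = FALSE]
    pos <- Tmat[col > 0, , drop = FALSE]
    neg <- Tmat[col < 0, , drop = FALSE]
    combos <- NULL
    if (nrow(pos) && nrow(neg)) {
      combos <- matrix(0, nrow = nrow(pos) * nrow(neg), ncol = ncol(Tmat))
      r <- 0L
      for (i in seq_len(nrow(pos))) {
        a <- pos[i, ]
        ac <- a[cIdx]
        for (k in seq_len(nrow(neg))) {
          b <- neg[k, ]
          v <- (-b[cIdx]) * a + ac * b
          g <- vecGCD(v)
          if (g > 1) v <- v / g
          r <- r + 1L
          combos[r, ] <- v
        }
      }
      .checkExact(combos)
    }
    Tmat <- rbind(zero, combos)
    if (nrow(Tmat) == 0L) break
    Tmat <- .pruneRows(Tmat, idCols)
    remaining <- setdiff(remaining, cIdx)
  }
  if (nrow(Tmat) == 0L) {
    return(matrix(0, nrow = 0, ncol = m))
  }
  X <- Tmat[, idCols, drop = FALSE]
  X <- X[rowSums(X) > 0, , drop = FALSE]
  .canonicalizeInvariants(X)
}

# gcd-normalize rows, drop support-dominated and duplicate rows, sort
# lexicographically by support
.canonicalizeInvariants <- function(X) {
  if (nrow(X) == 0L) return(X)
  g <- apply(X, 1, vecGCD)
  X <- X / g
  key <- apply(X, 1, paste, collapse = " ")
  X <- X[!duplicated(key), , drop = FALSE]
  if (nrow(X) > 1) {
    S <- (X > 0) * 1
    sz <- rowSums(S)
    outside <- S %*% t(1 - S)
    drop <- logical(nrow(X))
    for (j in seq_len(nrow(X))) {
      if (any(outside[, j] == 0 & sz < sz[j])) drop[j] <- TRUE
    }
    X <- X[!drop, , drop = FALSE]
  }
  X[.supportOrder(X > 0), , drop = FALSE]
}

# deterministic lexicographic-by-support row order
.supportOrder <- function(S) {
  if (nrow(S) <= 1) return(seq_len(nrow(S)))
  keys <- apply(S, 1, function(s) paste(sprintf("%06d", which(s)), collapse = ""))
  order(keys)
}

.makeInvariantSet <- function(vectors, kind, ids, netId = "") {
  colnames(vectors) <- ids
  rownames(vectors) <- NULL
  new("InvariantSet", kind = kind, vectors = vectors, netId = netId)
}

#' Minimal t-invariants of a Petri net
#'
#' Computes the complete set of minimal-support, gcd-canonical semi-positive
#' t-invariants: nonnegative integer vectors x != 0 with A x = 0, where A is
#' the incidence matrix. Each t-invariant describes a subprocess that leaves
#' the marking (system state) unchanged when every transition t_j in its
#' support fires x_j times.
#'
#' @param net a [PetriNet-class] with at least one transition.
#' @return an [InvariantSet-class] of kind `"t"`. An empty set is a valid
#'   result (the net is then not covered).
#' @examples
#' minimalTInvariants(cycleNet(3))
#' @seealso [minimalPInvariants()], [isCovered()], [bruteForceTInvariants()].
#' @export
minimalTInvariants <- function(net) {
  if (length(net@transitions) == 0L) stopInput("net has no transitions")
  X <- .minimalSemiflows(incidenceMatrix(net))
  .makeInvariantSet(X, "t", net@transitions, netId = "net")
}

#' Minimal p-invariants of a Petri net
#'
#' Computes the minimal semi-positive p-invariants: nonnegative integer
#' vectors y != 0 with y A = 0. A p-invariant defines a weighted token count
#' conserved by every firing.
#'
#' @param net a [PetriNet-class] with at least one place.
#' @return an [InvariantSet-class] of kind `"p"`.
#' @examples
#' minimalPInvariants(cycleNet(3))
#' @export
minimalPInvariants <- function(net) {
  if (length(net@places) == 0L) stopInput("net has no places")
  X <- .minimalSemiflows(t(incidenceMatrix(net)))
  .makeInvariantSet(X, "p", net@places, netId = "net")
}

#' Build an invariant set from explicit support sets
#'
#' Convenience constructor used by the subset-search analysis and the
#' synthetic support-family generator: each support becomes a 0/1 indicator
#' invariant. The supports must form an antichain (none strictly contained in
#' another).
#'
#' @param supports list of character vectors (ids with positive entries).
#' @param ids full ordered id universe (column names).
#' @param kind `"t"` (default) or `"p"`.
#' @param netId provenance tag.
#' @return an [InvariantSet-class].
#' @export
invariantSetFromSupports <- function(supports, ids, kind = "t", netId = "") {
  X <- matrix(0, nrow = length(supports), ncol = length(ids),
              dimnames = list(NULL, ids))
  for (i in seq_along(supports)) {
    unknown <- setdiff(supports[[i]], ids)
    if (length(unknown)) {
      stopInput("support refers to unknown id(s): ",
                paste(unknown, collapse = ", "))
    }
    X[i, supports[[i]]] <- 1
  }
  X <- X[.supportOrder(X > 0), , drop = FALSE]
  .makeInvariantSet(X, kind, ids, netId)
}

#' @rdname supports
#' @export
setMethod("supports", "InvariantSet", function(x) {
  ids <- colnames(x@vectors)
  lapply(seq_len(nrow(x@vectors)), function(i) ids[x@vectors[i, ] > 0])
})

#' Accessors for invariant sets
#'
#' `invariantKind()` returns `"t"` or `"p"`; `invariantVectors()` the
#' invariant matrix (one row per invariant, columns named by ids);
#' `length()` the number of invariants.
#'
#' @name InvariantSet
#' @aliases invariantKind invariantVectors
NULL

#' @rdname InvariantSet
#' @export
setMethod("invariantKind", "InvariantSet", function(x) x@kind)

#' @rdname InvariantSet
#' @export
setMethod("invariantVectors", "InvariantSet", function(x) x@vectors)

#' @rdname InvariantSet
#' @export
setMethod("length", "InvariantSet", function(x) nrow(x@vectors))

setMethod("show", "InvariantSet", function(object) {
  cat("InvariantSet:", nrow(object@vectors),
      paste0(object@kind, "-invariants over "),
      ncol(object@vectors), "ids\n")
  for (i in seq_len(min(5L, nrow(object@vectors)))) {
    s <- colnames(object@vectors)[object@vectors[i, ] > 0]
    cat("  {", paste(s, collapse = ", "), "}\n", sep = "")
  }
  if (nrow(object@vectors) > 5L) cat("  ...\n")
})

#' Coverage of a net by t-invariants
#'
#' A net is covered when every transition occurs in the support of at least
#' one t-invariant; coverage is a prerequisite for the significance analysis.
#'
#' @param net a [PetriNet-class].
#' @param invs an [InvariantSet-class] of kind `"t"` computed from `net`
#'   (computed on the fly when omitted).
#' @return list with elements `covered` (logical) and `uncovered`
#'   (character vector of transitions in no support).
#' @examples
#' isCovered(cycleNet(3))
#' @export
isCovered <- function(net, invs = NULL) {
  if (is.null(invs)) invs <- minimalTInvariants(net)
  if (invs@kind != "t") stopInput("coverage is defined for t-invariants")
  inSupport <- colnames(invs@vectors)[colSums(invs@vectors > 0) > 0]
  uncovered <- setdiff(net@transitions, inSupport)
  list(covered = length(uncovered) == 0L, uncovered = uncovered)
}
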