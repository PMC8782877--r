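# Structural analyses over a computed t-invariant set: significance,
# knockout exclusion, significant-subset search.

#' Transition significance analysis
#'
#' For each transition of the net, counts the t-invariant supports containing
#' it (f) and reports the percentage significance S = f * 100 / s, where s is
#' the total number of t-invariants. High-significance transitions take part
#' in many steady-state subprocesses and are candidates for key elementary
#' processes of the modeled pathway.
#'
#' Percentages are rounded half-up to two decimals; rows are sorted by
#' decreasing S, ties by transition id.
#'
#' @param invs a nonempty [InvariantSet-class] of kind `"t"`.
#' @param net the source [PetriNet-class]; every transition of the net
#'   appears in the report (possibly with f = 0). When omitted, the
#'   invariant set's column ids are used.
#' @return a [SignificanceReport-class].
#' @examples
#' net <- cycleNet(3)
#' transitionSignificance(minimalTInvariants(net), net)
#' @export
transitionSignificance <- function(invs, net = NULL) {
  if (invs@kind != "t") stopInput("significance analysis needs t-invariants")
  s <- nrow(invs@vectors)
  if (s == 0L) stopAnalysis("empty invariant set: significance undefined")
  ids <- colnames(invs@vectors)
  f <- colSums(invs@vectors > 0)
  nm <- stats::setNames(ids, ids)
  if (!is.null(net)) {
    extra <- setdiff(net@transitions, ids)
    if (length(extra)) f[extra] <- 0
    ids <- union(ids, net@transitions)
    nm <- net@transitionNames[ids]
    f <- f[ids]
  }
  S <- roundHalfUp(f * 100 / s, 2)
  tab <- data.frame(
    transition_id = ids,
    name = unname(nm),
    t_inv_count = unname(f),
    significance_pct = unname(S),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$significance_pct, tab$transition_id), ]
  rownames(tab) <- NULL
  new("SignificanceReport", table = tab, nInvariants = s)
}

#' @rdname SignificanceReport-class
#' @param x a [SignificanceReport-class].
#' @param ... unused.
#' @export
setMethod("as.data.frame", "SignificanceReport", function(x, ...) x@table)

#' @rdname SignificanceReport-class
#' @export
significanceTable <- function(x) x@table

setMethod("show", "SignificanceReport", function(object) {
  cat("SignificanceReport over", object@nInvariants, "t-invariants\n")
  print(utils::head(object@table, 10))
  if (nrow(object@table) > 10) cat("  ...", nrow(object@table), "rows\n")
})

#' Knockout analysis
#'
#' Knocks out a set of transitions and reports which subprocesses
#' (t-invariants) are excluded: the surviving invariants are those whose
#' support is disjoint from the knocked set, and the exclusion percentage is
#' E = (tinv_b - tinv_a) * 100 / tinv_b (rounded half-up to two decimals).
#'
#' Support filtering coincides with recomputing minimal t-invariants on the
#' net with the knocked transitions deleted (an invariant avoiding the
#' knocked columns is minimal in the reduced net iff minimal in the full
#' net); see [removeTransitions()] for the recompute route.
#'
#' @param invs a nonempty [InvariantSet-class] of kind `"t"`.
#' @param knocked character vector of transition ids to knock out (must be
#'   known to the invariant set).
#' @return a [KnockoutResult-class].
#' @examples
#' net <- cycleNet(3)
#' knockout(minimalTInvariants(net), "t1")
#' @export
knockout <- function(invs, knocked) {
  if (invs@kind != "t") stopInput("knockout analysis needs t-invariants")
  knocked <- unique(as.character(knocked))
  ids <- colnames(invs@vectors)
  unknown <- setdiff(knocked, ids)
  if (length(unknown)) {
    stopInput("unknown transition(s): ", paste(unknown, collapse = ", "))
  }
  before <- nrow(invs@vectors)
  if (before == 0L) stopAnalysis("empty invariant set: knockout undefined")
  hit <- rowSums(invs@vectors[, knocked, drop = FALSE] > 0) > 0
  surv <- invs@vectors[!hit, , drop = FALSE]
  after <- nrow(surv)
  E <- roundHalfUp((before - after) * 100 / before, 2)
  new("KnockoutResult",
      knocked = knocked, before = before, after = after, excluded = E,
      surviving = .makeInvariantSet(surv, "t", ids, invs@netId))
}

setMethod("show", "KnockoutResult", function(object) {
  cat("KnockoutResult: knocked {", paste(object@knocked, collapse = ", "),
      "}\n", sep = "")
  cat("  t-invariants:", object@before, "->", object@after,
      sprintf("(E = %.2f%%)\n", object@excluded))
})

#' @rdname KnockoutResult-class
#' @param x a [KnockoutResult-class].
#' @export
excludedPct <- function(x) x@excluded

#' @rdname KnockoutResult-class
#' @export
survivingInvariants <- function(x) x@surviving

# joint containment frequency of a transition set in the supports
.jointFrequency <- function(mat, set) {
  if (!length(set)) return(1)
  sum(rowSums(mat[, set, drop = FALSE] > 0) == length(set)) / nrow(mat)
}

# knockout exclusion percentage straight from a support indicator matrix
.knockoutE <- function(mat, set) {
  hit <- rowSums(mat[, set, drop = FALSE] > 0) > 0
  roundHalfUp(sum(hit) * 100 / nrow(mat), 2)
}

#' Search for significant transition subsets
#'
#' Two search modes over a t-invariant set:
#'
#' * `"joint"`: finds all maximal transition sets whose joint containment
#'   frequency (fraction of supports containing every member) is at least
#'   `threshold`, by level-wise (Apriori-style) expansion over the
#'   transitions whose individual frequency meets the threshold, pruning
#'   infrequent candidates. A set occurring in more than 80% of all supports
#'   is considered necessary for the system's functioning.
#' * `"union"`: greedy forward selection maximizing the knockout exclusion E
#'   gained by each added transition, reporting the selected set at every
#'   size up to `maxSetSize`; suits sets whose members cover complementary
#'   groups of crucial subprocesses.
#'
#' Results are ordered by larger set size, then higher frequency, then
#' lexicographic id order (also the greedy tie-break).
#'
#' @param invs a nonempty [InvariantSet-class] of kind `"t"`, or a plain
#'   list of supports (character vectors) when analyzing a support family
#'   that is not itself a minimal-invariant set.
#' @param threshold frequency threshold in (0, 1]; default 0.8.
#' @param maxSetSize cap on the set size (default 12).
#' @param mode `"joint"` or `"union"`.
#' @param initial for `"union"` mode, transitions forced into the set before
#'   the greedy expansion starts.
#' @return data.frame with columns `set` (comma-separated ids), `size`,
#'   `frequency` (joint containment) and `excluded_pct` (knockout E of the
#'   set).
#' @examples
#' significantSubsetSearch(
#'   list(c("t1", "t2"), c("t1", "t3"), c("t1", "t2", "t3")),
#'   threshold = 0.8)
#' @export
significantSubsetSearch <- function(invs, threshold = 0.8, maxSetSize = 12L,
                                    mode = c("joint", "union"),
                                    initial = character()) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1) {
    stopInput("threshold must be in (0, 1]")
  }
  if (maxSetSize < 1) stopInput("maxSetSize must be positive")
  if (is.list(invs)) {
    ids <- sort(unique(unlist(invs)))
    mat <- matrix(0, nrow = length(invs), ncol = length(ids),
                  dimnames = list(NULL, ids))
    for (i in seq_along(invs)) mat[i, invs[[i]]] <- 1
  } else {
    if (invs@kind != "t") stopInput("subset search needs t-invariants")
    mat <- invs@vectors
  }
  if (nrow(mat) == 0L) stopAnalysis("empty invariant set")
  ids <- colnames(mat)

  if (mode == "joint") {
    singles <- sort(ids[vapply(ids, function(t)
      .jointFrequency(mat, t), 0) >= threshold])
    frequent <- list()
    level <- lapply(singles, identity)
    while (length(level) && length(level[[1]]) <= maxSetSize) {
      frequent <- c(frequent, level)
      # candidate (k+1)-sets: join level sets sharing a (k-1)-prefix
      cand <- list()
      seen <- character()
      for (i in seq_along(level)) {
        for (j in seq_along(level)) {
          if (i >= j) next
          a <- level[[i]]; b <- level[[j]]
          k <- length(a)
          if (k > 1 && !identical(a[-k], b[-k])) next
          u <- sort(union(a, b))
          if (length(u) != k + 1) next
          key <- paste(u, collapse = ",")
          if (key %in% seen) next
          seen <- c(seen, key)
          if (.jointFrequency(mat, u) >= threshold) cand[[length(cand) + 1]] <- u
        }
      }
      level <- cand
    }
    if (!length(frequent)) {
      return(data.frame(set = character(), size = integer(),
                        frequency = numeric(), excluded_pct = numeric()))
    }
    # maximal frequent sets: no frequent strict superset
    keys <- vapply(frequent, paste, "", collapse = ",")
    isMax <- vapply(seq_along(frequent), function(i) {
      !any(vapply(seq_along(frequent), function(j) {
        j != i && length(frequent[[j]]) > length(frequent[[i]]) &&
          all(frequent[[i]] %in% frequent[[j]])
      }, TRUE))
    }, TRUE)
    sets <- frequent[isMax]
  } else {
    unknown <- setdiff(initial, ids)
    if (length(unknown)) {
      stopInput("unknown transition(s): ", paste(unknown, collapse = ", "))
    }
    current <- sort(unique(as.character(initial)))
    sets <- list()
    if (length(current)) sets[[1]] <- current
    while (length(current) < maxSetSize) {
      candidates <- sort(setdiff(ids, current))
      if (!length(candidates)) break
      E <- vapply(candidates, function(t)
        .knockoutE(mat, c(current, t)), 0)
      best <- candidates[which.max(E)]   # which.max: first = lexicographic tie
      current <- sort(c(current, best))
      sets[[length(sets) + 1]] <- current
      if (max(E) >= 100) break
    }
  }

  res <- data.frame(
    set = vapply(sets, paste, "", collapse = ","),
    size = vapply(sets, length, 0L),
    frequency = vapply(sets, function(s) .jointFrequency(mat, s), 0),
    excluded_pct = vapply(sets, function(s) .knockoutE(mat, s), 0),
    stringsAsFactors = FALSE
  )
  res <- res[order(-res$size, -res$frequency, res$set), ]
  rownames(res) <- NULL
  res
}

#' Write a significance report
#'
#' Serializes a [SignificanceReport-class] as CSV (columns `transition_id`,
#' `name`, `t_inv_count`, `significance_pct`) or JSON.
#'
#' @param report a [SignificanceReport-class].
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param header optional provenance comment lines prepended to the CSV.
#' @return `path`, invisibly.
#' @export
writeSignificance <- function(report, path, format = c("csv", "json"),
                              header = character()) {
  format <- match.arg(format)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(header)) writeLines(paste0("# ", header), con)
    utils::write.csv(report@table, con, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(
      list(n_invariants = report@nInvariants, rows = report@table),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a knockout result as JSON
#'
#' @param result a [KnockoutResult-class].
#' @param path output file path.
#' @param meta optional named list of provenance fields.
#' @return `path`, invisibly.
#' @export
writeKnockout <- function(result, path, meta = list()) {
  jsonlite::write_json(
    c(meta, list(
      knocked = result@knocked,
      tinv_before = result@before,
      tinv_after = result@after,
      excluded_pct = result@excluded,
      surviving_supports = lapply(supports(result@surviving), identity)
    )),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
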