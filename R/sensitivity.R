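# One-at-a-time (OAT) sensitivity analysis of ODE pathway models.

#' OAT configuration
#'
#' @param nRuns perturbed simulations per parameter (default 1000; reduce
#'   for desk-scale work).
#' @param delta perturbation halfwidth as a fraction of the nominal value
#'   (default 0.30, i.e. +/-30%).
#' @param seed integer seed; every draw is reproducible from
#'   (seed, parameter id, run index).
#' @param indexType `"l1"` (default) or `"dispersion"`; see
#'   [perVariableIndex()].
#' @param epsilon guard added to the normalization denominator.
#' @param maxFailFrac maximum tolerated fraction of failed integrations
#'   before the analysis errors out (default 0.1).
#' @return an [OATConfig-class].
#' @export
oatConfig <- function(nRuns = 1000, delta = 0.30, seed = 1,
                      indexType = c("l1", "dispersion"),
                      epsilon = 1e-9, maxFailFrac = 0.1) {
  indexType <- match.arg(indexType)
  new("OATConfig", nRuns = nRuns, delta = delta, seed = seed,
      indexType = indexType, epsilon = epsilon, maxFailFrac = maxFailFrac)
}

#' One-at-a-time perturbed parameter value
#'
#' Draws the perturbed value of a parameter for a given run: uniform within
#' `[nominal * (1 - delta), nominal * (1 + delta)]`. Across the `nRuns` runs
#' the draws are stratified (run r falls in the r-th of nRuns equal
#' sub-intervals of the band), so the ensemble is uniform over the whole
#' band while the Monte Carlo error of averaged indices shrinks much faster
#' than with independent draws. Each draw is reproducible from
#' (seed, parameter id, run index) alone and leaves the caller's RNG stream
#' untouched.
#'
#' @param nominal positive nominal parameter value.
#' @param cfg an [OATConfig-class].
#' @param paramId parameter id (keys the random stream).
#' @param run run index in `1:nRuns`.
#' @return the perturbed value.
#' @examples
#' cfg <- oatConfig(nRuns = 10, delta = 0.3, seed = 42)
#' oatSample(1, cfg, "k1", 1)
#' @export
oatSample <- function(nominal, cfg, paramId, run) {
  if (nominal <= 0) {
    warning("nonpositive nominal value for ", paramId, "; skipped")
    return(NA_real_)
  }
  if (run < 1 || run > cfg@nRuns) stopInput("run index out of range")
  v <- withLocalSeed(.mix31(cfg@seed, paramId, run), stats::runif(1))
  u <- -cfg@delta + 2 * cfg@delta * (run - 1 + v) / cfg@nRuns
  nominal * (1 + u)
}

# nominal trajectory for a (model, protocol); extracted for reuse
.nominalTrajectory <- function(model, protocol, rtol, atol) {
  suppressWarnings(simulateProtocol(model, protocol, rtol = rtol, atol = atol))
}

# window covering phases 2-3
.analysisWindow <- function(traj) {
  t0 <- traj@phaseEnds[1]
  traj@time >= t0
}

#' Per-variable OAT sensitivity index
#'
#' Default (`"l1"`) index of parameter `paramId` for model variable
#' `variable`: the mean over the perturbed runs of the normalized L1
#' deviation from the nominal trajectory over the stimulation and recovery
#' phases,
#' `integral |v_r(t) - v_bar(t)| dt / (integral |v_bar(t)| dt + epsilon)`.
#' The `"dispersion"` variant reports the time-averaged inter-run standard
#' deviation normalized by the mean nominal level. A parameter absent from
#' every rate term yields an index of exactly 0. Runs whose integration
#' fails are discarded and counted; more than `maxFailFrac` failures abort
#' the analysis.
#'
#' @param model an [ODEModel-class].
#' @param protocol a [SimulationProtocol-class].
#' @param paramId parameter to perturb.
#' @param variable species name.
#' @param cfg an [OATConfig-class].
#' @param nominalTraj optional precomputed nominal [Trajectory-class].
#' @param rtol,atol solver tolerances.
#' @return nonnegative scalar index; with attribute `"failed"` giving the
#'   number of discarded runs. When `variable` is a vector, a named vector
#'   of indices (the perturbed trajectories are simulated once).
#' @export
perVariableIndex <- function(model, protocol, paramId, variable, cfg,
                             nominalTraj = NULL, rtol = 1e-6, atol = 1e-9) {
  if (!paramId %in% names(model@parameters)) {
    stopInput("unknown parameter: ", paramId)
  }
  bad <- setdiff(variable, model@species)
  if (length(bad)) stopInput("unknown species: ", paste(bad, collapse = ", "))
  if (is.null(nominalTraj)) {
    nominalTraj <- .nominalTrajectory(model, protocol, rtol, atol)
  }
  sel <- .analysisWindow(nominalTraj)
  tt <- nominalTraj@time[sel]
  nominal <- model@parameters[[paramId]]
  vbar <- nominalTraj@values[sel, variable, drop = FALSE]
  denom <- apply(vbar, 2, function(col) trapz(tt, abs(col))) + cfg@epsilon
  failed <- 0L
  dev <- matrix(NA_real_, nrow = cfg@nRuns, ncol = length(variable),
                dimnames = list(NULL, variable))
  runsY <- vector("list", cfg@nRuns)
  for (r in seq_len(cfg@nRuns)) {
    val <- oatSample(nominal, cfg, paramId, r)
    if (is.na(val)) {
      failed <- failed + 1L
      next
    }
    traj <- tryCatch(
      suppressWarnings(simulateProtocol(
        model, protocol, overrides = stats::setNames(val, paramId),
        rtol = rtol, atol = atol)),
      error = function(e) NULL)
    if (is.null(traj)) {
      failed <- failed + 1L
      next
    }
    y <- traj@values[sel, variable, drop = FALSE]
    runsY[[r]] <- y
    dev[r, ] <- vapply(seq_along(variable), function(j)
      trapz(tt, abs(y[, j] - vbar[, j])), 0) / denom
  }
  if (failed > cfg@maxFailFrac * cfg@nRuns) {
    stopAnalysis(failed, " of ", cfg@nRuns, " integrations failed")
  }
  idx <- if (cfg@indexType == "l1") {
    colMeans(dev, na.rm = TRUE)
  } else {
    ok <- !vapply(runsY, is.null, TRUE)
    arr <- simplify2array(runsY[ok])  # time x var x run
    spread <- apply(arr, c(1, 2), stats::sd)
    meanLevel <- apply(abs(vbar), 2, mean) + cfg@epsilon
    apply(spread, 2, mean) / meanLevel
  }
  idx <- stats::setNames(as.numeric(idx), variable)
  out <- if (length(variable) == 1L) unname(idx) else idx
  attr(out, "failed") <- failed
  out
}

#' Full OAT sensitivity analysis
#'
#' Computes the index matrix (analyzed parameters x model variables), the
#' per-variable parameter rankings, and the combined ranking: per-variable
#' columns are max-normalized to [0, 1], the combined index is the
#' arithmetic row mean, and parameters are sorted by decreasing combined
#' index (ties by parameter id).
#'
#' @param model an [ODEModel-class].
#' @param protocol a [SimulationProtocol-class].
#' @param cfg an [OATConfig-class].
#' @param parameters parameter ids to analyze (default: all model
#'   parameters; restrict to kinetic parameters for pathway models).
#' @param variables species to include (default all).
#' @param rtol,atol solver tolerances.
#' @return a [SensitivityResult-class].
#' @export
sensitivityAnalysis <- function(model, protocol, cfg,
                                parameters = names(model@parameters),
                                variables = model@species,
                                rtol = 1e-6, atol = 1e-9) {
  nominalTraj <- .nominalTrajectory(model, protocol, rtol, atol)
  idx <- matrix(0, nrow = length(parameters), ncol = length(variables),
                dimnames = list(parameters, variables))
  for (p in parameters) {
    idx[p, ] <- perVariableIndex(model, protocol, p, variables, cfg,
                                 nominalTraj = nominalTraj,
                                 rtol = rtol, atol = atol)
  }
  .rankResult(idx, cfg)
}

.rankResult <- function(idx, cfg) {
  normalized <- apply(idx, 2, function(col) {
    m <- max(col)
    if (m > 0) col / m else col
  })
  if (is.null(dim(normalized))) {
    normalized <- matrix(normalized, ncol = ncol(idx), dimnames = dimnames(idx))
  }
  combined <- rowMeans(normalized)
  ord <- order(-combined, rownames(idx))
  perVar <- lapply(stats::setNames(colnames(idx), colnames(idx)), function(v) {
    rownames(idx)[order(-idx[, v], rownames(idx))]
  })
  new("SensitivityResult",
      indices = idx,
      normalized = normalized,
      combined = combined[ord],
      ranking = rownames(idx)[ord],
      perVariableRankings = perVar,
      config = cfg)
}

#' Combined parameter ranking from an index matrix
#'
#' Applies the per-variable max-normalization and arithmetic-mean
#' combination to an existing parameter x variable index matrix.
#'
#' @param indices nonnegative matrix (parameters x variables, dimnames set).
#' @param cfg an [OATConfig-class] recorded in the result (defaults to the
#'   package default configuration).
#' @return a [SensitivityResult-class].
#' @export
combinedRanking <- function(indices, cfg = oatConfig()) {
  if (is.null(rownames(indices)) || is.null(colnames(indices))) {
    stopInput("index matrix needs parameter/variable dimnames")
  }
  if (any(indices < 0)) stopInput("indices must be nonnegative")
  .rankResult(indices, cfg)
}

setMethod("show", "SensitivityResult", function(object) {
  cat("SensitivityResult:", nrow(object@indices), "parameters x",
      ncol(object@indices), "variables\n")
  top <- utils::head(object@ranking, 5)
  cat("  top ranked:", paste(top, collapse = ", "), "\n")
})

#' @rdname SensitivityResult-class
#' @param x a [SensitivityResult-class].
#' @export
sensitivityIndices <- function(x) x@indices

#' @rdname SensitivityResult-class
#' @export
parameterRanking <- function(x) x@ranking

#' @rdname SensitivityResult-class
#' @export
combinedIndices <- function(x) x@combined

#' @rdname SensitivityResult-class
#' @export
perVariableRankings <- function(x) x@perVariableRankings

#' Write a sensitivity ranking as CSV
#'
#' @param result a [SensitivityResult-class].
#' @param path output path; columns `rank`, `parameter`, `combined_index`.
#' @param header optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
writeRankingCSV <- function(result, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(rank = seq_along(result@ranking),
                   parameter = result@ranking,
                   combined_index = as.numeric(result@combined))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Perturbation comparison: level vs settling time
#'
#' Simulates the protocol with one parameter scaled by each factor and
#' reports, per variable, the recovery-phase mean level and the settling
#' time, together with their changes relative to the unscaled run. This
#' contrasts parameters whose perturbation shifts protein levels without
#' changing the settling time of the response with parameters acting the
#' opposite way.
#'
#' @param model an [ODEModel-class].
#' @param protocol a [SimulationProtocol-class].
#' @param paramId parameter to scale.
#' @param factors numeric scale factors (e.g. `c(0.7, 1, 1.3)`).
#' @param variables species to report (default all).
#' @param band settling-time band (see [settlingTime()]).
#' @param rtol,atol solver tolerances.
#' @return data.frame with columns `factor`, `variable`, `level`,
#'   `level_change`, `settling_h`, `settling_change_h`.
#' @export
perturbationComparison <- function(model, protocol, paramId,
                                   factors = c(0.7, 1, 1.3),
                                   variables = model@species, band = 0.05,
                                   rtol = 1e-6, atol = 1e-9) {
  if (!paramId %in% names(model@parameters)) {
    stopInput("unknown parameter: ", paramId)
  }
  nominal <- model@parameters[[paramId]]
  rows <- list()
  ref <- NULL
  for (f in sort(factors)) {
    traj <- suppressWarnings(simulateProtocol(
      model, protocol, overrides = stats::setNames(nominal * f, paramId),
      rtol = rtol, atol = atol))
    sel <- traj@time >= traj@phaseEnds[2]
    for (v in variables) {
      lv <- mean(traj@values[sel, v])
      st <- settlingTime(traj, v, band = band)
      rows[[length(rows) + 1]] <- data.frame(
        factor = f, variable = v, level = lv, settling_h = st)
    }
  }
  df <- do.call(rbind, rows)
  base <- df[df$factor == 1, ]
  if (nrow(base)) {
    df$level_change <- df$level -
      base$level[match(df$variable, base$variable)]
    df$settling_change_h <- df$settling_h -
      base$settling_h[match(df$variable, base$variable)]
  } else {
    df$level_change <- NA_real_
    df$settling_change_h <- NA_real_
  }
  df[, c("factor", "variable", "level", "level_change",
         "settling_h", "settling_change_h")]
}
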