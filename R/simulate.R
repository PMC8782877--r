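# Three-phase simulation protocol and trajectory utilities.

#' Construct a simulation protocol
#'
#' The canonical stimulation protocol has three consecutive phases:
#' a 24 h equilibration phase with no stimuli during which the model reaches
#' steady state, a 1 h stimulation phase with constant TNF (10 ng/ml) and an
#' ionizing-radiation pulse delivering the total dose uniformly over the
#' phase, and a 240 h recovery phase with TNF still present and IR off.
#'
#' @param phase1,phase2,phase3 phase durations in hours.
#' @param tnf TNF level (ng/ml) during phases 2-3.
#' @param ir total IR dose in Gy (4 or 10 in the canonical protocols);
#'   delivered as a rectangular dose-rate pulse of amplitude `ir / phase2`.
#' @param step output sampling step in hours.
#' @return a [SimulationProtocol-class].
#' @export
simulationProtocol <- function(phase1 = 24, phase2 = 1, phase3 = 240,
                               tnf = 10, ir = 4, step = 0.1) {
  new("SimulationProtocol", phase1 = phase1, phase2 = phase2,
      phase3 = phase3, tnf = tnf, ir = ir, step = step)
}

# input values per phase: list of named vectors
.phaseInputs <- function(protocol) {
  list(
    c(TNF = 0, IR = 0),
    c(TNF = protocol@tnf, IR = protocol@ir / protocol@phase2),
    c(TNF = protocol@tnf, IR = 0)
  )
}

#' Simulate a model under the three-phase protocol
#'
#' Integrates the model phase by phase with a stiff-capable adaptive solver
#' (`deSolve::ode`, lsoda), switching the inputs at the phase boundaries
#' (TNF off/on/on; IR off/pulse/off). Species are clamped at zero during
#' evaluation and in the returned trajectory (nonnegativity contract). At
#' the end of phase 1 the derivative norm is checked against the equilibrium
#' tolerance `||dx/dt||_inf < 1e-6 * ||x||_inf + 1e-9`; a warning is issued
#' when the model has not settled.
#'
#' @param model an [ODEModel-class].
#' @param protocol a [SimulationProtocol-class].
#' @param overrides optional named numeric vector of parameter overrides.
#' @param rtol,atol solver tolerances (defaults 1e-6, 1e-9).
#' @param method solver method passed to [deSolve::ode()].
#' @return a [Trajectory-class].
#' @examples
#' mod <- reducedFixtureModel()
#' prot <- simulationProtocol(ir = 4, step = 0.5)
#' traj <- simulateProtocol(mod, prot)
#' @export
simulateProtocol <- function(model, protocol, overrides = NULL,
                             rtol = 1e-6, atol = 1e-9, method = "lsoda") {
  pars <- model@parameters
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(pars))
    if (length(unknown)) {
      stopInput("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    pars[names(overrides)] <- overrides
  }
  exprs <- .compileRHS(model)
  sp <- model@species
  parsList <- as.list(pars)
  makeDeriv <- function(inputVals) {
    inp <- stats::setNames(rep(0, length(model@inputs)), model@inputs)
    common <- names(inputVals)[names(inputVals) %in% names(inp)]
    inp[common] <- inputVals[common]
    inpList <- as.list(inp)
    function(t, y, parms) {
      env <- list2env(c(as.list(pmax(y, 0)), parsList, inpList, list(t = t)))
      d <- vapply(sp, function(s) eval(exprs[[s]], env), 0)
      if (anyNA(d)) stopAnalysis("NaN in derivative at t = ", format(t))
      list(d)
    }
  }
  bounds <- cumsum(c(protocol@phase1, protocol@phase2, protocol@phase3))
  starts <- c(0, bounds[1:2])
  inputsPerPhase <- .phaseInputs(protocol)
  state <- model@initial
  if (is.null(names(state)) || !length(state)) {
    stopInput("model has no initial state")
  }
  allT <- numeric()
  allY <- NULL
  for (ph in 1:3) {
    times <- seq(starts[ph], bounds[ph], by = protocol@step)
    if (times[length(times)] < bounds[ph]) times <- c(times, bounds[ph])
    out <- tryCatch(
      deSolve::ode(y = state, times = times, func = makeDeriv(inputsPerPhase[[ph]]),
                   parms = NULL, method = method, rtol = rtol, atol = atol),
      error = function(e) stopAnalysis("integration failure in phase ", ph,
                                       ": ", conditionMessage(e)))
    if (attr(out, "istate")[1] < 0) {
      stopAnalysis("integration failure in phase ", ph, "; last valid time ",
                   format(max(out[, 1])))
    }
    y <- pmax(unclass(out)[, sp, drop = FALSE], 0)
    tvec <- out[, 1]
    if (ph == 1) {
      d <- makeDeriv(inputsPerPhase[[1]])(tvec[length(tvec)],
                                          y[nrow(y), ], NULL)[[1]]
      xs <- y[nrow(y), ]
      if (max(abs(d)) >= 1e-6 * max(abs(xs)) + 1e-9) {
        warning(sprintf(
          "model not at equilibrium at end of phase 1 (||dx/dt|| = %.3g)",
          max(abs(d))))
      }
    }
    keep <- if (ph == 1) seq_along(tvec) else -1L  # drop duplicated boundary
    allT <- c(allT, tvec[keep])
    allY <- rbind(allY, y[keep, , drop = FALSE])
    state <- y[nrow(y), ]
  }
  rownames(allY) <- NULL
  new("Trajectory", time = allT, values = allY, phaseEnds = bounds)
}

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@time), "time points,",
      ncol(object@values), "species; phases end at",
      paste(object@phaseEnds, collapse = ", "), "h\n")
})

#' @rdname Trajectory-class
#' @param x a [Trajectory-class].
#' @export
trajectoryTime <- function(x) x@time

#' @rdname Trajectory-class
#' @export
trajectoryValues <- function(x) x@values

#' @rdname Trajectory-class
#' @export
phaseEnds <- function(x) x@phaseEnds

#' Settling time of a trajectory
#'
#' The smallest time t* after the end of the stimulation phase such that the
#' species stays within a tolerance band around its final value at all later
#' sampled points. The band is `band * reference`; `reference` defaults to
#' the magnitude of the final value, falling back to the post-stimulation
#' amplitude when the trajectory decays to (near) zero. `NA` is returned
#' for trajectories that never settle (e.g. sustained oscillations).
#'
#' A trajectory only counts as settled when the in-band tail is a
#' substantial part of the analysis window (`minTailFrac`, default 10%);
#' otherwise an oscillation that happens to end near a sampled extremum
#' would spuriously report its last crossing as a settling time.
#'
#' @param traj a [Trajectory-class].
#' @param species species (column) name.
#' @param band tolerance band as a fraction of `reference` (default 0.05).
#' @param reference band reference value; numeric, or `NULL` for the default
#'   rule above.
#' @param minTailFrac minimum fraction of the window that must remain inside
#'   the band after t*.
#' @return settling time in hours measured from the end of the stimulation
#'   phase, or `NA_real_` if the trajectory does not settle.
#' @export
settlingTime <- function(traj, species, band = 0.05, reference = NULL,
                         minTailFrac = 0.1) {
  if (!species %in% colnames(traj@values)) {
    stopInput("unknown species: ", species)
  }
  t0 <- if (length(traj@phaseEnds) >= 2) traj@phaseEnds[2] else traj@time[1]
  sel <- traj@time >= t0
  tt <- traj@time[sel]
  v <- traj@values[sel, species]
  if (length(v) < 2) stopInput("trajectory does not extend past the stimulation phase")
  final <- v[length(v)]
  if (is.null(reference)) {
    reference <- abs(final)
    if (reference < 1e-12) reference <- max(abs(v))
    if (reference < 1e-12) return(0)
  }
  tol <- band * reference
  inside <- abs(v - final) <= tol
  if (!inside[length(inside)]) return(NA_real_)
  # last excursion outside the band decides
  lastOut <- max(c(0L, which(!inside)))
  if (lastOut == length(inside)) return(NA_real_)
  tStar <- tt[lastOut + 1L]
  if (tt[length(tt)] - tStar < minTailFrac * (tt[length(tt)] - t0)) {
    return(NA_real_)   # settled stretch too short to call it settled
  }
  tStar - t0
}

#' Write a trajectory as CSV
#'
#' @param traj a [Trajectory-class].
#' @param path output path; columns: `time` plus one column per species.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  df <- data.frame(time = traj@time, traj@values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
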