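# ODE pathway models as named additive rate terms.

#' Construct an ODE pathway model
#'
#' @param species ordered character vector of species names.
#' @param parameters named numeric vector of kinetic parameters.
#' @param terms list of terms; each a list with `target` (species), `sign`
#'   (+1 or -1), `rate` (character R expression over species, parameters and
#'   inputs) and `name` (process name).
#' @param inputs character vector of named time-dependent input signals
#'   (e.g. `c("TNF", "IR")`).
#' @param initial named numeric vector of initial species values (defaults
#'   to all zero).
#' @return an [ODEModel-class].
#' @examples
#' decay <- ODEModel(
#'   species = "x", parameters = c(p = 0.5),
#'   terms = list(list(target = "x", sign = -1, rate = "p * x",
#'                     name = "first-order decay")),
#'   initial = c(x = 1))
#' evaluateRHS(decay, c(x = 2), 0)
#' @export
ODEModel <- function(species, parameters, terms, inputs = character(),
                     initial = NULL) {
  if (is.null(initial)) initial <- stats::setNames(rep(0, length(species)), species)
  new("ODEModel",
      species = as.character(species),
      parameters = parameters,
      terms = terms,
      inputs = as.character(inputs),
      initial = initial[species])
}

setMethod("show", "ODEModel", function(object) {
  cat("ODEModel:", length(object@species), "species,",
      length(object@parameters), "parameters,",
      length(object@terms), "rate terms\n")
  cat("  species:", paste(object@species, collapse = ", "), "\n")
  if (length(object@inputs)) {
    cat("  inputs: ", paste(object@inputs, collapse = ", "), "\n")
  }
})

#' @rdname ODEModel
#' @param x an [ODEModel-class].
#' @export
speciesNames <- function(x) x@species

#' @rdname ODEModel
#' @export
modelParameters <- function(x) x@parameters

#' @rdname ODEModel
#' @export
modelTerms <- function(x) x@terms

#' @rdname ODEModel
#' @export
initialState <- function(x) x@initial

# Precompile one derivative expression per species (signed sum of its
# terms); returns list of unevaluated expressions named by species.
.compileRHS <- function(model) {
  exprs <- stats::setNames(vector("list", length(model@species)), model@species)
  for (tm in model@terms) {
    piece <- str2lang(sprintf("(%s)", tm$rate))
    piece <- if (tm$sign > 0) piece else call("-", piece)
    cur <- exprs[[tm$target]]
    exprs[[tm$target]] <- if (is.null(cur)) piece else call("+", cur, piece)
  }
  for (sp in model@species) if (is.null(exprs[[sp]])) exprs[[sp]] <- 0
  exprs
}

#' Evaluate the right-hand side of a model
#'
#' Computes the derivative vector at a given state: per species, the signed
#' sum of its rate terms. Species values are clamped at zero before
#' evaluation (concentrations are nonnegative by definition; the solver
#' contract documents the clamp).
#'
#' @param model an [ODEModel-class].
#' @param state named numeric vector over all species.
#' @param t time (hours), available to rate expressions as `t`.
#' @param inputs named numeric vector of input signal values at `t`
#'   (defaults to all zero).
#' @param parameters optional override of the model parameters.
#' @return named numeric derivative vector.
#' @export
evaluateRHS <- function(model, state, t = 0, inputs = NULL, parameters = NULL) {
  if (length(state) != length(model@species)) {
    stopInput("state length must equal number of species")
  }
  if (anyNA(state)) stopAnalysis("NaN/NA in state")
  if (is.null(names(state))) names(state) <- model@species
  if (is.null(parameters)) parameters <- model@parameters
  inp <- stats::setNames(rep(0, length(model@inputs)), model@inputs)
  if (!is.null(inputs)) inp[names(inputs)] <- inputs
  exprs <- .compileRHS(model)
  env <- list2env(c(as.list(pmax(state, 0)), as.list(parameters),
                    as.list(inp), list(t = t)))
  vapply(model@species, function(sp) eval(exprs[[sp]], env), 0)
}

#' Reduced nuclear-p53 activation fixture model
#'
#' A closed six-species ODE model around the nuclear phosphorylated p53
#' balance. The `p53pn` derivative is, term by term:
#' spontaneous activation `pa1 * p53n`, ATM-dependent activation
#' `pa2 * ATMan / (ATMan + pm1) * p53n`, Chk2-dependent activation
#' `pa3 * CHK2pn / (CHK2pn + pm2) * p53n`, Wip1-dependent inactivation
#' `pc1 * p53pn * WIP1n`, and spontaneous plus Mdm2-dependent degradation
#' `(pd4 + pd5 * MDM2pn^2) * p53pn`. `p53n` carries the synthesis source,
#' the mirrored activation/inactivation terms and first-order degradation;
#' the four driver species (`ATMan`, `CHK2pn`, `WIP1n`, `MDM2pn`) follow
#' first-order production/decay kinetics, with production of `ATMan` and
#' `CHK2pn` gated by the ionizing-radiation input `IR` (dose rate, Gy/h).
#'
#' Parameter values are package defaults chosen to give hour-scale kinetics
#' and low resting levels of the damage-detection species; they are
#' deliberately not calibrated to any published full-scale model. Units:
#' arbitrary concentration units and hours. The initial state is the resting
#' (no-input) steady state, computed analytically: the drivers are linear
#' and, at resting driver levels, so is the (p53n, p53pn) pair.
#'
#' @return an [ODEModel-class] with species `p53n`, `p53pn`, `ATMan`,
#'   `CHK2pn`, `WIP1n`, `MDM2pn` and inputs `IR`, `TNF`.
#' @examples
#' mod <- reducedFixtureModel()
#' max(abs(evaluateRHS(mod, initialState(mod), 0)))  # at steady state
#' @export
reducedFixtureModel <- function() {
  pars <- c(
    pa1 = 0.3, pa2 = 1.0, pa3 = 0.6, pm1 = 0.5, pm2 = 0.5,
    pc1 = 1.0, pd4 = 0.1, pd5 = 1.0,
    ps1 = 0.5, pd1 = 0.5,
    batm = 0.02, aatm = 1.0, gatm = 1.2,
    bchk2 = 0.02, achk2 = 0.5, gchk2 = 1.0,
    bwip1 = 0.5, gwip1 = 1.0,
    bmdm2 = 0.3, gmdm2 = 1.0
  )
  act <- c(
    spont = "pa1 * p53n",
    atm = "pa2 * ATMan / (ATMan + pm1) * p53n",
    chk2 = "pa3 * CHK2pn / (CHK2pn + pm2) * p53n"
  )
  terms <- list(
    # p53pn balance
    list(target = "p53pn", sign = 1, rate = act[["spont"]],
         name = "spontaneous phosphorylation of p53n"),
    list(target = "p53pn", sign = 1, rate = act[["atm"]],
         name = "phosphorylation of p53n by ATMan"),
    list(target = "p53pn", sign = 1, rate = act[["chk2"]],
         name = "phosphorylation of p53n by CHK2pn"),
    list(target = "p53pn", sign = -1, rate = "pc1 * p53pn * WIP1n",
         name = "dephosphorylation of p53pn by WIP1n"),
    list(target = "p53pn", sign = -1,
         rate = "(pd4 + pd5 * MDM2pn^2) * p53pn",
         name = "degradation of p53pn (spontaneous and by MDM2pn)"),
    # p53n balance (mirrors)
    list(target = "p53n", sign = 1, rate = "ps1",
         name = "production of p53n"),
    list(target = "p53n", sign = -1, rate = act[["spont"]],
         name = "spontaneous phosphorylation of p53n (loss)"),
    list(target = "p53n", sign = -1, rate = act[["atm"]],
         name = "phosphorylation of p53n by ATMan (loss)"),
    list(target = "p53n", sign = -1, rate = act[["chk2"]],
         name = "phosphorylation of p53n by CHK2pn (loss)"),
    list(target = "p53n", sign = 1, rate = "pc1 * p53pn * WIP1n",
         name = "dephosphorylation of p53pn by WIP1n (gain)"),
    list(target = "p53n", sign = -1, rate = "pd1 * p53n",
         name = "degradation of p53n"),
    # IR-gated drivers
    list(target = "ATMan", sign = 1, rate = "batm + aatm * IR",
         name = "activation of ATM (IR-gated)"),
    list(target = "ATMan", sign = -1, rate = "gatm * ATMan",
         name = "inactivation of ATMan"),
    list(target = "CHK2pn", sign = 1, rate = "bchk2 + achk2 * IR",
         name = "phosphorylation of Chk2 (IR-gated)"),
    list(target = "CHK2pn", sign = -1, rate = "gchk2 * CHK2pn",
         name = "dephosphorylation of CHK2pn"),
    # constitutive drivers
    list(target = "WIP1n", sign = 1, rate = "bwip1",
         name = "production of WIP1n"),
    list(target = "WIP1n", sign = -1, rate = "gwip1 * WIP1n",
         name = "degradation of WIP1n"),
    list(target = "MDM2pn", sign = 1, rate = "bmdm2",
         name = "production of MDM2pn"),
    list(target = "MDM2pn", sign = -1, rate = "gmdm2 * MDM2pn",
         name = "degradation of MDM2pn")
  )
  # resting steady state (IR = 0), analytically
  atm0 <- pars[["batm"]] / pars[["gatm"]]
  chk0 <- pars[["bchk2"]] / pars[["gchk2"]]
  wip0 <- pars[["bwip1"]] / pars[["gwip1"]]
  mdm0 <- pars[["bmdm2"]] / pars[["gmdm2"]]
  rAct <- pars[["pa1"]] +
    pars[["pa2"]] * atm0 / (atm0 + pars[["pm1"]]) +
    pars[["pa3"]] * chk0 / (chk0 + pars[["pm2"]])
  rBack <- pars[["pc1"]] * wip0
  rDeg <- pars[["pd4"]] + pars[["pd5"]] * mdm0^2
  # 0 = ps1 - (rAct + pd1) x + rBack y ; 0 = rAct x - (rBack + rDeg) y
  x0 <- pars[["ps1"]] * (rBack + rDeg) /
    ((pars[["pd1"]] + rAct) * (rBack + rDeg) - rAct * rBack)
  y0 <- rAct * x0 / (rBack + rDeg)
  ODEModel(
    species = c("p53n", "p53pn", "ATMan", "CHK2pn", "WIP1n", "MDM2pn"),
    parameters = pars,
    terms = terms,
    inputs = c("IR", "TNF"),
    initial = c(p53n = x0, p53pn = y0, ATMan = atm0, CHK2pn = chk0,
                WIP1n = wip0, MDM2pn = mdm0)
  )
}

#' Read an ODE model from a YAML configuration
#'
#' The configuration holds `species` (list), `parameters` (map),
#' `inputs` (list, optional), `initial` (map, optional) and `terms`: a list
#' of records with `target`, `sign`, `rate`, `name`.
#'
#' @param path YAML file path.
#' @return an [ODEModel-class].
#' @export
readODEModel <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stopInput("cannot read model config: ",
                                                conditionMessage(e)))
  need <- setdiff(c("species", "parameters", "terms"), names(cfg))
  if (length(need)) {
    stopInput("model config missing field(s): ", paste(need, collapse = ", "))
  }
  init <- NULL
  if (!is.null(cfg$initial)) init <- unlist(cfg$initial)
  ODEModel(
    species = unlist(cfg$species),
    parameters = unlist(cfg$parameters),
    terms = lapply(cfg$terms, function(tm) {
      tm$sign <- as.numeric(tm$sign)
      tm
    }),
    inputs = if (is.null(cfg$inputs)) character() else unlist(cfg$inputs),
    initial = init
  )
}
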