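# Translation motifs: building Petri net fragments from ODE rate terms.
#
# Each named rate term of an ODE pathway model maps onto a small net motif:
# spontaneous conversions, catalyzed conversions (with optional catalyst
# pools), inactivations, (mediated) degradations as output transitions,
# synthesis sources as input transitions, and inhibition drains. Classical
# nets have only one arc type, so catalysts are consumed and replenished
# through dedicated pool-source transitions, and inhibition is represented by
# a competing drain transition that weakens (but does not block) the
# inhibited reaction; complete inhibition is the job of the knockout
# analysis.

.ensurePlaces <- function(net, ids) {
  newIds <- setdiff(ids, net@places)
  if (!length(newIds)) return(net)
  clash <- intersect(newIds, net@transitions)
  if (length(clash)) {
    stopInput("id already used by a transition: ", paste(clash, collapse = ", "))
  }
  PetriNet(c(net@places, newIds), net@transitions, net@arcs,
           marking = net@marking,
           placeNames = c(net@placeNames,
                          stats::setNames(newIds, newIds)),
           transitionNames = net@transitionNames)
}

.freshTransitionId <- function(net, id = NULL) {
  if (!is.null(id)) {
    if (id %in% c(net@places, net@transitions)) {
      stopInput("transition id already in use: ", id)
    }
    return(id)
  }
  k <- length(net@transitions) + 1L
  repeat {
    cand <- paste0("t", k)
    if (!cand %in% c(net@places, net@transitions)) return(cand)
    k <- k + 1L
  }
}

.addTransition <- function(net, id, name, pre, post, preWeights = NULL,
                           postWeights = NULL) {
  net <- .ensurePlaces(net, c(pre, post))
  if (is.null(preWeights)) preWeights <- rep(1, length(pre))
  if (is.null(postWeights)) postWeights <- rep(1, length(post))
  newArcs <- rbind(
    if (length(pre)) data.frame(source = pre, target = id, weight = preWeights),
    if (length(post)) data.frame(source = id, target = post, weight = postWeights)
  )
  PetriNet(net@places, c(net@transitions, id),
           rbind(net@arcs, newArcs),
           marking = net@marking,
           placeNames = net@placeNames,
           transitionNames = c(net@transitionNames, stats::setNames(name, id)))
}

#' Motif: spontaneous conversion
#'
#' One transition converting `substrate` into `product` with no additional
#' stimulating component (e.g. spontaneous phosphorylation).
#'
#' @param net a [PetriNet-class]; missing places are created.
#' @param substrate,product place ids.
#' @param name display name of the new transition.
#' @param id optional transition id (auto-generated otherwise).
#' @return the extended [PetriNet-class]; exactly one transition is added.
#' @examples
#' net <- PetriNet(character(), character(),
#'                 data.frame(source = character(), target = character()))
#' net <- addSpontaneousConversion(net, "p53n", "p53pn",
#'                                 "spontaneous phosphorylation of p53n")
#' @export
addSpontaneousConversion <- function(net, substrate, product, name, id = NULL) {
  id <- .freshTransitionId(net, id)
  .addTransition(net, id, name, pre = substrate, post = product)
}

#' Motif: catalyzed conversion
#'
#' A transition with two pre-places (`substrate` and `catalyst`) and one
#' post-place (`product`): both components are required to fire. The
#' catalyst token is consumed; with `withPool = TRUE` a pool-source
#' transition replenishing the catalyst is added so it returns to
#' circulation.
#'
#' @inheritParams addSpontaneousConversion
#' @param catalyst place id of the catalyzing component.
#' @param withPool add a pool-source transition for the catalyst.
#' @param poolId optional id for the pool transition.
#' @return the extended [PetriNet-class].
#' @export
addCatalyzedConversion <- function(net, substrate, catalyst, product, name,
                                   withPool = FALSE, id = NULL, poolId = NULL) {
  id <- .freshTransitionId(net, id)
  net <- .addTransition(net, id, name,
                        pre = c(substrate, catalyst), post = product)
  if (withPool) {
    poolId <- .freshTransitionId(net, poolId)
    net <- .addTransition(net, poolId,
                          paste0("creation of pool of ", catalyst),
                          pre = character(), post = catalyst)
  }
  net
}

#' Motif: inactivation
#'
#' Mirror image of [addCatalyzedConversion()]: the active form plus the
#' inactivating agent precede the transition, the inactive form succeeds it
#' (only the arc directions differ from the activation motif).
#'
#' @inheritParams addSpontaneousConversion
#' @param active,inactive place ids of the active/inactive forms.
#' @param agent place id of the inactivating component.
#' @param withPool add a pool source for the agent.
#' @param poolId optional id for the pool transition.
#' @return the extended [PetriNet-class].
#' @export
addInactivation <- function(net, active, agent, inactive, name,
                            withPool = FALSE, id = NULL, poolId = NULL) {
  addCatalyzedConversion(net, substrate = active, catalyst = agent,
                         product = inactive, name = name,
                         withPool = withPool, id = id, poolId = poolId)
}

#' Motif: degradation (output transition)
#'
#' A transition with no post-places consuming `target` (and `mediator` when
#' given, e.g. Mdm2-mediated p53 degradation). Output transitions prevent
#' further token flow and are what makes coverage by t-invariants possible
#' for synthesis/conversion chains.
#'
#' @inheritParams addSpontaneousConversion
#' @param target place id of the degraded component.
#' @param mediator optional place id of a mediating component (consumed too).
#' @return the extended [PetriNet-class].
#' @export
addDegradation <- function(net, target, name, mediator = NULL, id = NULL) {
  id <- .freshTransitionId(net, id)
  .addTransition(net, id, name, pre = c(target, mediator), post = character())
}

#' Motif: synthesis source (input transition)
#'
#' A transition with no pre-places producing `product` (e.g. transcription
#' from a source).
#'
#' @inheritParams addSpontaneousConversion
#' @param product place id of the produced component.
#' @return the extended [PetriNet-class].
#' @export
addSynthesisSource <- function(net, product, name, id = NULL) {
  id <- .freshTransitionId(net, id)
  .addTransition(net, id, name, pre = character(), post = product)
}

#' Motif: inhibition drain
#'
#' Adds a transition whose pre-places are the inhibitor plus all pre-places
#' of the inhibited transition, draining their tokens: the inhibited reaction
#' is weakened, not blocked (complete inhibition is modeled by knockout
#' analysis instead).
#'
#' @inheritParams addSpontaneousConversion
#' @param inhibited id of the existing transition to weaken.
#' @param inhibitor place id of the inhibiting component.
#' @return the extended [PetriNet-class].
#' @export
addInhibitionDrain <- function(net, inhibited, inhibitor, name, id = NULL) {
  if (!inhibited %in% net@transitions) {
    stopInput("unknown transition: ", inhibited)
  }
  a <- net@arcs
  pre <- a[a$target == inhibited & a$source %in% net@places, , drop = FALSE]
  id <- .freshTransitionId(net, id)
  .addTransition(net, id, name,
                 pre = c(inhibitor, pre$source),
                 post = character(),
                 preWeights = c(1, pre$weight))
}

#' Assemble a net from a reaction list
#'
#' Builds a net by applying motif builders row by row. Each row names a motif
#' kind and its participant roles; recognized kinds are
#' `spontaneous_conversion` (roles `substrate`, `product`),
#' `catalyzed_conversion` (`substrate`, `catalyst`, `product`, optional
#' logical `with_pool`), `inactivation` (`active`, `agent`, `inactive`,
#' optional `with_pool`), `degradation` (`target`, optional `mediator`),
#' `synthesis_source` (`product`) and `inhibition_drain` (`inhibited`,
#' `inhibitor`).
#'
#' @param reactions data.frame with columns `kind`, `name`, the role columns
#'   above (unused roles `NA`), and optionally `id`; or the path to a YAML
#'   file with a `reactions` list of such records.
#' @return a [PetriNet-class].
#' @export
buildNetFromReactionList <- function(reactions) {
  if (is.character(reactions)) {
    cfg <- yaml::read_yaml(reactions)
    if (is.null(cfg$reactions)) stopInput("YAML must contain a 'reactions' list")
    reactions <- do.call(rbind, lapply(cfg$reactions, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  net <- PetriNet(character(), character(),
                  data.frame(source = character(), target = character()))
  gv <- function(row, field) {
    if (!field %in% names(row)) return(NULL)
    v <- row[[field]]
    if (is.null(v) || is.na(v) || identical(v, "")) NULL else v
  }
  for (i in seq_len(nrow(reactions))) {
    row <- reactions[i, , drop = FALSE]
    kind <- row$kind
    nm <- row$name
    id <- gv(row, "id")
    net <- switch(kind,
      spontaneous_conversion = addSpontaneousConversion(
        net, gv(row, "substrate"), gv(row, "product"), nm, id = id),
      catalyzed_conversion = addCatalyzedConversion(
        net, gv(row, "substrate"), gv(row, "catalyst"), gv(row, "product"),
        nm, withPool = isTRUE(as.logical(gv(row, "with_pool"))), id = id),
      inactivation = addInactivation(
        net, gv(row, "active"), gv(row, "agent"), gv(row, "inactive"),
        nm, withPool = isTRUE(as.logical(gv(row, "with_pool"))), id = id),
      degradation = addDegradation(
        net, gv(row, "target"), nm, mediator = gv(row, "mediator"), id = id),
      synthesis_source = addSynthesisSource(net, gv(row, "product"), nm, id = id),
      inhibition_drain = addInhibitionDrain(
        net, gv(row, "inhibited"), gv(row, "inhibitor"), nm, id = id),
      stopInput("unknown motif kind: ", kind))
  }
  net
}

#' Reduced nuclear-p53 activation fragment
#'
#' Builds the Petri net counterpart of the reduced p53 activation model: the
#' places `p53n`, `p53pn`, `ATMan`, `CHK2pn`, `WIP1n`, `MDM2pn` and one
#' transition per rate term of the nuclear phosphorylated p53 balance --
#' spontaneous activation, ATM- and Chk2-dependent activation,
#' Wip1-dependent inactivation, spontaneous and Mdm2-dependent degradation --
#' plus the p53 synthesis source and pool sources replenishing the four
#' catalytic/mediating species. The fragment is covered by t-invariants.
#'
#' Marking: 1 token on each source-fed place, 0 elsewhere (markings do not
#' affect the structural analyses; stated for reproducibility).
#'
#' @return a [PetriNet-class] with 6 places and 11 transitions.
#' @examples
#' frag <- buildP53Fragment()
#' isCovered(frag)$covered
#' @export
buildP53Fragment <- function() {
  net <- PetriNet(character(), character(),
                  data.frame(source = character(), target = character()))
  net <- addSynthesisSource(net, "p53n", "production of p53n", id = "t_p53_syn")
  net <- addSpontaneousConversion(net, "p53n", "p53pn",
    "spontaneous phosphorylation of p53n", id = "t_act_spont")
  net <- addCatalyzedConversion(net, "p53n", "ATMan", "p53pn",
    "phosphorylation of p53n by ATMan", withPool = TRUE,
    id = "t_act_atm", poolId = "t_pool_atm")
  net <- addCatalyzedConversion(net, "p53n", "CHK2pn", "p53pn",
    "phosphorylation of p53n by CHK2pn", withPool = TRUE,
    id = "t_act_chk2", poolId = "t_pool_chk2")
  net <- addInactivation(net, "p53pn", "WIP1n", "p53n",
    "dephosphorylation of p53pn by WIP1n", withPool = TRUE,
    id = "t_inact_wip1", poolId = "t_pool_wip1")
  net <- addDegradation(net, "p53pn", "degradation of p53pn",
    id = "t_deg_spont")
  net <- addDegradation(net, "p53pn", "degradation of p53pn by MDM2pn",
    mediator = "MDM2pn", id = "t_deg_mdm2")
  net <- .addTransition(net, "t_pool_mdm2", "creation of pool of MDM2pn",
                        pre = character(), post = "MDM2pn")
  sourceFed <- c("p53n", "ATMan", "CHK2pn", "WIP1n", "MDM2pn")
  mk <- net@marking
  mk[sourceFed] <- 1
  PetriNet(net@places, net@transitions, net@arcs, marking = mk,
           placeNames = net@placeNames, transitionNames = net@transitionNames)
}
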