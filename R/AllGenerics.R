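# Generics for the accessor surface.

#' @rdname PetriNet
#' @param object,x a [PetriNet-class] (or other object as documented).
#' @export
setGeneric("places", function(x) standardGeneric("places"))

#' @rdname PetriNet
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))

#' @rdname PetriNet
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))

#' @rdname PetriNet
#' @export
setGeneric("marking", function(x) standardGeneric("marking"))

#' @rdname PetriNet
#' @export
setGeneric("placeNames", function(x) standardGeneric("placeNames"))

#' @rdname PetriNet
#' @export
setGeneric("transitionNames", function(x) standardGeneric("transitionNames"))

#' Incidence matrix of a Petri net
#'
#' Builds the incidence matrix A (rows = places, columns = transitions):
#' entry (i, j) is the net token change of place i when transition j fires,
#' i.e. the summed weights of arcs t_j -> p_i minus those of p_i -> t_j.
#'
#' @param x a [PetriNet-class].
#' @return integer matrix with dimnames (place ids, transition ids).
#' @examples
#' net <- cycleNet(3)
#' incidenceMatrix(net)
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))

#' Supports of an invariant set
#'
#' The support s(x) of an invariant x is the set of transitions (t-kind) or
#' places (p-kind) with positive entries.
#'
#' @param x an [InvariantSet-class].
#' @return list of character vectors, one per invariant.
#' @export
setGeneric("supports", function(x) standardGeneric("supports"))

#' @rdname InvariantSet
#' @param x an [InvariantSet-class].
#' @export
setGeneric("invariantKind", function(x) standardGeneric("invariantKind"))

#' @rdname InvariantSet
#' @export
setGeneric("invariantVectors", function(x) standardGeneric("invariantVectors"))
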