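# Readers and writers for Petri net files: PNML (interchange format of
# record), Snoopy .spped (read-only, discrete place/transition dialect) and a
# simple CSV arc-list dialect.

.PNML_NS <- "http://www.pnml.org/version-2009/grammar/pnml"

.xmlText1 <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
}

#' Read a PNML file
#'
#' Parses a PNML core-model document (place/transition net): places with
#' `initialMarking`, transitions, and arcs with `inscription` weights
#' (defaults: marking 0, weight 1). Namespaces are ignored so documents with
#' or without the standard PNML namespace load identically.
#'
#' @param path file path (or connection) to a PNML document.
#' @return a [PetriNet-class].
#' @seealso [writePNML()], [readNet()].
#' @export
readPNML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopInput("malformed XML: ",
                                                conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  placeNodes <- xml2::xml_find_all(doc, ".//place")
  transNodes <- xml2::xml_find_all(doc, ".//transition")
  arcNodes <- xml2::xml_find_all(doc, ".//arc")
  pIds <- xml2::xml_attr(placeNodes, "id")
  tIds <- xml2::xml_attr(transNodes, "id")
  if (anyNA(pIds) || anyNA(tIds)) stopInput("node without id attribute")
  pNames <- vapply(placeNodes, function(n) {
    nm <- .xmlText1(n, "./name/text")
    if (is.na(nm)) xml2::xml_attr(n, "id") else nm
  }, "")
  tNames <- vapply(transNodes, function(n) {
    nm <- .xmlText1(n, "./name/text")
    if (is.na(nm)) xml2::xml_attr(n, "id") else nm
  }, "")
  markingOf <- vapply(placeNodes, function(n) {
    v <- .xmlText1(n, "./initialMarking/text")
    if (is.na(v)) 0 else as.numeric(v)
  }, 0)
  arcsDf <- data.frame(source = character(), target = character(),
                       weight = numeric())
  if (length(arcNodes)) {
    w <- vapply(arcNodes, function(n) {
      v <- .xmlText1(n, "./inscription/text")
      if (is.na(v)) 1 else as.numeric(v)
    }, 0)
    arcsDf <- data.frame(
      source = xml2::xml_attr(arcNodes, "source"),
      target = xml2::xml_attr(arcNodes, "target"),
      weight = w, stringsAsFactors = FALSE)
    ends <- c(arcsDf$source, arcsDf$target)
    unknown <- setdiff(ends, c(pIds, tIds))
    if (length(unknown)) {
      stopInput("arc endpoint not declared in document: ",
                paste(unknown, collapse = ", "))
    }
    bad <- !((arcsDf$source %in% pIds & arcsDf$target %in% tIds) |
             (arcsDf$source %in% tIds & arcsDf$target %in% pIds))
    if (any(bad)) {
      stopInput("non-bipartite arc at //arc[@source='",
                arcsDf$source[which(bad)[1]], "']")
    }
  }
  PetriNet(pIds, tIds, arcsDf,
           marking = stats::setNames(markingOf, pIds),
           placeNames = stats::setNames(pNames, pIds),
           transitionNames = stats::setNames(tNames, tIds))
}

#' Write a PNML file
#'
#' Emits a PNML core-model document with deterministic element order
#' (places, then transitions, then arcs, each by id) so that
#' `readPNML(writePNML(net))` reproduces the net exactly.
#'
#' @param net a [PetriNet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePNML <- function(net, path) {
  doc <- xml2::xml_new_root("pnml", xmlns = .PNML_NS)
  netNode <- xml2::xml_add_child(doc, "net", id = "net0",
    type = "http://www.pnml.org/version-2009/grammar/ptnet")
  page <- xml2::xml_add_child(netNode, "page", id = "page0")
  for (p in sort(net@places)) {
    pn <- xml2::xml_add_child(page, "place", id = p)
    nm <- xml2::xml_add_child(pn, "name")
    xml2::xml_add_child(nm, "text", net@placeNames[[p]])
    if (net@marking[[p]] > 0) {
      mk <- xml2::xml_add_child(pn, "initialMarking")
      xml2::xml_add_child(mk, "text", format(net@marking[[p]]))
    }
  }
  for (tr in sort(net@transitions)) {
    tn <- xml2::xml_add_child(page, "transition", id = tr)
    nm <- xml2::xml_add_child(tn, "name")
    xml2::xml_add_child(nm, "text", net@transitionNames[[tr]])
  }
  a <- net@arcs
  if (nrow(a)) {
    a <- a[order(a$source, a$target), , drop = FALSE]
    for (k in seq_len(nrow(a))) {
      an <- xml2::xml_add_child(page, "arc",
        id = paste0("a", k), source = a$source[k], target = a$target[k])
      if (a$weight[k] != 1) {
        ins <- xml2::xml_add_child(an, "inscription")
        xml2::xml_add_child(ins, "text", format(a$weight[k]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a Snoopy .spped file
#'
#' Best-effort reader for Snoopy's XML format for discrete
#' place/transition nets: extracts node ids, display names, markings, arcs
#' and multiplicities, ignoring all graphics. Duplicated graphical copies of
#' one place ("logical places", same display name) are merged into a single
#' place with their arcs rewired; merging is idempotent and preserves the
#' incidence matrix up to row identification.
#'
#' @param path path to a `.spped` document.
#' @return a [PetriNet-class].
#' @export
readSpped <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopInput("malformed XML: ",
                                                conditionMessage(e)))
  netclass <- xml2::xml_find_first(doc, "//netclass")
  if (!inherits(netclass, "xml_missing")) {
    cls <- xml2::xml_attr(netclass, "name")
    if (!is.na(cls) && !grepl("^Petri Net", cls)) {
      stopInput("unsupported Snoopy net class: ", cls)
    }
  }
  readNodes <- function(className) {
    nodes <- xml2::xml_find_all(doc,
      sprintf("//nodeclass[@name='%s']/node", className))
    if (!length(nodes)) return(NULL)
    ids <- xml2::xml_attr(nodes, "id")
    nms <- vapply(nodes, function(n)
      .xmlText1(n, "./attribute[@name='Name']"), "")
    nms <- trimws(nms)
    nms[is.na(nms) | nms == ""] <- ids[is.na(nms) | nms == ""]
    mk <- vapply(nodes, function(n) {
      v <- trimws(.xmlText1(n, "./attribute[@name='Marking']"))
      if (is.na(v) || v == "") 0 else as.numeric(v)
    }, 0)
    data.frame(id = ids, name = nms, marking = mk, stringsAsFactors = FALSE)
  }
  pl <- readNodes("Place")
  tr <- readNodes("Transition")
  if (is.null(pl) || is.null(tr)) {
    stopInput("no Place/Transition node classes found; not a ",
              "discrete place/transition .spped document")
  }
  edges <- xml2::xml_find_all(doc, "//edgeclass[@name='Edge']/edge")
  arcsDf <- data.frame(source = character(), target = character(),
                       weight = numeric())
  if (length(edges)) {
    w <- vapply(edges, function(e) {
      v <- trimws(.xmlText1(e, "./attribute[@name='Multiplicity']"))
      if (is.na(v) || v == "") 1 else as.numeric(v)
    }, 0)
    arcsDf <- data.frame(
      source = xml2::xml_attr(edges, "source"),
      target = xml2::xml_attr(edges, "target"),
      weight = w, stringsAsFactors = FALSE)
  }
  # merge logical places: identical display name -> one canonical place
  canon <- stats::setNames(pl$id, pl$id)
  for (nm in unique(pl$name[duplicated(pl$name)])) {
    grp <- pl$id[pl$name == nm]
    canon[grp] <- grp[1]
  }
  remap <- function(v) ifelse(v %in% names(canon), canon[v], v)
  arcsDf$source <- unname(remap(arcsDf$source))
  arcsDf$target <- unname(remap(arcsDf$target))
  mk <- tapply(pl$marking, canon[pl$id], sum)
  keep <- !duplicated(canon[pl$id])
  pIds <- pl$id[keep]
  suppressWarnings(
    PetriNet(pIds, tr$id, arcsDf,
             marking = stats::setNames(as.numeric(mk[pIds]), pIds),
             placeNames = stats::setNames(pl$name[keep], pIds),
             transitionNames = stats::setNames(tr$name, tr$id))
  )
}

#' Read a CSV arc list
#'
#' Assembles a net from a CSV file with header `source,target[,weight]`.
#' Ids beginning with `p`/`P` are places, ids beginning with `t`/`T` are
#' transitions; a missing weight column defaults to 1 and duplicate rows are
#' summed with a warning.
#'
#' @param path path to the CSV file.
#' @return a [PetriNet-class].
#' @export
readCSVArclist <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stopInput("cannot read CSV: ",
                                               conditionMessage(e)))
  if (!all(c("source", "target") %in% names(df))) {
    stopInput("CSV must have header source,target[,weight]")
  }
  ids <- unique(c(df$source, df$target))
  isP <- grepl("^[pP]", ids)
  isT <- grepl("^[tT]", ids)
  amb <- ids[!(isP | isT)]
  if (length(amb)) {
    stopInput("ambiguous id prefix (must start with p/P or t/T): ",
              paste(amb, collapse = ", "))
  }
  pIds <- ids[isP]
  tIds <- ids[isT]
  bad <- (df$source %in% pIds & df$target %in% pIds) |
         (df$source %in% tIds & df$target %in% tIds)
  if (any(bad)) {
    stopInput("non-bipartite row: ", df$source[which(bad)[1]], " -> ",
              df$target[which(bad)[1]])
  }
  PetriNet(pIds, tIds, df)
}

#' Read a Petri net, dispatching on format
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"pnml"`, `"spped"` or `"csv"`.
#' @return a [PetriNet-class].
#' @export
readNet <- function(path, format = c("auto", "pnml", "spped", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pnml = "pnml", xml = "pnml", spped = "spped",
                     csv = "csv",
                     stopInput("cannot infer format from extension: .", ext))
  }
  switch(format,
         pnml = readPNML(path),
         spped = readSpped(path),
         csv = readCSVArclist(path))
}
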