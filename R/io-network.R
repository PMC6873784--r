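#' Convert a TripartiteNetwork to an igraph graph
#'
#' Undirected; node attribute \code{class}, edge attribute \code{relation}.
#'
#' @param network a [TripartiteNetwork-class].
#' @return an \code{igraph} object.
#' @export
asIgraph <- function(network) {
  stopifnot(is(network, "TripartiteNetwork"))
  igraph::graph_from_data_frame(
    d = networkEdges(network), directed = FALSE,
    vertices = networkNodes(network))
}

.networkFromIgraph <- function(g) {
  nodes <- data.frame(id = igraph::V(g)$name,
                      class = igraph::V(g)$class,
                      stringsAsFactors = FALSE)
  if (igraph::ecount(g) > 0L) {
    ends <- igraph::as_edgelist(g)
    edges <- data.frame(from = ends[, 1L], to = ends[, 2L],
                        relation = igraph::E(g)$relation,
                        stringsAsFactors = FALSE)
  } else edges <- NULL
  TripartiteNetwork(nodes, edges)
}

#' Write a network for Cytoscape and friends
#'
#' Two dialects. \code{SIF}: one edge per line as
#' \code{source<TAB>relation<TAB>target} with the fixed relation vocabulary
#' (\code{lnc_mir}, \code{mir_mrna}, \code{lnc_mrna}); isolated nodes are
#' emitted as single-column lines. \code{GraphML}: full round-trip including
#' the node \code{class} and edge \code{relation} attributes.
#'
#' @param network a [TripartiteNetwork-class].
#' @param path output path.
#' @param dialect \code{"SIF"} or \code{"GraphML"}.
#' @return invisibly, \code{path}.
#' @export
writeNetwork <- function(network, path, dialect = c("SIF", "GraphML")) {
  stopifnot(is(network, "TripartiteNetwork"))
  dialect <- match.arg(dialect)
  if (dialect == "SIF") {
    ed <- networkEdges(network)
    lines <- if (nrow(ed)) paste(ed$from, ed$relation, ed$to, sep = "\t")
             else character()
    iso <- setdiff(networkNodes(network)$id, c(ed$from, ed$to))
    writeLines(c(lines, iso), path)
  } else {
    igraph::write_graph(asIgraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [writeNetwork()]
#'
#' For SIF, node classes are inferred from the relation vocabulary and the
#' writer's endpoint order; isolated nodes (single-column lines) carry no
#' class in SIF, so they require the \code{nodeClasses} argument. GraphML
#' restores everything from its attributes.
#'
#' @param path file path.
#' @param dialect \code{"SIF"} or \code{"GraphML"}.
#' @param nodeClasses optional named character vector id -> class used to
#'   type SIF nodes that no edge explains.
#' @return a [TripartiteNetwork-class].
#' @export
readNetwork <- function(path, dialect = c("SIF", "GraphML"),
                        nodeClasses = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "GraphML")
    return(.networkFromIgraph(
      igraph::read_graph(path, format = "graphml")))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(!nf %in% c(1L, 3L)))
    stop(sprintf("line %d: SIF lines must have 1 or 3 tab-separated fields",
                 which(!nf %in% c(1L, 3L))[1L]))
  eidx <- nf == 3L
  edges <- if (any(eidx)) {
    data.frame(from = vapply(fields[eidx], `[[`, "", 1L),
               relation = vapply(fields[eidx], `[[`, "", 2L),
               to = vapply(fields[eidx], `[[`, "", 3L),
               stringsAsFactors = FALSE)
  } else data.frame(from = character(), relation = character(),
                    to = character(), stringsAsFactors = FALSE)
  bad <- setdiff(unique(edges$relation), .RELATIONS)
  if (length(bad))
    stop("unknown SIF relation(s): ", paste(bad, collapse = ", "))
  cls <- character()
  for (i in seq_len(nrow(edges))) {
    want <- .RELATION_CLASSES[[edges$relation[i]]]
    cls[edges$from[i]] <- want[1L]
    cls[edges$to[i]] <- want[2L]
  }
  iso <- unlist(fields[!eidx])
  for (id in iso) {
    if (id %in% names(cls)) next
    if (is.null(nodeClasses) || is.na(nodeClasses[id]))
      stop("SIF carries no class for isolated node '", id,
           "'; supply it via nodeClasses")
    cls[id] <- nodeClasses[[id]]
  }
  TripartiteNetwork(
    nodes = data.frame(id = names(cls), class = unname(cls),
                       stringsAsFactors = FALSE),
    edges = edges[c("from", "to", "relation")])
}
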