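#' Assemble the tripartite ceRNA network from triplets
#'
#' Nodes are the union of triplet members; each triplet contributes its
#' lncRNA-miRNA and miRNA-mRNA edges, and — when
#' \code{includeLncMrnaEdges} — its lncRNA-mRNA co-expression edge.
#' Duplicate contributions collapse, so the operation is idempotent under
#' repeated triplets.
#'
#' @param triplets a [buildTriplets()] table.
#' @param includeLncMrnaEdges also add the co-expression edges (the
#'   lncRNA-mRNA view)? Default \code{FALSE}.
#' @return a [TripartiteNetwork-class].
#' @export
assembleNetwork <- function(triplets, includeLncMrnaEdges = FALSE) {
  need <- c("lncrna_id", "mirna_id", "mrna_id")
  if (!all(need %in% colnames(triplets)))
    stop("triplets needs columns ", paste(need, collapse = ", "))
  nodes <- unique(rbind(
    data.frame(id = triplets$lncrna_id, class = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mirna_id, class = "miRNA",
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mrna_id, class = "mRNA",
               stringsAsFactors = FALSE)))
  edges <- rbind(
    data.frame(from = triplets$lncrna_id, to = triplets$mirna_id,
               relation = "lnc_mir", stringsAsFactors = FALSE),
    data.frame(from = triplets$mirna_id, to = triplets$mrna_id,
               relation = "mir_mrna", stringsAsFactors = FALSE))
  if (includeLncMrnaEdges)
    edges <- rbind(edges,
      data.frame(from = triplets$lncrna_id, to = triplets$mrna_id,
                 relation = "lnc_mrna", stringsAsFactors = FALSE))
  edges <- unique(edges)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  TripartiteNetwork(nodes, edges)
}

#' Node centrality panel
#'
#' Per node: degree (incident edge count), unnormalized Brandes betweenness
#' on the undirected graph (each unordered source-target pair counted once),
#' harmonic closeness divided by (n - 1) — robust to disconnected networks,
#' where unreachable nodes contribute 0 — and PageRank with damping 0.85,
#' uniform teleport, iterated to an L1 change below 1e-12 (so scores sum
#' to 1).
#'
#' @param network a non-empty [TripartiteNetwork-class].
#' @return data.frame with columns \code{node_id}, \code{class},
#'   \code{degree}, \code{betweenness}, \code{closeness}, \code{pagerank}.
#' @export
nodeMetrics <- function(network) {
  stopifnot(is(network, "TripartiteNetwork"))
  if (nrow(networkNodes(network)) == 0L)
    stop("cannot compute metrics on an empty network")
  g <- asIgraph(network)
  ids <- igraph::V(g)$name
  pr <- randomWalkRestart(network, seeds = ids, restart = 0.15,
                          tolerance = 1e-12, maxIter = 100000L)
  out <- data.frame(
    node_id = ids,
    class = igraph::V(g)$class,
    degree = as.integer(igraph::degree(g)),
    betweenness = as.numeric(igraph::betweenness(g, directed = FALSE)),
    closeness = if (length(ids) > 1L)
      as.numeric(igraph::harmonic_centrality(g, normalized = TRUE))
      else 0,
    pagerank = unname(probabilities(pr)[ids]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Top-k ranking per centrality dimension
#'
#' Descending ranked lists for degree, betweenness, closeness and PageRank,
#' ties broken lexicographically by node id, plus the intersection of the
#' four top-k lists — the package's working definition of hub nodes.
#'
#' @param metrics a [nodeMetrics()] table.
#' @param k list length (>= 1); when \code{k >= n} every list holds all nodes.
#' @param classFilter optionally restrict the intersection report to one
#'   node class.
#' @return list with \code{degree}, \code{betweenness}, \code{closeness},
#'   \code{pagerank} (character vectors of node ids) and \code{hubs} (the
#'   intersection, in the degree-list order).
#' @export
rankTop <- function(metrics, k = 20, classFilter = NULL) {
  if (k < 1) stop("k must be >= 1")
  dims <- c("degree", "betweenness", "closeness", "pagerank")
  ranked <- lapply(dims, function(d) {
    ord <- order(-metrics[[d]], metrics$node_id)
    utils::head(metrics$node_id[ord], k)
  })
  names(ranked) <- dims
  hubs <- Reduce(intersect, ranked)
  if (!is.null(classFilter)) {
    keep <- metrics$node_id[metrics$class %in% classFilter]
    hubs <- hubs[hubs %in% keep]
  }
  c(ranked, list(hubs = hubs))
}

#' First and secondary relationship pair counts for one lncRNA
#'
#' \code{n_first}: the lncRNA's miRNA neighbours (its lncRNA-miRNA pairs);
#' \code{n_secondary}: distinct miRNA-mRNA edges incident to those miRNAs;
#' \code{total}: their sum.
#'
#' @param network a [TripartiteNetwork-class].
#' @param lncrnaId id of a node of class lncRNA.
#' @return list with \code{lncrna_id}, \code{n_first}, \code{n_secondary},
#'   \code{total}.
#' @export
countPairs <- function(network, lncrnaId) {
  nd <- networkNodes(network); ed <- networkEdges(network)
  if (!lncrnaId %in% nd$id) stop("unknown node id: ", lncrnaId)
  if (nd$class[nd$id == lncrnaId] != "lncRNA")
    stop("node '", lncrnaId, "' is not a lncRNA")
  lm <- ed[ed$relation == "lnc_mir" & ed$from == lncrnaId, , drop = FALSE]
  mirs <- unique(lm$to)
  mm <- ed[ed$relation == "mir_mrna" & ed$from %in% mirs, , drop = FALSE]
  list(lncrna_id = lncrnaId, n_first = nrow(lm), n_secondary = nrow(mm),
       total = nrow(lm) + nrow(mm))
}

#' Extract the subnetwork anchored at one lncRNA
#'
#' The lncRNA, its miRNA neighbours, the mRNAs adjacent to those miRNAs, and
#' exactly the lnc_mir / mir_mrna edges among them (co-expression edges are
#' not carried over).
#'
#' @param network a [TripartiteNetwork-class].
#' @param lncrnaId id of a node of class lncRNA.
#' @return a [TripartiteNetwork-class].
#' @export
extractSubnetwork <- function(network, lncrnaId) {
  nd <- networkNodes(network); ed <- networkEdges(network)
  if (!lncrnaId %in% nd$id) stop("unknown node id: ", lncrnaId)
  if (nd$class[nd$id == lncrnaId] != "lncRNA")
    stop("node '", lncrnaId, "' is not a lncRNA")
  lm <- ed[ed$relation == "lnc_mir" & ed$from == lncrnaId, , drop = FALSE]
  mirs <- unique(lm$to)
  mm <- ed[ed$relation == "mir_mrna" & ed$from %in% mirs, , drop = FALSE]
  keep <- unique(c(lncrnaId, mirs, mm$to))
  TripartiteNetwork(nd[nd$id %in% keep, , drop = FALSE], rbind(lm, mm))
}
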