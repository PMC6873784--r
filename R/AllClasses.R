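#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.FEATURE_CLASSES <- c("lncRNA", "miRNA", "mRNA")
.GROUP_LEVELS <- c("case", "control")
.RELATIONS <- c("lnc_mir", "mir_mrna", "lnc_mrna")

## endpoint classes implied by each edge relation, in canonical (from, to) order
.RELATION_CLASSES <- list(
  lnc_mir  = c("lncRNA", "miRNA"),
  mir_mrna = c("miRNA", "mRNA"),
  lnc_mrna = c("lncRNA", "mRNA")
)

#' ExpressionMatrix: a single-class case/control intensity matrix
#'
#' A thin extension of \link[SummarizedExperiment]{SummarizedExperiment}
#' holding one assay (\code{"exprs"}) of intensities for features of a single
#' transcript class (lncRNA, miRNA or mRNA), with a per-sample case/control
#' group label in \code{colData} and two pieces of metadata: the feature class
#' and whether values are on the log2 scale.
#'
#' @slot featureClass one of \code{"lncRNA"}, \code{"miRNA"}, \code{"mRNA"}.
#' @slot isLog2 logical flag; \code{FALSE} means linear-scale intensities
#'   (which must then be non-negative).
#'
#' @seealso [ExpressionMatrix()] for construction, [featureClass()],
#'   [isLog2()], [sampleGroups()] for access.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  slots = c(featureClass = "character", isLog2 = "logical")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!identical(SummarizedExperiment::assayNames(object), "exprs"))
    msg <- c(msg, "assays must be a single matrix named 'exprs'")
  if (length(object@featureClass) != 1L ||
      !object@featureClass %in% .FEATURE_CLASSES)
    msg <- c(msg, sprintf("featureClass must be one of %s",
                          paste(.FEATURE_CLASSES, collapse = ", ")))
  if (length(object@isLog2) != 1L || is.na(object@isLog2))
    msg <- c(msg, "isLog2 must be TRUE or FALSE")
  ids <- rownames(object)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    msg <- c(msg, "feature ids (rownames) must be unique non-empty strings")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else {
    grp <- as.character(object$group)
    if (!all(grp %in% .GROUP_LEVELS))
      msg <- c(msg, "group labels must be 'case' or 'control'")
    else if (any(table(factor(grp, levels = .GROUP_LEVELS)) < 2L))
      msg <- c(msg, "each of the case and control groups needs >= 2 samples")
  }
  if (length(msg) == 0L) {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(v) || anyNA(v))
      msg <- c(msg, "expression values must be numeric with no missing values")
    else if (!object@isLog2 && any(v < 0))
      msg <- c(msg, "linear-scale intensities must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids).
#' @param featureClass \code{"lncRNA"}, \code{"miRNA"} or \code{"mRNA"}.
#' @param group character vector of \code{"case"}/\code{"control"} labels, one
#'   per column of \code{values} (at least two samples per group).
#' @param isLog2 are the values log2 intensities? Default \code{TRUE}.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- ExpressionMatrix(m, "mRNA", c("case", "case", "control", "control"))
#' featureClass(em)
#' @export
ExpressionMatrix <- function(values, featureClass, group, isLog2 = TRUE) {
  values <- as.matrix(values)
  se <- SummarizedExperiment(
    assays  = SimpleList(exprs = values),
    colData = DataFrame(group = as.character(group),
                        row.names = colnames(values))
  )
  new("ExpressionMatrix", se,
      featureClass = as.character(featureClass), isLog2 = isLog2)
}

setMethod("show", "ExpressionMatrix", function(object) {
  grp <- table(factor(object$group, levels = .GROUP_LEVELS))
  cat(sprintf(
    "ExpressionMatrix: %d %s features x %d samples (%d case / %d control), %s scale\n",
    nrow(object), object@featureClass, ncol(object),
    grp[["case"]], grp[["control"]],
    if (object@isLog2) "log2" else "linear"))
})

#' TripartiteNetwork: typed lncRNA/miRNA/mRNA nodes and typed edges
#'
#' An undirected graph whose nodes carry a transcript class and whose edges
#' carry a relation label from the fixed vocabulary \code{lnc_mir},
#' \code{mir_mrna}, \code{lnc_mrna}. Edges are stored in a canonical endpoint
#' order (lncRNA before miRNA/mRNA, miRNA before mRNA) so equality and
#' deduplication are well defined. Regulatory direction lives in the relation
#' label, not in arc direction.
#'
#' @slot nodes data.frame with columns \code{id}, \code{class}.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{relation}.
#' @seealso [assembleNetwork()], [nodeMetrics()], [writeNetwork()]
#' @export
setClass("TripartiteNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame"))

setValidity("TripartiteNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  msg <- character()
  if (!all(c("id", "class") %in% colnames(nd)))
    return("nodes needs columns 'id' and 'class'")
  if (!all(c("from", "to", "relation") %in% colnames(ed)))
    return("edges needs columns 'from', 'to' and 'relation'")
  if (anyDuplicated(nd$id)) msg <- c(msg, "duplicate node ids")
  if (!all(nd$class %in% .FEATURE_CLASSES))
    msg <- c(msg, "node classes must be lncRNA/miRNA/mRNA")
  if (!all(ed$relation %in% .RELATIONS))
    msg <- c(msg, sprintf("edge relations must be in {%s}",
                          paste(.RELATIONS, collapse = ", ")))
  if (!all(c(ed$from, ed$to) %in% nd$id))
    msg <- c(msg, "edge endpoint not in node set")
  if (any(ed$from == ed$to)) msg <- c(msg, "self-loops are not allowed")
  if (anyDuplicated(paste(ed$from, ed$to, ed$relation)))
    msg <- c(msg, "duplicate edges")
  if (length(msg) == 0L && nrow(ed) > 0L) {
    cls <- stats::setNames(nd$class, nd$id)
    want <- .RELATION_CLASSES[ed$relation]
    ok <- mapply(function(f, t, w) cls[[f]] == w[1L] && cls[[t]] == w[2L],
                 ed$from, ed$to, want)
    if (!all(ok))
      msg <- c(msg, "edge relation inconsistent with endpoint classes/order")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TripartiteNetwork
#'
#' Endpoints of each edge are put into canonical order for their relation
#' (e.g. the lncRNA first for \code{lnc_mir}); duplicate edges after
#' canonicalisation are an error.
#'
#' @param nodes data.frame with columns \code{id}, \code{class}.
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{relation}; may have zero rows.
#' @return a [TripartiteNetwork-class].
#' @export
TripartiteNetwork <- function(nodes, edges = NULL) {
  nodes <- data.frame(id = as.character(nodes$id),
                      class = as.character(nodes$class),
                      stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        relation = character(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        relation = as.character(edges$relation),
                        stringsAsFactors = FALSE)
    cls <- stats::setNames(nodes$class, nodes$id)
    for (i in seq_len(nrow(edges))) {
      want <- .RELATION_CLASSES[[edges$relation[i]]]
      if (is.null(want))
        stop("unknown edge relation: ", edges$relation[i])
      if (identical(unname(cls[edges$from[i]]), want[2L]) &&
          identical(unname(cls[edges$to[i]]), want[1L])) {
        tmp <- edges$from[i]; edges$from[i] <- edges$to[i]; edges$to[i] <- tmp
      }
    }
    rownames(edges) <- NULL
  }
  new("TripartiteNetwork", nodes = nodes, edges = edges)
}

setMethod("show", "TripartiteNetwork", function(object) {
  tab <- table(factor(object@nodes$class, levels = .FEATURE_CLASSES))
  cat(sprintf(
    "TripartiteNetwork: %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges\n",
    nrow(object@nodes), tab[["lncRNA"]], tab[["miRNA"]], tab[["mRNA"]],
    nrow(object@edges)))
  if (nrow(object@edges)) {
    et <- table(factor(object@edges$relation, levels = .RELATIONS))
    cat(sprintf("  edge relations: %s\n",
                paste(sprintf("%s=%d", names(et), et), collapse = ", ")))
  }
})

#' SyntheticSpec: parameters of the planted-triplet simulator
#'
#' Describes a case/control three-class expression study with known ceRNA
#' ground truth: a set of planted lncRNA--miRNA--mRNA triplets in which the
#' lncRNA and mRNA share a latent signal (and a case-group shift) while the
#' miRNA carries its negation.
#'
#' @slot nCase,nControl samples per group (>= 2).
#' @slot nLnc,nMir,nMrna feature counts per class (>= 1).
#' @slot plantedTriplets data.frame with columns \code{lncrna_id},
#'   \code{mirna_id}, \code{mrna_id}, \code{effect} (log2 case-group shift > 0).
#' @slot latentSd standard deviation (log2) of the per-sample latent signal
#'   shared within a triplet.
#' @slot backgroundNoiseSd per-feature measurement noise sd (log2, >= 0).
#' @slot baselineMean baseline log2 intensity.
#' @slot decoyRatio decoy:true ratio for expression-unsupported interaction
#'   pairs emitted alongside the planted ones.
#' @slot seed integer RNG seed; identical specs reproduce identical datasets.
#' @slot allowSharedFeatures may a feature sit in two planted triplets?
#' @seealso [SyntheticSpec()], [simulateDataset()]
#' @export
setClass("SyntheticSpec",
  slots = c(nCase = "integer", nControl = "integer",
            nLnc = "integer", nMir = "integer", nMrna = "integer",
            plantedTriplets = "data.frame",
            latentSd = "numeric", backgroundNoiseSd = "numeric",
            baselineMean = "numeric", decoyRatio = "numeric",
            seed = "integer", allowSharedFeatures = "logical"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nCase < 2L) msg <- c(msg, "nCase must be >= 2")
  if (object@nControl < 2L) msg <- c(msg, "nControl must be >= 2")
  for (f in c("nLnc", "nMir", "nMrna"))
    if (slot(object, f) < 1L) msg <- c(msg, sprintf("%s must be >= 1", f))
  if (object@backgroundNoiseSd < 0)
    msg <- c(msg, "backgroundNoiseSd must be >= 0")
  if (object@latentSd < 0) msg <- c(msg, "latentSd must be >= 0")
  if (object@decoyRatio < 0) msg <- c(msg, "decoyRatio must be >= 0")
  pt <- object@plantedTriplets
  need <- c("lncrna_id", "mirna_id", "mrna_id", "effect")
  if (!all(need %in% colnames(pt)))
    return(c(msg, sprintf("plantedTriplets needs columns %s",
                          paste(need, collapse = ", "))))
  if (nrow(pt)) {
    ids <- .syntheticFeatureIds(object)
    for (col in c("lncrna_id", "mirna_id", "mrna_id")) {
      pool <- switch(col, lncrna_id = ids$lncRNA, mirna_id = ids$miRNA,
                     mrna_id = ids$mRNA)
      bad <- setdiff(pt[[col]], pool)
      if (length(bad))
        msg <- c(msg, sprintf("plantedTriplets$%s references unknown id(s): %s",
                              col, paste(bad, collapse = ", ")))
    }
    if (any(pt$effect <= 0))
      msg <- c(msg, "plantedTriplets$effect must be > 0 (log2 scale)")
    if (!object@allowSharedFeatures) {
      shared <- c(pt$lncrna_id[duplicated(pt$lncrna_id)],
                  pt$mirna_id[duplicated(pt$mirna_id)],
                  pt$mrna_id[duplicated(pt$mrna_id)])
      if (length(shared))
        msg <- c(msg, sprintf(
          "feature(s) %s appear in more than one planted triplet (set allowSharedFeatures = TRUE to permit)",
          paste(unique(shared), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d case / %d control samples; %d lncRNA, %d miRNA, %d mRNA features\n",
    object@nCase, object@nControl, object@nLnc, object@nMir, object@nMrna))
  cat(sprintf("  %d planted triplet(s); latent sd %.3g, noise sd %.3g, baseline %.3g log2; seed %d\n",
              nrow(object@plantedTriplets), object@latentSd,
              object@backgroundNoiseSd, object@baselineMean, object@seed))
})

#' SyntheticDataset: simulator output with ground truth
#'
#' @slot lncrna,mirna,mrna one [ExpressionMatrix-class] per class (log2 scale).
#' @slot interactions candidate miRNA->target table: planted true pairs plus
#'   expression-unsupported decoys (column \code{source} distinguishes them).
#' @slot truth the planted triplet table.
#' @slot spec the generating [SyntheticSpec-class].
#' @export
setClass("SyntheticDataset",
  slots = c(lncrna = "ExpressionMatrix", mirna = "ExpressionMatrix",
            mrna = "ExpressionMatrix", interactions = "data.frame",
            truth = "data.frame", spec = "SyntheticSpec"))

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset with planted ceRNA triplets\n")
  show(object@spec)
  cat(sprintf("  interaction table: %d pairs (%d true, %d decoy)\n",
              nrow(object@interactions),
              sum(object@interactions$source == "planted"),
              sum(object@interactions$source == "decoy")))
})

#' RWRProfile: the stationary profile of a random walk with restart
#'
#' @slot probabilities per-node visiting probabilities (named, sum to 1).
#' @slot seeds seed node ids.
#' @slot restart restart probability in (0, 1].
#' @slot tolerance L1 convergence tolerance.
#' @slot iterations power-iteration steps used.
#' @slot residual final L1 change.
#' @seealso [randomWalkRestart()]
#' @export
setClass("RWRProfile",
  slots = c(probabilities = "numeric", seeds = "character",
            restart = "numeric", tolerance = "numeric",
            iterations = "integer", residual = "numeric"))

setValidity("RWRProfile", function(object) {
  p <- object@probabilities
  msg <- character()
  if (is.null(names(p))) msg <- c(msg, "probabilities must be named by node id")
  if (any(p < 0)) msg <- c(msg, "probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) msg <- c(msg, "probabilities must sum to 1")
  if (length(object@seeds) == 0L) msg <- c(msg, "seed set must be non-empty")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RWRProfile", function(object) {
  cat(sprintf(
    "RWRProfile: %d nodes, %d seed(s), restart %.2f; converged in %d iterations (L1 residual %.2e)\n",
    length(object@probabilities), length(object@seeds), object@restart,
    object@iterations, object@residual))
  top <- utils::head(sort(object@probabilities, decreasing = TRUE), 5L)
  cat("  top nodes:", paste(sprintf("%s=%.4f", names(top), top),
                            collapse = ", "), "\n")
})
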