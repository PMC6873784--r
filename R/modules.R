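#' Bidirectional hierarchical clustering into co-expression modules
#'
#' Agglomerative clustering run independently on the rows and on the columns
#' of an expression (or correlation) matrix, cut into modules. The default
#' distance is 1 - Pearson correlation with average linkage — the
#' combination that groups features by co-expression pattern rather than by
#' absolute intensity; Euclidean distance and the other
#' \code{\link[stats]{hclust}} linkages are available. Constant rows/columns
#' are dropped with a warning (their correlation distance is undefined).
#'
#' @param x numeric matrix with dimnames, or an [ExpressionMatrix-class]
#'   (log2 values are used).
#' @param distance \code{"correlation"} (1 - Pearson, default) or
#'   \code{"euclidean"}.
#' @param linkage \code{\link[stats]{hclust}} method; default
#'   \code{"average"}.
#' @param k number of modules to cut into (default 2); ignored when \code{h}
#'   is given.
#' @param h alternatively, a cut height.
#' @return list with \code{rows} and \code{cols}, each a list holding
#'   \code{labels} (named module indices, contiguous from 1), \code{n_modules},
#'   \code{hclust}, and the \code{linkage}/\code{distance}/\code{cut} tags.
#' @examples
#' m <- rbind(matrix(rep(1:6, each = 3), 3, 6, byrow = FALSE),
#'            matrix(rep(6:1, each = 3), 3, 6, byrow = FALSE)) +
#'      matrix(rnorm(36, sd = .01), 6)
#' dimnames(m) <- list(paste0("f", 1:6), paste0("s", 1:6))
#' bicluster(m, k = 2)$rows$labels
#' @export
bicluster <- function(x, distance = c("correlation", "euclidean"),
                      linkage = "average", k = 2, h = NULL) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage, c("average", "complete", "single",
                                  "ward.D2", "ward.D", "mcquitty"))
  if (is(x, "ExpressionMatrix"))
    x <- .exprOnScale(x, log2scale = TRUE)
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 rows and 2 columns")
  oneAxis <- function(m, axis) {
    if (distance == "correlation") m <- .dropConstantRows(m, axis)
    if (nrow(m) < 2L)
      stop("fewer than 2 non-constant ", axis, "s left to cluster")
    d <- if (distance == "correlation")
      stats::as.dist(1 - stats::cor(t(m)))
    else stats::dist(m)
    hc <- stats::hclust(d, method = linkage)
    if (is.null(h)) {
      if (k > nrow(m)) stop("k exceeds the number of ", axis, " leaves")
      labels <- stats::cutree(hc, k = k)
    } else {
      labels <- stats::cutree(hc, h = h)
    }
    list(labels = labels, n_modules = length(unique(labels)), hclust = hc,
         linkage = linkage, distance = distance,
         cut = if (is.null(h)) list(k = k) else list(h = h))
  }
  list(rows = oneAxis(x, "feature_row"), cols = oneAxis(t(x), "feature_col"))
}

#' Plot the biclustered heatmap
#'
#' Basic heatmap of the matrix reordered by the row and column dendrograms
#' from [bicluster()].
#'
#' @param x the matrix that was clustered.
#' @param clustering a [bicluster()] result for \code{x}.
#' @param ... passed to \code{\link[stats]{heatmap}}.
#' @return invisibly, \code{NULL}.
#' @export
plotModuleHeatmap <- function(x, clustering, ...) {
  if (is(x, "ExpressionMatrix")) x <- .exprOnScale(x, TRUE)
  x <- as.matrix(x)
  x <- x[names(clustering$rows$labels), names(clustering$cols$labels),
         drop = FALSE]
  stats::heatmap(x, Rowv = stats::as.dendrogram(clustering$rows$hclust),
                 Colv = stats::as.dendrogram(clustering$cols$hclust), ...)
  invisible(NULL)
}

#' Hypergeometric gene-set enrichment
#'
#' One test per annotation set: the hypergeometric upper-tail probability of
#' an overlap at least as large as observed between the query and the set
#' (both restricted to the universe), with Benjamini-Hochberg adjustment
#' across all sets tested. Results are sorted by ascending p.
#'
#' @param query character vector of ids, must lie within \code{universe}.
#' @param annotationSets named list of character vectors (e.g. from
#'   [readGmt()]); each is intersected with the universe before testing.
#' @param universe character vector defining the tested id universe.
#' @return data.frame with columns \code{set_id}, \code{overlap},
#'   \code{set_size}, \code{query_size}, \code{universe_size}, \code{p_value},
#'   \code{q_value}.
#' @examples
#' enrichSets(letters[1:5], list(s = letters[1:5]), letters[1:10])  # p = 1/252
#' @export
enrichSets <- function(query, annotationSets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  query <- unique(query)
  out <- setdiff(query, universe)
  if (length(out))
    stop("query id(s) outside the universe: ",
         paste(utils::head(out, 5L), collapse = ", "))
  if (is.null(names(annotationSets)) || any(!nzchar(names(annotationSets))))
    stop("annotationSets must be a named list")
  res <- lapply(names(annotationSets), function(nm) {
    set <- intersect(unique(annotationSets[[nm]]), universe)
    ov <- length(intersect(query, set))
    p <- stats::phyper(ov - 1L, length(set), length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set_id = nm, overlap = ov, set_size = length(set),
               query_size = length(query), universe_size = length(universe),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_value <- stats::p.adjust(res$p_value, "BH")
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read GMT-style annotation sets
#'
#' Each tab-separated line: set id, description, then member ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions in
#'   \code{attr(, "description")}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop(sprintf("line %d: GMT lines need id, description and >= 1 member",
                 which(short)[1L]))
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicated set id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), ids)
  sets
}
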