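#' Random walk with restart over the ceRNA network
#'
#' Deterministic power iteration of
#' \code{p <- (1 - r) * W %*% p + r * p0}, where \code{W} is the
#' column-normalized (optionally weighted) adjacency matrix and \code{p0} is
#' uniform over the seed nodes. Mass on dangling (degree-0) nodes is
#' redistributed to \code{p0} each step, so the profile stays a probability
#' vector on every iteration. Iteration starts at \code{p0} and stops when
#' the L1 change drops below \code{tolerance}; within that tolerance the
#' fixed point does not depend on the start.
#'
#' @param network a [TripartiteNetwork-class].
#' @param seeds non-empty character vector of existing node ids.
#' @param restart restart probability r in (0, 1]; \code{restart = 1} returns
#'   \code{p0} itself. Default 0.7, a common choice for network-medicine
#'   prioritisation.
#' @param tolerance L1 convergence tolerance (> 0).
#' @param maxIter iteration cap; exceeding it without converging is an error
#'   that reports the last residual.
#' @param weights optional non-negative edge weights, one per row of
#'   \code{networkEdges(network)} (e.g. |r| of the supporting correlation);
#'   default unweighted.
#' @return an [RWRProfile-class].
#' @examples
#' tn <- TripartiteNetwork(
#'   nodes = data.frame(id = c("L", "m", "g"),
#'                      class = c("lncRNA", "miRNA", "mRNA")),
#'   edges = data.frame(from = c("L", "m"), to = c("m", "g"),
#'                      relation = c("lnc_mir", "mir_mrna")))
#' randomWalkRestart(tn, seeds = "L")
#' @export
randomWalkRestart <- function(network, seeds, restart = 0.7,
                              tolerance = 1e-10, maxIter = 1000L,
                              weights = NULL) {
  stopifnot(is(network, "TripartiteNetwork"))
  ids <- networkNodes(network)$id
  if (length(seeds) == 0L) stop("seed set must be non-empty")
  bad <- setdiff(seeds, ids)
  if (length(bad)) stop("seed node(s) not in network: ",
                        paste(bad, collapse = ", "))
  if (restart <= 0 || restart > 1) stop("restart must be in (0, 1]")
  if (tolerance <= 0) stop("tolerance must be > 0")

  ed <- networkEdges(network)
  nn <- length(ids)
  A <- matrix(0, nn, nn, dimnames = list(ids, ids))
  if (nrow(ed)) {
    w <- if (is.null(weights)) rep(1, nrow(ed)) else as.numeric(weights)
    if (length(w) != nrow(ed)) stop("weights must match the edge count")
    if (any(w < 0)) stop("weights must be non-negative")
    for (i in seq_len(nrow(ed))) {
      A[ed$from[i], ed$to[i]] <- A[ed$from[i], ed$to[i]] + w[i]
      A[ed$to[i], ed$from[i]] <- A[ed$to[i], ed$from[i]] + w[i]
    }
  }
  colSum <- colSums(A)
  dangling <- colSum == 0
  W <- A
  W[, !dangling] <- sweep(A[, !dangling, drop = FALSE], 2L,
                          colSum[!dangling], "/")

  p0 <- stats::setNames(numeric(nn), ids)
  p0[unique(seeds)] <- 1 / length(unique(seeds))
  p <- p0
  iter <- 0L
  residual <- Inf
  while (iter < maxIter) {
    iter <- iter + 1L
    pNext <- (1 - restart) * (as.vector(W %*% p) + sum(p[dangling]) * p0) +
             restart * p0
    residual <- sum(abs(pNext - p))
    p <- stats::setNames(pNext, ids)
    if (residual < tolerance) break
  }
  if (residual >= tolerance)
    stop(sprintf(
      "random walk did not converge in %d iterations (last L1 residual %.3e)",
      maxIter, residual))
  new("RWRProfile", probabilities = p / sum(p), seeds = unique(seeds),
      restart = restart, tolerance = tolerance, iterations = iter,
      residual = residual)
}
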