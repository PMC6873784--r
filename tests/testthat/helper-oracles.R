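## Independent brute-force references used to cross-check the package's
## implementations. Deliberately naive: plain string scans, BFS distance
## tables, combinatorial path counting and dense linear solves.

## ---- sequence oracle -------------------------------------------------------

oracle_revcomp <- function(s) {
  comp <- chartr("ACGT", "TGCA", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

## all-offset naive scan for canonical seed sites (0-based starts)
oracle_seed_scan <- function(mirna, target) {
  mir <- chartr("U", "T", toupper(mirna))
  tgt <- chartr("U", "T", toupper(target))
  core <- oracle_revcomp(substr(mir, 2, 7))
  m8c <- chartr("ACGT", "TGCA", substr(mir, 8, 8))
  out <- data.frame(start = integer(), site_length = integer(),
                    match_type = character(), stringsAsFactors = FALSE)
  for (i in seq_len(max(0L, nchar(tgt) - 5L))) { # 1-based core start
    if (substr(tgt, i, i + 5) != core) next
    m8 <- i > 1 && substr(tgt, i - 1, i - 1) == m8c
    a1 <- i + 6 <= nchar(tgt) && substr(tgt, i + 6, i + 6) == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8"
            else if (a1) "7mer-A1" else "6mer"
    start0 <- if (m8) i - 2L else i - 1L
    out <- rbind(out, data.frame(
      start = start0, site_length = 6L + m8 + a1, match_type = type,
      stringsAsFactors = FALSE))
  }
  out[order(out$start, out$match_type), , drop = FALSE]
}

random_rna <- function(len, alphabet = c("A", "C", "G", "U"))
  paste(sample(alphabet, len, replace = TRUE), collapse = "")

## ---- graph oracles ---------------------------------------------------------

## adjacency matrix (0/1, named) of a TripartiteNetwork
adjacency_of <- function(net) {
  ids <- networkNodes(net)$id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ed <- networkEdges(net)
  for (i in seq_len(nrow(ed))) {
    A[ed$from[i], ed$to[i]] <- 1
    A[ed$to[i], ed$from[i]] <- 1
  }
  A
}

## BFS single-source distances on an adjacency matrix
oracle_bfs <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      nb <- which(A[u, ] > 0)
      new <- nb[is.infinite(d[nb])]
      d[new] <- d[u] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

oracle_distances <- function(A)
  t(vapply(seq_len(nrow(A)), function(s) oracle_bfs(A, s),
           numeric(nrow(A))))

## shortest-path counts sigma[s, t] via DP over distance layers
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(D[s, ]))
    for (v in reach[order(D[s, reach])]) {
      if (v == s) next
      pred <- which(A[, v] > 0 & D[s, ] == D[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  sigma
}

## unnormalized betweenness, each unordered pair counted once
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sigma <- oracle_path_counts(A, D)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  stats::setNames(b, rownames(A))
}

oracle_harmonic_closeness <- function(A) {
  D <- oracle_distances(A)
  n <- nrow(A)
  if (n == 1) return(stats::setNames(0, rownames(A)))
  stats::setNames(vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    sum(1 / d[is.finite(d)]) / (n - 1)
  }, numeric(1)), rownames(A))
}

## dense linear solve for the damped walk; dangling columns jump to p0
oracle_walk_solve <- function(A, p0, damping) {
  n <- nrow(A)
  cs <- colSums(A)
  W <- A
  for (j in seq_len(n)) W[, j] <- if (cs[j] > 0) A[, j] / cs[j] else p0
  p <- solve(diag(n) - damping * W, (1 - damping) * p0)
  stats::setNames(as.vector(p), rownames(A))
}

oracle_pagerank <- function(A, damping = 0.85)
  oracle_walk_solve(A, rep(1 / nrow(A), nrow(A)), damping)

oracle_rwr <- function(A, seeds, restart) {
  p0 <- stats::setNames(rep(0, nrow(A)), rownames(A))
  p0[seeds] <- 1 / length(seeds)
  oracle_walk_solve(A, as.vector(p0), 1 - restart)
}

## random valid tripartite network on <= nMax nodes
random_network <- function(nMax = 12, edgeProb = 0.35) {
  n <- sample(2:nMax, 1)
  classes <- sample(c("lncRNA", "miRNA", "mRNA"), n, replace = TRUE)
  ids <- sprintf("N%02d", seq_len(n))
  nodes <- data.frame(id = ids, class = classes, stringsAsFactors = FALSE)
  rel <- function(a, b) {
    key <- paste(sort(c(classes[a], classes[b])), collapse = "+")
    switch(key, "lncRNA+miRNA" = "lnc_mir", "mRNA+miRNA" = "mir_mrna",
           "lncRNA+mRNA" = "lnc_mrna", NA_character_)
  }
  edges <- NULL
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    r <- rel(a, b)
    if (!is.na(r) && stats::runif(1) < edgeProb)
      edges <- rbind(edges, data.frame(from = ids[a], to = ids[b],
                                       relation = r,
                                       stringsAsFactors = FALSE))
  }
  TripartiteNetwork(nodes, edges)
}
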