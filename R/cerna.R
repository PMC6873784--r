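#' Pearson correlation with the t-transform p-value
#'
#' Textbook Pearson r between two profiles and the two-sided p-value from
#' \code{t = r * sqrt((n - 2) / (1 - r^2))} with \code{n - 2} degrees of
#' freedom; \code{r = +/-1} yields p = 0.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with \code{r}, \code{p_value}, \code{n}.
#' @examples
#' pearsonTest(1:5, c(2, 1, 4, 3, 6))
#' @export
pearsonTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired samples")
  if (stats::var(x) == 0)
    stop("constant profile: ", deparse(substitute(x)))
  if (stats::var(y) == 0)
    stop("constant profile: ", deparse(substitute(y)))
  r <- stats::cor(x, y)
  list(r = r, p_value = .pearsonPValue(r, length(x)), n = length(x))
}

.deIds <- function(de) {
  if (is.null(de)) return(NULL)
  if (is.data.frame(de)) de$feature_id[de$passes] else as.character(de)
}

#' Select strongly positively co-expressed lncRNA-mRNA pairs
#'
#' Tests every combination of the given (typically differentially expressed)
#' lncRNAs and mRNAs and keeps pairs with Pearson r above \code{pccThreshold}
#' and p below \code{pThreshold} — the stringent co-expression screen that
#' seeds ceRNA triplet construction. Correlations pool case and control
#' samples; profiles are taken on the log2 scale by default. Constant
#' features are dropped with a warning.
#'
#' @param lnc,mrna sample-aligned [ExpressionMatrix-class] objects of class
#'   lncRNA and mRNA.
#' @param deLnc,deMrna restriction of the tested features: a [selectDE()]
#'   table (its passing features are used), a character vector of ids, or
#'   \code{NULL} for all features.
#' @param pccThreshold retain pairs with r strictly above this (default 0.99).
#' @param pThreshold and p strictly below this (default 0.05).
#' @param useLog2 correlate log2 (default) or linear intensities.
#' @return data.frame \code{lncrna_id}, \code{mrna_id}, \code{r},
#'   \code{p_value}, \code{n}, sorted by descending r (ties lexicographic).
#' @export
selectLncMrnaPairs <- function(lnc, mrna, deLnc = NULL, deMrna = NULL,
                               pccThreshold = 0.99, pThreshold = 0.05,
                               useLog2 = TRUE) {
  stopifnot(is(lnc, "ExpressionMatrix"), is(mrna, "ExpressionMatrix"))
  .checkSampleAlignment(lnc, mrna)
  L <- .exprOnScale(lnc, useLog2)
  M <- .exprOnScale(mrna, useLog2)
  keepL <- .deIds(deLnc) %||% rownames(L)
  keepM <- .deIds(deMrna) %||% rownames(M)
  L <- .dropConstantRows(L[intersect(keepL, rownames(L)), , drop = FALSE],
                         "lncRNA")
  M <- .dropConstantRows(M[intersect(keepM, rownames(M)), , drop = FALSE],
                         "mRNA")
  empty <- data.frame(lncrna_id = character(), mrna_id = character(),
                      r = numeric(), p_value = numeric(), n = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(L) || !nrow(M)) return(empty)
  n <- ncol(L)
  R <- stats::cor(t(L), t(M))
  hit <- which(R > pccThreshold, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- data.frame(lncrna_id = rownames(R)[hit[, 1L]],
                    mrna_id = colnames(R)[hit[, 2L]],
                    r = R[hit], stringsAsFactors = FALSE)
  out$p_value <- .pearsonPValue(out$r, n)
  out$n <- n
  out <- out[out$p_value < pThreshold, , drop = FALSE]
  out <- out[order(-out$r, out$lncrna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared-miRNA ceRNA score
#'
#' For one lncRNA-mRNA pair: the number of miRNAs predicted to target both,
#' and the hypergeometric upper-tail probability of observing at least that
#' overlap between the two target sets drawn from the miRNA universe. This
#' overlap score is this package's explicit stand-in for a "ceRNA score";
#' outputs label it as such.
#'
#' @param lncTargets,mrnaTargets character vectors: miRNAs targeting the
#'   lncRNA resp. the mRNA.
#' @param universe size of the miRNA universe (>= both set sizes).
#' @return list with \code{shared} and \code{p_hyper}.
#' @examples
#' sharedMiRNAScore(c("m1","m2","m3"), c("m2","m3","m4"), 11)  # 2, 25/165
#' @export
sharedMiRNAScore <- function(lncTargets, mrnaTargets, universe) {
  a <- unique(lncTargets); b <- unique(mrnaTargets)
  if (length(a) > universe || length(b) > universe)
    stop("target set larger than the miRNA universe")
  shared <- length(intersect(a, b))
  p <- stats::phyper(shared - 1L, length(a), universe - length(a),
                     length(b), lower.tail = FALSE)
  list(shared = shared, p_hyper = p)
}

#' Assemble co-expression competing triplets
#'
#' For each retained lncRNA-mRNA pair, every miRNA that (a) is a predicted
#' target partner of both members in the interaction table and (b) is
#' negatively co-expressed with both (r below \code{negThreshold} with p
#' below \code{pThreshold} on each side) yields one lncRNA-miRNA-mRNA
#' "co-expression competing triplet". Interaction support is required even
#' when the correlations would pass. miRNAs present in the interaction table
#' but absent from the expression matrix are skipped with a warning and
#' reported in the \code{"skipped"} attribute.
#'
#' @param pairs output of [selectLncMrnaPairs()].
#' @param interactions interaction pair table covering both target classes.
#' @param mirna,lnc,mrna sample-aligned [ExpressionMatrix-class] objects.
#' @param negThreshold anticorrelation cutoff; default 0 (any r < 0), since
#'   "negatively co-expressed" fixes a sign, not a magnitude.
#' @param pThreshold p cutoff for both anticorrelations (default 0.05).
#' @param useLog2 correlate log2 (default) or linear intensities.
#' @return data.frame, one row per triplet, with all six correlation
#'   statistics, the shared-miRNA count and the hypergeometric ceRNA score;
#'   deterministic lexicographic order; attribute \code{"skipped"} lists
#'   dropped miRNA ids.
#' @export
buildTriplets <- function(pairs, interactions, mirna, lnc, mrna,
                          negThreshold = 0, pThreshold = 0.05,
                          useLog2 = TRUE) {
  stopifnot(is(mirna, "ExpressionMatrix"))
  .checkSampleAlignment(mirna, lnc)
  .checkSampleAlignment(mirna, mrna)
  interactions <- .validateInteractions(interactions)

  empty <- data.frame(
    lncrna_id = character(), mirna_id = character(), mrna_id = character(),
    lnc_mrna_r = numeric(), lnc_mrna_p = numeric(),
    mir_lnc_r = numeric(), mir_lnc_p = numeric(),
    mir_mrna_r = numeric(), mir_mrna_p = numeric(),
    n_shared_mirna = integer(), cerna_score = numeric(),
    stringsAsFactors = FALSE)

  known <- rownames(mirna)
  skipped <- setdiff(unique(interactions$mirna_id), known)
  if (length(skipped))
    warning(sprintf(
      "skipping %d miRNA id(s) in the interaction table with no expression profile: %s",
      length(skipped), paste(utils::head(skipped, 5L), collapse = ", ")),
      call. = FALSE)
  interactions <- interactions[interactions$mirna_id %in% known, ,
                               drop = FALSE]
  if (!nrow(pairs) || !nrow(interactions)) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }

  byTarget <- split(interactions$mirna_id, interactions$target_id)
  Mi <- .dropConstantRows(.exprOnScale(mirna, useLog2), "miRNA")
  L <- .exprOnScale(lnc, useLog2)
  G <- .exprOnScale(mrna, useLog2)
  n <- ncol(Mi)
  universe <- nrow(mirna)

  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$lncrna_id[i]; g <- pairs$mrna_id[i]
    tl <- byTarget[[l]] %||% character()
    tg <- byTarget[[g]] %||% character()
    cand <- intersect(intersect(tl, tg), rownames(Mi))
    score <- sharedMiRNAScore(tl, tg, universe)
    for (m in sort(cand)) {
      rml <- suppressWarnings(stats::cor(Mi[m, ], L[l, ]))
      rmg <- suppressWarnings(stats::cor(Mi[m, ], G[g, ]))
      if (is.na(rml) || is.na(rmg)) next  # constant profile slipped through
      pml <- .pearsonPValue(rml, n)
      pmg <- .pearsonPValue(rmg, n)
      if (rml < negThreshold && pml < pThreshold &&
          rmg < negThreshold && pmg < pThreshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          lncrna_id = l, mirna_id = m, mrna_id = g,
          lnc_mrna_r = pairs$r[i], lnc_mrna_p = pairs$p_value[i],
          mir_lnc_r = rml, mir_lnc_p = pml,
          mir_mrna_r = rmg, mir_mrna_p = pmg,
          n_shared_mirna = score$shared, cerna_score = score$p_hyper,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$lncrna_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
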