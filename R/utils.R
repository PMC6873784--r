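## internal helpers shared across modules

## run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## feature id vocabulary used by the synthetic generator
.syntheticFeatureIds <- function(spec) {
  list(lncRNA = sprintf("LNC%04d", seq_len(spec@nLnc)),
       miRNA  = sprintf("MIR%04d", seq_len(spec@nMir)),
       mRNA   = sprintf("MRNA%04d", seq_len(spec@nMrna)))
}

#' Convert an ExpressionMatrix between log2 and linear scale
#'
#' @param x an [ExpressionMatrix-class].
#' @return `x` on the requested scale (no-op when already there).
#' @export
linearScale <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (!isLog2(x)) return(x)
  ExpressionMatrix(2 ^ SummarizedExperiment::assay(x, "exprs"),
                   featureClass(x), sampleGroups(x), isLog2 = FALSE)
}

#' @rdname linearScale
#' @export
log2Scale <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (isLog2(x)) return(x)
  v <- SummarizedExperiment::assay(x, "exprs")
  if (any(v <= 0))
    stop("cannot log2-transform non-positive intensities")
  ExpressionMatrix(log2(v), featureClass(x), sampleGroups(x), isLog2 = TRUE)
}

## values on the scale correlations/t-tests are run on
.exprOnScale <- function(x, log2scale = TRUE) {
  x <- if (log2scale) log2Scale(x) else linearScale(x)
  SummarizedExperiment::assay(x, "exprs")
}

## two-sided p-value for a Pearson r at sample size n via the t transform
.pearsonPValue <- function(r, n) {
  p <- numeric(length(r))
  exact <- abs(r) >= 1 - 1e-15
  p[exact] <- 0
  t <- r[!exact] * sqrt((n - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * stats::pt(-abs(t), df = n - 2)
  p
}

## drop rows with zero variance, warning with their ids
.dropConstantRows <- function(m, what = "feature") {
  v <- apply(m, 1L, stats::var)
  const <- v <= 0 | !is.finite(v)
  if (any(const)) {
    warning(sprintf("dropping %d constant %s(s) before correlation: %s",
                    sum(const), what,
                    paste(utils::head(rownames(m)[const], 5L), collapse = ", ")),
            call. = FALSE)
    m <- m[!const, , drop = FALSE]
  }
  m
}

## assert two ExpressionMatrix objects share the same samples in the same order
.checkSampleAlignment <- function(a, b) {
  if (!identical(colnames(a), colnames(b)))
    stop("expression matrices are not sample-aligned: ",
         "sample ids (or their order) differ")
  if (!identical(unname(sampleGroups(a)), unname(sampleGroups(b))))
    stop("expression matrices disagree on case/control group labels")
  invisible(TRUE)
}
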