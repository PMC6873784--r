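#' Describe a planted-triplet simulation
#'
#' Builds a [SyntheticSpec-class] for the generator. The simulated study
#' mirrors a small case/control microarray design: three feature classes
#' measured on the same samples, log2-scale intensities around a common
#' baseline, a minority of features carrying large case-group fold changes,
#' and a set of planted ceRNA triplets in which the lncRNA and mRNA are
#' positively correlated while both are anticorrelated with a shared miRNA.
#'
#' Planted triplets can be given explicitly via \code{plantedTriplets}
#' (columns \code{lncrna_id}, \code{mirna_id}, \code{mrna_id}, \code{effect})
#' or implicitly via \code{nPlanted}, which assigns the first \code{nPlanted}
#' features of each class with a common \code{effect}. Feature ids follow the
#' generator's vocabulary \code{LNC0001...}, \code{MIR0001...},
#' \code{MRNA0001...}.
#'
#' @param nCase,nControl samples per group (>= 2); defaults mirror a
#'   three-vs-three array design.
#' @param nLnc,nMir,nMrna feature counts per class.
#' @param plantedTriplets explicit triplet table, or \code{NULL}.
#' @param nPlanted number of implicitly planted triplets when
#'   \code{plantedTriplets} is \code{NULL}.
#' @param effect case-group shift on the log2 scale (> 0) used for implicit
#'   triplets; 2 corresponds to a 4-fold change, well inside the range of
#'   fold changes differential microarray screens report.
#' @param latentSd sd (log2) of the shared per-sample latent signal.
#' @param backgroundNoiseSd per-feature noise sd (log2).
#' @param baselineMean baseline log2 intensity.
#' @param decoyRatio decoy:true ratio for interaction pairs without
#'   expression support.
#' @param seed integer RNG seed.
#' @param allowSharedFeatures allow one feature in several triplets.
#' @return a validated [SyntheticSpec-class].
#' @examples
#' spec <- SyntheticSpec(nPlanted = 2, seed = 7)
#' spec
#' @export
SyntheticSpec <- function(nCase = 3, nControl = 3,
                          nLnc = 30, nMir = 20, nMrna = 40,
                          plantedTriplets = NULL, nPlanted = 0, effect = 2,
                          latentSd = 0.5, backgroundNoiseSd = 0.25,
                          baselineMean = 8, decoyRatio = 3, seed = 1L,
                          allowSharedFeatures = FALSE) {
  if (is.null(plantedTriplets)) {
    nPlanted <- as.integer(nPlanted)
    if (nPlanted > min(nLnc, nMir, nMrna))
      stop("nPlanted exceeds the smallest feature class")
    plantedTriplets <- data.frame(
      lncrna_id = sprintf("LNC%04d", seq_len(nPlanted)),
      mirna_id  = sprintf("MIR%04d", seq_len(nPlanted)),
      mrna_id   = sprintf("MRNA%04d", seq_len(nPlanted)),
      effect    = rep(as.numeric(effect), length.out = nPlanted),
      stringsAsFactors = FALSE)
  }
  new("SyntheticSpec",
      nCase = as.integer(nCase), nControl = as.integer(nControl),
      nLnc = as.integer(nLnc), nMir = as.integer(nMir),
      nMrna = as.integer(nMrna), plantedTriplets = plantedTriplets,
      latentSd = latentSd, backgroundNoiseSd = backgroundNoiseSd,
      baselineMean = baselineMean, decoyRatio = decoyRatio,
      seed = as.integer(seed), allowSharedFeatures = allowSharedFeatures)
}

#' Simulate a case/control dataset with planted ceRNA triplets
#'
#' For each planted triplet one latent signal per sample is drawn; the lncRNA
#' and mRNA are \code{baseline + latent + shift + noise} and the miRNA is
#' \code{baseline - latent - shift + noise}, where \code{shift} equals the
#' triplet's effect size in case samples and 0 in controls. This is the
#' minimal construction that makes the lncRNA and mRNA positively
#' co-expressed, both anticorrelated with the miRNA, and all three
#' differentially expressed between groups. Background features are
#' independent noise around the baseline. The interaction table contains the
#' planted miRNA->lncRNA and miRNA->mRNA pairs plus \code{decoyRatio} times as
#' many decoy pairs drawn from combinations with at least one background
#' endpoint, so they carry no expression support for the anticorrelation
#' filter to accept.
#'
#' The same spec (including its seed) reproduces the dataset exactly.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [SyntheticDataset-class]; expression matrices are log2 scale.
#' @examples
#' ds <- simulateDataset(SyntheticSpec(nPlanted = 1, backgroundNoiseSd = 0))
#' lncv <- SummarizedExperiment::assay(ds@lncrna)["LNC0001", ]
#' mrnav <- SummarizedExperiment::assay(ds@mrna)["MRNA0001", ]
#' cor(lncv, mrnav)  # exactly +1
#' @export
simulateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  ids <- .syntheticFeatureIds(spec)
  n <- spec@nCase + spec@nControl
  samples <- sprintf("S%02d", seq_len(n))
  group <- rep(c("case", "control"), c(spec@nCase, spec@nControl))
  pt <- spec@plantedTriplets

  .withSeed(spec@seed, {
    latent <- matrix(stats::rnorm(nrow(pt) * n, sd = spec@latentSd),
                     nrow = nrow(pt), ncol = n)
    shift <- outer(pt$effect, as.numeric(group == "case"))

    mk <- function(class) {
      feat <- ids[[class]]
      m <- matrix(stats::rnorm(length(feat) * n, mean = spec@baselineMean,
                               sd = spec@backgroundNoiseSd),
                  nrow = length(feat), ncol = n,
                  dimnames = list(feat, samples))
      if (nrow(pt)) {
        col <- switch(class, lncRNA = "lncrna_id", miRNA = "mirna_id",
                      mRNA = "mrna_id")
        sgn <- if (class == "miRNA") -1 else 1
        for (k in seq_len(nrow(pt))) {
          f <- pt[[col]][k]
          m[f, ] <- m[f, ] + sgn * (latent[k, ] + shift[k, ])
        }
      }
      ExpressionMatrix(m, class, group, isLog2 = TRUE)
    }
    lnc <- mk("lncRNA"); mir <- mk("miRNA"); mrna <- mk("mRNA")

    truePairs <- if (nrow(pt)) data.frame(
      mirna_id = rep(pt$mirna_id, 2L),
      target_id = c(pt$lncrna_id, pt$mrna_id),
      target_class = rep(c("lncRNA", "mRNA"), each = nrow(pt)),
      source = "planted", score = NA_real_, mfe = NA_real_,
      stringsAsFactors = FALSE)
    else data.frame(mirna_id = character(), target_id = character(),
                    target_class = character(), source = character(),
                    score = numeric(), mfe = numeric(),
                    stringsAsFactors = FALSE)

    nDecoy <- round(spec@decoyRatio * nrow(truePairs))
    decoys <- .drawDecoyPairs(ids, pt, nDecoy)
    inter <- rbind(truePairs, decoys)
    inter <- inter[order(inter$mirna_id, inter$target_id), , drop = FALSE]
    rownames(inter) <- NULL

    new("SyntheticDataset", lncrna = lnc, mirna = mir, mrna = mrna,
        interactions = inter, truth = pt, spec = spec)
  })
}

## decoy candidates: miRNA x (lncRNA u mRNA) pairs with at least one
## background endpoint, minus nothing (planted pairs always have two planted
## endpoints so they are excluded by construction)
.drawDecoyPairs <- function(ids, pt, nDecoy) {
  empty <- data.frame(mirna_id = character(), target_id = character(),
                      target_class = character(), source = character(),
                      score = numeric(), mfe = numeric(),
                      stringsAsFactors = FALSE)
  if (nDecoy <= 0) return(empty)
  targets <- data.frame(
    target_id = c(ids$lncRNA, ids$mRNA),
    target_class = rep(c("lncRNA", "mRNA"), c(length(ids$lncRNA),
                                              length(ids$mRNA))),
    stringsAsFactors = FALSE)
  pool <- expand.grid(mi = seq_along(ids$miRNA), tg = seq_len(nrow(targets)),
                      KEEP.OUT.ATTRS = FALSE)
  mirPlanted <- ids$miRNA[pool$mi] %in% pt$mirna_id
  tgtPlanted <- targets$target_id[pool$tg] %in% c(pt$lncrna_id, pt$mrna_id)
  pool <- pool[!(mirPlanted & tgtPlanted), , drop = FALSE]
  if (nrow(pool) < nDecoy) {
    warning("fewer background pairs available than requested decoys; ",
            "emitting ", nrow(pool), call. = FALSE)
    take <- seq_len(nrow(pool))
  } else {
    take <- sample.int(nrow(pool), nDecoy)
  }
  sel <- pool[take, , drop = FALSE]
  data.frame(mirna_id = ids$miRNA[sel$mi],
             target_id = targets$target_id[sel$tg],
             target_class = targets$target_class[sel$tg],
             source = "decoy", score = NA_real_, mfe = NA_real_,
             stringsAsFactors = FALSE)
}

#' Write a SyntheticDataset to delimited files
#'
#' Writes one expression table per class (linear scale, with the log-status
#' flag recorded in the file header), the sample-group table, the interaction
#' table and the planted-triplet truth table into \code{dir}.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(lncrna = file.path(dir, "lncrna_expression.tsv"),
             mirna = file.path(dir, "mirna_expression.tsv"),
             mrna = file.path(dir, "mrna_expression.tsv"),
             samples = file.path(dir, "sample_groups.tsv"),
             interactions = file.path(dir, "interactions.tsv"),
             truth = file.path(dir, "planted_triplets.tsv"))
  writeExpression(linearScale(dataset@lncrna), paths[["lncrna"]])
  writeExpression(linearScale(dataset@mirna), paths[["mirna"]])
  writeExpression(linearScale(dataset@mrna), paths[["mrna"]])
  writeSampleGroups(sampleGroups(dataset@lncrna), paths[["samples"]])
  writeInteractions(dataset@interactions, paths[["interactions"]])
  utils::write.table(dataset@truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Serialize / restore a SyntheticSpec as YAML
#'
#' @param spec a [SyntheticSpec-class].
#' @param path file path.
#' @return `readSyntheticSpec` returns the restored [SyntheticSpec-class].
#' @export
writeSyntheticSpec <- function(spec, path) {
  stopifnot(is(spec, "SyntheticSpec"))
  obj <- list(nCase = spec@nCase, nControl = spec@nControl,
              nLnc = spec@nLnc, nMir = spec@nMir, nMrna = spec@nMrna,
              plantedTriplets = lapply(seq_len(nrow(spec@plantedTriplets)),
                                       function(i) as.list(spec@plantedTriplets[i, ])),
              latentSd = spec@latentSd,
              backgroundNoiseSd = spec@backgroundNoiseSd,
              baselineMean = spec@baselineMean, decoyRatio = spec@decoyRatio,
              seed = spec@seed,
              allowSharedFeatures = spec@allowSharedFeatures)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeSyntheticSpec
#' @export
readSyntheticSpec <- function(path) {
  obj <- yaml::read_yaml(path)
  pt <- if (length(obj$plantedTriplets))
    do.call(rbind, lapply(obj$plantedTriplets, as.data.frame))
  else data.frame(lncrna_id = character(), mirna_id = character(),
                  mrna_id = character(), effect = numeric())
  SyntheticSpec(nCase = obj$nCase, nControl = obj$nControl, nLnc = obj$nLnc,
                nMir = obj$nMir, nMrna = obj$nMrna, plantedTriplets = pt,
                latentSd = obj$latentSd,
                backgroundNoiseSd = obj$backgroundNoiseSd,
                baselineMean = obj$baselineMean, decoyRatio = obj$decoyRatio,
                seed = obj$seed, allowSharedFeatures = obj$allowSharedFeatures)
}
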