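## shared fixture builders

exprs_of <- function(em) SummarizedExperiment::assay(em, "exprs")

## minimal valid ExpressionMatrix from a plain matrix-free recipe
toy_expression <- function(values, class = "mRNA",
                           group = NULL, isLog2 = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(group))
    group <- rep(c("case", "control"), each = ncol(values) / 2)
  ExpressionMatrix(values, class, group, isLog2 = isLog2)
}

## the 5-node toy used across topology tests:
## L - m1, L - m2 ; m1 - g1, m1 - g2, m2 - g2
toy_network <- function() {
  TripartiteNetwork(
    nodes = data.frame(
      id = c("L", "m1", "m2", "g1", "g2"),
      class = c("lncRNA", "miRNA", "miRNA", "mRNA", "mRNA"),
      stringsAsFactors = FALSE),
    edges = data.frame(
      from = c("L", "L", "m1", "m1", "m2"),
      to = c("m1", "m2", "g1", "g2", "g2"),
      relation = c("lnc_mir", "lnc_mir", "mir_mrna", "mir_mrna", "mir_mrna"),
      stringsAsFactors = FALSE))
}

## one run of the recovery benchmark: simulate, DE-filter, pair, build
## triplets; returns the emitted and true triplet keys
recovery_run <- function(seed, nPlanted = 10, noiseSd = 0.05, nPerGroup = 12) {
  ds <- simulateDataset(SyntheticSpec(
    nCase = nPerGroup, nControl = nPerGroup, nPlanted = nPlanted,
    backgroundNoiseSd = noiseSd, seed = seed))
  deL <- selectDE(ds@lncrna); deM <- selectDE(ds@mirna)
  deG <- selectDE(ds@mrna)
  pairs <- selectLncMrnaPairs(ds@lncrna, ds@mrna, deL, deG)
  inter <- ds@interactions[
    ds@interactions$mirna_id %in% deM$feature_id[deM$passes], , drop = FALSE]
  tr <- suppressWarnings(
    buildTriplets(pairs, inter, ds@mirna, ds@lncrna, ds@mrna))
  list(emitted = paste(tr$lncrna_id, tr$mirna_id, tr$mrna_id),
       truth = paste(ds@truth$lncrna_id, ds@truth$mirna_id,
                     ds@truth$mrna_id))
}

table1_fixture <- function() {
  path <- system.file("extdata", "dcm_mirna_array_stats.tsv",
                      package = "ceRNAnet")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
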