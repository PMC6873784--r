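test_that("pearsonTest matches the covariance/sigma formula and t transform", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r0 <- cov(x, y) / (sd(x) * sd(y))
  res <- pearsonTest(x, y)
  expect_equal(res$r, r0, tolerance = 1e-12)
  t0 <- r0 * sqrt((5 - 2) / (1 - r0^2))
  expect_equal(res$p_value, 2 * pt(-abs(t0), df = 3), tolerance = 1e-12)
  ## identity and anti-identity
  expect_equal(pearsonTest(x, x), list(r = 1, p_value = 0, n = 5))
  expect_equal(pearsonTest(x, -x)$r, -1)
  expect_equal(pearsonTest(x, -x)$p_value, 0)
  expect_error(pearsonTest(rep(1, 5), x), "constant")
  expect_error(pearsonTest(1:2, 1:2), "at least 3")
})

test_that("pair selection keeps only r above the threshold", {
  l <- toy_expression(rbind(l1 = c(1, 2, 3, 4)), "lncRNA")
  near <- toy_expression(rbind(g1 = c(2, 4, 6, 8),    # r = 1
                               g2 = c(1, 2, 3, 5)),   # r ~ 0.983
                         "mRNA")
  expect_lt(cor(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.99)
  pairs <- selectLncMrnaPairs(l, near, pccThreshold = 0.99)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$mrna_id, "g1")
  expect_equal(pairs$r, 1)
})

test_that("sample misalignment between matrices is an error", {
  l <- toy_expression(rbind(l1 = 1:4), "lncRNA")
  m <- exprs_of(toy_expression(rbind(g1 = 1:4), "mRNA"))
  colnames(m) <- c("s01", "s02", "s04", "s03")
  g <- ExpressionMatrix(m, "mRNA", c("case", "case", "control", "control"))
  expect_error(selectLncMrnaPairs(l, g), "sample-aligned")
})

test_that("a zero-noise planted triplet is retained and assembled", {
  ds <- simulateDataset(SyntheticSpec(nPlanted = 1, backgroundNoiseSd = 0,
                                      seed = 8))
  pairs <- suppressWarnings(selectLncMrnaPairs(ds@lncrna, ds@mrna))
  expect_true(any(pairs$lncrna_id == "LNC0001" &
                  pairs$mrna_id == "MRNA0001"))
  tr <- suppressWarnings(buildTriplets(pairs, ds@interactions, ds@mirna,
                                       ds@lncrna, ds@mrna))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$lncrna_id, "LNC0001")
  expect_equal(tr$mirna_id, "MIR0001")
  expect_equal(tr$mir_lnc_r, -1)
  expect_equal(tr$mir_mrna_r, -1)
})

test_that("interaction support is required even when correlations pass", {
  ds <- simulateDataset(SyntheticSpec(nPlanted = 1, backgroundNoiseSd = 0,
                                      seed = 8))
  pairs <- suppressWarnings(selectLncMrnaPairs(ds@lncrna, ds@mrna))
  inter <- ds@interactions
  pruned <- inter[!(inter$mirna_id == "MIR0001" &
                    inter$target_id == "MRNA0001"), ]
  tr <- suppressWarnings(
    buildTriplets(pairs, pruned, ds@mirna, ds@lncrna, ds@mrna))
  expect_equal(nrow(tr), 0)
})

test_that("miRNAs without expression profiles are skipped with a warning", {
  ds <- simulateDataset(SyntheticSpec(nPlanted = 1, backgroundNoiseSd = 0,
                                      seed = 8))
  pairs <- suppressWarnings(selectLncMrnaPairs(ds@lncrna, ds@mrna))
  inter <- rbind(ds@interactions,
                 data.frame(mirna_id = "MIR_GHOST", target_id = "LNC0001",
                            target_class = "lncRNA", source = "imported",
                            score = NA_real_, mfe = NA_real_))
  expect_warning(
    expect_warning(
      tr <- buildTriplets(pairs, inter, ds@mirna, ds@lncrna, ds@mrna),
      "MIR_GHOST"),
    "constant")  # zero-noise background miRNAs are dropped too
  expect_equal(attr(tr, "skipped"), "MIR_GHOST")
  expect_equal(nrow(tr), 1)
})

test_that("raising the correlation threshold never adds triplets", {
  ds <- simulateDataset(SyntheticSpec(nPlanted = 5, nCase = 8, nControl = 8,
                                      backgroundNoiseSd = 0.3, seed = 19))
  counts <- vapply(c(0.5, 0.9, 0.99, 0.999), function(th) {
    pairs <- selectLncMrnaPairs(ds@lncrna, ds@mrna, pccThreshold = th)
    nrow(buildTriplets(pairs, ds@interactions, ds@mirna, ds@lncrna,
                       ds@mrna))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("triplet emission is invariant to sample column order", {
  ds <- simulateDataset(SyntheticSpec(nPlanted = 3, nCase = 6, nControl = 6,
                                      backgroundNoiseSd = 0.05, seed = 4))
  set.seed(77)
  perm <- sample(ncol(ds@lncrna))
  shuffle <- function(em) ExpressionMatrix(
    exprs_of(em)[, perm, drop = FALSE], featureClass(em),
    unname(sampleGroups(em))[perm], isLog2 = TRUE)
  p1 <- selectLncMrnaPairs(ds@lncrna, ds@mrna)
  p2 <- selectLncMrnaPairs(shuffle(ds@lncrna), shuffle(ds@mrna))
  t1 <- buildTriplets(p1, ds@interactions, ds@mirna, ds@lncrna, ds@mrna)
  t2 <- buildTriplets(p2, ds@interactions, shuffle(ds@mirna),
                      shuffle(ds@lncrna), shuffle(ds@mrna))
  expect_equal(t1$lncrna_id, t2$lncrna_id)
  expect_equal(t1$mir_lnc_r, t2$mir_lnc_r, tolerance = 1e-12)
})

test_that("shared-miRNA score reproduces exact hypergeometric values", {
  s <- sharedMiRNAScore(c("m1", "m2", "m3"), c("m2", "m3", "m4"), 11)
  expect_equal(s$shared, 2)
  ## exact enumeration: sum_k>=2 C(3,k) C(8,3-k) / C(11,3) = 25/165
  expect_equal(s$p_hyper,
               (choose(3, 2) * choose(8, 1) + choose(3, 3)) / choose(11, 3),
               tolerance = 1e-12)
  expect_equal(sharedMiRNAScore(c("a", "b"), c("c", "d"), 10)$p_hyper, 1)
  full <- sharedMiRNAScore(letters[1:5], letters[1:5], 5)
  expect_equal(full$shared, 5)
  expect_equal(full$p_hyper, 1)
  expect_error(sharedMiRNAScore(letters[1:6], letters[1:2], 5), "universe")
})
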