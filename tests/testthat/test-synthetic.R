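test_that("zero-noise planted correlations are exactly +/-1", {
  ds <- simulateDataset(SyntheticSpec(nPlanted = 1, backgroundNoiseSd = 0,
                                      seed = 11))
  l <- exprs_of(ds@lncrna)["LNC0001", ]
  m <- exprs_of(ds@mirna)["MIR0001", ]
  g <- exprs_of(ds@mrna)["MRNA0001", ]
  expect_equal(cor(l, g), 1)
  expect_equal(cor(m, l), -1)
  expect_equal(cor(m, g), -1)
})

test_that("identical spec (including seed) reproduces the dataset exactly", {
  spec <- SyntheticSpec(nPlanted = 3, seed = 42)
  a <- simulateDataset(spec)
  b <- simulateDataset(spec)
  expect_identical(exprs_of(a@lncrna), exprs_of(b@lncrna))
  expect_identical(exprs_of(a@mirna), exprs_of(b@mirna))
  expect_identical(exprs_of(a@mrna), exprs_of(b@mrna))
  expect_identical(a@interactions, b@interactions)
  c <- simulateDataset(SyntheticSpec(nPlanted = 3, seed = 43))
  expect_false(identical(exprs_of(a@lncrna), exprs_of(c@lncrna)))
})

test_that("invalid specs fail validation naming the offending field", {
  expect_error(SyntheticSpec(nCase = 1), "nCase")
  expect_error(SyntheticSpec(nLnc = 0), "nLnc")
  expect_error(SyntheticSpec(backgroundNoiseSd = -1), "backgroundNoiseSd")
  expect_error(
    SyntheticSpec(plantedTriplets = data.frame(
      lncrna_id = "LNC9999", mirna_id = "MIR0001", mrna_id = "MRNA0001",
      effect = 2)),
    "lncrna_id.*LNC9999")
  expect_error(
    SyntheticSpec(plantedTriplets = data.frame(
      lncrna_id = c("LNC0001", "LNC0001"),
      mirna_id = c("MIR0001", "MIR0002"),
      mrna_id = c("MRNA0001", "MRNA0002"), effect = 2)),
    "more than one planted triplet")
  ## the escape hatch for deliberately shared features
  expect_s4_class(
    SyntheticSpec(plantedTriplets = data.frame(
      lncrna_id = c("LNC0001", "LNC0001"),
      mirna_id = c("MIR0001", "MIR0002"),
      mrna_id = c("MRNA0001", "MRNA0002"), effect = 2),
      allowSharedFeatures = TRUE),
    "SyntheticSpec")
  expect_error(
    SyntheticSpec(plantedTriplets = data.frame(
      lncrna_id = "LNC0001", mirna_id = "MIR0001", mrna_id = "MRNA0001",
      effect = 0)),
    "effect")
})

test_that("interaction table carries planted pairs plus the decoy quota", {
  ds <- simulateDataset(SyntheticSpec(nPlanted = 4, decoyRatio = 3,
                                      seed = 9))
  inter <- ds@interactions
  expect_equal(sum(inter$source == "planted"), 8)   # 2 pairs per triplet
  expect_equal(sum(inter$source == "decoy"), 24)    # 3:1 ratio
  ## every decoy touches at least one background feature
  planted <- c(ds@truth$lncrna_id, ds@truth$mirna_id, ds@truth$mrna_id)
  decoys <- inter[inter$source == "decoy", ]
  expect_true(all(!(decoys$mirna_id %in% planted) |
                  !(decoys$target_id %in% planted)))
  ## planted pairs reference the truth table exactly
  truePairs <- inter[inter$source == "planted", ]
  expect_setequal(
    paste(truePairs$mirna_id, truePairs$target_id),
    c(paste(ds@truth$mirna_id, ds@truth$lncrna_id),
      paste(ds@truth$mirna_id, ds@truth$mrna_id)))
})

test_that("feature ids are unique across classes and columns match design", {
  ds <- simulateDataset(SyntheticSpec(nCase = 4, nControl = 3, seed = 2))
  ids <- c(rownames(ds@lncrna), rownames(ds@mirna), rownames(ds@mrna))
  expect_equal(anyDuplicated(ids), 0L)
  expect_equal(ncol(ds@lncrna), 7)
  expect_equal(as.integer(table(sampleGroups(ds@mirna))[c("case",
                                                          "control")]),
               c(4L, 3L))
})

test_that("spec YAML serialization round-trips", {
  spec <- SyntheticSpec(nPlanted = 2, nCase = 5, latentSd = 0.3, seed = 77)
  path <- tempfile(fileext = ".yaml")
  writeSyntheticSpec(spec, path)
  back <- readSyntheticSpec(path)
  expect_identical(simulateDataset(spec)@interactions,
                   simulateDataset(back)@interactions)
  expect_equal(back@latentSd, 0.3)
  expect_equal(back@plantedTriplets, spec@plantedTriplets)
})
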