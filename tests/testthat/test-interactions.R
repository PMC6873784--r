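test_that("a single canonical site is found where the seed complement sits", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"           # seed (2-8) GAGGUAG -> CTACCTC
  tgt <- paste0("GGGG", "CTACCTC", "GGGG")  # m8 match, no A1
  hits <- seedMatchScan(mir, tgt)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 4)
  expect_equal(hits$match_type, "7mer-m8")
  ## with a downstream A it becomes an 8mer spanning 8 nt
  hits8 <- seedMatchScan(mir, paste0("GGGG", "CTACCTCA", "GGG"))
  expect_equal(hits8$match_type, "8mer")
  expect_equal(hits8$site_length, 8)
  expect_equal(hits8$start, 4)
})

test_that("targets without the seed complement yield an empty site list", {
  hits <- seedMatchScan("UGAGGUAGUAGGUUGUAUAGUU",
                        "AAAAAAAAAAAAAAAAAAAAAAAA")
  expect_equal(nrow(hits), 0)
})

test_that("tandem duplication doubles the site list with a fixed offset", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  unit <- "GGCTACCTCAGGGGGG"
  hits <- seedMatchScan(mir, paste0(unit, unit))
  expect_equal(nrow(hits), 2)
  expect_equal(diff(hits$start), nchar(unit))
})

test_that("scanner equals the naive all-offset oracle on random instances", {
  set.seed(501)
  for (i in 1:150) {
    mir <- random_rna(sample(8:24, 1))
    tgt <- random_rna(sample(15:200, 1))
    got <- seedMatchScan(mir, tgt, minClass = "6mer")
    want <- oracle_seed_scan(mir, tgt)
    expect_equal(got$start, want$start)
    expect_equal(got$match_type, want$match_type)
    expect_equal(got$site_length, want$site_length)
  }
})

test_that("short miRNAs and bad alphabets are rejected", {
  expect_error(seedMatchScan("UGAGGUA", "ACGTACGT"), "at least 8")
  expect_error(seedMatchScan("UGAGGUAGUA", "ACGTXCGT"), "outside")
  expect_error(seedMatchScan("UGAGGUAGUA", ""), "non-empty")
})

test_that("sites collapse to one scored pair per (miRNA, target)", {
  sites <- data.frame(
    mirna_id = c("m1", "m1", "m1", "m2"),
    target_id = c("t1", "t1", "t1", "t1"),
    target_class = "lncRNA", stringsAsFactors = FALSE)
  pairs <- pairsFromSites(sites)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$score[pairs$mirna_id == "m1"], 3)
  expect_equal(pairs$score[pairs$mirna_id == "m2"], 1)
})

test_that("predictInteractions scans all combinations deterministically", {
  mirs <- c(mirB = "UGAGGUAGUAGGUUGUAUAGUU", mirA = "ACGUACGUACGU")
  tgts <- c(t2 = "GGGCTACCTCGGG", t1 = "GGGGTACGTACGTGGGG")
  pairs <- predictInteractions(mirs, tgts, "mRNA", minClass = "6mer")
  expect_equal(pairs$mirna_id, sort(pairs$mirna_id))
  expect_true(all(pairs$source == "seed_match"))
  expect_gte(nrow(pairs), 1)
  again <- predictInteractions(mirs, tgts, "mRNA", minClass = "6mer")
  expect_identical(pairs, again)
})

test_that("merge is a key union keeping the best score", {
  a <- data.frame(mirna_id = sprintf("m%d", 1:4),
                  target_id = sprintf("t%d", 1:4),
                  target_class = "mRNA", score = 1:4,
                  stringsAsFactors = FALSE)
  b <- data.frame(mirna_id = sprintf("m%d", 3:7),
                  target_id = sprintf("t%d", 3:7),
                  target_class = "mRNA", score = c(10, 1, 5, 6, 7),
                  stringsAsFactors = FALSE)
  merged <- mergeInteractions(a, b)
  expect_equal(nrow(merged), 4 + 5 - 2)
  expect_equal(merged$score[merged$mirna_id == "m3"], 10)  # best kept
  expect_equal(merged$score[merged$mirna_id == "m4"], 4)
  expect_equal(merged$mirna_id, sort(merged$mirna_id))
  disjoint <- mergeInteractions(a, b[b$mirna_id %in% c("m5", "m6"), ])
  expect_equal(nrow(disjoint), 6)
  expect_error(mergeInteractions(a, b, dedupe = FALSE), "duplicate")
})

test_that("conflicting target classes across tables are an error", {
  a <- data.frame(mirna_id = "m1", target_id = "t1",
                  target_class = "mRNA", stringsAsFactors = FALSE)
  b <- data.frame(mirna_id = "m2", target_id = "t1",
                  target_class = "lncRNA", stringsAsFactors = FALSE)
  expect_error(mergeInteractions(a, b), "conflicting target_class")
})
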