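## Built-in canonical seed-match predictor. External prediction tables
## (miRanda/TargetScan/RNAhybrid-style) are imported via readInteractions()
## and merged with mergeInteractions(); seed matching is the only predictor
## implemented here.

.MATCH_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

#' Scan a transcript for canonical miRNA seed-match sites
#'
#' Finds every occurrence on the target (5'->3') of the reverse complement of
#' the miRNA seed (positions 2-7, 1-based 5'->3') and classifies it by the
#' canonical site taxonomy: extension by a match to miRNA position 8 gives
#' the m8 variants, an adenosine on the target opposite miRNA position 1
#' gives the A1 variants, both give an 8mer. Overlapping sites are all
#' reported; only the given strand is scanned (targets are transcripts).
#' Coordinates are 0-based half-open on the target.
#'
#' @param mirnaSeq miRNA sequence, 5'->3', RNA or DNA alphabet, >= 8 nt.
#' @param targetSeq target transcript sequence, 5'->3'.
#' @param minClass weakest site class to report: \code{"6mer"},
#'   \code{"7mer"} (default: both 7mers and 8mers) or \code{"8mer"}.
#' @return data.frame with columns \code{start}, \code{site_length},
#'   \code{match_type} (zero rows when nothing matches).
#' @examples
#' seedMatchScan("UGAGGUAGUAGGUUGUAUAGUU", "GGGCTACCTCAGG", minClass = "6mer")
#' @export
seedMatchScan <- function(mirnaSeq, targetSeq,
                          minClass = c("7mer", "6mer", "8mer")) {
  minClass <- match.arg(minClass)
  mir <- .normalizeSeq(mirnaSeq, "miRNA sequence")
  tgt <- .normalizeSeq(targetSeq, "target sequence")
  if (nchar(mir) < 8L)
    stop("miRNA must be at least 8 nt to define the seed region")

  seed6 <- substr(mir, 2L, 7L)                   # miRNA positions 2-7
  core <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seed6)))               # target-strand 6mer core
  m8comp <- as.character(Biostrings::complement(
    Biostrings::DNAString(substr(mir, 8L, 8L)))) # pairs miRNA position 8

  hits <- Biostrings::matchPattern(core, Biostrings::DNAString(tgt))
  if (length(hits) == 0L)
    return(data.frame(start = integer(), site_length = integer(),
                      match_type = character(), stringsAsFactors = FALSE))
  s0 <- Biostrings::start(hits) - 1L             # 0-based core offset
  len <- nchar(tgt)
  hasM8 <- s0 >= 1L & substr(rep(tgt, length(s0)), s0, s0) == m8comp
  hasA1 <- s0 + 7L <= len &
    substr(rep(tgt, length(s0)), s0 + 7L, s0 + 7L) == "A"
  type <- ifelse(hasM8 & hasA1, "8mer",
          ifelse(hasM8, "7mer-m8",
          ifelse(hasA1, "7mer-A1", "6mer")))
  start <- ifelse(hasM8, s0 - 1L, s0)
  siteLen <- 6L + hasM8 + hasA1

  out <- data.frame(start = as.integer(start),
                    site_length = as.integer(siteLen),
                    match_type = type, stringsAsFactors = FALSE)
  keep <- switch(minClass,
                 "6mer" = .MATCH_TYPES,
                 "7mer" = c("7mer-A1", "7mer-m8", "8mer"),
                 "8mer" = "8mer")
  out <- out[out$match_type %in% keep, , drop = FALSE]
  out <- out[order(out$start, out$match_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict interaction pairs for sets of sequences
#'
#' Runs [seedMatchScan()] over every (miRNA, target) combination and
#' collapses sites into one [readInteractions()]-style pair per combination
#' with \code{score} = number of sites.
#'
#' @param mirnas named character vector or \code{DNAStringSet} of miRNA
#'   sequences.
#' @param targets named character vector or \code{DNAStringSet} of target
#'   transcript sequences.
#' @param targetClass \code{"lncRNA"} or \code{"mRNA"}.
#' @param minClass passed to [seedMatchScan()].
#' @return interaction pair data.frame, lexicographically ordered.
#' @export
predictInteractions <- function(mirnas, targets,
                                targetClass = c("lncRNA", "mRNA"),
                                minClass = "7mer") {
  targetClass <- match.arg(targetClass)
  mirnas <- stats::setNames(as.character(mirnas), names(mirnas))
  targets <- stats::setNames(as.character(targets), names(targets))
  if (is.null(names(mirnas)) || is.null(names(targets)))
    stop("mirnas and targets must be named")
  rows <- list()
  for (m in sort(names(mirnas))) {
    for (t in sort(names(targets))) {
      sites <- seedMatchScan(mirnas[[m]], targets[[t]], minClass = minClass)
      if (nrow(sites))
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = m, target_id = t, target_class = targetClass,
          source = "seed_match", score = nrow(sites), mfe = NA_real_,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(), target_id = character(),
                      target_class = character(), source = character(),
                      score = numeric(), mfe = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collapse per-site hits into interaction pairs
#'
#' One pair per (miRNA, target) regardless of site count, scored by the
#' number of sites; output ordered lexicographically by miRNA then target.
#'
#' @param sites data.frame with columns \code{mirna_id}, \code{target_id},
#'   \code{target_class} (one row per site).
#' @return interaction pair data.frame.
#' @export
pairsFromSites <- function(sites) {
  need <- c("mirna_id", "target_id", "target_class")
  if (!all(need %in% colnames(sites)))
    stop("sites needs columns ", paste(need, collapse = ", "))
  if (!nrow(sites))
    return(data.frame(mirna_id = character(), target_id = character(),
                      target_class = character(), source = character(),
                      score = numeric(), mfe = numeric(),
                      stringsAsFactors = FALSE))
  key <- paste(sites$mirna_id, sites$target_id, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  out <- data.frame(
    mirna_id = vapply(parts, `[[`, "", 1L),
    target_id = vapply(parts, `[[`, "", 2L),
    stringsAsFactors = FALSE)
  cls <- unique(sites[c("mirna_id", "target_id", "target_class")])
  out <- merge(out, cls, by = c("mirna_id", "target_id"), sort = FALSE)
  if (nrow(out) != length(parts))
    stop("conflicting target_class for the same (miRNA, target) pair")
  out$source <- "seed_match"
  out$score <- agg$Freq
  out$mfe <- NA_real_
  out <- .validateInteractions(out, "pairsFromSites")
  out <- out[order(out$mirna_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge imported and computed interaction tables
#'
#' Set union on (mirna_id, target_id); duplicated keys keep the best
#' (largest) score, with \code{NA} scores treated as lowest. Conflicting
#' target classes for the same target id are an error. Output is
#' lexicographically ordered, hence deterministic.
#'
#' @param imported,computed interaction pair data.frames.
#' @param dedupe collapse duplicate keys (default \code{TRUE}); when
#'   \code{FALSE} a duplicated key is an error.
#' @return merged interaction pair data.frame.
#' @export
mergeInteractions <- function(imported, computed, dedupe = TRUE) {
  imported <- .validateInteractions(imported, "imported")
  computed <- .validateInteractions(computed, "computed")
  all <- rbind(imported, computed)
  conf <- tapply(all$target_class, all$target_id,
                 function(x) length(unique(x)))
  if (any(conf > 1L))
    stop("conflicting target_class across tables for target id(s) ",
         paste(names(conf)[conf > 1L], collapse = ", "))
  key <- paste(all$mirna_id, all$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    if (!dedupe) stop("duplicate (miRNA, target) keys with dedupe = FALSE")
    ord <- order(key, -ifelse(is.na(all$score), -Inf, all$score))
    all <- all[ord, , drop = FALSE]
    all <- all[!duplicated(paste(all$mirna_id, all$target_id, sep = "\r")), ,
               drop = FALSE]
  }
  all <- all[order(all$mirna_id, all$target_id), , drop = FALSE]
  rownames(all) <- NULL
  all
}
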