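#' Read transcript sequences from FASTA
#'
#' Sequence ids are the FASTA headers up to the first whitespace and must be
#' unique. RNA input is accepted and normalised to the DNA alphabet (U -> T);
#' which records were RNA is kept in \code{metadata(x)$wasRNA}. Any character
#' outside A/C/G/T/U (after upper-casing) is an error.
#'
#' @param path FASTA file path.
#' @return a \link[Biostrings]{DNAStringSet}.
#' @export
readTranscriptFasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path)
  if (anyDuplicated(ids))
    stop("duplicated FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  wasRNA <- grepl("U", seqs, fixed = TRUE)
  norm <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGT]", norm)
  if (any(bad))
    stop("non-ACGT/U character(s) in record(s): ",
         paste(ids[bad], collapse = ", "))
  out <- Biostrings::DNAStringSet(stats::setNames(norm, ids))
  S4Vectors::metadata(out)$wasRNA <- stats::setNames(wasRNA, ids)
  out
}

## normalise a single sequence string to upper-case DNA, validating alphabet
.normalizeSeq <- function(seq, what = "sequence") {
  s <- chartr("U", "T", toupper(as.character(seq)))
  if (!nzchar(s)) stop(what, " must be non-empty")
  if (grepl("[^ACGT]", s))
    stop(what, " contains characters outside A/C/G/T/U")
  s
}
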