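## Delimited-text IO. Convention: tab-separated, "." decimal, mandatory header
## row (GEO series-matrix style); one optional leading "#" metadata line
## written by this package records the feature class and log2 status.

.parseMetaLine <- function(line) {
  out <- list()
  if (grepl("^#", line)) {
    m <- regmatches(line, regexec("class=([A-Za-z]+)", line))[[1]]
    if (length(m) == 2L) out$class <- m[2L]
    m <- regmatches(line, regexec("log2=(TRUE|FALSE)", line))[[1]]
    if (length(m) == 2L) out$log2 <- as.logical(m[2L])
  }
  out
}

#' Read an expression table
#'
#' Expects tab-delimited text: a mandatory header row, first column the
#' feature id, remaining columns one per sample. The sample-to-group mapping
#' comes from \code{groupPath} (or a named vector via \code{groups}). Loading
#' is strict: duplicate feature ids, non-numeric cells, samples without a
#' group, and group-table samples missing from the matrix are all errors that
#' name the offending file line.
#'
#' @param path expression table path.
#' @param classLabel feature class (\code{"lncRNA"}, \code{"miRNA"},
#'   \code{"mRNA"}); may be omitted if the file carries the package's
#'   metadata header line.
#' @param groupPath path of a two-column (sample_id, group) table; mutually
#'   exclusive with \code{groups}.
#' @param groups named character vector sample id -> \code{"case"}/\code{"control"}.
#' @param isLog2 logical; overrides the file's metadata line. Defaults to the
#'   metadata line, else \code{FALSE}.
#' @return an [ExpressionMatrix-class].
#' @export
readExpression <- function(path, classLabel = NULL, groupPath = NULL,
                           groups = NULL, isLog2 = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty expression file: ", path)
  meta <- .parseMetaLine(lines[1L])
  offset <- 0L
  if (grepl("^#", lines[1L])) { lines <- lines[-1L]; offset <- 1L }
  if (!length(lines)) stop("expression file has no header row: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L)
    stop("expression header must name a feature-id column and >= 1 sample")
  sampleIds <- header[-1L]
  if (anyDuplicated(sampleIds)) stop("duplicate sample ids in header")
  body <- fields[-1L]
  if (!length(body)) stop("expression file has no data rows: ", path)
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop(sprintf("line %d: expected %d fields, found %d",
                 which(nf != length(header))[1L] + 1L + offset,
                 length(header), nf[nf != length(header)][1L]))
  ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop(sprintf("line %d: duplicated feature id '%s'",
                 which(duplicated(ids))[1L] + 1L + offset,
                 ids[duplicated(ids)][1L]))
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(sampleIds))))
  vals <- matrix(vals, nrow = length(sampleIds))  # guards 1-sample edge shape
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1L]
    stop(sprintf("line %d: non-numeric expression value for feature '%s'",
                 bad + 1L + offset, ids[bad]))
  }
  m <- t(vals)
  dimnames(m) <- list(ids, sampleIds)

  if (is.null(groups)) {
    if (is.null(groupPath))
      stop("either groupPath or groups must be supplied")
    groups <- readSampleGroups(groupPath)
  }
  unknown <- setdiff(names(groups), sampleIds)
  if (length(unknown))
    stop("group table names sample(s) absent from the matrix: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(sampleIds, names(groups))
  if (length(missing))
    stop("sample(s) without a group assignment: ",
         paste(missing, collapse = ", "))

  classLabel <- classLabel %||% meta$class
  if (is.null(classLabel))
    stop("feature class not given and not recorded in the file header")
  ExpressionMatrix(m, classLabel, unname(groups[sampleIds]),
                   isLog2 = isLog2 %||% meta$log2 %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an expression table
#'
#' Tab-delimited with a leading metadata line recording the feature class and
#' log2 status, so [readExpression()] round-trips without extra arguments
#' (the sample-group table is written separately, see
#' [writeSampleGroups()]).
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeExpression <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ceRNAnet expression table | class=%s | log2=%s",
                     featureClass(x), isLog2(x)), con)
  m <- SummarizedExperiment::assay(x, "exprs")
  writeLines(paste(c("feature_id", colnames(m)), collapse = "\t"), con)
  writeLines(paste(rownames(m),
                   apply(m, 1L, function(r)
                     paste(format(r, digits = 15, trim = TRUE,
                                  scientific = FALSE), collapse = "\t")),
                   sep = "\t"), con)
  invisible(path)
}

#' Read / write the sample-group table
#'
#' Two tab-separated columns, \code{sample_id} and \code{group}
#' (case/control), with a header row.
#'
#' @param path file path.
#' @return `readSampleGroups` returns a named character vector
#'   (sample id -> group).
#' @export
readSampleGroups <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(tab)))
    stop("sample-group table needs columns 'sample_id' and 'group'")
  if (anyDuplicated(tab$sample_id)) stop("duplicated sample id in group table")
  bad <- setdiff(tab$group, .GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (allowed: case, control)")
  stats::setNames(tab$group, tab$sample_id)
}

#' @rdname readSampleGroups
#' @param groups named character vector sample id -> group.
#' @export
writeSampleGroups <- function(groups, path) {
  utils::write.table(
    data.frame(sample_id = names(groups), group = unname(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.INTERACTION_COLS <- c("mirna_id", "target_id", "target_class")

.validateInteractions <- function(tab, context = "interaction table") {
  if (!all(.INTERACTION_COLS %in% colnames(tab)))
    stop(context, " needs columns ", paste(.INTERACTION_COLS, collapse = ", "))
  bad <- setdiff(unique(tab$target_class), c("lncRNA", "mRNA"))
  if (length(bad))
    stop(context, ": unknown target_class token(s) ",
         paste(sprintf("'%s'", bad), collapse = ", "),
         " (allowed: lncRNA, mRNA)")
  if (!"score" %in% colnames(tab)) tab$score <- NA_real_
  if (!"mfe" %in% colnames(tab)) tab$mfe <- NA_real_
  if (!"source" %in% colnames(tab)) tab$source <- "imported"
  if (any(stats::na.omit(tab$mfe) > 0))
    stop(context, ": duplex minimum free energy (mfe) must be <= 0 kcal/mol")
  dup <- duplicated(tab[c("mirna_id", "target_id")])
  if (any(dup))
    stop(context, ": duplicated (mirna_id, target_id) pair(s), e.g. ",
         tab$mirna_id[dup][1L], " -> ", tab$target_id[dup][1L])
  conf <- tapply(tab$target_class, tab$target_id,
                 function(x) length(unique(x)))
  if (any(conf > 1L))
    stop(context, ": conflicting target_class for target id(s) ",
         paste(names(conf)[conf > 1L], collapse = ", "))
  tab[c("mirna_id", "target_id", "target_class", "source", "score", "mfe")]
}

#' Read / write candidate miRNA->target interaction tables
#'
#' Tab-delimited with header; required columns \code{mirna_id},
#' \code{target_id}, \code{target_class} (lncRNA or mRNA), optional
#' \code{source}, \code{score} and \code{mfe} (kcal/mol, non-positive). Rows
#' are validated strictly; a target id carrying two different classes is an
#' error.
#'
#' @param path file path.
#' @return `readInteractions` returns the validated data.frame.
#' @export
readInteractions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- .validateInteractions(tab, context = path)
  rownames(tab) <- NULL
  tab
}

#' @rdname readInteractions
#' @param interactions a data.frame of interaction pairs.
#' @export
writeInteractions <- function(interactions, path) {
  interactions <- .validateInteractions(interactions)
  utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
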