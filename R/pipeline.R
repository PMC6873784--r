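.defaultConfig <- function() list(
  seed = 1L,
  fc_mirna = 2.0, fc_lnc = 1.5, fc_mrna = 1.5, p = 0.05,
  pcc = 0.99, neg = 0, restart = 0.7, top_k = 20, cut_k = 2,
  use_log2 = TRUE, include_lnc_mrna_edges = FALSE,
  restrict_mirna_to_de = TRUE,
  rwr_seeds = NULL, gmt = NULL,
  simulate = NULL,
  lncrna = NULL, mirna = NULL, mrna = NULL, samples = NULL,
  interactions = NULL,
  out_dir = NULL)

.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(config))]), tf)
  substr(unname(tools::md5sum(tf)), 1L, 8L)
}

#' Run the full ceRNA inference pipeline
#'
#' Executes, in order: differential expression per class, lncRNA-mRNA pair
#' selection, triplet construction, network assembly, topology metrics and
#' pair counting, random walk with restart, co-expression module clustering
#' and (optionally) enrichment. Every stage writes its table into a
#' config-hash-named run directory, plus a machine-readable JSON run report
#' (stage, input/output counts, parameters, seed). Re-running the same
#' config reproduces identical outputs.
#'
#' The configuration is a named list (or the path of a YAML file holding
#' one). Inputs are either a \code{simulate} block — arguments for
#' [SyntheticSpec()] — or file paths \code{lncrna}, \code{mirna},
#' \code{mrna}, \code{samples}, \code{interactions} in the package's
#' delimited formats. Thresholds default to the conventional values
#' (fold change > 2 for miRNA, > 1.5 otherwise, p < 0.05, PCC > 0.99,
#' anticorrelation r < 0, restart 0.7, top 20, 2 modules).
#'
#' @param config named list or YAML path; unknown keys are an error.
#' @return invisibly, a list with \code{dir} (the run directory),
#'   \code{report}, and the main in-memory results (\code{de},
#'   \code{pairs}, \code{triplets}, \code{network}, \code{metrics},
#'   \code{ranking}, \code{pair_counts}, \code{rwr}, \code{modules},
#'   \code{enrichment}).
#' @examples
#' cfg <- list(simulate = list(nPlanted = 1, backgroundNoiseSd = 0),
#'             out_dir = tempfile())
#' res <- suppressWarnings(runPipeline(cfg))
#' nrow(res$triplets)  # 1
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- .defaultConfig()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  runDir <- file.path(cfg$out_dir, paste0("run-", .configHash(cfg)))
  dir.create(runDir, showWarnings = FALSE, recursive = TRUE)

  report <- list(seed = cfg$seed, parameters = cfg[c(
    "fc_mirna", "fc_lnc", "fc_mrna", "p", "pcc", "neg", "restart",
    "top_k", "cut_k", "use_log2", "include_lnc_mrna_edges",
    "restrict_mirna_to_de")], stages = list())
  note <- function(stage, nIn, nOut, extra = list()) {
    report$stages[[stage]] <<- c(list(stage = stage, n_in = nIn,
                                      n_out = nOut), extra)
  }
  fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  ## -- inputs ---------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    spec <- do.call(SyntheticSpec,
                    utils::modifyList(list(seed = cfg$seed), cfg$simulate))
    ds <- tryCatch(simulateDataset(spec), error = function(e)
      fail("simulate", e))
    lnc <- ds@lncrna; mir <- ds@mirna; mrna <- ds@mrna
    inter <- ds@interactions
    writeDataset(ds, file.path(runDir, "input"))
    note("simulate", nrow(spec@plantedTriplets),
         nrow(lnc) + nrow(mir) + nrow(mrna))
  } else {
    lnc <- tryCatch({
      grp <- readSampleGroups(cfg$samples)
      readExpression(cfg$lncrna, "lncRNA", groups = grp)
    }, error = function(e) fail("load", e))
    mir <- tryCatch(readExpression(cfg$mirna, "miRNA",
                                   groups = readSampleGroups(cfg$samples)),
                    error = function(e) fail("load", e))
    mrna <- tryCatch(readExpression(cfg$mrna, "mRNA",
                                    groups = readSampleGroups(cfg$samples)),
                     error = function(e) fail("load", e))
    inter <- tryCatch(readInteractions(cfg$interactions),
                      error = function(e) fail("load", e))
    note("load", NA_integer_, nrow(lnc) + nrow(mir) + nrow(mrna))
  }

  ## -- differential expression ---------------------------------------------
  de <- tryCatch(list(
    lncRNA = selectDE(lnc, cfg$fc_lnc, cfg$p),
    miRNA = selectDE(mir, cfg$fc_mirna, cfg$p),
    mRNA = selectDE(mrna, cfg$fc_mrna, cfg$p)),
    error = function(e) fail("de", e))
  for (cl in names(de)) {
    utils::write.table(de[[cl]],
                       file.path(runDir, sprintf("de_%s.tsv", cl)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note(paste0("de_", cl), nrow(de[[cl]]), sum(de[[cl]]$passes))
  }

  ## -- pairs and triplets ----------------------------------------------------
  pairs <- tryCatch(
    selectLncMrnaPairs(lnc, mrna, de$lncRNA, de$mRNA,
                       pccThreshold = cfg$pcc, pThreshold = cfg$p,
                       useLog2 = cfg$use_log2),
    error = function(e) fail("pairs", e))
  utils::write.table(pairs, file.path(runDir, "lnc_mrna_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("pairs", sum(de$lncRNA$passes) * sum(de$mRNA$passes), nrow(pairs))

  interUsed <- inter
  if (isTRUE(cfg$restrict_mirna_to_de))
    interUsed <- inter[inter$mirna_id %in%
                         de$miRNA$feature_id[de$miRNA$passes], , drop = FALSE]
  triplets <- tryCatch(
    buildTriplets(pairs, interUsed, mir, lnc, mrna,
                  negThreshold = cfg$neg, pThreshold = cfg$p,
                  useLog2 = cfg$use_log2),
    error = function(e) fail("triplets", e))
  utils::write.table(triplets, file.path(runDir, "triplets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("triplets", nrow(pairs), nrow(triplets),
       list(interactions_used = nrow(interUsed),
            mirna_skipped = length(attr(triplets, "skipped"))))

  ## -- network and topology -------------------------------------------------
  network <- assembleNetwork(triplets,
                             includeLncMrnaEdges = cfg$include_lnc_mrna_edges)
  writeNetwork(network, file.path(runDir, "network.sif"), "SIF")
  writeNetwork(network, file.path(runDir, "network.graphml"), "GraphML")
  note("network", nrow(triplets), nrow(networkNodes(network)),
       list(n_edges = nrow(networkEdges(network))))

  metrics <- ranking <- pairCounts <- rwr <- NULL
  if (nrow(networkNodes(network)) > 0L) {
    metrics <- tryCatch(nodeMetrics(network),
                        error = function(e) fail("topology", e))
    ## column order follows the conventional hub-table layout
    utils::write.table(
      metrics[c("betweenness", "closeness", "degree", "pagerank",
                "node_id", "class")],
      file.path(runDir, "node_metrics.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    ranking <- rankTop(metrics, k = cfg$top_k)
    writeLines(jsonlite::toJSON(ranking, pretty = TRUE),
               file.path(runDir, "top_ranking.json"))
    lncIds <- sort(networkNodes(network)$id[
      networkNodes(network)$class == "lncRNA"])
    pairCounts <- do.call(rbind, lapply(lncIds, function(id)
      as.data.frame(countPairs(network, id), stringsAsFactors = FALSE)))
    pairCounts <- pairCounts[order(-pairCounts$total, pairCounts$lncrna_id), ,
                             drop = FALSE]
    utils::write.table(pairCounts, file.path(runDir, "pair_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("topology", nrow(networkNodes(network)), nrow(metrics))

    seeds <- cfg$rwr_seeds %||% lncIds
    if (length(seeds)) {
      rwr <- tryCatch(
        randomWalkRestart(network, seeds, restart = cfg$restart),
        error = function(e) fail("rwr", e))
      rt <- data.frame(node_id = names(probabilities(rwr)),
                       probability = unname(probabilities(rwr)),
                       stringsAsFactors = FALSE)
      rt <- rt[order(-rt$probability, rt$node_id), , drop = FALSE]
      utils::write.table(rt, file.path(runDir, "rwr_ranking.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("rwr", length(seeds), nrow(rt),
           list(iterations = rwr@iterations))
    }
  } else {
    note("topology", 0L, 0L, list(skipped = "empty network"))
  }

  ## -- co-expression modules ------------------------------------------------
  modules <- NULL
  deL <- de$lncRNA$feature_id[de$lncRNA$passes]
  deG <- de$mRNA$feature_id[de$mRNA$passes]
  expr <- rbind(.exprOnScale(lnc, TRUE)[deL, , drop = FALSE],
                .exprOnScale(mrna, TRUE)[deG, , drop = FALSE])
  rowsOk <- sum(apply(expr, 1L, stats::var) > 0) >= max(2L, cfg$cut_k)
  colsOk <- sum(apply(t(expr), 1L, stats::var) > 0) >= 2L
  if (nrow(expr) >= max(2L, cfg$cut_k) && rowsOk && colsOk) {
    modules <- tryCatch(bicluster(expr, k = cfg$cut_k),
                        error = function(e) fail("modules", e))
    utils::write.table(
      data.frame(feature_id = names(modules$rows$labels),
                 module = unname(modules$rows$labels)),
      file.path(runDir, "modules.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    note("modules", nrow(expr), modules$rows$n_modules)
  } else {
    note("modules", nrow(expr), 0L,
         list(skipped = "too few non-degenerate DE features to cluster"))
  }

  ## -- enrichment ------------------------------------------------------------
  enrichment <- NULL
  if (!is.null(cfg$gmt) && !is.null(metrics)) {
    sets <- tryCatch(readGmt(cfg$gmt), error = function(e) fail("enrich", e))
    universe <- rownames(mrna)
    nd <- networkNodes(network); ed <- networkEdges(network)
    lncIds <- sort(nd$id[nd$class == "lncRNA"])
    enrichment <- do.call(rbind, lapply(lncIds, function(id) {
      sub <- extractSubnetwork(network, id)
      q <- networkNodes(sub)$id[networkNodes(sub)$class == "mRNA"]
      if (!length(q)) return(NULL)
      res <- enrichSets(intersect(q, universe), sets, universe)
      cbind(lncrna_id = id, res, stringsAsFactors = FALSE)
    }))
    if (!is.null(enrichment))
      utils::write.table(enrichment, file.path(runDir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    note("enrich", length(lncIds),
         if (is.null(enrichment)) 0L else nrow(enrichment))
  }

  report$stages <- unname(report$stages)
  jsonlite::write_json(report, file.path(runDir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dir = runDir, report = report, de = de, pairs = pairs,
                 triplets = triplets, network = network, metrics = metrics,
                 ranking = ranking, pair_counts = pairCounts, rwr = rwr,
                 modules = modules, enrichment = enrichment))
}
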