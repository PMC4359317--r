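#' Run the full miRNA-pathway association pipeline
#'
#' Orchestrates every stage on files in the package's tabular formats:
#' multi-tool target filtering, universe restriction, per-pathway
#' best-miRNA enrichment with Storey q-values, the optional
#' randomized-pathway null, probabilistic pathway activity, phenotype
#' stratification (t-test scan, and survival split when the phenotype table
#' carries time/event), group-wise miRNA-pathway correlation for the top
#' association, and the bipartite network export. All outputs are written
#' under \code{outDir}; the run is a pure function of the inputs, the
#' parameters and the seed, so a rerun with identical arguments reproduces
#' identical files.
#'
#' @param predictionsFile,gmtFile,mrnaFile,mirnaFile,phenotypeFile input
#'   paths in the formats of the \code{read*} functions
#' @param interactionsFile optional interactions TSV (NULL for gene-set
#'   fallback activity)
#' @param outDir output directory, created if missing
#' @param groupA,groupB phenotype group labels to contrast
#' @param minTools minimum tool support k (default 2)
#' @param qThreshold network edge threshold (default 0.05)
#' @param nullIterations randomized-pathway iterations; 0 skips the null
#'   stage (the reference analysis uses 1000)
#' @param seed master seed for the null stage
#' @param tail tail convention, see \code{\link{hypergeomTail}}
#' @return invisibly, the report list (also written as \code{report.json})
#' @export
runPipeline <- function(predictionsFile, gmtFile, mrnaFile, mirnaFile,
                        phenotypeFile, interactionsFile = NULL,
                        outDir = ".", groupA = "A", groupB = "B",
                        minTools = 2L, qThreshold = 0.05,
                        nullIterations = 0L, seed = 1L, tail = "gt") {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  f <- function(x) file.path(outDir, x)
  report <- list(parameters = list(min_tools = as.integer(minTools),
                                   q_threshold = qThreshold,
                                   null_iterations = as.integer(nullIterations),
                                   seed = as.integer(seed), tail = tail,
                                   group_a = groupA, group_b = groupB))

  preds <- stage("read", readPredictions(predictionsFile))
  db <- stage("read", readGmt(gmtFile))
  if (!is.null(interactionsFile))
    db <- stage("read", readInteractions(interactionsFile, db))
  mrna <- stage("read", readExpression(mrnaFile))
  mirna <- stage("read", readExpression(mirnaFile))
  phen <- stage("read", readPhenotypes(phenotypeFile))
  report$counts <- list(prediction_triples = nrow(predictions(preds)),
                        pathways = length(pathwayIds(db)),
                        genes = length(pathwayGenes(db)),
                        samples = nrow(phen))

  pairs <- stage("targets", {
    sp <- filterMinTools(preds, minTools)
    restrictToUniverse(sp, db)
  })
  report$counts$supported_pairs <- nrow(supportedPairs(pairs))
  report$counts$universe_size <- universeSize(pairs)

  assoc <- stage("enrichment",
                 suppressMessages(associateAll(db, pairs, tail = tail)))
  writeAssociations(assoc, f("associations.tsv"))
  ranked <- rankAssociations(assoc)
  ok <- !is.na(ranked$mirna_id)
  report$counts$associations <- sum(ok)
  report$top_association <- if (any(ok))
    as.list(ranked[which(ok)[1], c("pathway_id", "mirna_id", "x", "K", "N",
                                   "M", "p_value", "q_value")]) else NULL

  if (nullIterations > 0) {
    nd <- stage("null_model",
                nullDistribution(pairs, nPathways = length(pathwayIds(db)),
                                 nIterations = nullIterations, seed = seed,
                                 tail = tail))
    obsQ <- assoc@table$q_value[!is.na(assoc@table$q_value)]
    cmpres <- stage("null_model", compareObservedVsNull(obsQ, pooledNullQ(nd)))
    nullSummary <- list(iterations = length(nd@qValues),
                        observed_median_q = median(obsQ),
                        null_median_q = median(pooledNullQ(nd)),
                        iteration_median_q = iterationMedianQ(nd),
                        welch_t = cmpres$statistic, p_value = cmpres$p_value)
    jsonlite::write_json(nullSummary, f("null_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write.table(data.frame(iteration = rep(seq_along(nd@qValues),
                                           lengths(nd@qValues)),
                           q_value = pooledNullQ(nd)),
                f("null_qvalues.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$null <- nullSummary[c("iterations", "observed_median_q",
                                 "null_median_q", "welch_t", "p_value")]
  }

  states <- stage("activity", fitGeneStates(mrna))
  act <- stage("activity", suppressWarnings(pathwayActivity(db, states)))
  writeActivity(act, f("activity.tsv"))

  strat <- stage("phenotype", scanStratification(act, phen, groupA, groupB))
  write.table(strat, f("stratification.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  topStrat <- strat[order(strat$p_value), ][1, ]
  report$top_stratified_pathway <- list(pathway_id = topStrat$pathway_id,
                                        p_value = topStrat$p_value,
                                        q_value = topStrat$q_value)

  ## group-wise correlation of the top association's miRNA with its pathway
  if (!is.null(report$top_association)) {
    top <- report$top_association
    mirMat <- SummarizedExperiment::assay(mirna)
    if (top$mirna_id %in% rownames(mirMat)) {
      corr <- stage("phenotype", groupCorrelation(
        mirMat[top$mirna_id, ],
        SummarizedExperiment::assay(act)[top$pathway_id, ],
        phen, groupA, groupB))
      corDf <- data.frame(pathway_id = top$pathway_id,
                          mirna_id = top$mirna_id,
                          r_a = corr$r_a, n_a = corr$n_a, r_b = corr$r_b,
                          n_b = corr$n_b, z = corr$z, p_value = corr$p_value)
      write.table(corDf, f("correlations.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      report$top_correlation <- as.list(corDf)
    }
    if (!is.null(phen$time)) {
      surv <- stage("phenotype", survivalSplitTest(
        SummarizedExperiment::assay(act)[top$pathway_id, ], phen))
      report$top_survival <- surv[c("statistic", "p_value", "n_high",
                                    "n_low")]
    }
  }

  net <- stage("network", buildNetwork(assoc, qThreshold))
  exportNetwork(net, f("network.sif"), "sif")
  report$counts$network_nodes <- nrow(networkNodes(net))
  report$counts$network_edges <- nrow(networkEdges(net))

  jsonlite::write_json(report, f("report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(report)
}
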