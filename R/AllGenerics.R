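#' @rdname TargetPredictions-class
#' @param object,x an object of the documented class
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))
#' @rdname TargetPredictions-class
#' @export
setMethod("predictions", "TargetPredictions", function(object) object@predictions)

#' @rdname PathwayDb-class
#' @export
setGeneric("pathwayIds", function(object) standardGeneric("pathwayIds"))
#' @rdname PathwayDb-class
#' @export
setMethod("pathwayIds", "PathwayDb", function(object) names(object@geneSets))

#' @rdname PathwayDb-class
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))
#' @rdname PathwayDb-class
#' @export
setMethod("geneSets", "PathwayDb", function(object) object@geneSets)

#' @rdname PathwayDb-class
#' @export
setGeneric("pathwaySizes", function(object) standardGeneric("pathwaySizes"))
#' @rdname PathwayDb-class
#' @export
setMethod("pathwaySizes", "PathwayDb", function(object) lengths(object@geneSets))

#' @rdname PathwayDb-class
#' @export
setGeneric("interactions", function(object) standardGeneric("interactions"))
#' @rdname PathwayDb-class
#' @export
setMethod("interactions", "PathwayDb", function(object) object@interactions)

#' @rdname PathwayDb-class
#' @export
setGeneric("pathwayGenes", function(object) standardGeneric("pathwayGenes"))
#' @rdname PathwayDb-class
#' @export
setMethod("pathwayGenes", "PathwayDb",
          function(object) sort(unique(unlist(object@geneSets, use.names = FALSE))))

#' @rdname SupportedPairs-class
#' @export
setGeneric("supportedPairs", function(object) standardGeneric("supportedPairs"))
#' @rdname SupportedPairs-class
#' @export
setMethod("supportedPairs", "SupportedPairs", function(object) object@pairs)

#' @rdname SupportedPairs-class
#' @export
setGeneric("universeSize", function(object) standardGeneric("universeSize"))
#' @rdname SupportedPairs-class
#' @export
setMethod("universeSize", "SupportedPairs", function(object) object@universeSize)

#' Per-miRNA total target counts K
#'
#' Number of retained target genes for each miRNA in the evidence set (the
#' paper-level quantity K per miRNA). Only meaningful after
#' \code{\link{restrictToUniverse}}.
#'
#' @param object a \linkS4class{SupportedPairs} object
#' @return named integer vector, one entry per miRNA
#' @export
setGeneric("mirnaTargetCounts", function(object) standardGeneric("mirnaTargetCounts"))
#' @rdname mirnaTargetCounts
#' @export
setMethod("mirnaTargetCounts", "SupportedPairs", function(object) {
  if (!nrow(object@pairs)) return(setNames(integer(), character()))
  tab <- table(object@pairs$mirna)
  setNames(as.integer(tab), names(tab))
})

#' @rdname AssociationSet-class
#' @export
setGeneric("associations", function(object) standardGeneric("associations"))
#' @rdname AssociationSet-class
#' @export
setMethod("associations", "AssociationSet", function(object) object@table)

#' @rdname GeneStates-class
#' @export
setGeneric("pUp", function(object) standardGeneric("pUp"))
#' @rdname GeneStates-class
#' @export
setMethod("pUp", "GeneStates", function(object) object@pUp)

#' @rdname GeneStates-class
#' @export
setGeneric("stateFits", function(object) standardGeneric("stateFits"))
#' @rdname GeneStates-class
#' @export
setMethod("stateFits", "GeneStates", function(object) object@fits)

#' Pooled q-values across null iterations
#' @param object a \linkS4class{NullDistribution}
#' @return numeric vector of all null q-values
#' @export
setGeneric("pooledNullQ", function(object) standardGeneric("pooledNullQ"))
#' @rdname pooledNullQ
#' @export
setMethod("pooledNullQ", "NullDistribution",
          function(object) unlist(object@qValues, use.names = FALSE))

#' Per-iteration median q-values
#' @param object a \linkS4class{NullDistribution}
#' @return numeric vector, one median per iteration
#' @export
setGeneric("iterationMedianQ", function(object) standardGeneric("iterationMedianQ"))
#' @rdname iterationMedianQ
#' @export
setMethod("iterationMedianQ", "NullDistribution",
          function(object) vapply(object@qValues, median, numeric(1)))

#' @rdname AssociationNetwork-class
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @rdname AssociationNetwork-class
#' @export
setMethod("networkNodes", "AssociationNetwork", function(object) object@nodes)

#' @rdname AssociationNetwork-class
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname AssociationNetwork-class
#' @export
setMethod("networkEdges", "AssociationNetwork", function(object) object@edges)

#' @rdname ScenarioBundle-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname ScenarioBundle-class
#' @export
setMethod("groundTruth", "ScenarioBundle", function(object) object@groundTruth)

setMethod("show", "TargetPredictions", function(object) {
  df <- object@predictions
  cat("TargetPredictions:", nrow(df), "triples,",
      length(unique(df$mirna)), "miRNAs,", length(unique(df$gene)), "genes,",
      length(unique(df$tool)), "tools")
  if (object@nDuplicatesDropped)
    cat(" (", object@nDuplicatesDropped, " duplicate triples dropped)", sep = "")
  cat("\n")
})

setMethod("show", "PathwayDb", function(object) {
  n <- length(object@geneSets)
  cat("PathwayDb:", n, "pathways,", length(pathwayGenes(object)),
      "distinct genes")
  if (n) cat("; sizes", min(lengths(object@geneSets)), "-",
             max(lengths(object@geneSets)))
  ni <- if (nrow(object@interactions))
    length(unique(paste(object@interactions$pathway_id,
                        object@interactions$interaction_id))) else 0L
  cat(";", ni, "interactions\n")
})

setMethod("show", "SupportedPairs", function(object) {
  cat("SupportedPairs:", nrow(object@pairs), "pairs with >=",
      object@minTools, "tools;")
  if (is.na(object@universeSize)) cat(" not yet restricted to a universe\n")
  else cat(" universe M =", object@universeSize, "\n")
})

setMethod("show", "AssociationSet", function(object) {
  df <- object@table
  ok <- !is.na(df$mirna_id)
  cat("AssociationSet:", nrow(df), "pathways,", sum(ok), "with an associated",
      "miRNA; pi0 =", signif(object@pi0, 3), "\n")
  if (any(ok))
    cat("  q <= 0.05:", sum(df$q_value[ok] <= 0.05), "pathways\n")
})

setMethod("show", "GeneStates", function(object) {
  cat("GeneStates:", nrow(object@pUp), "genes x", ncol(object@pUp),
      "samples;", sum(object@fits$degenerate), "degenerate,",
      sum(!object@fits$converged), "unconverged\n")
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution:", length(object@qValues), "iterations, pathway sizes",
      object@sizeRange[1], "-", object@sizeRange[2], "; pooled median q =",
      signif(median(pooledNullQ(object)), 3), "\n")
})

setMethod("show", "AssociationNetwork", function(object) {
  cat("AssociationNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges (q <=", object@qThreshold, ")\n")
})

setMethod("show", "ScenarioBundle", function(object) {
  gt <- object@groundTruth
  cat("ScenarioBundle:", length(object@pathways@geneSets), "pathways,",
      nrow(object@predictions@predictions), "prediction triples,",
      nrow(object@mrna), "genes x", ncol(object@mrna), "samples\n")
  if (!is.null(gt$primary))
    cat("  primary planted pair:", gt$primary$pathway_id, "<-",
        gt$primary$mirna_id, "\n")
})
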