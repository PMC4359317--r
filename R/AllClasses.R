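#' @import methods
#' @importFrom stats cor dnorm lm median p.adjust phyper pnorm poly predict
#'   quantile rbinom rexp rnorm runif sd setNames t.test var
#' @importFrom utils read.delim write.table
NULL

#' Multi-tool miRNA target predictions
#'
#' Holds (miRNA, gene, tool) prediction triples, the evidence base for the
#' enrichment analysis. Duplicate triples are collapsed on construction;
#' duplicate (miRNA, gene) pairs from different tools are retained because
#' they are the multi-tool support that the downstream filter counts.
#'
#' @slot predictions data.frame with character columns \code{mirna},
#'   \code{gene}, \code{tool}; one row per unique triple.
#' @slot nDuplicatesDropped number of duplicate triples removed on load.
#' @export
setClass("TargetPredictions",
  representation(predictions = "data.frame", nDuplicatesDropped = "integer"),
  prototype(predictions = data.frame(mirna = character(), gene = character(),
                                     tool = character()),
            nDuplicatesDropped = 0L))

setValidity("TargetPredictions", function(object) {
  df <- object@predictions
  need <- c("mirna", "gene", "tool")
  if (!all(need %in% names(df)))
    return(paste("predictions must have columns", paste(need, collapse = ", ")))
  for (cl in need) {
    v <- df[[cl]]
    if (!is.character(v)) return(paste0("column '", cl, "' must be character"))
    if (any(!nzchar(v)) || any(grepl("[[:space:]]", v)))
      return(paste0("column '", cl, "' contains empty or whitespace tokens"))
  }
  if (anyDuplicated(df)) return("duplicate (mirna, gene, tool) triples present")
  TRUE
})

#' Pathway database
#'
#' Named gene sets with optional signed interactions. Each interaction has
#' promoter, inhibitor and output roles; every interaction gene must belong
#' to its pathway's gene set.
#'
#' @slot geneSets named list of character vectors, one per pathway.
#' @slot source named character vector of per-pathway provenance labels.
#' @slot interactions data.frame with columns \code{pathway_id},
#'   \code{interaction_id}, \code{gene}, \code{role} (one of
#'   \code{promoter}, \code{inhibitor}, \code{output}); may have zero rows.
#' @export
setClass("PathwayDb",
  representation(geneSets = "list", source = "character",
                 interactions = "data.frame"),
  prototype(geneSets = list(), source = character(),
            interactions = data.frame(pathway_id = character(),
                                      interaction_id = character(),
                                      gene = character(), role = character())))

setValidity("PathwayDb", function(object) {
  gs <- object@geneSets
  if (length(gs)) {
    if (is.null(names(gs)) || any(!nzchar(names(gs))))
      return("every pathway needs a non-empty id")
    if (anyDuplicated(names(gs))) return("pathway ids must be unique")
    if (any(lengths(gs) == 0L)) return("pathway gene sets must be non-empty")
    if (any(vapply(gs, anyDuplicated, 0L) > 0L))
      return("a pathway gene set may not repeat a gene")
  }
  it <- object@interactions
  need <- c("pathway_id", "interaction_id", "gene", "role")
  if (!all(need %in% names(it)))
    return(paste("interactions must have columns", paste(need, collapse = ", ")))
  if (nrow(it)) {
    if (!all(it$role %in% c("promoter", "inhibitor", "output")))
      return("interaction role must be promoter, inhibitor or output")
    if (!all(it$pathway_id %in% names(gs)))
      return("interaction refers to an unknown pathway_id")
    for (pid in unique(it$pathway_id)) {
      sub <- it[it$pathway_id == pid, ]
      if (!all(sub$gene %in% gs[[pid]]))
        return(paste0("interaction gene outside gene set of pathway '", pid, "'"))
      reg <- tapply(sub$role %in% c("promoter", "inhibitor"),
                    sub$interaction_id, any)
      if (!all(reg))
        return(paste0("an interaction in '", pid,
                      "' has neither promoter nor inhibitor"))
    }
  }
  TRUE
})

#' Tool-supported miRNA-gene pairs
#'
#' The evidence set after the minimum-tool filter, optionally restricted to
#' the pathway gene universe. \code{universeSize} is M, the number of
#' distinct genes across all pathways under analysis (not only predicted
#' targets); it is \code{NA} until \code{\link{restrictToUniverse}} is
#' applied.
#'
#' @slot pairs data.frame with columns \code{mirna}, \code{gene},
#'   \code{support} (number of distinct predicting tools).
#' @slot minTools the minimum tool count k used by the filter.
#' @slot universe character vector of universe gene ids (empty before
#'   restriction).
#' @slot universeSize integer M, \code{NA} before restriction.
#' @export
setClass("SupportedPairs",
  representation(pairs = "data.frame", minTools = "integer",
                 universe = "character", universeSize = "integer"),
  prototype(pairs = data.frame(mirna = character(), gene = character(),
                               support = integer()),
            minTools = 1L, universe = character(),
            universeSize = NA_integer_))

setValidity("SupportedPairs", function(object) {
  df <- object@pairs
  if (!all(c("mirna", "gene", "support") %in% names(df)))
    return("pairs must have columns mirna, gene, support")
  if (nrow(df) && any(df$support < object@minTools))
    return("a pair has support below minTools")
  if (nrow(df) && anyDuplicated(df[c("mirna", "gene")]))
    return("duplicate (mirna, gene) pairs")
  if (!is.na(object@universeSize) &&
      object@universeSize != length(object@universe))
    return("universeSize must equal length(universe)")
  TRUE
})

#' Per-pathway best-miRNA association records
#'
#' One record per pathway: the miRNA with the most supported targets inside
#' the pathway, the counts (x, K, N, M) and the hypergeometric tail p-value,
#' with Storey q-values computed jointly over all records that have an
#' associated miRNA. Pathways no miRNA targets carry \code{NA} in the miRNA
#' and statistic columns and are excluded from the FDR computation.
#'
#' @slot table data.frame with columns \code{pathway_id}, \code{mirna_id},
#'   \code{x}, \code{K}, \code{N}, \code{M}, \code{p_value}, \code{q_value}.
#' @slot minTools the tool filter behind the pair evidence.
#' @slot pi0 the Storey null-proportion estimate used for the q-values.
#' @export
setClass("AssociationSet",
  representation(table = "data.frame", minTools = "integer", pi0 = "numeric"),
  prototype(table = data.frame(pathway_id = character(),
                               mirna_id = character(), x = integer(),
                               K = integer(), N = integer(), M = integer(),
                               p_value = numeric(), q_value = numeric()),
            minTools = 2L, pi0 = NA_real_))

setValidity("AssociationSet", function(object) {
  df <- object@table
  need <- c("pathway_id", "mirna_id", "x", "K", "N", "M", "p_value", "q_value")
  if (!all(need %in% names(df)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  ok <- !is.na(df$mirna_id)
  if (any(ok)) {
    with_na <- function(x) ifelse(is.na(x), FALSE, x)
    if (any(with_na(df$x[ok] > pmin(df$K[ok], df$N[ok]))))
      return("x must satisfy 0 <= x <= min(K, N)")
    if (any(with_na(df$N[ok] > df$M[ok])) || any(with_na(df$K[ok] > df$M[ok])))
      return("N and K may not exceed M")
    p <- df$p_value[ok]; q <- df$q_value[ok]
    if (any(p < 0 | p > 1, na.rm = TRUE) || any(q < 0 | q > 1, na.rm = TRUE))
      return("p_value and q_value must lie in [0, 1]")
  }
  TRUE
})

#' Probabilistic gene states
#'
#' Per-(gene, sample) posterior probability that the gene sits in the upper
#' ("on") component of its two-component Gaussian expression mixture, plus
#' the per-gene fitted model.
#'
#' @slot pUp numeric matrix, genes x samples, values in [0, 1].
#' @slot fits data.frame with one row per gene: \code{gene},
#'   \code{mean_low}, \code{mean_high}, \code{variance}, \code{weight_up},
#'   \code{converged}, \code{degenerate} (constant gene flagged, p = 0.5).
#' @export
setClass("GeneStates",
  representation(pUp = "matrix", fits = "data.frame"),
  prototype(pUp = matrix(numeric(), 0, 0),
            fits = data.frame(gene = character(), mean_low = numeric(),
                              mean_high = numeric(), variance = numeric(),
                              weight_up = numeric(), converged = logical(),
                              degenerate = logical())))

setValidity("GeneStates", function(object) {
  p <- object@pUp
  if (length(p) && (min(p) < 0 || max(p) > 1))
    return("pUp must lie in [0, 1]")
  if (nrow(object@fits) != nrow(p))
    return("fits must have one row per gene")
  TRUE
})

#' Randomized-pathway null distribution
#'
#' The q-value distributions obtained by rebuilding random pathways from the
#' pool of pathway genes and rerunning the best-miRNA association, iteration
#' by iteration.
#'
#' @slot qValues list of numeric vectors, one per iteration.
#' @slot seeds integer vector of per-iteration RNG seeds, derived
#'   deterministically from the master seed.
#' @slot sizeRange integer length-2 vector of the random pathway size range.
#' @export
setClass("NullDistribution",
  representation(qValues = "list", seeds = "integer", sizeRange = "integer"),
  prototype(qValues = list(), seeds = integer(), sizeRange = c(4L, 50L)))

setValidity("NullDistribution", function(object) {
  if (length(object@qValues) != length(object@seeds))
    return("one seed per iteration required")
  TRUE
})

#' Bipartite miRNA-pathway association network
#'
#' Nodes are pathways and miRNAs; edges are best-miRNA associations passing
#' a q-value threshold. Isolated nodes are omitted, so the network is
#' bipartite by construction and has at most one edge per pathway.
#'
#' @slot nodes data.frame with columns \code{id}, \code{type} ("mirna" or
#'   "pathway").
#' @slot edges data.frame with columns \code{mirna_id}, \code{pathway_id},
#'   \code{q_value}.
#' @slot qThreshold the inclusion threshold used.
#' @export
setClass("AssociationNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 qThreshold = "numeric"),
  prototype(nodes = data.frame(id = character(), type = character()),
            edges = data.frame(mirna_id = character(),
                               pathway_id = character(), q_value = numeric()),
            qThreshold = 0.05))

setValidity("AssociationNetwork", function(object) {
  e <- object@edges; n <- object@nodes
  if (nrow(e)) {
    if (anyDuplicated(e$pathway_id))
      return("at most one edge (best miRNA) per pathway")
    if (!all(c(e$mirna_id, e$pathway_id) %in% n$id))
      return("edge endpoint missing from node table")
    tp <- setNames(n$type, n$id)
    if (!all(tp[e$mirna_id] == "mirna") || !all(tp[e$pathway_id] == "pathway"))
      return("edges must connect a miRNA to a pathway")
  }
  TRUE
})

#' Synthetic scenario configuration
#'
#' Parameters of the synthetic study: pathway and universe geometry, the
#' multi-tool prediction background, the planted miRNA-pathway regulation,
#' the expression model, the group contrast and the survival model. The
#' defaults are the package's reference study conditions; see the methods
#' vignette for the rationale behind each value.
#'
#' @slot nPathways number of pathways (default 100).
#' @slot sizeRange pathway size range, inclusive (default 4..50).
#' @slot nGenes universe size before pathway membership (default 1500).
#' @slot nMirnas number of miRNAs (default 300).
#' @slot nTools number of prediction tools (default 8).
#' @slot backgroundPairProb probability a background (miRNA, gene) pair is
#'   predicted at all (default 0.01).
#' @slot supportProbs probabilities of 1, 2, 3 supporting tools for a
#'   background pair (default 0.50/0.35/0.15, so about half pass k = 2).
#' @slot plantedFraction fraction of a pathway's genes targeted by its
#'   planted miRNA (default 0.5).
#' @slot primaryFraction planted fraction for the primary pathway
#'   (default 0.8; the primary pathway also takes size sizeRange[2] so the
#'   ground-truth top association is unambiguous).
#' @slot plantAll if TRUE every pathway gets a planted miRNA (the reference
#'   condition); if FALSE only the primary pathway is planted; set
#'   \code{plantedFraction = 0} via \code{noSignal} for a null bundle.
#' @slot noSignal if TRUE no association, shift or correlation is planted.
#' @slot extraTargetRange range of out-of-pathway targets each planted miRNA
#'   receives (default 30..90), so planted miRNAs have K well above x.
#' @slot nSamplesPerGroup samples per phenotype group (default 100).
#' @slot noiseSd expression noise SD sigma (default 1).
#' @slot modeSeparation distance between the two expression modes in SD
#'   units (default 3).
#' @slot delta planted group-A activity shift on primary-pathway genes, in
#'   SD units (default 2).
#' @slot rho planted miRNA-target correlation in group A (default -0.6).
#' @slot positiveFraction fraction of the primary miRNA's planted targets
#'   correlated with sign opposite to rho (default 0.5).
#' @slot hazardRatio group-B vs group-A hazard ratio for exponential
#'   survival (default 3).
#' @slot medianSurvivalA group-A median survival in days (default 1000,
#'   censored at 3000).
#' @slot seed master seed; every random draw derives from it.
#' @export
setClass("ScenarioConfig",
  representation(nPathways = "integer", sizeRange = "integer",
                 nGenes = "integer", nMirnas = "integer", nTools = "integer",
                 backgroundPairProb = "numeric", supportProbs = "numeric",
                 plantedFraction = "numeric", primaryFraction = "numeric",
                 plantAll = "logical", noSignal = "logical",
                 extraTargetRange = "integer", nSamplesPerGroup = "integer",
                 noiseSd = "numeric", modeSeparation = "numeric",
                 delta = "numeric", rho = "numeric",
                 positiveFraction = "numeric", hazardRatio = "numeric",
                 medianSurvivalA = "numeric", seed = "integer"),
  prototype(nPathways = 100L, sizeRange = c(4L, 50L), nGenes = 1500L,
            nMirnas = 300L, nTools = 8L, backgroundPairProb = 0.01,
            supportProbs = c(0.50, 0.35, 0.15), plantedFraction = 0.5,
            primaryFraction = 0.8, plantAll = TRUE, noSignal = FALSE,
            extraTargetRange = c(30L, 90L), nSamplesPerGroup = 100L,
            noiseSd = 1, modeSeparation = 3, delta = 2, rho = -0.6,
            positiveFraction = 0.5, hazardRatio = 3, medianSurvivalA = 1000,
            seed = 1L))

setValidity("ScenarioConfig", function(object) {
  if (object@nPathways < 1L || object@nGenes < 1L || object@nMirnas < 1L)
    return("all counts must be positive")
  if (length(object@sizeRange) != 2L || object@sizeRange[1] < 1L ||
      object@sizeRange[1] > object@sizeRange[2])
    return("sizeRange must be an increasing pair of positive sizes")
  if (object@sizeRange[2] > object@nGenes)
    return("largest pathway may not exceed the gene universe")
  if (!object@noSignal &&
      (object@plantedFraction <= 0 || object@plantedFraction > 1))
    return("plantedFraction must lie in (0, 1]")
  if (object@rho <= -1 || object@rho >= 1) return("rho must lie in (-1, 1)")
  if (abs(sum(object@supportProbs) - 1) > 1e-8)
    return("supportProbs must sum to 1")
  if (!object@noSignal &&
      object@plantedFraction * object@sizeRange[1] < 1)
    return("plantedFraction x smallest pathway size must reach 1 gene")
  TRUE
})

#' Synthetic data bundle with planted ground truth
#'
#' Everything one pipeline run consumes, generated from a
#' \linkS4class{ScenarioConfig}: pathway database with interactions, target
#' predictions, mRNA and miRNA expression, phenotypes with survival, and the
#' planted ground truth.
#'
#' @slot pathways \linkS4class{PathwayDb}.
#' @slot predictions \linkS4class{TargetPredictions}.
#' @slot mrna SummarizedExperiment of gene expression (assay "exprs").
#' @slot mirna SummarizedExperiment of miRNA expression (assay "exprs").
#' @slot phenotypes S4Vectors DataFrame: \code{sample}, \code{group},
#'   \code{time}, \code{event}.
#' @slot groundTruth list: planted pairs, primary pair, planted target gene
#'   signs, delta, rho, hazard ratio, seed.
#' @export
setClass("ScenarioBundle",
  representation(pathways = "PathwayDb", predictions = "TargetPredictions",
                 mrna = "ANY", mirna = "ANY", phenotypes = "ANY",
                 groundTruth = "list"))
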