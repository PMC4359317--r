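# Shared fixtures and independent oracles, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive-enumeration oracle for the hypergeometric tail: enumerate every
# N-subset of a universe of M genes whose first K are the miRNA's targets and
# count draws with more than x targets. Independent of the package's
# log-space summation path.
enumTailOracle <- function(x, K, N, M) {
  draws <- utils::combn(M, N)
  hits <- colSums(draws <= K)
  mean(hits > x)
}

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toyPredictionsDf <- function() {
  # 2 miRNAs x 3 genes, tools A/B -> 6 rows
  data.frame(mirna = rep(c("mirX", "mirY"), each = 3),
             gene = rep(c("gA", "gB", "gC"), 2),
             tool = rep(c("toolA", "toolB", "toolA"), 2),
             stringsAsFactors = FALSE)
}

toyPathwayDb <- function() {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("P1\tsrc\tgA\tgB\tgC", "P2\tsrc\tgB\tgD"), gmt)
  readGmt(gmt)
}

makeStates <- function(pUp) {
  # wrap a hand-written p_up matrix as a GeneStates object
  fits <- data.frame(gene = rownames(pUp), mean_low = 0, mean_high = 1,
                     variance = 1, weight_up = 0.5, converged = TRUE,
                     degenerate = FALSE, stringsAsFactors = FALSE)
  new("GeneStates", pUp = pUp, fits = fits)
}

makePhenotypes <- function(samples, groups, time = NULL, event = NULL) {
  df <- S4Vectors::DataFrame(sample = samples, group = factor(groups),
                             row.names = samples)
  if (!is.null(time)) {
    df$time <- time
    df$event <- event
  }
  df
}

# small bundle for fast pipeline-level tests
smallConfig <- function(seed = 1, ...) {
  scenarioConfig(nPathways = 25, nGenes = 400, nMirnas = 60,
                 nSamplesPerGroup = 25, sizeRange = c(4L, 20L),
                 extraTargetRange = c(10L, 30L), seed = seed, ...)
}
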