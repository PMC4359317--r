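#' Filter miRNA-gene pairs by minimum tool support
#'
#' Keeps the (miRNA, gene) pairs predicted by at least \code{minTools}
#' distinct tools. The default of 2 is the consensus rule used throughout
#' the analysis: a pair counts as evidence only when at least two of the
#' prediction tools agree on it.
#'
#' @param predictions a \linkS4class{TargetPredictions}
#' @param minTools minimum number of distinct supporting tools (k >= 1)
#' @return a \linkS4class{SupportedPairs}, not yet restricted to a universe
#' @export
filterMinTools <- function(predictions, minTools = 2L) {
  stopifnot(is(predictions, "TargetPredictions"))
  minTools <- as.integer(minTools)
  if (is.na(minTools) || minTools < 1L) stop("minTools must be >= 1")
  df <- predictions@predictions
  if (nrow(df)) {
    key <- paste(df$mirna, df$gene, sep = "\r")
    supp <- table(key)   # triples are unique, so rows per key = distinct tools
    keep <- names(supp)[supp >= minTools]
    parts <- strsplit(keep, "\r", fixed = TRUE)
    out <- data.frame(mirna = vapply(parts, `[[`, "", 1L),
                      gene = vapply(parts, `[[`, "", 2L),
                      support = as.integer(supp[keep]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$mirna, out$gene), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(mirna = character(), gene = character(),
                      support = integer())
  }
  new("SupportedPairs", pairs = out, minTools = minTools)
}

#' Restrict supported pairs to the pathway gene universe
#'
#' Drops pairs whose gene belongs to no pathway and fixes the universe size
#' M as the number of distinct genes across all pathways under analysis.
#' Pathway genes that are nobody's predicted target still count in M: M is
#' the number of genes "tested", not the number of targets.
#'
#' @param pairs a \linkS4class{SupportedPairs}
#' @param db a \linkS4class{PathwayDb}
#' @return the restricted \linkS4class{SupportedPairs} with universe set
#' @export
restrictToUniverse <- function(pairs, db) {
  stopifnot(is(pairs, "SupportedPairs"), is(db, "PathwayDb"))
  uni <- pathwayGenes(db)
  df <- pairs@pairs
  df <- df[df$gene %in% uni, , drop = FALSE]
  if (!nrow(df))
    stop("no overlap between predictions and pathways")
  rownames(df) <- NULL
  new("SupportedPairs", pairs = df, minTools = pairs@minTools,
      universe = uni, universeSize = length(uni))
}
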