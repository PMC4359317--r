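#' Hypergeometric tail probability of a miRNA-pathway overlap
#'
#' Probability of more than \code{x} of a miRNA's \code{K} target genes
#' falling inside a pathway of \code{N} genes drawn from a universe of
#' \code{M} genes:
#' \deqn{p = 1 - \sum_{i=0}^{x} \binom{K}{i}\binom{M-K}{N-i} / \binom{M}{N}.}
#' Note the strict inequality: the sum runs through \code{x} itself, so the
#' statistic is P(X > x), one term smaller than the conventional enrichment
#' tail P(X >= x). \code{tail = "geq"} gives the conventional tail instead.
#' Terms are accumulated from log-space binomials for numerical stability.
#'
#' @param x observed number of targeted genes inside the pathway
#' @param K the miRNA's total number of target genes in the universe
#' @param N the pathway size
#' @param M the universe size (total genes tested)
#' @param tail \code{"gt"} for P(X > x) (default), \code{"geq"} for
#'   P(X >= x)
#' @details The complement is evaluated as the direct sum over the upper
#'   tail, \eqn{\sum_{i=x+1}^{\min(K,N)}}, which is algebraically identical
#'   to the one-minus form above but does not cancel to zero when the
#'   tail is far below machine precision.
#' @return tail probability in [0, 1]; vectorized over \code{x} and \code{K}
#' @examples
#' hypergeomTail(6, 124, 13, 1460)   # ~3e-05
#' @export
hypergeomTail <- function(x, K, N, M, tail = c("gt", "geq")) {
  tail <- match.arg(tail)
  n <- max(length(x), length(K), length(N), length(M))
  x <- rep_len(as.numeric(x), n); K <- rep_len(as.numeric(K), n)
  N <- rep_len(as.numeric(N), n); M <- rep_len(as.numeric(M), n)
  if (any(is.na(x) | is.na(K) | is.na(N) | is.na(M)))
    stop("hypergeomTail: NA argument")
  if (any(x < 0 | N < 0 | K < 0 | M < 0 | x > N | N > M | K > M))
    stop("hypergeomTail: need 0 <= x <= N <= M and 0 <= K <= M")
  if (tail == "geq") x <- x - 1
  vapply(seq_len(n), function(j) {
    xj <- x[j]; Kj <- K[j]; Nj <- N[j]; Mj <- M[j]
    if (xj < 0) return(1)                 # geq tail at x = 0
    if (xj >= min(Kj, Nj)) return(0)      # support exhausted: X cannot exceed x
    i <- (xj + 1):min(Kj, Nj)
    logTerms <- lchoose(Kj, i) + lchoose(Mj - Kj, Nj - i) - lchoose(Mj, Nj)
    mx <- max(logTerms)
    min(max(exp(mx) * sum(exp(logTerms - mx)), 0), 1)
  }, numeric(1))
}

#' Best miRNA for one gene set
#'
#' Selects the miRNA with the most supported targets inside the given gene
#' set (the largest x). Ties are broken by the smaller tail p-value, then by
#' lexicographic miRNA id, so the choice is deterministic and independent of
#' input ordering.
#'
#' @param genes character vector of the pathway's genes
#' @param pairs a universe-restricted \linkS4class{SupportedPairs}
#' @param tail tail convention passed to \code{\link{hypergeomTail}}
#' @return list with \code{mirna_id}, \code{x}, \code{K}, \code{p_value},
#'   or NULL when no miRNA targets any of the genes
#' @export
bestMirna <- function(genes, pairs, tail = "gt") {
  stopifnot(length(genes) >= 1L, is(pairs, "SupportedPairs"))
  if (is.na(pairs@universeSize))
    stop("pairs must be restricted to the pathway universe first")
  df <- pairs@pairs
  hit <- df[df$gene %in% genes, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  xs <- table(hit$mirna)
  xmax <- max(xs)
  cand <- names(xs)[xs == xmax]
  Kall <- mirnaTargetCounts(pairs)
  ps <- hypergeomTail(xmax, Kall[cand], length(unique(genes)),
                      pairs@universeSize, tail = tail)
  pick <- cand[order(ps, cand)][1]
  list(mirna_id = pick, x = as.integer(xmax),
       K = as.integer(Kall[[pick]]),
       p_value = ps[[match(pick, cand)]])
}

## Best-miRNA selection for all pathways at once through one sparse
## gene x miRNA product; identical tie-breaking to bestMirna().
.associateCore <- function(geneSets, pairs, tail) {
  df <- pairs@pairs
  uni <- pairs@universe
  M <- pairs@universeSize
  mirs <- sort(unique(df$mirna))
  A <- Matrix::sparseMatrix(i = match(df$gene, uni),
                            j = match(df$mirna, mirs),
                            x = 1, dims = c(length(uni), length(mirs)))
  P <- Matrix::sparseMatrix(
    i = rep(seq_along(geneSets), lengths(geneSets)),
    j = match(unlist(geneSets, use.names = FALSE), uni),
    x = 1, dims = c(length(geneSets), length(uni)))
  X <- as.matrix(P %*% A)                 # pathways x miRNAs overlap counts
  K <- Matrix::colSums(A)
  N <- lengths(geneSets)
  res <- data.frame(pathway_id = names(geneSets),
                    mirna_id = NA_character_, x = NA_integer_,
                    K = NA_integer_, N = as.integer(N), M = as.integer(M),
                    p_value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(geneSets)) {
    xmax <- max(X[i, ])
    if (xmax == 0) next
    cand <- which(X[i, ] == xmax)
    ps <- hypergeomTail(xmax, K[cand], N[i], M, tail = tail)
    pick <- cand[order(ps, mirs[cand])][1]
    res$mirna_id[i] <- mirs[pick]
    res$x[i] <- as.integer(xmax)
    res$K[i] <- as.integer(K[pick])
    res$p_value[i] <- ps[[match(pick, cand)]]
  }
  res
}

#' Associate every pathway with its best miRNA
#'
#' For each pathway, selects the single miRNA with the most supported
#' targets inside it, scores the overlap with the hypergeometric tail, and
#' corrects across pathways with Storey q-values. Pathways that no miRNA
#' targets are reported with \code{NA} statistics and excluded from the
#' q-value computation (their tail probability would be near 1 and
#' uninformative).
#'
#' @param db a \linkS4class{PathwayDb}
#' @param pairs a \linkS4class{SupportedPairs}; restricted to \code{db}'s
#'   universe automatically when its universe is unset
#' @param tail tail convention, see \code{\link{hypergeomTail}}
#' @param pi0 optional fixed Storey null proportion (e.g. 1 for
#'   Benjamini-Hochberg behaviour); estimated from the p-values when NULL
#' @return an \linkS4class{AssociationSet}
#' @export
associateAll <- function(db, pairs, tail = "gt", pi0 = NULL) {
  stopifnot(is(db, "PathwayDb"), is(pairs, "SupportedPairs"))
  if (!length(db@geneSets)) stop("empty pathway database")
  if (!nrow(pairs@pairs)) stop("empty pair evidence set")
  if (is.na(pairs@universeSize)) pairs <- restrictToUniverse(pairs, db)
  res <- .associateCore(db@geneSets, pairs, tail)
  ok <- !is.na(res$p_value)
  if (any(!ok))
    message(sum(!ok), " pathway(s) with no targeting miRNA excluded from FDR")
  res$q_value <- NA_real_
  pi0hat <- NA_real_
  if (any(ok)) {
    sq <- storeyQvalues(res$p_value[ok], pi0 = pi0)
    res$q_value[ok] <- sq
    pi0hat <- attr(sq, "pi0")
  }
  new("AssociationSet", table = res, minTools = pairs@minTools,
      pi0 = pi0hat)
}

#' Storey q-values
#'
#' False-discovery-rate adjusted p-values with the null proportion
#' \eqn{\pi_0} estimated from the p-value distribution: for each
#' \eqn{\lambda} in the grid, \eqn{\hat\pi_0(\lambda) = \#\{p >
#' \lambda\} / (m(1-\lambda))}; the grid values are smoothed by a cubic
#' polynomial fit and the fit is evaluated at the largest \eqn{\lambda},
#' then clipped to (0, 1]. q-values are the step-up
#' \eqn{q_{(i)} = \hat\pi_0 \min_{j \ge i} m p_{(j)} / j}, which reduces to
#' Benjamini-Hochberg when \eqn{\pi_0 = 1}.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @param lambda grid of lambda values in [0, 1) for the pi0 estimate
#' @param pi0 optional fixed pi0 overriding the estimate
#' @return numeric vector of q-values in input order, with the pi0 used
#'   attached as attribute \code{"pi0"}
#' @export
storeyQvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                          pi0 = NULL) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (any(lambda < 0 | lambda >= 1)) stop("lambda grid must lie in [0, 1)")
  m <- length(p)
  if (is.null(pi0)) {
    lambda <- sort(lambda)
    pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    if (length(lambda) >= 4L) {
      fit <- lm(pi0l ~ poly(lambda, 3))
      pi0 <- predict(fit, data.frame(lambda = max(lambda)))[[1]]
    } else {
      pi0 <- pi0l[length(pi0l)]
    }
    pi0 <- min(max(pi0, 1e-8), 1)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  }
  o <- order(p)
  qs <- pi0 * m * p[o] / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  qs <- pmin(qs, 1)
  out <- numeric(m)
  out[o] <- qs
  attr(out, "pi0") <- pi0
  out
}

#' Write an association table
#'
#' TSV with columns pathway_id, mirna_id, x, K, N, M, p_value, q_value
#' (the package's analogue of a full per-pathway association supplement).
#'
#' @param object an \linkS4class{AssociationSet}
#' @param path output TSV path
#' @export
writeAssociations <- function(object, path) {
  write.table(object@table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Rank associations by significance
#'
#' Orders the association table by q-value, then p-value, then descending
#' overlap x, then pathway id; ties are therefore resolved
#' deterministically. Pathways without an associated miRNA sort last.
#'
#' @param object an \linkS4class{AssociationSet}
#' @return the ordered association data.frame
#' @export
rankAssociations <- function(object) {
  df <- object@table
  ord <- order(is.na(df$mirna_id), df$q_value, df$p_value, -xtfrm(df$x),
               df$pathway_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}
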