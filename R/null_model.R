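#' Build a randomized pathway database
#'
#' Draws \code{nPathways} random "pathways" from a pool of gene ids: each
#' size uniform on [\code{sizeMin}, \code{sizeMax}], genes sampled uniformly
#' without replacement within a pathway (and with replacement across
#' pathways). Fully determined by \code{seed}.
#'
#' @param pool character vector of candidate gene ids (typically the genes
#'   that are members of any observed pathway)
#' @param nPathways number of random pathways
#' @param sizeMin,sizeMax inclusive size range (defaults 4 and 50)
#' @param seed integer RNG seed
#' @return a \linkS4class{PathwayDb} with ids \code{rand0001}, ...
#' @export
randomPathwaySet <- function(pool, nPathways, sizeMin = 4L, sizeMax = 50L,
                             seed = 1L) {
  if (sizeMin < 1L) stop("sizeMin must be >= 1")
  if (sizeMin > sizeMax) stop("sizeMin must not exceed sizeMax")
  if (length(pool) < sizeMax)
    stop("gene pool smaller than the largest pathway size")
  set.seed(as.integer(seed))
  sizes <- sizeMin +
    sample.int(sizeMax - sizeMin + 1L, nPathways, replace = TRUE) - 1L
  gs <- lapply(sizes, function(s) sample(pool, s))
  names(gs) <- sprintf("rand%04d", seq_len(nPathways))
  new("PathwayDb", geneSets = gs,
      source = setNames(rep("random", nPathways), names(gs)))
}

#' Randomized-pathway null distribution of association q-values
#'
#' Repeats the best-miRNA association on random pathway sets built from the
#' observed pathway-gene pool: per iteration, random pathways are drawn,
#' every pathway gets its best miRNA and hypergeometric tail p-value, and
#' Storey q-values are computed within the iteration. The universe size M is
#' held at the observed value (the random sets are drawn from the same pool
#' of tested genes, so the number of genes tested does not change).
#' Per-iteration seeds are derived deterministically from the master seed,
#' so results do not depend on execution order.
#'
#' @param pairs a universe-restricted \linkS4class{SupportedPairs} (the same
#'   evidence set used for the observed associations)
#' @param nPathways random pathways per iteration (match the observed count)
#' @param nIterations number of iterations (the reference analysis uses
#'   1000; scale down for quick checks)
#' @param sizeMin,sizeMax random pathway size range
#' @param seed master seed
#' @param tail tail convention, see \code{\link{hypergeomTail}}
#' @return a \linkS4class{NullDistribution}
#' @export
nullDistribution <- function(pairs, nPathways, nIterations = 1000L,
                             sizeMin = 4L, sizeMax = 50L, seed = 1L,
                             tail = "gt") {
  stopifnot(is(pairs, "SupportedPairs"))
  if (nIterations < 1L) stop("nIterations must be >= 1")
  if (is.na(pairs@universeSize))
    stop("pairs must be restricted to the pathway universe first")
  seeds <- as.integer((as.integer(seed) + 11L * seq_len(nIterations)) %%
                        .Machine$integer.max)
  qv <- vector("list", nIterations)
  for (it in seq_len(nIterations)) {
    db <- randomPathwaySet(pairs@universe, nPathways, sizeMin, sizeMax,
                           seed = seeds[it])
    res <- .associateCore(db@geneSets, pairs, tail)
    ok <- !is.na(res$p_value)
    qv[[it]] <- if (any(ok)) as.numeric(storeyQvalues(res$p_value[ok]))
                else numeric()
  }
  new("NullDistribution", qValues = qv, seeds = seeds,
      sizeRange = c(as.integer(sizeMin), as.integer(sizeMax)))
}

#' Compare observed and null q-value distributions
#'
#' Welch two-sample t-test of the observed q-values against the pooled null
#' q-values, the package's analogue of testing whether randomized pathways
#' show systematically higher FDR-adjusted p-values than curated ones. When
#' both samples are constant the test degenerates: equal constants give
#' t = 0, p = 1; distinct constants give p = 0 with a warning.
#'
#' @param observedQ numeric vector of observed q-values
#' @param nullQ numeric vector of pooled null q-values (see
#'   \code{\link{pooledNullQ}})
#' @return list with \code{statistic} (Welch t), \code{p_value},
#'   \code{observed_mean}, \code{null_mean}
#' @export
compareObservedVsNull <- function(observedQ, nullQ) {
  if (length(observedQ) < 2L || length(nullQ) < 2L)
    stop("need at least 2 values per sample")
  if (sd(observedQ) == 0 && sd(nullQ) == 0) {
    if (observedQ[1] == nullQ[1])
      return(list(statistic = 0, p_value = 1,
                  observed_mean = mean(observedQ), null_mean = mean(nullQ)))
    warning("both samples constant but unequal; returning p = 0")
    return(list(statistic = sign(observedQ[1] - nullQ[1]) * Inf, p_value = 0,
                observed_mean = mean(observedQ), null_mean = mean(nullQ)))
  }
  tt <- t.test(observedQ, nullQ, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       observed_mean = mean(observedQ), null_mean = mean(nullQ))
}
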