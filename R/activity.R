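#' Fit probabilistic gene states from expression
#'
#' Per gene, fits a two-component Gaussian mixture across all samples by EM
#' and returns the posterior probability of the higher-mean ("up")
#' component per sample. The fit is deterministic: components are
#' initialized at the 25th and 75th expression percentiles with a shared
#' variance, the shared variance is floored at \code{varFloorFrac} times the
#' gene's variance, and EM runs to parameter tolerance \code{tol} or
#' \code{maxIter} iterations. All genes iterate together on a shrinking
#' active set, so the fit is fast for expression-sized matrices.
#' Constant (zero-variance) genes cannot be assigned a state and get
#' p_up = 0.5 everywhere, flagged \code{degenerate}.
#'
#' @param expr SummarizedExperiment (first assay) or numeric matrix,
#'   features x samples
#' @param tol parameter-change convergence tolerance (default 1e-8)
#' @param maxIter maximum EM iterations (default 500)
#' @param varFloorFrac shared-variance floor as a fraction of the gene
#'   variance (default 1e-4)
#' @param minSamples minimum sample count for mixture fitting (default 8);
#'   below it the fit degrades to the degenerate p_up = 0.5 state with a
#'   warning rather than fitting an unidentifiable mixture
#' @return a \linkS4class{GeneStates}
#' @export
fitGeneStates <- function(expr, tol = 1e-8, maxIter = 500L,
                          varFloorFrac = 1e-4, minSamples = 8L) {
  Y <- if (is.matrix(expr)) expr else SummarizedExperiment::assay(expr)
  if (!is.numeric(Y) || any(!is.finite(Y)))
    stop("expression must be a finite numeric matrix")
  if (is.null(rownames(Y))) stop("expression needs feature names")
  G <- nrow(Y); S <- ncol(Y)
  if (S < minSamples) {
    warning("fewer than ", minSamples,
            " samples: gene states degenerate to p_up = 0.5")
    pUp <- matrix(0.5, G, S, dimnames = dimnames(Y))
    fits <- data.frame(gene = rownames(Y), mean_low = rowMeans(Y),
                       mean_high = rowMeans(Y),
                       variance = apply(Y, 1, var), weight_up = 0.5,
                       converged = FALSE, degenerate = TRUE,
                       stringsAsFactors = FALSE)
    return(new("GeneStates", pUp = pUp, fits = fits))
  }
  v <- apply(Y, 1, var)
  degen <- v < 1e-12
  mu1 <- apply(Y, 1, quantile, 0.25, names = FALSE)
  mu2 <- apply(Y, 1, quantile, 0.75, names = FALSE)
  s2 <- pmax(v / 4, 1e-8)
  w <- rep(0.5, G)
  floorv <- pmax(varFloorFrac * v, 1e-12)
  conv <- degen    # degenerate genes do not iterate
  active <- which(!conv)
  for (it in seq_len(maxIter)) {
    if (!length(active)) break
    Ya <- Y[active, , drop = FALSE]
    sa <- sqrt(s2[active])
    d1 <- dnorm(Ya, mu1[active], sa) * (1 - w[active])
    d2 <- dnorm(Ya, mu2[active], sa) * w[active]
    tot <- d1 + d2
    tot[tot == 0] <- 1
    R <- d2 / tot
    r2 <- rowSums(R)
    wNew <- r2 / S
    mu2New <- rowSums(R * Ya) / pmax(r2, 1e-12)
    mu1New <- rowSums((1 - R) * Ya) / pmax(S - r2, 1e-12)
    s2New <- pmax(rowSums(R * (Ya - mu2New)^2 +
                            (1 - R) * (Ya - mu1New)^2) / S, floorv[active])
    delta <- pmax(abs(mu1New - mu1[active]), abs(mu2New - mu2[active]),
                  abs(s2New - s2[active]), abs(wNew - w[active]))
    mu1[active] <- mu1New; mu2[active] <- mu2New
    s2[active] <- s2New; w[active] <- wNew
    done <- delta < tol
    conv[active[done]] <- TRUE
    active <- active[!done]
  }
  d1 <- dnorm(Y, mu1, sqrt(s2)) * (1 - w)
  d2 <- dnorm(Y, mu2, sqrt(s2)) * w
  tot <- d1 + d2
  tot[tot == 0] <- 1
  pUp <- d2 / tot
  flip <- mu2 < mu1   # ensure p_up refers to the higher-mean component
  pUp[flip, ] <- 1 - pUp[flip, ]
  pUp[degen, ] <- 0.5
  pUp <- pmin(pmax(pUp, 0), 1)
  dimnames(pUp) <- dimnames(Y)
  fits <- data.frame(gene = rownames(Y),
                     mean_low = pmin(mu1, mu2), mean_high = pmax(mu1, mu2),
                     variance = s2,
                     weight_up = ifelse(flip, 1 - w, w),
                     converged = conv & !degen, degenerate = degen,
                     stringsAsFactors = FALSE)
  fits$mean_low[degen] <- fits$mean_high[degen] <- rowMeans(Y)[degen]
  new("GeneStates", pUp = pUp, fits = fits)
}

#' Likelihood that one interaction occurs
#'
#' The probability that all promoter genes are in their up state and all
#' inhibitor genes are in their down state:
#' \deqn{\prod_{g \in promoters} p_{up}(g, s) \prod_{g \in inhibitors}
#'   (1 - p_{up}(g, s)).}
#' Output-role genes do not enter the product.
#'
#' @param states a \linkS4class{GeneStates}
#' @param promoters character vector of promoter gene ids
#' @param inhibitors character vector of inhibitor gene ids (may be empty)
#' @return numeric vector over samples, values in [0, 1]
#' @export
interactionActivity <- function(states, promoters, inhibitors = character()) {
  p <- states@pUp
  miss <- setdiff(c(promoters, inhibitors), rownames(p))
  if (length(miss))
    stop("gene(s) absent from gene states: ", paste(miss, collapse = ", "))
  out <- rep(1, ncol(p))
  if (length(promoters))
    out <- out * apply(p[promoters, , drop = FALSE], 2, prod)
  if (length(inhibitors))
    out <- out * apply(1 - p[inhibitors, , drop = FALSE], 2, prod)
  setNames(out, colnames(p))
}

#' Per-sample pathway activity scores
#'
#' For pathways with interactions, the activity of a sample is the mean
#' over the pathway's interactions of the interaction likelihood.
#' Interactions referring to genes missing from the expression data are
#' skipped with a warning; a pathway with more than half of its
#' interactions skipped is flagged low-coverage. Pathways without
#' interaction annotation fall back to the mean of p_up over their
#' measurable genes. A pathway with no measurable gene at all yields a row
#' of NaN and is flagged for downstream exclusion.
#'
#' @param db a \linkS4class{PathwayDb}
#' @param states a \linkS4class{GeneStates}
#' @return SummarizedExperiment, pathways x samples, assay
#'   \code{activity} in [0, 1]; rowData columns \code{n_interactions_used},
#'   \code{low_coverage}, \code{measurable}
#' @export
pathwayActivity <- function(db, states) {
  stopifnot(is(db, "PathwayDb"), is(states, "GeneStates"))
  p <- states@pUp
  ids <- names(db@geneSets)
  act <- matrix(NA_real_, length(ids), ncol(p),
                dimnames = list(ids, colnames(p)))
  nUsed <- integer(length(ids))
  lowCov <- logical(length(ids))
  measurable <- logical(length(ids))
  it <- db@interactions
  nSkipped <- 0L
  for (i in seq_along(ids)) {
    pid <- ids[i]
    sub <- it[it$pathway_id == pid, , drop = FALSE]
    if (nrow(sub)) {
      vals <- NULL
      nTot <- 0L
      for (iid in unique(sub$interaction_id)) {
        nTot <- nTot + 1L
        ss <- sub[sub$interaction_id == iid, ]
        prom <- ss$gene[ss$role == "promoter"]
        inhb <- ss$gene[ss$role == "inhibitor"]
        if (!all(c(prom, inhb) %in% rownames(p))) {
          nSkipped <- nSkipped + 1L
          next
        }
        vals <- rbind(vals, interactionActivity(states, prom, inhb))
      }
      nUsed[i] <- if (is.null(vals)) 0L else nrow(vals)
      lowCov[i] <- nUsed[i] < nTot / 2
      if (!is.null(vals)) {
        act[i, ] <- colMeans(vals)
        measurable[i] <- TRUE
        next
      }
    }
    ## gene-set fallback: mean p_up over measurable pathway genes
    genes <- intersect(db@geneSets[[pid]], rownames(p))
    if (length(genes)) {
      act[i, ] <- colMeans(p[genes, , drop = FALSE])
      measurable[i] <- TRUE
    } else {
      act[i, ] <- NaN
    }
  }
  if (nSkipped)
    warning(nSkipped, " interaction(s) skipped: gene(s) missing from ",
            "expression data")
  if (any(!measurable))
    warning(sum(!measurable), " pathway(s) with no measurable gene: ",
            "activity is NaN")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(activity = act),
    rowData = S4Vectors::DataFrame(n_interactions_used = nUsed,
                                   low_coverage = lowCov,
                                   measurable = measurable,
                                   row.names = ids))
}

#' Write an activity matrix
#' @param act SummarizedExperiment from \code{\link{pathwayActivity}}
#' @param path output TSV path
#' @export
writeActivity <- function(act, path) {
  writeExpression(SummarizedExperiment::assay(act), path,
                  idColumn = "pathway_id")
}
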