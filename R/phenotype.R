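#' Group stratification test on one pathway activity row
#'
#' Welch two-sample t-test of a pathway's activity between two phenotype
#' groups (e.g. ER+ vs ER-).
#'
#' @param values named numeric vector of per-sample activity (names are
#'   sample ids)
#' @param phenotypes DataFrame as from \code{\link{readPhenotypes}}
#' @param groupA,groupB the two group labels to contrast
#' @return list with \code{test} = "t_test", \code{statistic},
#'   \code{p_value}, \code{mean_a}, \code{mean_b}, \code{n_a}, \code{n_b}
#' @export
activityGroupTest <- function(values, phenotypes, groupA, groupB) {
  grp <- as.character(phenotypes$group)
  for (g in c(groupA, groupB))
    if (!g %in% grp) stop("group label not in phenotype table: '", g, "'")
  sa <- phenotypes$sample[grp == groupA]
  sb <- phenotypes$sample[grp == groupB]
  a <- values[intersect(sa, names(values))]
  b <- values[intersect(sb, names(values))]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 samples with finite activity")
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- a[1] == b[1]
    return(list(test = "t_test", statistic = if (eq) 0 else Inf * sign(a[1] - b[1]),
                p_value = if (eq) 1 else 0, mean_a = mean(a), mean_b = mean(b),
                n_a = length(a), n_b = length(b)))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(test = "t_test", statistic = unname(tt$statistic),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' Stratification scan over all pathways
#'
#' Applies \code{\link{activityGroupTest}} to every measurable pathway row
#' of an activity matrix and attaches Storey q-values across pathways.
#'
#' @param act SummarizedExperiment from \code{\link{pathwayActivity}}
#' @param phenotypes DataFrame as from \code{\link{readPhenotypes}}
#' @param groupA,groupB group labels to contrast
#' @return data.frame ordered as the activity rows: pathway_id, statistic,
#'   p_value, q_value, mean_a, mean_b
#' @export
scanStratification <- function(act, phenotypes, groupA, groupB) {
  m <- SummarizedExperiment::assay(act)
  ok <- apply(m, 1, function(r) any(is.finite(r)))
  res <- data.frame(pathway_id = rownames(m), statistic = NA_real_,
                    p_value = NA_real_, q_value = NA_real_,
                    mean_a = NA_real_, mean_b = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in which(ok)) {
    r <- activityGroupTest(m[i, ], phenotypes, groupA, groupB)
    res$statistic[i] <- r$statistic
    res$p_value[i] <- r$p_value
    res$mean_a[i] <- r$mean_a
    res$mean_b[i] <- r$mean_b
  }
  has <- !is.na(res$p_value)
  if (any(has)) res$q_value[has] <- as.numeric(storeyQvalues(res$p_value[has]))
  res
}

#' Median-split survival stratification of one pathway
#'
#' Splits samples at the median of the pathway's activity, draws
#' Kaplan-Meier curves for the two halves and returns the log-rank test.
#'
#' @param values named numeric vector of per-sample activity
#' @param phenotypes DataFrame with columns \code{time} and \code{event}
#' @return list with \code{test} = "logrank", \code{statistic} (chi-square),
#'   \code{p_value}, \code{n_high}, \code{n_low}, \code{median_split}, and
#'   \code{fit} (the survfit object for the two curves)
#' @export
survivalSplitTest <- function(values, phenotypes) {
  if (is.null(phenotypes$time) || is.null(phenotypes$event))
    stop("phenotype table lacks survival columns 'time'/'event'")
  common <- intersect(names(values), phenotypes$sample)
  v <- values[common]
  keep <- is.finite(v)
  v <- v[keep]; common <- common[keep]
  idx <- match(common, phenotypes$sample)
  tm <- phenotypes$time[idx]; ev <- phenotypes$event[idx]
  if (length(v) < 10L)
    stop("need at least 10 samples with survival data")
  if (!any(ev)) stop("all samples censored: log-rank test undefined")
  med <- median(v)
  high <- v > med
  if (!any(high) || all(high))
    stop("median split produced an empty group (constant activity?)")
  sd_ <- survival::survdiff(survival::Surv(tm, ev) ~ high)
  pval <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(tm, ev) ~ high)
  list(test = "logrank", statistic = unname(sd_$chisq), p_value = pval,
       n_high = sum(high), n_low = sum(!high), median_split = med,
       fit = fit)
}

.fisherZTest <- function(r1, n1, r2, n2) {
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Group-wise correlation and differential-correlation test
#'
#' Correlates two per-sample quantities (typically a miRNA's expression and
#' a pathway's activity) separately inside each phenotype group and
#' contrasts the two correlation coefficients with Fisher's z test:
#' \deqn{z = (\mathrm{atanh}\, r_1 - \mathrm{atanh}\, r_2) /
#'   \sqrt{1/(n_1-3) + 1/(n_2-3)}.}
#' A correlation present in one group and absent in the other ("broken
#' control") shows as a significant differential p.
#'
#' @param x,y named numeric vectors over samples
#' @param phenotypes DataFrame as from \code{\link{readPhenotypes}}
#' @param groupA,groupB group labels
#' @param method \code{"pearson"} (default) or \code{"spearman"}
#' @return list with per-group \code{r_a}, \code{n_a}, \code{r_b},
#'   \code{n_b}, the differential \code{z} and \code{p_value}, and
#'   \code{flagged} = TRUE when a group had zero variance (r undefined)
#' @export
groupCorrelation <- function(x, y, phenotypes, groupA, groupB,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  grp <- as.character(phenotypes$group)
  out <- list(r_a = NA_real_, n_a = NA_integer_, r_b = NA_real_,
              n_b = NA_integer_, z = NA_real_, p_value = NA_real_,
              flagged = FALSE)
  rs <- list()
  for (g in c(groupA, groupB)) {
    ss <- phenotypes$sample[grp == g]
    ss <- intersect(ss, intersect(names(x), names(y)))
    xi <- x[ss]; yi <- y[ss]
    keep <- is.finite(xi) & is.finite(yi)
    xi <- xi[keep]; yi <- yi[keep]
    if (length(xi) < 4L)
      stop("group '", g, "' has fewer than 4 usable samples")
    if (sd(xi) == 0 || sd(yi) == 0) {
      rs[[g]] <- list(r = NA_real_, n = length(xi))
      out$flagged <- TRUE
    } else {
      rs[[g]] <- list(r = cor(xi, yi, method = method), n = length(xi))
    }
  }
  out$r_a <- rs[[groupA]]$r; out$n_a <- rs[[groupA]]$n
  out$r_b <- rs[[groupB]]$r; out$n_b <- rs[[groupB]]$n
  if (!out$flagged) {
    ft <- .fisherZTest(out$r_a, out$n_a, out$r_b, out$n_b)
    out$z <- ft$z
    out$p_value <- ft$p
  }
  out
}

#' Gene-level group-wise correlation against a miRNA
#'
#' Applies \code{\link{groupCorrelation}} per target gene, correlating the
#' miRNA's expression with each gene's expression instead of a pathway
#' activity. Genes absent from the expression matrix are skipped with a
#' warning.
#'
#' @param mirnaValues named numeric vector of the miRNA's expression
#' @param expr SummarizedExperiment or matrix of gene expression
#' @param targetGenes character vector of gene ids to test
#' @param phenotypes DataFrame as from \code{\link{readPhenotypes}}
#' @param groupA,groupB group labels
#' @param method correlation method
#' @return data.frame with one row per tested gene: gene, r_a, n_a, r_b,
#'   n_b, z, p_value
#' @export
geneLevelCorrelation <- function(mirnaValues, expr, targetGenes, phenotypes,
                                 groupA, groupB, method = "pearson") {
  m <- if (is.matrix(expr)) expr else SummarizedExperiment::assay(expr)
  miss <- setdiff(targetGenes, rownames(m))
  if (length(miss))
    warning(length(miss), " target gene(s) absent from expression, skipped: ",
            paste(utils::head(miss, 3), collapse = ", "))
  genes <- intersect(targetGenes, rownames(m))
  rows <- lapply(genes, function(g) {
    r <- groupCorrelation(mirnaValues, m[g, ], phenotypes, groupA, groupB,
                          method = method)
    data.frame(gene = g, r_a = r$r_a, n_a = r$n_a, r_b = r$r_b, n_b = r$n_b,
               z = r$z, p_value = r$p_value, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(gene = character(), r_a = numeric(), n_a = integer(),
                      r_b = numeric(), n_b = integer(), z = numeric(),
                      p_value = numeric()))
  do.call(rbind, rows)
}
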