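#' Build a synthetic scenario configuration
#'
#' Convenience constructor for \linkS4class{ScenarioConfig}; any slot can be
#' overridden by name, everything else keeps the reference default. See the
#' class documentation and the methods vignette for what each parameter
#' encodes.
#'
#' @param ... named slot overrides, e.g. \code{nSamplesPerGroup = 150}
#' @return a validated \linkS4class{ScenarioConfig}
#' @examples
#' scenarioConfig(seed = 7, delta = 0)
#' @export
scenarioConfig <- function(...) {
  args <- list(...)
  obj <- new("ScenarioConfig")
  intSlots <- c("nPathways", "sizeRange", "nGenes", "nMirnas", "nTools",
                "extraTargetRange", "nSamplesPerGroup", "seed")
  for (nm in names(args)) {
    if (!nm %in% slotNames("ScenarioConfig"))
      stop("unknown scenario parameter: ", nm)
    val <- args[[nm]]
    if (nm %in% intSlots) val <- as.integer(val)
    if (nm %in% c("plantAll", "noSignal")) val <- as.logical(val)
    slot(obj, nm) <- val
  }
  validObject(obj)
  obj
}

#' Generate a complete synthetic input bundle with planted ground truth
#'
#' Emulates the statistical structure of a miRNA-pathway study: a pathway
#' database with signed interactions, an 8-tool target-prediction table, a
#' bimodal gene expression matrix, a miRNA expression matrix, and a two-group
#' phenotype table with exponential survival. Unless \code{noSignal} is set,
#' every pathway is planted with a dominating miRNA (targeting
#' \code{plantedFraction} of its genes with at least 2 tools), and the
#' primary pathway additionally carries a group-A activity shift of
#' \code{delta} SD and a planted miRNA-target expression correlation of
#' \code{rho} in group A only (with a \code{positiveFraction} of targets
#' correlated with the opposite sign). Planted miRNAs also receive
#' out-of-pathway targets so their total target count K is realistic (well
#' above the in-pathway hit count x). The bundle is a pure function of the
#' configuration, including the seed.
#'
#' @param config a \linkS4class{ScenarioConfig}
#' @return a \linkS4class{ScenarioBundle}
#' @export
generateScenario <- function(config = scenarioConfig()) {
  stopifnot(is(config, "ScenarioConfig"))
  validObject(config)
  set.seed(config@seed)
  nG <- config@nGenes; nMir <- config@nMirnas; nP <- config@nPathways
  genes <- sprintf("g%04d", seq_len(nG))
  mirs <- sprintf("mir%03d", seq_len(nMir))
  tools <- sprintf("tool%d", seq_len(config@nTools))
  planting <- !config@noSignal

  ## pathways
  sizes <- config@sizeRange[1] +
    sample.int(config@sizeRange[2] - config@sizeRange[1] + 1L, nP,
               replace = TRUE) - 1L
  if (planting) sizes[1] <- config@sizeRange[2]  # unambiguous primary
  gs <- lapply(sizes, function(s) sample(genes, s))
  names(gs) <- sprintf("pw%03d", seq_len(nP))
  src <- setNames(rep("synthetic", nP), names(gs))

  ## interactions: ceiling(N/3) per pathway, 1-3 promoters + 0-1 inhibitors
  ## + 1 output, all from the pathway's gene set
  itRows <- vector("list", nP)
  for (k in seq_len(nP)) {
    pg <- gs[[k]]
    nInt <- ceiling(sizes[k] / 3)
    rows <- vector("list", nInt)
    for (j in seq_len(nInt)) {
      nProm <- sample(1:3, 1)
      nInh <- sample(0:1, 1)
      take <- min(nProm + nInh + 1L, length(pg))
      pick <- sample(pg, take)
      nProm <- min(nProm, take)
      roles <- c(rep("promoter", nProm),
                 rep("inhibitor", min(nInh, max(0L, take - nProm - 1L))))
      roles <- c(roles, rep("output", take - length(roles)))
      rows[[j]] <- data.frame(pathway_id = names(gs)[k],
                              interaction_id = sprintf("i%d", j),
                              gene = pick, role = roles,
                              stringsAsFactors = FALSE)
    }
    itRows[[k]] <- do.call(rbind, rows)
  }
  interactions <- do.call(rbind, itRows)
  rownames(interactions) <- NULL
  db <- new("PathwayDb", geneSets = gs, source = src,
            interactions = interactions)

  ## background predictions: each (gene, miRNA) cell independently present
  nCells <- as.numeric(nG) * nMir
  nBg <- rbinom(1, nCells, config@backgroundPairProb)
  cell <- sample.int(nCells, nBg)
  bg <- data.frame(geneIdx = as.integer((cell - 1) %% nG + 1),
                   mirIdx = as.integer((cell - 1) %/% nG + 1),
                   support = sample.int(3L, nBg, replace = TRUE,
                                        prob = config@supportProbs))

  planted <- data.frame(pathway_id = character(), mirna_id = character(),
                        fraction = numeric(), stringsAsFactors = FALSE)
  plantRows <- list()
  primaryTargets <- character()
  if (planting) {
    plantIdx <- if (config@plantAll) seq_len(nP) else 1L
    if (nP > nMir) stop("need at least one miRNA per planted pathway")
    for (k in plantIdx) {
      frac <- if (k == 1L) config@primaryFraction else config@plantedFraction
      nT <- ceiling(frac * sizes[k])
      tg <- gs[[k]][seq_len(nT)]   # gene sets are already random draws
      if (k == 1L) primaryTargets <- tg
      nExtra <- config@extraTargetRange[1] +
        sample.int(config@extraTargetRange[2] -
                     config@extraTargetRange[1] + 1L, 1) - 1L
      extra <- sample(setdiff(genes, gs[[k]]), nExtra)
      plantRows[[length(plantRows) + 1L]] <-
        data.frame(geneIdx = match(c(tg, extra), genes),
                   mirIdx = k, support = 2L)
      planted <- rbind(planted,
                       data.frame(pathway_id = names(gs)[k],
                                  mirna_id = mirs[k], fraction = frac,
                                  stringsAsFactors = FALSE))
    }
  }
  allPairs <- rbind(bg, do.call(rbind, plantRows))
  key <- allPairs$geneIdx + nG * (allPairs$mirIdx - 1)
  supp <- tapply(allPairs$support, key, max)   # planted support floors at 2
  key <- as.numeric(names(supp))
  pairTab <- data.frame(geneIdx = as.integer((key - 1) %% nG + 1),
                        mirIdx = as.integer((key - 1) %/% nG + 1),
                        support = as.integer(supp))
  pairTab <- pairTab[order(pairTab$mirIdx, pairTab$geneIdx), ]
  toolPick <- lapply(pairTab$support, function(s) sample(tools, s))
  preds <- data.frame(
    mirna = rep(mirs[pairTab$mirIdx], pairTab$support),
    gene = rep(genes[pairTab$geneIdx], pairTab$support),
    tool = unlist(toolPick), stringsAsFactors = FALSE)
  predictions <- suppressMessages(TargetPredictions(preds))

  ## expression: per gene a two-state Gaussian generative model
  nPer <- config@nSamplesPerGroup
  nS <- 2L * nPer
  samples <- sprintf("S%03d", seq_len(nS))
  groupOf <- rep(c("A", "B"), each = nPer)
  sdE <- config@noiseSd
  muLow <- 5
  sep <- config@modeSeparation * sdE
  state <- matrix(rbinom(nG * nS, 1, 0.5), nG, nS)
  Y <- matrix(rnorm(nG * nS, muLow + sep * state, sdE), nG, nS,
              dimnames = list(genes, samples))
  zMir <- rnorm(nPer)   # latent factor shared by miRNA and targets, group A
  signs <- integer(0)
  if (planting) {
    aCols <- which(groupOf == "A")
    prim <- gs[[1]]
    Y[prim, aCols] <- Y[prim, aCols] + config@delta * sdE
    ## planted targets of the primary miRNA: joint draw with the latent
    ## factor in group A (copula-style), sign-mixed as configured
    nT <- length(primaryTargets)
    nPos <- floor(config@positiveFraction * nT)
    signs <- c(rep(-1L, nT - nPos), rep(1L, nPos))
    rho <- abs(config@rho)
    muC <- muLow + sep / 2 + config@delta * sdE
    for (t in seq_len(nT)) {
      eps <- rnorm(nPer)
      Y[primaryTargets[t], aCols] <-
        muC + sdE * (signs[t] * rho * zMir + sqrt(1 - rho^2) * eps)
    }
  }
  mrna <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = Y), metadata = list(scale = "synthetic-RMA-like"))

  mirMu <- runif(nMir, 5, 9)
  Ym <- matrix(rnorm(nMir * nS, rep(mirMu, nS), 1), nMir, nS,
               dimnames = list(mirs, samples))
  if (planting) Ym[1, groupOf == "A"] <- mirMu[1] + zMir
  mirna <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = Ym), metadata = list(scale = "synthetic"))

  ## survival: exponential, group B at hazardRatio times group A's hazard
  rateA <- log(2) / config@medianSurvivalA
  hr <- if (planting) config@hazardRatio else 1
  rate <- ifelse(groupOf == "A", rateA, rateA * hr)
  raw <- rexp(nS, rate)
  horizon <- 3 * config@medianSurvivalA
  phen <- S4Vectors::DataFrame(sample = samples, group = factor(groupOf),
                               time = pmin(raw, horizon),
                               event = raw <= horizon,
                               row.names = samples)

  gt <- list(planted = planted,
             primary = if (planting)
               list(pathway_id = names(gs)[1], mirna_id = mirs[1]) else NULL,
             primary_targets = if (planting)
               data.frame(gene = primaryTargets, sign = signs,
                          stringsAsFactors = FALSE) else NULL,
             delta = if (planting) config@delta else 0,
             rho = if (planting) config@rho else 0,
             hazard_ratio = hr,
             groups = c("A", "B"),
             seed = config@seed)
  new("ScenarioBundle", pathways = db, predictions = predictions,
      mrna = mrna, mirna = mirna, phenotypes = phen, groundTruth = gt)
}

#' Write a scenario bundle to a directory
#'
#' Emits exactly seven files in the package's tabular formats:
#' \code{pathways.gmt}, \code{interactions.tsv}, \code{predictions.tsv},
#' \code{mrna.tsv}, \code{mirna.tsv}, \code{phenotypes.tsv} and
#' \code{ground_truth.json}. \code{\link{readBundle}} reconstructs the
#' bundle from them.
#'
#' @param bundle a \linkS4class{ScenarioBundle}
#' @param dir output directory (created if missing)
#' @return invisibly, the vector of file paths written
#' @export
writeBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "ScenarioBundle"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  f <- function(x) file.path(dir, x)
  writeGmt(bundle@pathways, f("pathways.gmt"))
  writeInteractions(bundle@pathways, f("interactions.tsv"))
  writePredictions(bundle@predictions, f("predictions.tsv"))
  writeExpression(bundle@mrna, f("mrna.tsv"), idColumn = "gene")
  writeExpression(bundle@mirna, f("mirna.tsv"), idColumn = "mirna")
  writePhenotypes(bundle@phenotypes, f("phenotypes.tsv"))
  jsonlite::write_json(bundle@groundTruth, f("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(vapply(c("pathways.gmt", "interactions.tsv", "predictions.tsv",
                     "mrna.tsv", "mirna.tsv", "phenotypes.tsv",
                     "ground_truth.json"), f, ""))
}

#' Read a scenario bundle back from a directory
#' @param dir directory written by \code{\link{writeBundle}}
#' @return a \linkS4class{ScenarioBundle}
#' @export
readBundle <- function(dir) {
  f <- function(x) file.path(dir, x)
  db <- readGmt(f("pathways.gmt"))
  db <- readInteractions(f("interactions.tsv"), db)
  gt <- jsonlite::read_json(f("ground_truth.json"), simplifyVector = TRUE)
  if (!is.null(gt$planted) && length(gt$planted) == 0)
    gt$planted <- data.frame(pathway_id = character(),
                             mirna_id = character(), fraction = numeric())
  new("ScenarioBundle", pathways = db,
      predictions = readPredictions(f("predictions.tsv")),
      mrna = readExpression(f("mrna.tsv"), scale = "synthetic-RMA-like"),
      mirna = readExpression(f("mirna.tsv"), scale = "synthetic"),
      phenotypes = readPhenotypes(f("phenotypes.tsv")),
      groundTruth = gt)
}
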