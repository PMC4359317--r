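test_that("gene-state mixture recovers well-separated modes deterministically", {
  set.seed(13)
  n <- 60
  lowIdx <- 1:30
  y <- c(rnorm(30, 2, 0.1), rnorm(30, 8, 0.1))
  Y <- rbind(gene1 = y, gene2 = rev(y))
  colnames(Y) <- paste0("s", 1:n)
  st <- fitGeneStates(Y)
  p <- pUp(st)
  expect_true(all(p["gene1", lowIdx] < 0.01))
  expect_true(all(p["gene1", -lowIdx] > 0.99))
  expect_true(all(p["gene2", lowIdx] > 0.99))
  expect_true(stateFits(st)$converged[1])
  # the two fitted means bracket the true modes
  expect_equal(stateFits(st)$mean_low[1], 2, tolerance = 0.2)
  expect_equal(stateFits(st)$mean_high[1], 8, tolerance = 0.2)

  # deterministic: same data, same fit
  st2 <- fitGeneStates(Y)
  expect_identical(pUp(st), pUp(st2))
})

test_that("degenerate and small-sample inputs fall back to p_up = 0.5", {
  Y <- rbind(flat = rep(3, 20),
             ok = c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1)))
  colnames(Y) <- paste0("s", 1:20)
  st <- fitGeneStates(Y)
  expect_true(all(pUp(st)["flat", ] == 0.5))
  expect_true(stateFits(st)$degenerate[1])
  expect_false(stateFits(st)$degenerate[2])

  small <- Y[, 1:5]
  expect_warning(stS <- fitGeneStates(small), "fewer than")
  expect_true(all(pUp(stS) == 0.5))
})

test_that("relabelling samples permutes the posteriors identically", {
  set.seed(17)
  Y <- matrix(rnorm(200, rep(c(0, 4), each = 100), 0.8), 5, 40)
  rownames(Y) <- paste0("g", 1:5); colnames(Y) <- paste0("s", 1:40)
  perm <- sample(40)
  a <- pUp(fitGeneStates(Y))[, perm]
  b <- pUp(fitGeneStates(Y[, perm]))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("interaction likelihood is the promoter/inhibitor product", {
  p <- rbind(gP1 = c(1, 0.8), gP2 = c(1, 0.5), gI = c(1, 0.3))
  colnames(p) <- c("s1", "s2")
  st <- makeStates(p)
  # all promoters certain, no inhibitor -> certain interaction
  expect_equal(unname(interactionActivity(st, c("gP1", "gP2"))[1]), 1)
  expect_equal(unname(interactionActivity(st, "gP2")[2]), 0.5)
  # a certainly-up inhibitor blocks the interaction
  expect_equal(unname(interactionActivity(st, "gP1", "gI")[1]), 0)
  # hand product: 0.8 * 0.5 * (1 - 0.3) = 0.28
  expect_equal(unname(interactionActivity(st, c("gP1", "gP2"), "gI")[2]),
               0.8 * 0.5 * 0.7, tolerance = 1e-12)
  expect_error(interactionActivity(st, "gMissing"), "absent")
})

test_that("an added inhibitor can never increase interaction activity", {
  set.seed(23)
  for (rep in 1:20) {
    p <- matrix(runif(4 * 6), 4, 6,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
    st <- makeStates(p)
    base <- interactionActivity(st, c("g1", "g2"), "g3")
    more <- interactionActivity(st, c("g1", "g2"), c("g3", "g4"))
    expect_true(all(more <= base + 1e-15))
  }
})

test_that("pathway activity averages interactions with gene-set fallback", {
  p <- rbind(a = c(0.2, 1), b = c(0.4, 1), c = c(0.9, 1))
  colnames(p) <- c("s1", "s2")
  st <- makeStates(p)

  # single-interaction pathway: activity equals the interaction value
  it <- data.frame(pathway_id = "P1", interaction_id = "i1",
                   gene = c("a", "b"), role = c("promoter", "inhibitor"))
  db <- new("PathwayDb", geneSets = list(P1 = c("a", "b", "c")),
            source = c(P1 = "x"), interactions = it)
  act <- SummarizedExperiment::assay(pathwayActivity(db, st))
  expect_equal(unname(act["P1", "s1"]), 0.2 * 0.6, tolerance = 1e-12)

  # annotation-free pathway: mean of p_up over its genes
  db2 <- new("PathwayDb", geneSets = list(P2 = c("a", "b", "c")),
             source = c(P2 = "x"))
  act2 <- SummarizedExperiment::assay(pathwayActivity(db2, st))
  expect_equal(unname(act2["P2", "s1"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(act2["P2", "s2"]), 1)

  # everything in [0, 1] on random inputs
  set.seed(29)
  pR <- matrix(runif(30), 5, 6,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  dbR <- new("PathwayDb",
             geneSets = list(PA = paste0("g", 1:3), PB = paste0("g", 2:5)),
             source = c(PA = "x", PB = "x"))
  aR <- SummarizedExperiment::assay(pathwayActivity(dbR, makeStates(pR)))
  expect_true(all(aR >= 0 & aR <= 1))
})

test_that("missing expression coverage is flagged, not silently averaged", {
  p <- rbind(a = c(0.5, 0.5))
  colnames(p) <- c("s1", "s2")
  st <- makeStates(p)
  it <- data.frame(pathway_id = rep("P1", 4),
                   interaction_id = c("i1", "i2", "i2", "i3"),
                   gene = c("a", "zz", "a", "zz"),
                   role = c("promoter", "promoter", "output", "promoter"))
  db <- new("PathwayDb", geneSets = list(P1 = c("a", "zz"), P9 = "qq"),
            source = c(P1 = "x", P9 = "x"), interactions = it)
  expect_warning(expect_warning(res <- pathwayActivity(db, st), "skipped"),
                 "no measurable")
  rd <- SummarizedExperiment::rowData(res)
  expect_equal(rd["P1", "n_interactions_used"], 1L)
  expect_true(rd["P1", "low_coverage"])     # 2 of 3 interactions skipped
  expect_false(rd["P9", "measurable"])
  expect_true(all(is.nan(SummarizedExperiment::assay(res)["P9", ])))
})

test_that("a planted group shift in pathway genes lifts group activity", {
  # two-state generative data matching the fitted family
  set.seed(31)
  nG <- 120; nPer <- 100
  grp <- rep(c("A", "B"), each = nPer)
  state <- matrix(rbinom(nG * 2 * nPer, 1, 0.5), nG)
  Y <- matrix(rnorm(nG * 2 * nPer, 5 + 3 * state, 1), nG)
  rownames(Y) <- paste0("g", 1:nG); colnames(Y) <- paste0("s", 1:(2 * nPer))
  planted <- paste0("g", 1:15)
  Y[planted, grp == "A"] <- Y[planted, grp == "A"] + 2
  db <- new("PathwayDb", geneSets = list(PW = planted),
            source = c(PW = "x"))
  act <- SummarizedExperiment::assay(
    pathwayActivity(db, fitGeneStates(Y)))["PW", ]
  tt <- t.test(act[grp == "A"], act[grp == "B"])
  expect_gt(mean(act[grp == "A"]), mean(act[grp == "B"]))
  expect_lt(tt$p.value, 0.01)
})
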