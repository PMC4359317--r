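test_that("hypergeometric tail follows the strict-inequality convention", {
  # P(X > 0) with K=3 targets, pathway of 2, universe of 6:
  # of the 15 two-gene draws, 3 contain no target -> 1 - 3/15 = 0.8
  expect_equal(hypergeomTail(0, 3, 2, 6), 0.8, tolerance = 1e-12)
  expect_equal(enumTailOracle(0, 3, 2, 6), 0.8)

  # X can never exceed the pathway size or the miRNA's target count
  expect_identical(hypergeomTail(5, 9, 5, 20), 0)
  expect_identical(hypergeomTail(3, 3, 7, 20), 0)

  # the conventional >= tail is one term larger
  expect_equal(hypergeomTail(2, 4, 3, 10, tail = "geq"),
               hypergeomTail(1, 4, 3, 10), tolerance = 1e-15)
  expect_equal(hypergeomTail(0, 4, 3, 10, tail = "geq"), 1)

  expect_error(hypergeomTail(-1, 3, 2, 6), "need")
  expect_error(hypergeomTail(3, 3, 2, 6), "need")   # x > N
  expect_error(hypergeomTail(0, 7, 2, 6), "need")   # K > M
})

test_that("tail probability agrees with the survival-function cross-check", {
  # independent route: stats::phyper upper tail
  set.seed(21)
  for (i in 1:200) {
    M <- sample(20:400, 1)
    N <- sample(1:min(60, M), 1)
    K <- sample(0:M, 1)
    x <- sample(0:N, 1)
    expect_equal(hypergeomTail(x, K, N, M),
                 phyper(x, K, M - K, N, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # extreme tails stay positive instead of cancelling to zero
  p <- hypergeomTail(40, 85, 50, 1269)
  expect_gt(p, 0)
  expect_equal(p, phyper(40, 85, 1269 - 85, 50, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("tail is monotone in the hit count and the target count", {
  M <- 200; N <- 25
  for (K in c(10, 50, 120)) {
    ps <- hypergeomTail(0:N, K, N, M)
    expect_true(all(diff(ps) <= 1e-15))
  }
  for (x in c(0, 3, 7)) {
    ps <- hypergeomTail(x, seq(x, M, by = 7), N, M)
    expect_true(all(diff(ps) >= -1e-15))
  }
})

test_that("best miRNA maximizes overlap with deterministic tie-breaking", {
  db <- new("PathwayDb",
            geneSets = list(PW = paste0("g", 1:5)),
            source = c(PW = "toy"))
  mk <- function(df) {
    tp <- suppressMessages(TargetPredictions(df))
    restrictToUniverse(filterMinTools(tp, 1), db)
  }
  # mirHi hits 3 of 5; mirLo hits 2 -> mirHi wins on x
  df <- data.frame(mirna = c(rep("mirHi", 3), rep("mirLo", 2)),
                   gene = c("g1", "g2", "g3", "g1", "g2"), tool = "t1")
  got <- bestMirna(paste0("g", 1:5), mk(df))
  expect_equal(got$mirna_id, "mirHi")
  expect_equal(got$x, 3L)

  # no miRNA targets the pathway -> no association
  expect_null(bestMirna(c("zz1", "zz2"), mk(df)))

  # equal x: the miRNA with fewer total targets has the smaller tail and wins
  dbBig <- new("PathwayDb",
               geneSets = list(PW = paste0("g", 1:5),
                               REST = paste0("h", 1:95)),
               source = c(PW = "toy", REST = "toy"))
  lean <- data.frame(mirna = "mirLean",
                     gene = c("g1", "g2", "g3", paste0("h", 1:7)), tool = "t1")
  fat <- data.frame(mirna = "mirFat",
                    gene = c("g1", "g2", "g3", paste0("h", 1:47)), tool = "t1")
  sp <- restrictToUniverse(
    filterMinTools(suppressMessages(TargetPredictions(rbind(lean, fat))), 1),
    dbBig)
  got <- bestMirna(paste0("g", 1:5), sp)
  expect_equal(got$mirna_id, "mirLean")
  expect_equal(got$K, 10L)
  # oracle check on both tails: smaller K gives the smaller P(X > 3)
  expect_lt(hypergeomTail(3, 10, 5, 100), hypergeomTail(3, 50, 5, 100))

  # exact tie in x and K: lexicographically smaller id, stable under order
  tie <- data.frame(mirna = rep(c("mirB", "mirA"), each = 2),
                    gene = c("g1", "g2", "g1", "g2"), tool = "t1")
  got <- bestMirna(paste0("g", 1:5), mk(tie))
  expect_equal(got$mirna_id, "mirA")
})

test_that("associateAll fills records that match per-pathway hand computation", {
  db <- new("PathwayDb",
            geneSets = list(P1 = c("a", "b", "c"), P2 = c("c", "d"),
                            P3 = c("e", "f")),
            source = c(P1 = "s", P2 = "s", P3 = "s"))
  df <- rbind(
    data.frame(mirna = "m1", gene = c("a", "b"), tool = c("t1", "t1")),
    data.frame(mirna = "m2", gene = c("c", "d", "e"), tool = "t1"))
  sp <- restrictToUniverse(
    filterMinTools(suppressMessages(TargetPredictions(df)), 1), db)
  res <- suppressMessages(associateAll(db, sp))
  tab <- associations(res)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$M, rep(6L, 3))
  # P1: m1 hits {a,b} (x=2, K=2) beats m2's {c} -> hand-check the record
  p1 <- tab[tab$pathway_id == "P1", ]
  expect_equal(p1$mirna_id, "m1")
  expect_equal(p1$x, 2L); expect_equal(p1$K, 2L); expect_equal(p1$N, 3L)
  expect_equal(p1$p_value, enumTailOracle(2, 2, 3, 6), tolerance = 1e-12)
  # P2: m2 hits both genes
  p2 <- tab[tab$pathway_id == "P2", ]
  expect_equal(p2$mirna_id, "m2")
  expect_equal(p2$x, 2L); expect_equal(p2$K, 3L)
  # q-values cover exactly the associated records
  expect_true(all(!is.na(tab$q_value)))
})

test_that("associateAll flags untargeted pathways and is order-invariant", {
  db <- new("PathwayDb",
            geneSets = list(P1 = c("a", "b"), P0 = c("x1", "x2"),
                            P2 = c("c", "d")),
            source = c(P1 = "s", P0 = "s", P2 = "s"))
  df <- data.frame(mirna = c("m1", "m1", "m2"), gene = c("a", "b", "c"),
                   tool = "t1")
  sp <- filterMinTools(suppressMessages(TargetPredictions(df)), 1)
  expect_message(res <- associateAll(db, sp), "no targeting miRNA")
  tab <- associations(res)
  expect_true(is.na(tab$mirna_id[tab$pathway_id == "P0"]))
  expect_true(is.na(tab$q_value[tab$pathway_id == "P0"]))

  # permuting pathway order permutes records without changing them
  dbPerm <- new("PathwayDb", geneSets = db@geneSets[c(3, 1, 2)],
                source = db@source[c(3, 1, 2)])
  resPerm <- suppressMessages(associateAll(dbPerm, sp))
  a <- associations(res); b <- associations(resPerm)
  b <- b[match(a$pathway_id, b$pathway_id), ]
  rownames(b) <- NULL
  expect_equal(a, b)

  # certain event: one pathway covering the whole universe, fully targeted
  dbAll <- new("PathwayDb", geneSets = list(P = c("a", "b")),
               source = c(P = "s"))
  spAll <- filterMinTools(suppressMessages(TargetPredictions(
    data.frame(mirna = "m", gene = c("a", "b"), tool = "t1"))), 1)
  resAll <- suppressMessages(associateAll(dbAll, spAll))
  expect_identical(associations(resAll)$p_value, 0)
})

test_that("Storey q-values behave like BH at pi0 = 1 and stay monotone", {
  # frozen hand case: pi0 = 1 on p = (.01,.02,.03,.8) reproduces step-up BH
  p <- c(0.01, 0.02, 0.03, 0.8)
  expect_equal(as.numeric(storeyQvalues(p, pi0 = 1)),
               c(0.04, 0.04, 0.04, 0.8), tolerance = 1e-12)
  expect_equal(as.numeric(storeyQvalues(p, pi0 = 1)), p.adjust(p, "BH"),
               tolerance = 1e-12)

  # all-ones input is a fixed point
  expect_equal(as.numeric(storeyQvalues(rep(1, 10))), rep(1, 10))

  # q ordering follows p ordering (non-strictly), estimated pi0
  set.seed(31)
  p <- runif(200)^1.5
  q <- storeyQvalues(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_true(all(q >= 0 & q <= 1))
  expect_true(attr(q, "pi0") > 0 && attr(q, "pi0") <= 1)

  expect_error(storeyQvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(storeyQvalues(0.5, lambda = c(0.5, 1)), "lambda")
})
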