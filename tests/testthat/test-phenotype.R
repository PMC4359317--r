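phen2 <- makePhenotypes(paste0("s", 1:20), rep(c("A", "B"), each = 10))

test_that("group stratification test is a Welch t-test with validation", {
  v <- setNames(c(rnorm(10, 0.5, 0.05), rnorm(10, 0.5, 0.05)), paste0("s", 1:20))
  # identical groups: zero statistic, p = 1
  same <- setNames(rep(c(0.2, 0.4, 0.6, 0.8, 0.5), 4), paste0("s", 1:20))
  got <- activityGroupTest(same, phen2, "A", "B")
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_equal(got$p_value, 1, tolerance = 1e-12)

  # well-separated groups
  set.seed(41)
  v <- setNames(c(rnorm(10, 0.7, 0.05), rnorm(10, 0.3, 0.05)), paste0("s", 1:20))
  got <- activityGroupTest(v, phen2, "A", "B")
  expect_lt(got$p_value, 1e-6)
  expect_gt(got$mean_a, got$mean_b)
  # matches the closed-form Welch statistic
  a <- v[1:10]; b <- v[11:20]
  expect_equal(got$statistic, (mean(a) - mean(b)) / sqrt(var(a)/10 + var(b)/10),
               tolerance = 1e-12)

  expect_error(activityGroupTest(v, phen2, "A", "ERneg"), "ERneg")
  expect_error(activityGroupTest(v[1:11], phen2, "A", "B"), "at least 2")
})

test_that("stratification tests are invariant to ordering and affine scale", {
  set.seed(43)
  v <- setNames(runif(20), paste0("s", 1:20))
  got <- activityGroupTest(v, phen2, "A", "B")
  perm <- sample(20)
  gotPerm <- activityGroupTest(v[perm], phen2, "A", "B")
  expect_equal(got$p_value, gotPerm$p_value, tolerance = 1e-12)
  gotAff <- activityGroupTest(3 * v + 1, phen2, "A", "B")
  expect_equal(got$p_value, gotAff$p_value, tolerance = 1e-10)
})

test_that("median-split survival test behaves on null, planted and bad input", {
  # identical survival in both halves: log-rank chi-square 0
  act <- setNames(c(seq(0.1, 0.5, length.out = 10),
                    seq(0.6, 1.0, length.out = 10)), paste0("s", 1:20))
  tm <- rep(rep(c(100, 200, 300, 400, 500), 2), 2)  # same curve in each half
  ev <- rep(TRUE, 20)
  ph <- makePhenotypes(paste0("s", 1:20), rep("A", 20), time = tm, event = ev)
  got <- survivalSplitTest(act, ph)
  expect_equal(got$statistic, 0, tolerance = 1e-9)
  expect_equal(got$p_value, 1, tolerance = 1e-9)
  expect_equal(got$n_high, 10L)

  # planted hazard ratio of 3 between the halves is detected
  set.seed(47)
  hits <- 0L
  for (s in 1:5) {
    n <- 200
    act2 <- setNames(c(runif(n / 2, 0.6, 1), runif(n / 2, 0, 0.4)),
                     paste0("s", 1:n))
    raw <- c(rexp(n / 2, 1 / 1000), rexp(n / 2, 3 / 1000))
    ph2 <- makePhenotypes(paste0("s", 1:n), rep("A", n),
                          time = pmin(raw, 3000), event = raw <= 3000)
    if (survivalSplitTest(act2, ph2)$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 4L)

  expect_error(survivalSplitTest(act[1:9], ph), "at least 10")
  phC <- makePhenotypes(paste0("s", 1:20), rep("A", 20), time = tm,
                        event = rep(FALSE, 20))
  expect_error(survivalSplitTest(act, phC), "censored")
  expect_error(survivalSplitTest(act, phen2), "survival columns")
})

test_that("group-wise correlation contrasts r with Fisher's z", {
  set.seed(53)
  n <- 40
  samples <- paste0("s", 1:(2 * n))
  ph <- makePhenotypes(samples, rep(c("A", "B"), each = n))
  # same underlying correlation in both groups -> z near 0; exact symmetric
  # case: group B duplicates group A's values
  x <- setNames(rep(rnorm(n), 2), samples)
  y <- setNames(rep(rnorm(n), 2), samples)
  got <- groupCorrelation(x, y, ph, "A", "B")
  expect_equal(got$r_a, got$r_b, tolerance = 1e-12)
  expect_equal(got$z, 0, tolerance = 1e-12)
  expect_equal(got$p_value, 1, tolerance = 1e-12)

  # planted negative correlation in A only
  z <- rnorm(n)
  xa <- z; ya <- -0.8 * z + sqrt(1 - 0.64) * rnorm(n)
  x2 <- setNames(c(xa, rnorm(n)), samples)
  y2 <- setNames(c(ya, rnorm(n)), samples)
  got <- groupCorrelation(x2, y2, ph, "A", "B")
  expect_lt(got$r_a, -0.5)
  expect_lt(got$p_value, 0.01)

  # zero variance in a group flags the record instead of erroring
  x3 <- setNames(c(rep(1, n), rnorm(n)), samples)
  got <- groupCorrelation(x3, y2, ph, "A", "B")
  expect_true(got$flagged)
  expect_true(is.na(got$z))

  tiny <- makePhenotypes(paste0("s", 1:6), c("A", "A", "A", "B", "B", "B"))
  expect_error(groupCorrelation(setNames(rnorm(6), paste0("s", 1:6)),
                                setNames(rnorm(6), paste0("s", 1:6)),
                                tiny, "A", "B"), "fewer than 4")
})

test_that("gene-level correlation recovers a planted sign mix per target", {
  set.seed(59)
  n <- 150
  samples <- paste0("s", 1:(2 * n))
  ph <- makePhenotypes(samples, rep(c("A", "B"), each = n))
  zmir <- rnorm(n)
  mir <- setNames(c(zmir, rnorm(n)), samples)
  signs <- c(-1, -1, -1, 1, 1, 1)
  genes <- paste0("g", 1:6)
  Y <- matrix(rnorm(8 * 2 * n), 8, 2 * n,
              dimnames = list(c(genes, "g7", "g8"), samples))
  for (i in 1:6)
    Y[i, 1:n] <- signs[i] * 0.6 * zmir + sqrt(1 - 0.36) * rnorm(n)
  res <- geneLevelCorrelation(mir, Y, genes, ph, "A", "B")
  expect_equal(nrow(res), 6L)
  expect_equal(sign(res$r_a), signs)
  expect_true(all(abs(res$r_b) < 0.3))

  expect_warning(res2 <- geneLevelCorrelation(mir, Y, c(genes, "gNone"),
                                              ph, "A", "B"), "absent")
  expect_equal(nrow(res2), 6L)
})

test_that("stratification scan ranks a planted pathway first with q-values", {
  set.seed(61)
  nS <- 60
  samples <- paste0("s", 1:nS)
  ph <- makePhenotypes(samples, rep(c("A", "B"), each = nS / 2))
  act <- matrix(runif(10 * nS), 10, nS,
                dimnames = list(sprintf("pw%02d", 1:10), samples))
  act[1, 1:(nS / 2)] <- act[1, 1:(nS / 2)] + 1.5   # planted shift
  se <- SummarizedExperiment::SummarizedExperiment(list(activity = act))
  res <- scanStratification(se, ph, "A", "B")
  expect_equal(res$pathway_id[which.min(res$p_value)], "pw01")
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  expect_equal(res$q_value[order(res$p_value)],
               sort(res$q_value), tolerance = 1e-12)
})
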