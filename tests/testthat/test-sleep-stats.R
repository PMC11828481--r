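test_that("a null interaction construction gives interaction F = 0", {
  # per-condition within-cell differences share the same multiset, so the
  # condition x measurement interaction sum of squares vanishes
  d <- expand.grid(cell_id = sprintf("c%02d", 1:12),
                   measurement = c("m90", "p50"), stringsAsFactors = FALSE)
  d$condition <- rep(rep(c("CS", "SD", "RS"), each = 4), 2)
  base <- rnorm(12)
  diffs <- rep(c(1, 2, 3, 4), 3)
  d$value <- ifelse(d$measurement == "m90", base[match(d$cell_id, unique(d$cell_id))],
                    base[match(d$cell_id, unique(d$cell_id))] + diffs)
  res <- twoWayMixedAnova(d)
  expect_equal(res$F[res$effect == "interaction"], 0, tolerance = 1e-10)
})

test_that("the mixed ANOVA matches car::Anova with sum contrasts", {
  skip_if_not_installed("car")
  set.seed(7)
  d <- expand.grid(cell_id = sprintf("c%02d", 1:24),
                   measurement = c("A", "B"), stringsAsFactors = FALSE)
  d$condition <- rep(rep(c("CS", "SD", "RS"), each = 8), 2)
  d$value <- rnorm(48)
  res <- twoWayMixedAnova(d)

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  wide <- stats::reshape(d, idvar = "cell_id", timevar = "measurement",
                         direction = "wide", v.names = "value")
  mod <- stats::lm(cbind(value.A, value.B) ~ condition, data = wide)
  aa <- car::Anova(mod, idata = data.frame(measurement = factor(c("A", "B"))),
                   idesign = ~measurement, type = 3)
  ref <- summary(aa, multivariate = FALSE)$univariate.tests
  expect_equal(res$F[res$effect == "between"],
               unname(ref["condition", "F value"]), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "within"],
               unname(ref["measurement", "F value"]), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "interaction"],
               unname(ref["condition:measurement", "F value"]), tolerance = 1e-8)
  expect_equal(res$df1[res$effect == "interaction"], 2)
  expect_equal(res$df2[res$effect == "interaction"], 21)

  # unbalanced data are refused, naming the offending cell
  expect_error(twoWayMixedAnova(d[-1L, ]), "c01")
})

test_that("the Greenhouse-Geisser epsilon matches car for k = 3 within levels", {
  skip_if_not_installed("car")
  set.seed(11)
  d <- expand.grid(cell_id = sprintf("c%02d", 1:18),
                   measurement = c("A", "B", "C"), stringsAsFactors = FALSE)
  d$condition <- rep(rep(c("CS", "SD", "RS"), each = 6), 3)
  d$value <- rnorm(54) + as.numeric(factor(d$measurement)) *
    rep(rnorm(18, sd = 0.8), 3)
  res <- twoWayMixedAnova(d, ggCorrection = TRUE)

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  wide <- stats::reshape(d, idvar = "cell_id", timevar = "measurement",
                         direction = "wide", v.names = "value")
  mod <- stats::lm(cbind(value.A, value.B, value.C) ~ condition, data = wide)
  aa <- car::Anova(mod,
                   idata = data.frame(measurement = factor(c("A", "B", "C"))),
                   idesign = ~measurement, type = 3)
  sm <- summary(aa, multivariate = FALSE)
  eps <- sm$pval.adjustments["measurement", "GG eps"]
  expect_equal(res$epsilon[res$effect == "within"], unname(eps),
               tolerance = 1e-8)
  expect_equal(res$p[res$effect == "within"],
               unname(sm$pval.adjustments["measurement", "Pr(>F[GG])"]),
               tolerance = 1e-8)
  # fractional degrees of freedom
  expect_lt(res$df1[res$effect == "interaction"], 4)

  # two within levels: epsilon is exactly 1
  d2 <- d[d$measurement != "C", ]
  res2 <- twoWayMixedAnova(d2, ggCorrection = TRUE)
  expect_equal(res2$epsilon[res2$effect == "within"], 1)
})

test_that("Kruskal-Wallis matches the hand rank formula and handles ties", {
  expect_equal(kruskalWallis(list(c(1, 1, 1), c(1, 1, 1)))$statistic, 0)
  # untied groups {1,2,3},{4,5,6},{7,8,9}: H = 12/(9*10) * 3*18 = 7.2
  kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)

  # permutation null: p-values approximately uniform
  set.seed(21)
  x <- rnorm(30)
  g <- rep(1:3, each = 10)
  pv <- replicate(2000, kruskalWallis(x, sample(g))$p.value)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BKY two-stage decisions match an independent hand-coded oracle", {
  p25 <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
           0.216, 0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569,
           0.594, 0.696, 0.762, 0.94, 0.942, 0.975, 0.986)
  got <- bkyTwoStage(p25, 0.05)
  expect_identical(got$rejected, bkyOracle(p25, 0.05))

  expect_identical(bkyTwoStage(rep(1, 10), 0.05)$rejected, rep(FALSE, 10))
  expect_identical(bkyTwoStage(0.001, 0.05)$rejected, TRUE)
  expect_identical(bkyTwoStage(numeric(), 0.05)$rejected, logical())

  set.seed(14)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- switch(sample(3, 1),
                runif(m),
                c(runif(ceiling(m / 2), 0, 0.01), runif(floor(m / 2))),
                rbeta(m, 0.3, 1))
    q <- sample(c(0.01, 0.05, 0.1), 1)
    got <- bkyTwoStage(p, q)
    expect_identical(got$rejected, bkyOracle(p, q))
    # the stage-2 level is >= q/(1+q), so the rejections always contain the
    # BH rejections at that stage-1 level (containment of BH at q itself can
    # fail when stage 1 rejects nothing, e.g. p = (0.024, 0.9), q = 0.05)
    bh <- stats::p.adjust(p, "BH") <= q / (1 + q)
    expect_true(all(got$rejected[bh]))
    # decisions are reproduced by thresholding the adjusted values
    expect_identical(got$rejected, unname(got$adjusted <= got$qPrime))
  }
})

test_that("Sidak adjustment follows its closed form and is bounded by Bonferroni", {
  expect_equal(sidakAdjust(0.01, 3), 0.029701, tolerance = 1e-12)
  expect_equal(sidakAdjust(0), 1 - (1 - 0)^1)
  expect_equal(sidakAdjust(c(0, 1)), c(0, 1))
  set.seed(2)
  p <- runif(20)
  adj <- sidakAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= pmin(1, p * 20) + 1e-12))
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("Wilcoxon matched pairs matches a hand-computed signed-rank statistic", {
  x <- 1:10
  res <- wilcoxonMatchedPairs(x + 1, x)
  expect_equal(res$minStatistic, 0)

  set.seed(3)
  a <- rnorm(17)
  b <- rnorm(17)
  res <- wilcoxonMatchedPairs(a, b)
  d <- a - b
  vHand <- sum(rank(abs(d))[d > 0])
  expect_equal(res$statistic, vHand)
  expect_equal(res$n, 17)
  # exact p at n = 17 from the signed-rank distribution
  expect_equal(res$p.value,
               stats::psignrank(min(vHand, 17 * 9 - vHand), 17) * 2,
               tolerance = 1e-12)

  expect_error(wilcoxonMatchedPairs(a, a), "AllTies")
})

test_that("Yates chi-square follows the corrected formula", {
  got <- chiSquareYates(matrix(c(10, 30, 20, 40), 2))
  N <- 100
  hand <- N * (abs(10 * 40 - 20 * 30) - N / 2)^2 / (30 * 70 * 40 * 60)
  expect_equal(got$statistic, hand, tolerance = 1e-12)
  expect_equal(got$df, 1)

  # |ad - bc| below N/2: continuity term floors at zero
  expect_equal(chiSquareYates(matrix(c(5, 5, 5, 5), 2))$statistic, 0)

  expect_error(chiSquareYates(matrix(c(0, 0, 5, 5), 2)), "margins")
  expect_error(chiSquareYates(matrix(c(1.5, 2, 3, 4), 2)), "integers")

  # doubled table against the reference implementation
  tab <- matrix(c(24, 12, 9, 33), 2)
  ref <- suppressWarnings(stats::chisq.test(2 * tab, correct = TRUE))
  got2 <- chiSquareYates(2 * tab)
  expect_equal(got2$statistic, unname(ref$statistic), tolerance = 1e-12)
})
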