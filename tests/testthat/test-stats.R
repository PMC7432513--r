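test_that("Levene test matches hand-computed ANOVA on absolute deviations", {
  x <- c(1, 2, 3, 4); y <- c(1, 1, 1, 9)
  # |dev| from group means: {1.5,.5,.5,1.5} and {2,2,2,6};
  # SSB = 4(1-2)^2 + 4(3-2)^2 = 8, SSW = 1 + 12 = 13, F = 8 / (13/6)
  lv <- leveneTest2(x, y)
  expect_equal(lv$F, 48 / 13, tolerance = 1e-12)
  expect_equal(lv$p, pf(48 / 13, 1, 6, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Levene test agrees with the mean-centred reference implementation", {
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(8 + i, sd = 1); y <- rnorm(12, sd = 1 + i / 2)
    ref <- car::leveneTest(c(x, y),
                           factor(rep(1:2, c(length(x), length(y)))),
                           center = mean)
    lv <- leveneTest2(x, y)
    expect_equal(lv$F, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(lv$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("Levene F is location-invariant and zero for identical samples", {
  x <- c(2, 4, 4, 7); y <- c(1, 3, 8, 9)
  expect_equal(leveneTest2(x, y)$F, leveneTest2(x + 100, y)$F,
               tolerance = 1e-10)
  expect_identical(leveneTest2(x, x)$F, 0)
  expect_identical(leveneTest2(c(3, 3, 3), c(3, 3))$p, 1)
})

test_that("Welch df equals the Welch-Satterthwaite formula evaluated by hand", {
  x <- c(1, 2, 3); y <- c(10, 20, 30, 40)
  a <- var(x) / 3; b <- var(y) / 4
  df_hand <- (a + b)^2 / (a^2 / 2 + b^2 / 3)
  expect_equal(twoSampleT(x, y, "welch")$df, df_hand, tolerance = 1e-9)
  expect_equal(twoSampleTSummary(mean(x), sd(x), 3, mean(y), sd(y), 4,
                                 "welch")$df, df_hand, tolerance = 1e-9)
})

test_that("summary-statistic t equals the raw-sample t", {
  set.seed(11)
  for (rule in c("pooled", "welch")) {
    x <- rnorm(14, 3, 2); y <- rnorm(23, 2, 1)
    raw <- twoSampleT(x, y, rule)
    summ <- twoSampleTSummary(mean(x), sd(x), 14, mean(y), sd(y), 23, rule)
    expect_equal(raw$t, summ$t, tolerance = 1e-9)
    expect_equal(raw$df, summ$df, tolerance = 1e-9)
    expect_equal(raw$p, summ$p, tolerance = 1e-9)
  }
})

test_that("the auto rule gates on Levene at the stated level", {
  set.seed(21)
  same <- twoSampleT(rnorm(40, sd = 1), rnorm(40, sd = 1), "auto")
  expect_identical(same$method,
                   if (same$levene_p < 0.05) "welch" else "pooled")
  hetero <- twoSampleT(rnorm(60, sd = 0.5), rnorm(60, sd = 4), "auto")
  expect_lt(hetero$levene_p, 0.05)
  expect_identical(hetero$method, "welch")
})

test_that("degenerate samples signal zero or infinite separation explicitly", {
  expect_identical(twoSampleT(c(1, 1), c(1, 1))$t, 0)
  inf <- twoSampleT(c(2, 2), c(1, 1))
  expect_identical(inf$t, Inf)
  expect_identical(inf$p, 0)
  expect_identical(cohensD(5, 0, 10, 5, 0, 10), 0)
  expect_identical(cohensD(5, 0, 10, 4, 0, 10), Inf)
  expect_identical(twoSampleT(c(1, 2, 3), c(1, 2, 3))$t, 0)
})

test_that("Cohen's d is shift-invariant and scale-invariant", {
  set.seed(3)
  x <- rnorm(20, 5, 2); y <- rnorm(30, 4, 3)
  d0 <- cohensD(mean(x), sd(x), 20, mean(y), sd(y), 30)
  d_shift <- cohensD(mean(x) + 7, sd(x), 20, mean(y) + 7, sd(y), 30)
  d_scale <- cohensD(mean(3 * x), sd(3 * x), 20, mean(3 * y), sd(3 * y), 30)
  expect_equal(d_shift, d0, tolerance = 1e-12)
  expect_equal(d_scale, d0, tolerance = 1e-12)
})

test_that("effect-size magnitude bands follow the stated cut points", {
  expect_identical(
    classifyD(c(0, 0.18, 0.19999, 0.20, 0.35, 0.50, 0.505, 0.51,
                0.69, 0.80, 0.801, 1.12)),
    c("below_threshold", "below_threshold", "below_threshold",
      "small", "small", "small", "moderate", "moderate",
      "moderate", "moderate", "large", "large"))
})

test_that("rank AUC equals exhaustive pair counting, with ties as one half", {
  expect_equal(rocAuc(c(2, 3, 4), c(1, 2, 3)), 7 / 9, tolerance = 1e-12)
  expect_identical(rocAuc(c(5, 6), c(1, 2)), 1)
  x <- c(1, 2, 3, 4)
  expect_identical(rocAuc(x, x), 0.5)
  set.seed(77)
  for (i in 1:25) {
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    pos <- sample(0:6, n1, replace = TRUE) + rnorm(n1, 0, 0.2) *
      rbinom(n1, 1, 0.5)  # mixture of ties and distinct values
    neg <- sample(0:6, n2, replace = TRUE)
    a <- rocAuc(pos, neg)
    expect_equal(a, bruteAuc(pos, neg), tolerance = 1e-12)
    expect_equal(a + rocAuc(neg, pos), 1, tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with the ROC-curve reference implementation", {
  set.seed(13)
  pos <- round(rnorm(40, 1), 1); neg <- round(rnorm(50), 1)
  ref <- as.numeric(pROC::auc(
    pROC::roc(response = rep(1:0, c(40, 50)), predictor = c(pos, neg),
              quiet = TRUE, direction = "<")))
  expect_equal(rocAuc(pos, neg), ref, tolerance = 1e-10)
})

test_that("AUC accuracy bands follow the stated cut points", {
  expect_identical(as.character(classifyAuc(0.5)), "chance")
  expect_identical(as.character(classifyAuc(0.69)), "lower")
  expect_identical(as.character(classifyAuc(0.70)), "moderate")
  expect_identical(as.character(classifyAuc(0.79)), "moderate")
  expect_identical(as.character(classifyAuc(0.90)), "moderate")
  expect_identical(as.character(classifyAuc(0.95)), "higher")
  inv <- classifyAuc(0.3)
  expect_identical(as.character(inv), "chance")
  expect_true(attr(inv, "inverted"))
  expect_false(attr(classifyAuc(0.8), "inverted"))
})

test_that("kappa matches hand-computed margins and the reference", {
  expect_identical(cohensKappa(diag(c(7, 5, 9))), 1)
  # [[20,5],[10,15]]: p_o = 35/50 = 0.7, p_e = (30*25 + 20*25)/2500 = 0.5
  tab <- matrix(c(20, 10, 5, 15), 2)
  expect_equal(cohensKappa(tab), 0.4, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:5) {
    k <- sample(2:5, 1)
    t2 <- matrix(rpois(k * k, 5), k)
    expect_equal(cohensKappa(t2), e1071::classAgreement(t2)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("kappa stays in [-1, 1] and handles degenerate tables", {
  set.seed(14)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    tab <- matrix(rpois(k * k, 3), k)
    if (sum(tab) == 0) next
    kap <- cohensKappa(tab)
    expect_gte(kap, -1); expect_lte(kap, 1)
    if (sum(tab) - sum(diag(tab)) == 0 && sum(diag(tab) > 0) > 1)
      expect_equal(kap, 1)
  }
  const <- matrix(c(12, 0, 0, 0), 2)  # both observers always category 1
  expect_identical(as.numeric(cohensKappa(const)), 1)
  expect_true(attr(cohensKappa(const), "degenerate"))
  expect_error(cohensKappa(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("a group compared against itself yields zero everywhere", {
  set.seed(30)
  ms <- makeMatrixList(4, 10, function(r, c) matrix(abs(rnorm(r * c, 5)), r))
  cmp <- compareGroups(ms, ms)
  expect_identical(nrow(cmp), 17L)
  expect_identical(cmp$joint, analysisJoints())
  expect_true(all(cmp$t == 0))
  expect_true(all(cmp$d == 0))
  expect_true(all(cmp$magnitude == "below_threshold"))
})

test_that("compareGroups recovers a programmed shift of half a pooled SD", {
  set.seed(41)
  g1 <- makeMatrixList(10, 100, function(r, c)
    matrix(pmax(0, rnorm(r * c, 6, 1.5)), r))
  g2 <- makeMatrixList(10, 100, function(r, c)
    matrix(pmax(0, rnorm(r * c, 6 + 0.5 * 1.5, 1.5)), r), prefix = "t")
  cmp <- compareGroups(g2, g1)  # 1000 minute-observations per group
  expect_lt(abs(mean(cmp$d) - 0.5), 0.1)
  expect_true(all(cmp$t > 0))  # group with larger mean listed first
})

test_that("missing minutes and absent joints are handled, not dropped", {
  set.seed(52)
  gen <- function(r, c) matrix(abs(rnorm(r * c, 5)), r)
  g1 <- makeMatrixList(3, 8, gen)
  g2 <- makeMatrixList(3, 8, gen, prefix = "u")
  # knock out one joint entirely in group 1
  for (m in seq_along(g1)) {
    vv <- pathLength(g1[[m]]); vv["neck", ] <- NA
    g1[[m]] <- MovementMatrix(vv, meta = sessionMeta(
      subjectId(g1[[m]]), sessionLength = 8))
  }
  cmp <- compareGroups(g1, g2)
  neckRow <- cmp[cmp$joint == "neck", ]
  expect_identical(neckRow$flag, "insufficient_data")
  expect_true(is.na(neckRow$t))
  expect_identical(nrow(cmp), 17L)  # row kept
  # subject unit: one observation per subject
  cmp_s <- compareGroups(g1, g2, unit = "subject")
  expect_identical(cmp_s$n1[cmp_s$joint == "head"], 3L)
})

test_that("the Holm-corrected column is an opt-in extension", {
  set.seed(60)
  gen <- function(r, c) matrix(abs(rnorm(r * c, 5)), r)
  g1 <- makeMatrixList(3, 10, gen)
  g2 <- makeMatrixList(3, 10, gen, prefix = "w")
  expect_false("p_holm" %in% names(compareGroups(g1, g2)))
  withHolm <- compareGroups(g1, g2, holm = TRUE)
  expect_true(all(withHolm$p_holm >= withHolm$p, na.rm = TRUE))
})

test_that("rocTable reports one banded AUC per analysis joint", {
  set.seed(71)
  g1 <- makeMatrixList(4, 25, function(r, c)
    matrix(pmax(0, rnorm(r * c, 8, 1)), r))
  g2 <- makeMatrixList(4, 25, function(r, c)
    matrix(pmax(0, rnorm(r * c, 5, 1)), r), prefix = "z")
  tab <- rocTable(g1, g2)
  expect_identical(tab$joint, analysisJoints())
  expect_true(all(tab$auc > 0.9))  # 3-SD separation
  expect_true(all(tab$band == "higher"))
})
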