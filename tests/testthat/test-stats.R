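test_that("paired t-test matches the closed-form Student distribution", {
  a <- c(1, 2, 3, 4)
  expect_equal(pairedTTest(a, a)$p, 1)
  expect_true(pairedTTest(a, a)$degenerate)
  # differences {0.9, 1.0, 1.1}: t = 1.0 / (0.1/sqrt(3)) = 17.32, df = 2;
  # closed-form df = 2 survival: p = 1 - t / sqrt(2 + t^2)
  b <- c(0, 0, 0)
  res <- pairedTTest(c(0.9, 1.0, 1.1), b)
  tExp <- 1.0 / (0.1 / sqrt(3))
  expect_equal(res$t, tExp, tolerance = 1e-6)
  expect_equal(res$t, 17.32, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_equal(res$p, 1 - tExp / sqrt(2 + tExp^2), tolerance = 1e-10)
  expect_equal(res$p, 0.0033, tolerance = 1e-2)
  # antisymmetry: swapping the pair flips t, keeps p
  swp <- pairedTTest(b, c(0.9, 1.0, 1.1))
  expect_equal(swp$t, -res$t)
  expect_equal(swp$p, res$p)
  # constant nonzero difference: flagged degenerate, p undefined
  deg <- pairedTTest(c(1, 2, 3), c(0, 1, 2))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  expect_error(pairedTTest(1:3, 1:4), "equal length")
})

test_that("Pearson correlation and its significance behave canonically", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearsonR(x, 2 * x + 1)$r, 1)
  res <- pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  # p from t = r sqrt((n-2)/(1-r^2))
  tStat <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(-tStat, df = 2), tolerance = 1e-10)
  # affine invariance
  y <- c(2, 1, 4, 3, 5)
  expect_equal(pearsonR(3 * x - 2, y)$r, pearsonR(x, y)$r, tolerance = 1e-12)
  expect_equal(pearsonR(x, -y)$r, -pearsonR(x, y)$r, tolerance = 1e-12)
  expect_error(pearsonR(rep(1, 5), y), "variance")
})

test_that("one-way ANOVA with Tukey HSD separates only the distinct group", {
  # three identical groups: F = 0, all adjusted p = 1
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  null <- anovaTukey(v, g)
  expect_equal(null$F, 0)
  expect_equal(null$tukey$pAdj, rep(1, 3))
  # one far-away group: its two pairwise p < 0.01, the near pair clearly
  # non-significant and equal to the closed-form studentized-range value
  # q = |mean diff| / sqrt(MSE/2 (1/n1 + 1/n2)) = 1/sqrt(1/3)
  v2 <- c(1, 2, 3, 2, 3, 4, 10, 11, 12)
  res <- anovaTukey(v2, g)
  expect_lt(res$anovaP, 0.001)
  pAB <- res$tukey$pAdj[res$tukey$pair == "b-a"]
  expect_equal(pAB, 1 - ptukey(sqrt(3), nmeans = 3, df = 6),
               tolerance = 1e-10)
  expect_gt(pAB, 0.25)
  expect_true(all(res$tukey$pAdj[res$tukey$pair %in% c("c-a", "c-b")] < 0.01))
  # group order does not change the pairwise p values
  res2 <- anovaTukey(v2, factor(g, levels = c("c", "a", "b")))
  expect_equal(sort(res2$tukey$pAdj), sort(res$tukey$pAdj), tolerance = 1e-12)
  # two groups: ANOVA reproduces the unpaired t-test, F = t^2
  x <- c(1.2, 0.8, 1.1, 0.9)
  y <- c(2.0, 2.2, 1.7)
  two <- anovaTukey(c(x, y), rep(c("x", "y"), c(4, 3)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(two$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(two$anovaP, tt$p.value, tolerance = 1e-10)
  expect_error(anovaTukey(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("ROC AUC equals the normalized Mann-Whitney pair count", {
  # exhaustive pair count: 8 of 9 pairs concordant, one tie-free loss
  res <- rocAUC(c(0.3, 0.4, 0.5), c(0.1, 0.2, 0.35))
  expect_equal(res$auc, 8 / 9)
  expect_equal(res$nPos, 3)
  # perfect separation
  expect_equal(rocAUC(4:6, 1:3)$auc, 1)
  # ties get half credit
  expect_equal(rocAUC(c(1, 2), c(1, 0))$auc, (0.5 + 1 + 1 + 1) / 4)
  # negating scores mirrors the AUC
  set.seed(1)
  p <- rnorm(20, 1); n <- rnorm(30)
  expect_equal(rocAUC(-p, -n)$auc, 1 - rocAUC(p, n)$auc)
  # monotone transform invariance
  expect_equal(rocAUC(exp(p), exp(n))$auc, rocAUC(p, n)$auc)
  # CI brackets the estimate and stays in [0, 1]
  r2 <- rocAUC(p, n)
  expect_lte(r2$ci95Low, r2$auc)
  expect_gte(r2$ci95High, r2$auc)
  expect_gte(r2$ci95Low, 0)
  expect_lte(r2$ci95High, 1)
  # Hanley-McNeil SE at AUC = 0.5 reduces to sqrt((nP+nN+1)/(12 nP nN))
  even <- rocAUC(c(1, 3), c(2, 2, 2))
  expect_equal(even$se, sqrt((even$auc * (1 - even$auc) +
                                (2 - 1) * (even$auc / (2 - even$auc) - even$auc^2) +
                                (3 - 1) * (2 * even$auc^2 / (1 + even$auc) - even$auc^2)) / 6))
  expect_error(rocAUC(numeric(0), 1:3), "nonempty")
})

test_that("logistic combination matches an independent MLE and preserves AUC", {
  # 6-point toy set with a unique finite MLE
  X <- matrix(c(-2, -1, 0, 0.5, 1, 2), ncol = 1)
  y <- c(0, 0, 1, 0, 1, 1)
  res <- logisticCombine(X, y)
  oracle <- .logisticNewton(X, y)
  expect_equal(unname(res$coefficients), oracle, tolerance = 1e-4)
  expect_true(res$converged)
  expect_lt(res$gradientNorm, 1e-6)
  # a single feature: the combined score is monotone in it, same AUC
  expect_equal(res$roc$auc, rocAUC(X[y == 1, 1], X[y == 0, 1])$auc)
  # adding a pure-noise feature cannot lose discrimination (n = 200 draws)
  set.seed(77)
  n <- 200
  yy <- rep(c(0, 1), each = n / 2)
  f1 <- yy * 1.2 + rnorm(n)
  f2 <- rnorm(n)
  aucSingle <- rocAUC(f1[yy == 1], f1[yy == 0])$auc
  both <- logisticCombine(cbind(f1, f2), yy)
  expect_gte(both$roc$auc, aucSingle - 0.02)
  # perfect separation flagged, AUC still reported
  sep <- logisticCombine(matrix(c(1, 2, 3, 10, 11, 12), ncol = 1),
                         c(0, 0, 0, 1, 1, 1))
  expect_true(sep$separated)
  expect_false(sep$converged)
  expect_equal(sep$roc$auc, 1)
  expect_error(logisticCombine(X, c(0, 0, 0, 0, 0, 1)), "2 samples")
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  set.seed(9)
  pos <- rnorm(40, 0.8)
  neg <- c(rnorm(55), pos[1:3])        # include ties across classes
  mine <- rocAUC(pos, neg)$auc
  ref <- suppressMessages(as.numeric(
    pROC::auc(c(rep(1, 40), rep(0, 58)), c(pos, neg), direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("binormal AUC converges to the probit closed form", {
  # two unit-variance Gaussians a distance dmu apart:
  # AUC -> Phi(dmu / sqrt(2))
  dmu <- 1
  for (seed in 1:2) {
    set.seed(seed)
    pos <- rnorm(1e4, dmu); neg <- rnorm(1e4, 0)
    expect_lt(abs(rocAUC(pos, neg)$auc - pnorm(dmu / sqrt(2))), 0.01)
  }
})
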