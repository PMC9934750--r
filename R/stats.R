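## Statistical battery accompanying the model comparison: paired t-test on
## fit RMSE, Pearson correlation between model parameters, one-way ANOVA
## with Tukey HSD across tissue classes, ROC/AUC with a Hanley-McNeil
## confidence interval, and binary logistic regression for combined
## parameters. Standard tests delegate to base R; AUC and its CI are
## computed directly from the Mann-Whitney statistic.

#' Paired t-test
#'
#' Two-sided paired Student t-test on the per-pair differences, df = n - 1.
#' With zero-variance differences the test statistic is undefined: the
#' result is p = 1 when the mean difference is zero (identical vectors),
#' otherwise the `degenerate` flag is set and p is NA.
#'
#' @param a,b paired numeric vectors of equal length (n >= 2).
#' @return list with `t`, `df`, `p`, `meanDiff`, `degenerate`.
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("a and b must be paired vectors of equal length >= 2")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = length(d) - 1L, p = 1, meanDiff = 0,
                  degenerate = TRUE))
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                meanDiff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanDiff = unname(tt$estimate), degenerate = FALSE)
}

#' Pearson correlation with significance test
#'
#' Product-moment correlation; p from `t = r sqrt((n-2)/(1-r^2))` on n - 2
#' degrees of freedom (two-sided).
#'
#' @param x,y numeric vectors, length >= 3, each with nonzero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must share length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' One-way ANOVA with post-hoc Tukey HSD
#'
#' Omnibus one-way ANOVA followed by all pairwise comparisons adjusted via
#' the studentized-range distribution (Tukey-Kramer for unequal group
#' sizes).
#'
#' @param values numeric vector of observations.
#' @param group factor/character of group labels (>= 2 groups, each n >= 2).
#' @return list with `F`, `anovaP`, `tukey` (data.frame: pair, diff, pAdj).
#' @export
anovaTukey <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs n >= 2")
  if (length(values) != length(group))
    stop("values and group must share length")
  fit <- stats::aov(values ~ group)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(F = s[["F value"]][1], anovaP = s[["Pr(>F)"]][1],
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          pAdj = tk[, "p adj"], row.names = NULL))
}

#' ROC analysis: AUC with a Hanley-McNeil 95 percent confidence interval
#'
#' AUC from the Mann-Whitney U statistic (ties credited 1/2), equal to the
#' probability that a random positive scores above a random negative. The
#' 95 percent CI uses the Hanley-McNeil standard error and is clipped to
#' `[0, 1]`.
#'
#' @param pos scores of the positive class (e.g. cancer ROIs).
#' @param neg scores of the negative class (e.g. normal tissue ROIs).
#' @return list with `auc`, `ci95Low`, `ci95High`, `se`, `nPos`, `nNeg`.
#' @export
rocAUC <- function(pos, neg) {
  nPos <- length(pos); nNeg <- length(neg)
  if (nPos == 0L || nNeg == 0L) stop("both score groups must be nonempty")
  r <- rank(c(pos, neg))
  U <- sum(r[seq_len(nPos)]) - nPos * (nPos + 1) / 2
  auc <- U / (nPos * nNeg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) +
                (nNeg - 1) * (q2 - auc^2)) / (nPos * nNeg))
  z <- stats::qnorm(0.975)
  list(auc = auc, ci95Low = max(0, auc - z * se),
       ci95High = min(1, auc + z * se), se = se, nPos = nPos, nNeg = nNeg)
}

#' Combine parameters with binary logistic regression and score by ROC
#'
#' Maximum-likelihood logistic regression (with intercept, no
#' regularization) of a binary outcome on a set of kinetic parameters,
#' fitted by iteratively reweighted least squares. The combined score is the
#' in-sample linear predictor; its discrimination is summarized by
#' [rocAUC()]. Perfect separation is flagged (`separated = TRUE`,
#' `converged = FALSE`) and the AUC is still reported from the final linear
#' predictor.
#'
#' @param features numeric matrix (samples x parameters) or vector.
#' @param labels binary vector (0/1 or logical), >= 2 samples per class.
#' @return list with `coefficients`, `scores` (linear predictor),
#'   `roc` (see [rocAUC()]), `converged`, `separated`, `gradientNorm`.
#' @export
logisticCombine <- function(features, labels) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1)")
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  if (any(!is.finite(X))) stop("features must be finite")
  df <- data.frame(y = y, X)
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning"))
  eta <- as.numeric(stats::predict(fit, type = "link"))
  p <- as.numeric(stats::fitted(fit))
  grad <- crossprod(cbind(1, X), y - p)           # score vector of the MLE
  gradNorm <- sqrt(sum(grad^2))
  separated <- any(p > 1 - 1e-8 & y == 1) && any(p < 1e-8 & y == 0) &&
    all(abs(p - y) < 1e-6)
  converged <- fit$converged && !separated && gradNorm < 1e-6
  list(coefficients = stats::coef(fit), scores = eta,
       roc = rocAUC(eta[y == 1], eta[y == 0]),
       converged = converged, separated = separated,
       gradientNorm = gradNorm)
}
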