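test_that("saturated single-predictor fit recovers the closed-form log odds", {
  # 2x2 table (8,2; 2,8): slope = log(16), intercept = log(2/8)
  x <- matrix(c(rep(1, 10), rep(0, 10)))
  y <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  fit <- fit_logistic(x, y, ridge = 0)
  expect_equal(unname(coef(fit)), c(log(2 / 8), log(16)), tolerance = 1e-6)
  # the default tiny ridge barely moves the estimate
  fit_r <- fit_logistic(x, y)
  expect_equal(unname(coef(fit_r)), c(log(2 / 8), log(16)), tolerance = 1e-3)
})

test_that("unpenalized fit matches glm and has a null gradient", {
  set.seed(41)
  x <- matrix(rnorm(120), 40, 3)
  colnames(x) <- c("a", "b", "c")
  y <- rbinom(40, 1, plogis(0.3 + x %*% c(1, -0.5, 0)))
  fit <- fit_logistic(x, y, ridge = 0)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$std_error),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-8)
  # gradient of the log-likelihood at the optimum
  mu <- fit$fitted
  g <- crossprod(cbind(1, x), y - mu)
  expect_lt(max(abs(g)), 1e-6)
  expect_true(fit$converged)
  # Wald statistics are (b/se)^2 with chi-square(1) p-values
  td <- tidy(fit)
  expect_equal(td$statistic, (td$estimate / td$std.error)^2)
  expect_equal(td$p.value, pchisq(td$statistic, 1, lower.tail = FALSE))
})

test_that("uninformative predictors give a null slope and logit(mean) intercept", {
  set.seed(43)
  x <- matrix(rnorm(400))
  y <- rep(c(0, 1), 200)
  fit <- fit_logistic(x, y, ridge = 0)
  expect_equal(unname(coef(fit))[2], 0, tolerance = 0.25)
  expect_equal(unname(coef(fit))[1], qlogis(mean(y)), tolerance = 0.25)
})

test_that("separation is detected and handled", {
  x <- matrix(c(1:5, 11:15))
  y <- rep(c(0, 1), each = 5)
  expect_warning(fit0 <- fit_logistic(x, y, ridge = 0), "separation")
  expect_false(fit0$converged)
  expect_true(fit0$separable)
  # a small ridge yields finite estimates that still separate perfectly
  fit <- fit_logistic(x, y)
  expect_true(all(is.finite(coef(fit))))
  cls <- classify(fit)
  expect_equal(cls$sensitivity + cls$specificity, 2)
  expect_error(fit_logistic(x, rep(1, 10)), "both classes")
  expect_error(fit_logistic(cbind(x, x[, 1] * 2), y), "collinear|Constant")
})

test_that("classification tables follow the >= cutoff rule", {
  # cases (0.9, 0.4), controls (0.8, 0.1) at cutoff 0.5
  cls <- classify(c(0.9, 0.4, 0.8, 0.1), c(1, 1, 0, 0))
  expect_equal(cls$confusion, c(tp = 1, fp = 1, tn = 1, fn = 1))
  expect_equal(cls$sensitivity, 0.5)
  expect_equal(cls$specificity, 0.5)
  # ties at the cutoff go to class 1
  tie <- classify(rep(0.5, 4), c(1, 0, 1, 0))
  expect_equal(unname(tie$confusion["fp"]), 2)
  expect_equal(tie$sensitivity, 1)
  # perfectly separated fit classifies perfectly
  x <- matrix(c(1:5, 11:15))
  y <- rep(c(0, 1), each = 5)
  fit <- fit_logistic(x, y)
  perfect <- classify(fit)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
})

test_that("ROC curves integrate to the pair-counting AUC", {
  expect_equal(auc(roc_curve(c(0.9, 0.4, 0.8, 0.1), c(1, 1, 0, 0))), 0.75)
  # complete separation
  expect_equal(auc(roc_curve(c(5, 6, 1, 2), c(1, 1, 0, 0))), 1)
  set.seed(47)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n, y), i %% 3)  # rounding induces ties
    r <- roc_curve(s, y)
    expect_equal(auc(r), auc_pairs(s, y), tolerance = 1e-9)
    # invariance under strictly increasing transforms
    expect_equal(auc(roc_curve(exp(s), y)), auc(r), tolerance = 1e-12)
    # curve is monotone after sorting
    o <- order(r$fpr, r$tpr)
    expect_true(all(diff(r$fpr[o]) >= 0) && all(diff(r$tpr[o]) >= 0))
  }
  # permuted labels at large n concentrate near 0.5
  set.seed(48)
  y <- rep(c(0, 1), 5000)
  expect_equal(auc(roc_curve(rnorm(10000), y)), 0.5, tolerance = 0.02)
  expect_error(roc_curve(1:4, rep(1, 4)), "Both classes")
})
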