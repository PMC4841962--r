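test_that("Mann-Whitney U statistic and exact p match enumeration", {
  # fully separated groups: U = 0, two-sided exact p = 2 / C(6,3)
  res <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  # symmetry: swapping groups flips U around n1*n2/2, same p
  res2 <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))
  expect_equal(res2$U, 9)
  expect_equal(res2$p, 0.1)
  # identical multisets: U = n1*n2/2 and p capped at 1
  res3 <- mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(res3$U, 8)
  expect_equal(res3$p, 1)
  # random small samples with ties against the full-enumeration oracle
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    expect_equal(mann_whitney_u(x, y, exact = TRUE)$p,
                 mw_exact_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney normal approximation matches wilcox.test", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- rnorm(12, 0.5)
    if (i > 5) { # introduce ties to exercise the tie-corrected variance
      x <- round(x)
      y <- round(y)
    }
    res <- mann_whitney_u(x, y, exact = FALSE)
    ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
    expect_equal(unname(res$U), unname(ref$statistic))
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Benjamini-Hochberg step-up matches the direct formula", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand step-up oracle on random vectors; q >= p elementwise
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))^2
    m <- length(p)
    o <- order(p)
    q_or <- numeric(m)
    prev <- 1
    for (j in rev(seq_len(m))) {
      prev <- min(prev, m * p[o[j]] / j)
      q_or[o[j]] <- prev
    }
    expect_equal(bh_fdr(p), q_or, tolerance = 1e-12)
    expect_true(all(bh_fdr(p) >= p - 1e-15))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Z-score difference and Cohen's d follow their definitions", {
  eq <- effect_sizes(c(1, 2, 3), c(2, 2, 2) + c(-1, 0, 1))
  expect_equal(eq$z_diff, 0)
  expect_equal(eq$d, 0)
  # hand computation: delta = 2, pooled SD = sqrt(2), control SD = sqrt(2)
  hand <- effect_sizes(c(2, 4), c(0, 2))
  expect_equal(hand$d, 2 / sqrt(2))
  expect_equal(hand$z_diff, 2 / sqrt(2))
  expect_warning(res <- effect_sizes(c(1, 2), c(3, 3)), "z_diff undefined")
  expect_true(is.na(res$z_diff))
})

test_that("Spearman correlation matches rank formula and cor.test", {
  expect_equal(spearman_cor(1:6, c(2, 4, 5, 7, 10, 11))$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(1, 3, 2))$rho, 0.5)
  set.seed(13)
  for (i in 1:8) {
    x <- rnorm(20)
    y <- 0.5 * x + rnorm(20)
    if (i > 4) y <- round(y)  # midrank handling under ties
    res <- spearman_cor(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(unname(res$rho), unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
  # pairwise-complete handling of missing scores
  x <- c(1, 2, 3, 4, NA)
  y <- c(2, 1, 4, NA, 5)
  expect_equal(spearman_cor(x, y)$n, 3)
  expect_warning(res <- spearman_cor(c(1, 1, 1), c(1, 2, 3)), "Constant")
  expect_true(is.na(res$rho))
})

test_that("rank statistics are invariant under strictly monotone transforms", {
  set.seed(17)
  x <- rexp(12)
  y <- rexp(10, 0.6)
  f <- function(v) log(v + 1) * 3 - 2
  expect_equal(mann_whitney_u(x, y), mann_whitney_u(f(x), f(y)))
  z <- rnorm(12)
  expect_equal(spearman_cor(x, z)$rho, spearman_cor(f(x), z)$rho)
})
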