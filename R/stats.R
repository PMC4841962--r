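# Rank and effect-size statistics used by the differential screen.

#' Mann-Whitney U test
#'
#' Two-sample rank test. `U` counts the pairs `(x_i, y_j)` with
#' `x_i > y_j`, plus half the tied pairs, so `U / (n1 * n2)` is the
#' probability that a random `x` exceeds a random `y` (the single-feature
#' ROC AUC). The two-sided p-value comes from the normal approximation
#' with tie-corrected variance and a 0.5 continuity correction; for small
#' samples (`n1 + n2 <= 12` by default) every label assignment is
#' enumerated instead and the p-value is the exact probability of a `U` at
#' least as far from its null mean `n1 n2 / 2` as observed.
#'
#' @param x,y Numeric value vectors for the two groups (each non-empty).
#' @param exact `TRUE`/`FALSE` to force or suppress exact enumeration;
#'   `NULL` (default) enumerates when `length(x) + length(y) <= 12`.
#' @return Tibble with columns `U` and `p`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 11, 12))  # U = 0, exact p = 0.1
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("Both groups must be non-empty.")
  N <- n1 + n2
  if (is.null(exact)) exact <- N <= 12
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (exact) {
    Us <- u_enumerate(c(x, y), n1)
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
  }
  tibble::tibble(U = U, p = p)
}

# All U statistics over the C(N, n1) assignments of the pooled values.
u_enumerate <- function(pooled, n1) {
  r <- rank(pooled)
  idx <- combn(length(pooled), n1)
  colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1, returned in the input
#' order. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, elementwise `>= p`.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] and be non-missing.")
  }
  p.adjust(p, method = "BH")
}

#' Standardized group effect sizes
#'
#' Computes, on whatever scale the inputs are given (the screen uses
#' `log2(RPM + 1)`):
#' * `z_diff` -- the mean case-control difference in units of the control
#'   group's standard deviation;
#' * `d` -- Cohen's d, the same difference over the pooled standard
#'   deviation `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' A zero reference SD yields `NA` with a warning rather than a silent 0.
#'
#' @param case,control Numeric vectors of per-group values (each length
#'   >= 2).
#' @return Tibble with columns `z_diff` and `d`.
#' @export
effect_sizes <- function(case, control) {
  stopifnot(length(case) >= 2, length(control) >= 2)
  delta <- mean(case) - mean(control)
  s_ctrl <- sd(control)
  n1 <- length(case)
  n2 <- length(control)
  pooled <- sqrt(((n1 - 1) * var(case) + (n2 - 1) * var(control)) /
                   (n1 + n2 - 2))
  z_diff <- if (s_ctrl > 0) delta / s_ctrl else {
    warn("Control SD is zero; z_diff undefined.")
    NA_real_
  }
  d <- if (pooled > 0) delta / pooled else {
    warn("Pooled SD is zero; Cohen's d undefined.")
    NA_real_
  }
  tibble::tibble(z_diff = z_diff, d = d)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of midranks over pairwise-complete observations;
#' the p-value uses `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. Constant inputs give `NA` with a warning.
#'
#' @param x,y Numeric vectors (pairwise-complete length >= 3).
#' @return Tibble with columns `rho`, `p`, and `n` (complete pairs used).
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant input; Spearman rho undefined.")
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n)
}
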