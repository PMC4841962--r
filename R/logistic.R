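#' Maximum-likelihood logistic regression with an optional ridge penalty
#'
#' Fits `P(Y = 1 | x) = 1 / (1 + exp(-(a + b'x)))` by Newton / iteratively
#' reweighted least squares, iterating until the relative change in the
#' (penalized) log-likelihood falls below `tol` or `max_iter` iterations.
#' Predictors are z-scored internally for numerical stability and the
#' coefficients mapped back to the original scale; Wald statistics are
#' scale-invariant. A small ridge penalty (`ridge/2 * sum(b^2)`, never on
#' the intercept; default `1e-6`) keeps estimates finite under the perfect
#' separation that is near-certain with many predictors and few subjects,
#' while leaving non-separable fits numerically unchanged. With
#' `ridge = 0` on separable data the best iterate is returned with
#' `converged = FALSE` and a separation warning.
#'
#' @param x Predictor matrix or data frame (subjects x predictors).
#' @param y Binary outcome: 0/1, logical, or `case`/`control` labels
#'   (case = 1).
#' @param ridge Non-negative penalty on the slope coefficients.
#' @param max_iter,tol Iteration controls.
#'
#' @return Object of class `mir_logit` with coefficients, standard errors,
#'   Wald statistics (`(b/se)^2`, chi-square on 1 df), log-likelihood,
#'   fitted probabilities and convergence information. Supports
#'   [predict()], [tidy()] and [glance()].
#' @export
#' @examples
#' x <- matrix(c(rep(1, 10), rep(0, 10)))
#' y <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
#' coef(fit_logistic(x, y, ridge = 0))  # intercept -log(4), slope log(16)
fit_logistic <- function(x, y, ridge = 1e-6, max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- if (is.numeric(y) || is.logical(y)) as.integer(y) else group_to_y(y)
  if (length(unique(y)) < 2) abort("`y` must contain both classes.")
  stopifnot(nrow(x) == length(y), ridge >= 0)

  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0)) {
    abort(paste0("Constant predictor(s): ",
                 paste(colnames(x)[scl == 0], collapse = ", ")))
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  qx <- qr(cbind(1, xs))
  if (qx$rank < ncol(xs) + 1) {
    bad <- colnames(xs)[setdiff(seq_len(ncol(xs)), qx$pivot[seq_len(qx$rank)] - 1L)]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }

  X1 <- cbind(`(Intercept)` = 1, xs)
  p <- ncol(X1)
  pen <- c(0, rep(ridge, p - 1L))
  beta <- rep(0, p)
  pll <- function(b) {
    eta <- drop(X1 %*% b)
    # log(1 + e^eta) = max(eta, 0) + log1p(e^-|eta|), overflow-safe
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) -
      sum(pen * b^2) / 2
  }
  ll_old <- pll(beta)
  converged <- FALSE
  separable <- FALSE
  iter <- 0L
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- plogis(drop(X1 %*% beta))
    w <- mu * (1 - mu)
    H <- crossprod(X1, X1 * w) + diag(pen, p)
    g <- drop(crossprod(X1, y - mu)) - pen * beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      separable <- TRUE
      break
    }
    # step-halving if the penalized log-likelihood does not improve
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- pll(cand)
      if (ll_new >= ll_old - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- cand
    if (abs(ll_new - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  mu <- plogis(drop(X1 %*% beta))
  if (all(abs(mu - y) < 1e-8)) separable <- TRUE
  if (ridge == 0 && separable) {
    converged <- FALSE
    warn("Perfect separation detected; coefficients are not identified (consider a small ridge).")
  }

  # covariance on the standardized scale, then linear map to original units
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(X1, X1 * w) + diag(pen, p)
  cov_std <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  Tm <- diag(1 / c(1, scl))
  Tm[1, -1] <- -ctr / scl
  coef_orig <- drop(Tm %*% beta)
  cov_orig <- Tm %*% cov_std %*% t(Tm)
  se <- sqrt(diag(cov_orig))
  names(coef_orig) <- names(se) <- c("(Intercept)", colnames(xs))
  wald <- (coef_orig / se)^2
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))

  structure(
    list(coefficients = coef_orig, std_error = se, wald = wald,
         wald_p = pchisq(wald, 1, lower.tail = FALSE),
         log_likelihood = ll, fitted = mu, y = y,
         center = ctr, scale = scl, coef_std = beta,
         ridge = ridge, converged = converged, separable = separable,
         n_iterations = iter),
    class = "mir_logit"
  )
}

#' @export
coef.mir_logit <- function(object, ...) object$coefficients

#' @export
predict.mir_logit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x <- as.matrix(newdata)
  b <- object$coefficients
  plogis(drop(b[1] + x %*% b[-1]))
}

#' @export
print.mir_logit <- function(x, ...) {
  cat(sprintf("<mir_logit> %d predictors, logLik %.3f, %s in %d iterations%s\n",
              length(x$coefficients) - 1L, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations,
              if (x$separable) " (separation)" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mir_logit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$std_error),
                 statistic = unname(x$wald),
                 p.value = unname(x$wald_p))
}

#' @exportS3Method generics::glance
glance.mir_logit <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood,
                 deviance = -2 * x$log_likelihood,
                 nobs = length(x$y),
                 n_iterations = x$n_iterations,
                 converged = x$converged,
                 separable = x$separable)
}

#' Classification table at a probability cutoff
#'
#' Assigns each subject to the positive (case) class iff its predicted
#' probability is `>= cutoff` (ties go to the positive class) and
#' tabulates the 2x2 confusion table with sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and accuracy.
#'
#' @param probs Predicted probabilities, or a `mir_logit` model (its
#'   fitted probabilities are used).
#' @param y Binary outcomes or group labels; defaults to the model's
#'   training outcome when `probs` is a model.
#' @param cutoff Probability cutoff (default 0.5).
#' @return List of class `mir_classification`: `confusion` (tp, fp, tn,
#'   fn), `sensitivity`, `specificity`, `accuracy`, `cutoff`,
#'   `probabilities`, `predicted`.
#' @export
classify <- function(probs, y = NULL, cutoff = 0.5) {
  if (inherits(probs, "mir_logit")) {
    if (is.null(y)) y <- probs$y
    probs <- probs$fitted
  }
  y <- if (is.numeric(y) || is.logical(y)) as.integer(y) else group_to_y(y)
  stopifnot(length(probs) == length(y))
  pred <- as.integer(probs >= cutoff)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  structure(
    list(confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         accuracy = (tp + tn) / length(y),
         cutoff = cutoff, probabilities = probs, predicted = pred),
    class = "mir_classification"
  )
}

#' @export
print.mir_classification <- function(x, ...) {
  cat(sprintf("<mir_classification> cutoff %.2f | sens %.1f%% spec %.1f%% acc %.1f%%\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mir_classification <- function(x, ...) {
  tibble::tibble(tp = x$confusion["tp"], fp = x$confusion["fp"],
                 tn = x$confusion["tn"], fn = x$confusion["fn"],
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 accuracy = x$accuracy, cutoff = x$cutoff)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the classification cutoff over every distinct score (plus
#' infinite endpoints), records (FPR, TPR) at each, and integrates by the
#' trapezoidal rule; tied scores contribute half, so the area equals the
#' Mann-Whitney `U / (n1 n2)` of the scores.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param y Binary outcomes or group labels (both classes required).
#' @return Tibble of class `mir_roc` with columns `cutoff`, `fpr`, `tpr`;
#'   the area is in `attr(, "auc")` (see [auc()]).
#' @export
#' @examples
#' r <- roc_curve(c(0.9, 0.4, 0.8, 0.1), c(1, 1, 0, 0))
#' auc(r)  # 0.75
roc_curve <- function(scores, y) {
  y <- if (is.numeric(y) || is.logical(y)) as.integer(y) else group_to_y(y)
  stopifnot(length(scores) == length(y))
  if (length(unique(y)) < 2) abort("Both classes must be present.")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  cutoffs <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- purrr::map_dfr(cutoffs, function(ct) {
    pred <- scores >= ct
    tibble::tibble(cutoff = ct,
                   fpr = sum(pred & y == 0) / n0,
                   tpr = sum(pred & y == 1) / n1)
  })
  o <- order(pts$fpr, pts$tpr)
  a <- sum(diff(pts$fpr[o]) * (pts$tpr[o][-1] + pts$tpr[o][-nrow(pts)]) / 2)
  structure(pts, class = c("mir_roc", class(pts)), auc = a)
}

#' @rdname roc_curve
#' @param roc A `mir_roc` object.
#' @export
auc <- function(roc) {
  attr(roc, "auc")
}

#' @exportS3Method ggplot2::autoplot
autoplot.mir_roc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}
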