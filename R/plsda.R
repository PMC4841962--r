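#' Partial least squares discriminant analysis (NIPALS)
#'
#' Fits a PLS1 regression of the centered 0/1 class code on the
#' column-standardized predictor matrix by NIPALS deflation: each
#' component's X-weights are the (normalized) covariance of the current
#' residual matrix with the class residual, scores are the corresponding
#' linear combination, and both X and y are deflated before the next
#' component. Successive score vectors are mutually orthogonal. The
#' regression coefficient vector on the standardized predictors is
#' `W (P'W)^{-1} q`; predictions are `ybar + x_std %*% coef`.
#'
#' @param x Predictor matrix or data frame (subjects x features).
#' @param y Binary outcome: 0/1, logical, or `case`/`control` labels.
#' @param n_components Number of latent components; silently capped at
#'   `min(n_samples - 1, n_features)` and reduced with a warning if the
#'   residual matrix runs out of rank.
#'
#' @return Object of class `mir_plsda` with weights, loadings, training
#'   scores, standardized coefficients, centering/scaling vectors and the
#'   fraction of (standardized) X-variance explained per component.
#'   Supports [predict()] (raw continuous class score; clip to \[0, 1\]
#'   for a probability) and [plsda_scores()].
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2)
#' y <- rbinom(20, 1, 0.5)
#' fit <- fit_plsda(x, y, n_components = 2)
#' round(crossprod(fit$scores), 8)  # diagonal: orthogonal scores
fit_plsda <- function(x, y, n_components = 3) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- if (is.numeric(y) || is.logical(y)) as.numeric(y) else group_to_y(y)
  stopifnot(nrow(x) == length(y))
  n <- nrow(x)
  p <- ncol(x)
  A <- min(n_components, n - 1L, p)

  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1  # constant columns carry no information
  X <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  tss <- sum(X^2)
  ybar <- mean(y)
  yc <- y - ybar

  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  varx <- numeric(A)
  a <- 0L
  for (h in seq_len(A)) {
    w <- drop(crossprod(X, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_h <- drop(X %*% w)
    tt <- sum(t_h^2)
    if (tt < 1e-12) break
    p_h <- drop(crossprod(X, t_h)) / tt
    q_h <- sum(yc * t_h) / tt
    X <- X - tcrossprod(t_h, p_h)
    yc <- yc - q_h * t_h
    a <- h
    W[, h] <- w
    P[, h] <- p_h
    Tm[, h] <- t_h
    q[h] <- q_h
    varx[h] <- tt * sum(p_h^2) / tss
  }
  if (a < n_components && a < min(n - 1L, p)) {
    warn(sprintf("Residual rank exhausted; fitted %d of %d components.",
                 a, n_components))
  }
  if (a == 0L) abort("No usable PLS component (X'y is null).")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  varx <- varx[seq_len(a)]

  R <- W %*% solve(crossprod(P, W))
  coef_std <- drop(R %*% q)
  names(coef_std) <- colnames(x)
  rownames(Tm) <- rownames(x)

  structure(
    list(weights = W, loadings = P, y_loadings = q, scores = Tm,
         rotation = R, coef_std = coef_std, center = ctr, scale = scl,
         ybar = ybar, var_explained = varx, n_components = a,
         n_requested = n_components),
    class = "mir_plsda"
  )
}

#' @export
predict.mir_plsda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  drop(object$ybar + xs %*% object$coef_std)
}

#' @export
print.mir_plsda <- function(x, ...) {
  cat(sprintf("<mir_plsda> %d components, X-variance explained %s\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * x$var_explained),
                    collapse = " + ")))
  invisible(x)
}

#' Per-subject PLS-DA component scores
#'
#' Projects subjects onto the latent components of a fitted PLS-DA model
#' (the 3-axis coordinates used to visualize group separation) together
#' with the per-component and cumulative fractions of predictor variance
#' they explain.
#'
#' @param model A `mir_plsda` fit.
#' @param x Optional new data (subjects x features); defaults to the
#'   training scores.
#' @return Tibble with `subject_id` and one `comp_*` column per component;
#'   attributes `var_explained` and `cum_var_explained`.
#' @export
plsda_scores <- function(model, x = NULL) {
  Tm <- if (is.null(x)) {
    model$scores
  } else {
    xs <- sweep(sweep(as.matrix(x), 2, model$center), 2, model$scale, "/")
    xs %*% model$rotation
  }
  out <- tibble::as_tibble(Tm, .name_repair = ~ paste0("comp_", seq_along(.x)))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = rownames(Tm) %||% as.character(seq_len(nrow(Tm)))),
    out
  )
  attr(out, "var_explained") <- model$var_explained
  attr(out, "cum_var_explained") <- cumsum(model$var_explained)
  out
}

#' @importFrom rlang %||%
NULL

#' Coefficient-based feature importance
#'
#' Ranks features by the sum over models of the absolute standardized
#' PLS-DA regression coefficients, descending, with deterministic
#' alphabetical tie-breaking. With a single model this is simply `|b_j|`.
#'
#' @param models A `mir_plsda` fit or a list of them (e.g., one per
#'   cross-validation iteration).
#' @return Tibble with columns `feature`, `importance`, `rank`.
#' @export
feature_importance <- function(models) {
  if (inherits(models, "mir_plsda")) models <- list(models)
  stopifnot(length(models) >= 1)
  imp <- purrr::map(models, ~ abs(.x$coef_std)) |>
    purrr::reduce(`+`)
  out <- tibble::tibble(feature = names(imp), importance = unname(imp))
  # rank on 12 significant digits so float-noise ties break by feature id
  out <- out[order(-signif(out$importance, 12), out$feature), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.mir_plsda <- function(object, y = NULL, ...) {
  sc <- plsda_scores(object)
  df <- sc
  if (!is.null(y)) df$group <- as_group(y)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$comp_1, y = .data$comp_2)) +
    ggplot2::labs(
      x = sprintf("Component 1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("Component 2 (%.1f%%)",
                  100 * object$var_explained[min(2, object$n_components)])) +
    ggplot2::theme_minimal()
  if (is.null(y)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}
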