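#' Monte-Carlo cross-validated PLS-DA panel evaluation
#'
#' Repeats `n_iter` times: draw a class-stratified training set
#' (`round(train_frac * n)` subjects per class, preserving the class
#' ratio -- "balanced subsampling"), fit a full-panel PLS-DA on it, rank
#' the features by absolute standardized coefficient, then for each panel
#' size `k` refit on the top-`k` training features (with
#' `min(n_components, k)` components) and score the held-out third. The
#' held-out continuous PLS prediction, clipped to \[0, 1\], is the class
#' probability. Reported per panel size: the mean held-out ROC AUC across
#' iterations with a 95% t-interval. Per subject: the average predicted
#' probability over the iterations in which the subject was held out
#' (largest panel), classified at `cutoff` into a confusion table with the
#' misclassified subject list. Iteration `i` consumes an independent seed
#' substream, so results do not depend on the order of `panel_sizes`.
#'
#' @param x Predictor matrix or data frame (subjects x features); row
#'   names identify subjects.
#' @param y Binary outcome or `case`/`control` labels (>= 3 per class).
#' @param n_iter Number of Monte-Carlo iterations (default 100).
#' @param train_frac Training fraction per class (default 2/3).
#' @param panel_sizes Panel sizes to evaluate (default 2, 3, 5, 7, 10, 14);
#'   sizes above `ncol(x)` are capped.
#' @param n_components PLS components (capped at panel size and rank).
#' @param seed Integer seed governing the whole iteration stream.
#' @param cutoff Probability cutoff for the averaged-probability
#'   classification.
#' @param equal_classes If `TRUE`, draw class-equal training sets of size
#'   `round(train_frac * min(n_case, n_control))` per class instead of
#'   proportional ones.
#'
#' @return Object of class `mir_mccv` with elements `auc` (per-panel-size
#'   tibble: `panel_size`, `mean_auc`, `ci_low`, `ci_high`, `n_iter`),
#'   `importance` (aggregate ranking, summed `|b|` over iterations),
#'   `subject_probs`, `classification` (a `mir_classification` at
#'   `cutoff` on the averaged probabilities), `misclassified`,
#'   `pooled_auc` (ROC AUC of the averaged probabilities), `splits`, and
#'   the call parameters. Supports [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' set.seed(9)
#' x <- rbind(matrix(rnorm(60, 2), 10), matrix(rnorm(60, -2), 10))
#' y <- rep(c(1, 0), each = 10)
#' res <- mccv(x, y, n_iter = 10, panel_sizes = c(2, 4), seed = 3)
#' tidy(res)
mccv <- function(x, y, n_iter = 100, train_frac = 2 / 3,
                 panel_sizes = c(2, 3, 5, 7, 10, 14), n_components = 3,
                 seed = 1L, cutoff = 0.5, equal_classes = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- sprintf("s%02d", seq_len(nrow(x)))
  yy <- if (is.numeric(y) || is.logical(y)) as.integer(y) else group_to_y(y)
  n <- nrow(x)
  p <- ncol(x)
  if (sum(yy == 1) < 3 || sum(yy == 0) < 3) {
    abort("Need at least 3 subjects per class.")
  }
  panel_sizes <- sort(unique(pmin(panel_sizes, p)))
  k_max <- max(panel_sizes)
  idx1 <- which(yy == 1)
  idx0 <- which(yy == 0)
  n_tr1 <- if (equal_classes) round(train_frac * min(length(idx1), length(idx0))) else round(train_frac * length(idx1))
  n_tr0 <- if (equal_classes) n_tr1 else round(train_frac * length(idx0))

  iter_seeds <- derive_seeds(seed, n_iter)
  auc_mat <- matrix(NA_real_, n_iter, length(panel_sizes),
                    dimnames = list(NULL, panel_sizes))
  prob_sum <- numeric(n)
  prob_n <- integer(n)
  imp_sum <- setNames(numeric(p), colnames(x))
  splits <- vector("list", n_iter)

  for (i in seq_len(n_iter)) {
    res_i <- withr::with_seed(iter_seeds[i], {
      repeat {
        train <- c(sample(idx1, n_tr1), sample(idx0, n_tr0))
        test <- setdiff(seq_len(n), train)
        if (length(unique(yy[test])) == 2L) break
        inform("Held-out fold missed a class; redrawing split.")
      }
      full <- suppressWarnings(
        fit_plsda(x[train, , drop = FALSE], yy[train],
                  n_components = min(n_components, k_max, length(train) - 1L))
      )
      ranking <- feature_importance(full)$feature
      per_k <- lapply(panel_sizes, function(k) {
        feats <- ranking[seq_len(k)]
        fit_k <- suppressWarnings(
          fit_plsda(x[train, feats, drop = FALSE], yy[train],
                    n_components = min(n_components, k, length(train) - 1L))
        )
        prob <- clip01(predict(fit_k, x[test, feats, drop = FALSE]))
        list(auc = auc(roc_curve(prob, yy[test])), prob = prob)
      })
      list(train = train, test = test, per_k = per_k,
           imp = abs(full$coef_std))
    })
    splits[[i]] <- list(train = rownames(x)[res_i$train],
                        test = rownames(x)[res_i$test])
    auc_mat[i, ] <- vapply(res_i$per_k, `[[`, numeric(1), "auc")
    imp_sum <- imp_sum + res_i$imp
    full_prob <- res_i$per_k[[length(panel_sizes)]]$prob
    test <- res_i$test
    prob_sum[test] <- prob_sum[test] + full_prob
    prob_n[test] <- prob_n[test] + 1L
  }

  auc_tbl <- purrr::map_dfr(seq_along(panel_sizes), function(j) {
    v <- auc_mat[, j]
    se <- sd(v) / sqrt(n_iter)
    hw <- qt(0.975, n_iter - 1) * se
    tibble::tibble(panel_size = panel_sizes[j], mean_auc = mean(v),
                   ci_low = max(0, mean(v) - hw),
                   ci_high = min(1, mean(v) + hw), n_iter = n_iter)
  })

  imp_tbl <- tibble::tibble(feature = names(imp_sum),
                            importance = unname(imp_sum)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature) |>
    dplyr::mutate(rank = dplyr::row_number())

  held <- prob_n > 0
  mean_prob <- ifelse(held, prob_sum / pmax(prob_n, 1L), NA_real_)
  subject_probs <- tibble::tibble(
    subject_id = rownames(x), y = yy, n_heldout = prob_n,
    mean_prob = mean_prob,
    predicted = ifelse(held, as.integer(mean_prob >= cutoff), NA_integer_)
  )
  cls <- classify(mean_prob[held], yy[held], cutoff = cutoff)
  pooled_auc <- auc(roc_curve(mean_prob[held], yy[held]))
  miscl <- subject_probs$subject_id[held][cls$predicted != yy[held]]

  structure(
    list(auc = auc_tbl, importance = imp_tbl,
         subject_probs = subject_probs, classification = cls,
         misclassified = miscl, pooled_auc = pooled_auc, splits = splits,
         n_iter = n_iter, train_frac = train_frac,
         panel_sizes = panel_sizes, n_components = n_components,
         seed = seed, cutoff = cutoff),
    class = "mir_mccv"
  )
}

#' @export
print.mir_mccv <- function(x, ...) {
  full <- x$auc[x$auc$panel_size == max(x$auc$panel_size), ]
  cat(sprintf(
    "<mir_mccv> %d iterations | full-panel mean AUC %.3f [%.3f, %.3f] | accuracy %.1f%%\n",
    x$n_iter, full$mean_auc, full$ci_low, full$ci_high,
    100 * x$classification$accuracy))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mir_mccv <- function(x, ...) x$auc

#' @exportS3Method generics::glance
glance.mir_mccv <- function(x, ...) {
  full <- x$auc[x$auc$panel_size == max(x$auc$panel_size), ]
  cls <- x$classification
  tibble::tibble(mean_auc_full = full$mean_auc, pooled_auc = x$pooled_auc,
                 accuracy = cls$accuracy, sensitivity = cls$sensitivity,
                 specificity = cls$specificity,
                 n_misclassified = length(x$misclassified),
                 n_iter = x$n_iter, seed = x$seed)
}

#' @exportS3Method ggplot2::autoplot
autoplot.mir_mccv <- function(object, ...) {
  ggplot2::ggplot(object$auc,
                  ggplot2::aes(x = .data$panel_size, y = .data$mean_auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$auc$panel_size) +
    ggplot2::labs(x = "Panel size (miRNAs)", y = "Mean held-out ROC AUC") +
    ggplot2::theme_minimal()
}
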