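#' Differential screen of miRNA features
#'
#' Per-feature two-group screening on a normalized, detection-filtered
#' expression matrix: Mann-Whitney U with two-sided p, Benjamini-Hochberg
#' q, the control-referenced Z-score difference and Cohen's d computed on
#' `log2(RPM + 1)`, and Spearman correlations with behavior measures
#' pooled across both groups. A feature is selected for the panel iff
#' `p < p_threshold` **and** `q < q_threshold` (defaults p < 0.05,
#' FDR < 0.15).
#'
#' @param rpm Reads-per-million tibble or matrix from [rpm_normalize()],
#'   already passed through [detection_filter()].
#' @param metadata Subject table with `subject_id` and a binary `group`
#'   column (`case`/`control`); rows must cover the matrix columns.
#' @param p_threshold,q_threshold Joint selection thresholds.
#' @param measures Character vector of metadata columns to correlate with
#'   each feature (Spearman, pairwise complete, subjects pooled). `NULL`
#'   auto-detects numeric columns such as `age_years`, `ados` and the
#'   `vabs_*` scores; `character(0)` skips correlations.
#' @param exact Passed to [mann_whitney_u()].
#'
#' @return A tibble of class `mir_screen`, one row per feature in input
#'   order: `mirna_id`, `U`, `p`, `q`, `z_diff`, `d`, one `rho_*` /
#'   `rho_p_*` pair per measure, and `selected`. The selected panel
#'   (feature ids ordered by increasing p) is in `attr(, "panel")`.
#' @export
#' @examples
#' sim <- sim_counts(sim_design(n_case = 8, n_control = 8, n_features = 25,
#'                              informative_effects = c(2.5, -2.5), seed = 7))
#' rpm <- detection_filter(sim$counts) |> rpm_normalize()
#' meta <- sim$subjects[, c("subject_id", "group")]
#' scr <- run_screen(rpm, meta, measures = character(0))
#' attr(scr, "panel")
run_screen <- function(rpm, metadata,
                       p_threshold = 0.05, q_threshold = 0.15,
                       measures = NULL, exact = NULL) {
  m <- log2_rpm(rpm)
  metadata <- metadata[match(colnames(m), metadata$subject_id), ]
  if (anyNA(metadata$subject_id)) {
    abort("Metadata does not cover all subjects in the matrix.")
  }
  grp <- as_group(metadata$group)
  is_case <- grp == levels(grp)[2]
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    abort("Need at least 2 subjects per group.")
  }
  if (is.null(measures)) {
    candidates <- c("age_years", "ados", "vabs_comm", "vabs_social",
                    "vabs_adl", "vabs_comp")
    measures <- intersect(candidates, names(metadata))
    measures <- measures[vapply(metadata[measures], is.numeric, logical(1))]
  }

  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    mw <- mann_whitney_u(v[is_case], v[!is_case], exact = exact)
    es <- suppressWarnings(effect_sizes(v[is_case], v[!is_case]))
    row <- tibble::tibble(mirna_id = rownames(m)[i], U = mw$U, p = mw$p,
                          z_diff = es$z_diff, d = es$d)
    for (ms in measures) {
      sc <- suppressWarnings(spearman_cor(v, metadata[[ms]]))
      row[[paste0("rho_", ms)]] <- sc$rho
      row[[paste0("rho_p_", ms)]] <- sc$p
    }
    row
  })
  res$q <- bh_fdr(res$p)
  res$selected <- res$p < p_threshold & res$q < q_threshold
  res <- dplyr::relocate(res, "q", .after = "p")

  panel <- res$mirna_id[res$selected][order(res$p[res$selected])]
  structure(res,
            class = c("mir_screen", class(res)),
            panel = panel,
            thresholds = c(p = p_threshold, q = q_threshold))
}

#' Selected panel of a screen result
#'
#' @param screen A `mir_screen` result.
#' @param max_size Optional cap; keeps the `max_size` smallest-p features.
#' @return Character vector of feature identifiers ordered by p-value.
#' @export
screen_panel <- function(screen, max_size = Inf) {
  panel <- attr(screen, "panel")
  head(panel, min(length(panel), max_size))
}

#' @exportS3Method ggplot2::autoplot
autoplot.mir_screen <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = -log10(.data$p),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "thresholds")["p"]),
                        linetype = "dashed") +
    ggplot2::labs(x = "Cohen's d (log2 RPM + 1)",
                  y = expression(-log[10](p)),
                  colour = "Selected") +
    ggplot2::theme_minimal()
}
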