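#' Keep the top-scoring fraction of predicted targets per miRNA
#'
#' Per miRNA, retains the `ceiling(fraction * n_targets)` highest-scoring
#' prediction rows ("top 20%" by default, rounding up so the kept set is
#' never empty). Ties at the boundary are broken by score descending then
#' gene identifier ascending, so the output is deterministic and never
#' keeps extra rows.
#'
#' @param targets Prediction tibble with columns `mirna`, `gene`, `score`.
#' @param fraction Fraction in (0, 1] of targets kept per miRNA.
#' @return Filtered tibble (same columns).
#' @export
top_fraction_filter <- function(targets, fraction = 0.20) {
  stopifnot(fraction > 0, fraction <= 1)
  if (anyNA(targets$score)) abort("Missing prediction scores.")
  targets |>
    dplyr::group_by(.data$mirna) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene, .by_group = TRUE) |>
    dplyr::slice(seq_len(ceiling(fraction * dplyr::n()))) |>
    dplyr::ungroup()
}

#' De-duplicated union of target genes
#'
#' @param targets Prediction tibble (e.g., after [top_fraction_filter()]).
#' @return Character vector of unique gene identifiers.
#' @export
unique_targets <- function(targets) {
  unique(targets$gene)
}

#' Fisher's exact enrichment of a gene set among predicted targets
#'
#' Forms the 2x2 table of membership in the high-confidence target set
#' versus membership in the candidate gene set over a stated gene universe
#' of size `universe`: `a` genes in both, `b` targets outside the set,
#' `c` set genes that are not targets, and `d = universe - a - b - c`
#' neither. Reports the sample odds ratio `ad / bc` (with a 0.5 Haldane
#' correction only if a cell is zero, flagged), its 95% Wald confidence
#' interval on the log scale, the two-sided Fisher exact p-value
#' (hypergeometric summation of all tables with probability not exceeding
#' the observed one), and the fold enrichment
#' `(a / (a + b)) / ((a + c) / universe)`.
#'
#' @param target_genes Character vector of high-confidence target genes.
#' @param gene_set Character vector of candidate genes (assumed within the
#'   universe).
#' @param universe Gene universe size `N` (must cover both sets). The
#'   published analysis never states its universe; it is therefore an
#'   explicit, echoed parameter here (20,000 protein-coding genes by
#'   default in the pipeline).
#' @return List of class `mir_enrichment`: `table` (a, b, c, d),
#'   `odds_ratio`, `ci_low`, `ci_high`, `fisher_p`, `fold_enrichment`,
#'   `universe`, `n_targets`, `n_set`, `overlap_genes`, `haldane`.
#' @export
#' @examples
#' fisher_enrichment(sprintf("g%02d", 1:10), sprintf("g%02d", 6:25), 100)
fisher_enrichment <- function(target_genes, gene_set, universe) {
  target_genes <- unique(target_genes)
  gene_set <- unique(gene_set)
  a <- length(intersect(target_genes, gene_set))
  b <- length(target_genes) - a
  c_ <- length(gene_set) - a
  d <- universe - a - b - c_
  if (d < 0) abort("`universe` is smaller than the union of the two sets.")

  haldane <- any(c(a, b, c_, d) == 0)
  cc <- if (haldane) 0.5 else 0
  or <- ((a + cc) * (d + cc)) / ((b + cc) * (c_ + cc))
  se_log <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c_ + cc) + 1 / (d + cc))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se_log)

  # two-sided exact p: hypergeometric tables as or less probable than observed
  k_range <- max(0, a + c_ - (c_ + d)):min(a + b, a + c_)
  dens <- dhyper(k_range, a + b, c_ + d, a + c_)
  p <- sum(dens[dens <= dhyper(a, a + b, c_ + d, a + c_) * (1 + 1e-7)])
  p <- min(1, p)

  fold <- (a / (a + b)) / ((a + c_) / universe)

  structure(
    list(table = c(a = a, b = b, c = c_, d = d),
         odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
         fisher_p = p, fold_enrichment = fold, universe = universe,
         n_targets = length(target_genes), n_set = length(gene_set),
         overlap_genes = sort(intersect(target_genes, gene_set)),
         haldane = haldane),
    class = "mir_enrichment"
  )
}

#' @export
print.mir_enrichment <- function(x, ...) {
  cat(sprintf(
    "<mir_enrichment> overlap %d of %d targets vs %d set genes (N = %d)\n",
    x$table["a"], x$n_targets, x$n_set, x$universe))
  cat(sprintf("  OR %.2f [%.2f, %.2f], Fisher p %.3g, fold %.2f%s\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$fisher_p,
              x$fold_enrichment,
              if (x$haldane) " (Haldane-corrected)" else ""))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mir_enrichment <- function(x, ...) {
  tibble::tibble(a = x$table["a"], b = x$table["b"], c = x$table["c"],
                 d = x$table["d"], odds_ratio = x$odds_ratio,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 fisher_p = x$fisher_p, fold_enrichment = x$fold_enrichment,
                 universe = x$universe)
}
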