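#' Run the full biomarker-discovery pipeline
#'
#' Orchestrates every stage in the published analysis order on either
#' simulated or user-supplied data: simulate/load counts and metadata,
#' normalize to reads per million and apply the detection filter, run the
#' differential screen, fit the best-fit multivariate logistic classifier
#' on the selected panel with ROC analysis, evaluate the panel by
#' Monte-Carlo cross-validated PLS-DA, export clustering and component
#' scores, and test the panel's predicted targets for gene-set enrichment.
#' All tables are written as headered TSV (metadata as CSV), summaries as
#' JSON, and a `manifest.json` records every stage with its inputs,
#' outputs, parameters, seed and wall time. Progress is logged to standard
#' error; results go only to files. If the screen selects no feature, the
#' classification and cross-validation stages are skipped with an explicit
#' notice in the manifest.
#'
#' @param out_dir Output directory (created if missing).
#' @param design,bdesign Simulation designs used when `counts` is `NULL`.
#' @param counts,metadata,targets,gene_set Optional user data (tibbles /
#'   character vector) replacing the simulated inputs.
#' @param p_threshold,q_threshold Screen selection thresholds.
#' @param cutoff Classification probability cutoff.
#' @param n_iter,train_frac,panel_sizes,n_components MCCV settings.
#' @param fraction,universe,enrichment_factor Enrichment settings.
#' @param seed Master seed. If absent one is generated and logged; it is
#'   never silently defaulted.
#'
#' @return Invisibly, the manifest list. Stage results are also attached
#'   as attribute `"results"`.
#' @export
run_pipeline <- function(out_dir,
                         design = sim_design(),
                         bdesign = behavior_design(),
                         counts = NULL, metadata = NULL,
                         targets = NULL, gene_set = NULL,
                         p_threshold = 0.05, q_threshold = 0.15,
                         cutoff = 0.5,
                         n_iter = 100, train_frac = 2 / 3,
                         panel_sizes = c(2, 3, 5, 7, 10, 14),
                         n_components = 3,
                         fraction = 0.20, universe = 20000,
                         enrichment_factor = 2.4,
                         seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    inform(sprintf("No seed supplied; generated seed %d.", seed))
  }
  seeds <- derive_seeds(seed, 4L)
  manifest <- list(seed = seed, stages = list())
  results <- list()
  path <- function(...) file.path(out_dir, ...)
  stage <- function(name, inputs, outputs, expr) {
    inform(sprintf("[%s] running ...", name))
    t0 <- proc.time()[["elapsed"]]
    value <- expr
    manifest$stages[[name]] <<- list(
      stage = name, inputs = inputs, outputs = outputs,
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
    value
  }

  # -- simulate / load -------------------------------------------------
  simulated <- is.null(counts)
  if (simulated) {
    ds <- stage("simulate", "design",
                c("counts.tsv", "metadata.csv", "targets.tsv",
                  "gene_set.txt", "truth.json"), {
      ds <- sim_dataset(design, bdesign, n_genes = universe,
                        enrichment_factor = enrichment_factor,
                        seed = seeds[1])
      write_counts(ds$counts, path("counts.tsv"))
      write_metadata(ds$metadata, path("metadata.csv"))
      write_targets(ds$targets, path("targets.tsv"))
      write_gene_set(ds$gene_set, path("gene_set.txt"))
      truth <- ds$truth$features[ds$truth$features$informative, ]
      jsonlite::write_json(list(
        seed = seeds[1],
        informative = truth$mirna_id, true_d = truth$d_true,
        count_model = "log-normal on log2 scale, library-scaled, rounded",
        correlation_structure = "features independent given group",
        enrichment_factor = enrichment_factor
      ), path("truth.json"), auto_unbox = TRUE, digits = NA)
      ds
    })
    counts <- ds$counts
    metadata <- ds$metadata
    targets <- ds$targets
    gene_set <- ds$gene_set
    results$truth <- ds$truth
  }

  # -- normalize + detection filter ------------------------------------
  rpm <- stage("normalize", "counts", "rpm.tsv", {
    filtered <- detection_filter(counts)
    inform(sprintf("[normalize] %d of %d features pass the detection filter.",
                   nrow(filtered), nrow(counts)))
    rpm <- rpm_normalize(filtered)
    write_counts(rpm, path("rpm.tsv"))
    rpm
  })

  # -- screen ----------------------------------------------------------
  scr <- stage("screen", "rpm.tsv", "screen.tsv", {
    scr <- run_screen(rpm, metadata, p_threshold = p_threshold,
                      q_threshold = q_threshold)
    readr::write_tsv(tibble::as_tibble(scr), path("screen.tsv"))
    scr
  })
  results$screen <- scr
  panel <- screen_panel(scr, max_size = max(panel_sizes))
  inform(sprintf("[screen] %d feature(s) selected (p < %g, q < %g).",
                 length(panel), p_threshold, q_threshold))

  x_log <- log2_rpm(rpm)
  y <- metadata$group[match(colnames(x_log), metadata$subject_id)]

  if (length(panel) == 0) {
    inform("[classify/mccv] skipped: empty panel after screening.")
    manifest$stages$classify <- list(stage = "classify", skipped = TRUE,
                                     reason = "empty panel")
    manifest$stages$mccv <- list(stage = "mccv", skipped = TRUE,
                                 reason = "empty panel")
  } else {
    xp <- t(x_log[panel, , drop = FALSE])

    # -- best-fit logistic classifier ---------------------------------
    results$classify <- stage(
      "classify", "screen panel",
      c("coefficients.tsv", "roc.tsv", "classify_summary.json"), {
      fit <- fit_logistic(xp, y)
      cls <- classify(fit, cutoff = cutoff)
      roc <- roc_curve(fit$fitted, y)
      readr::write_tsv(tidy(fit), path("coefficients.tsv"))
      readr::write_tsv(tibble::as_tibble(roc), path("roc.tsv"))
      miscl <- colnames(x_log)[cls$predicted != fit$y]
      jsonlite::write_json(list(
        auc = auc(roc), sensitivity = cls$sensitivity,
        specificity = cls$specificity, accuracy = cls$accuracy,
        cutoff = cutoff, misclassified = miscl,
        converged = fit$converged, separable = fit$separable
      ), path("classify_summary.json"), auto_unbox = TRUE, digits = NA)
      list(fit = fit, classification = cls, roc = roc)
    })

    # -- Monte-Carlo cross-validation ---------------------------------
    results$mccv <- stage(
      "mccv", "screen panel",
      c("mccv_auc.tsv", "mccv_probs.tsv", "mccv_importance.tsv",
        "mccv_summary.json"), {
      cv <- mccv(xp, y, n_iter = n_iter, train_frac = train_frac,
                 panel_sizes = panel_sizes, n_components = n_components,
                 seed = seeds[2], cutoff = cutoff)
      readr::write_tsv(cv$auc, path("mccv_auc.tsv"))
      readr::write_tsv(cv$subject_probs, path("mccv_probs.tsv"))
      readr::write_tsv(cv$importance, path("mccv_importance.tsv"))
      jsonlite::write_json(c(
        as.list(glance(cv)),
        list(confusion = as.list(cv$classification$confusion),
             misclassified = cv$misclassified)
      ), path("mccv_summary.json"), auto_unbox = TRUE, digits = NA)
      cv
    })

    # -- clustering / component exports -------------------------------
    results$cluster <- stage(
      "cluster", "screen panel",
      c("zscores.tsv", "merges.tsv", "dendrogram.nwk",
        "component_scores.tsv"), {
      z <- zscore_rows(x_log[panel, , drop = FALSE])
      readr::write_tsv(matrix_to_counts(z), path("zscores.tsv"))
      hc <- NULL
      if (nrow(z) >= 2) {
        hc <- cluster_features(z)
        readr::write_tsv(merge_table(hc), path("merges.tsv"))
        readr::write_lines(dendro_newick(hc), path("dendrogram.nwk"))
      }
      pls <- suppressWarnings(fit_plsda(xp, y, n_components = n_components))
      sc <- plsda_scores(pls)
      sc$group <- as.character(y)
      readr::write_tsv(sc, path("component_scores.tsv"))
      inform(sprintf(
        "[cluster] %d components explain %.1f%% of panel variance.",
        pls$n_components, 100 * sum(pls$var_explained)))
      list(hclust = hc, plsda = pls, scores = sc)
    })
  }

  # -- enrichment ------------------------------------------------------
  if (!is.null(targets) && !is.null(gene_set)) {
    results$enrichment <- stage(
      "enrich", c("targets", "gene_set"),
      c("filtered_targets.tsv", "overlap_genes.txt",
        "enrichment_summary.json"), {
      filt <- top_fraction_filter(targets, fraction)
      enr <- fisher_enrichment(unique_targets(filt), gene_set, universe)
      write_targets(filt, path("filtered_targets.tsv"))
      write_gene_set(enr$overlap_genes, path("overlap_genes.txt"))
      jsonlite::write_json(as.list(glance(enr)),
                           path("enrichment_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      enr
    })
  }

  manifest$parameters <- list(
    p_threshold = p_threshold, q_threshold = q_threshold, cutoff = cutoff,
    n_iter = n_iter, train_frac = train_frac, panel_sizes = panel_sizes,
    n_components = n_components, fraction = fraction, universe = universe,
    simulated = simulated)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  inform(sprintf("Pipeline complete; %d stage entries in %s.",
                 length(manifest$stages), path("manifest.json")))
  invisible(structure(manifest, results = results))
}

#' Read a flat key:value run configuration
#'
#' Parses a plain-text configuration with one `key: value` pair per line
#' (`#` comments and blank lines ignored). Comma-separated values become
#' numeric vectors when possible. Recognized keys mirror the arguments of
#' [run_pipeline()] (e.g. `seed: 7`, `n_iter: 100`,
#' `panel_sizes: 2,3,5,7,10,14`).
#'
#' @param path Path to the configuration file.
#' @return Named list suitable for `do.call(run_pipeline, ...)` after
#'   adding `out_dir`.
#' @export
read_run_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) {
    abort(paste0("Malformed config line(s): ",
                 paste(lines[bad], collapse = "; ")))
  }
  out <- lapply(kv, function(x) {
    val <- trimws(paste(x[-1], collapse = ":"))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else val
  })
  names(out) <- trimws(vapply(kv, `[[`, character(1), 1))
  out
}
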