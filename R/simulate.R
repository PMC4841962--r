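#' Simulate a case-control miRNA-seq count matrix
#'
#' Draws per-feature baseline log2 expression uniformly over the design
#' range, adds independent Gaussian biological noise (`log_sd`), shifts the
#' informative features by `d * log_sd` log2 units in the case group,
#' scales each subject's expression so the expected total matches a
#' uniformly drawn library size, and rounds to integer counts. Dividing a
#' subject's counts by its recorded `library_size` recovers the expression
#' scale exactly; reads-per-million normalization (dividing by the
#' *realized* total) additionally introduces the mild compositional
#' coupling real sequencing data carry. Null features additionally receive
#' per-cell dropout: each null feature gets its own zeroing probability
#' drawn from a Beta distribution with mean `dropout_rate`, so a tail of
#' poorly detected features exists for [detection_filter()] to remove.
#' Informative features are exempt from dropout -- their configured effect
#' sizes are a contract (the sample Cohen's d must recover `d`), which
#' uniform zero-inflation would break.
#'
#' A per-subject latent severity is recorded alongside the truth: the
#' average of the direction-aligned standardized noise deviations of the
#' informative features. [sim_behavior()] couples behavior scores to it.
#'
#' @param design A [sim_design()] object.
#' @param seed Optional integer overriding `design$seed`.
#'
#' @return A list of class `mir_sim` with elements
#'   * `counts`: tibble, first column `mirna_id`, then one integer column
#'     per subject;
#'   * `features`: truth tibble (`mirna_id`, `informative`, `d_true`,
#'     `baseline_log2`, `dropout`);
#'   * `subjects`: tibble (`subject_id`, `group`, `severity`,
#'     `library_size`);
#'   * `design`: the design used (with the effective seed).
#' @export
#' @examples
#' sim <- sim_counts(sim_design(n_case = 5, n_control = 5, n_features = 20,
#'                              informative_effects = c(2, -2), seed = 1))
#' dim(sim$counts)
sim_counts <- function(design = sim_design(), seed = NULL) {
  stopifnot(inherits(design, "mir_design"))
  if (!is.null(seed)) design$seed <- as.integer(seed)
  p <- design$n_features
  n1 <- design$n_case
  n0 <- design$n_control
  n <- n1 + n0
  d <- design$informative_effects
  k <- length(d)

  withr::with_seed(design$seed, {
    mu <- runif(p, design$baseline_log_mean_range[1],
                design$baseline_log_mean_range[2])
    idx_inf <- if (k > 0) sort(sample.int(p, k)) else integer(0)
    d_true <- rep(0, p)
    d_true[idx_inf] <- d
    # Per-feature dropout rates for null features only; Beta(2r, 2(1-r))
    # has mean r and enough spread that some features fall below 50%
    # detection while most stay well above it.
    q <- rep(0, p)
    if (design$dropout_rate > 0) {
      nulls <- setdiff(seq_len(p), idx_inf)
      q[nulls] <- stats::rbeta(length(nulls),
                               2 * design$dropout_rate,
                               2 * (1 - design$dropout_rate))
    }

    group <- rep(c("case", "control"), c(n1, n0))
    subject_id <- c(sprintf("case_%02d", seq_len(n1)),
                    sprintf("ctrl_%02d", seq_len(n0)))
    shift <- outer(d_true * design$log_sd, as.numeric(group == "case"))
    z <- matrix(rnorm(p * n), p, n)
    x <- mu + shift + design$log_sd * z

    # direction-aligned average of the informative-feature noise
    severity <- if (k > 0) {
      colSums(sign(d) * z[idx_inf, , drop = FALSE]) / sqrt(k)
    } else {
      rnorm(n)
    }

    lib <- round(runif(n, design$library_size_range[1],
                       design$library_size_range[2]))
    w <- 2^x
    zero <- matrix(rbinom(p * n, 1L, rep(q, n)), p, n)
    w[zero == 1L] <- 0
    # scale by the expected library total so counts of different features
    # stay independent and per-subject totals land near the drawn size
    s_exp <- sum((1 - q) * 2^mu) * exp((design$log_sd * log(2))^2 / 2)
    counts <- round(sweep(w, 2, lib / s_exp, "*"))
  })

  mirna_id <- sprintf("miR-syn-%03d", seq_len(p))
  dimnames(counts) <- list(mirna_id, subject_id)
  validate_counts(counts)

  structure(
    list(
      counts = matrix_to_counts(counts),
      features = tibble::tibble(
        mirna_id = mirna_id,
        informative = seq_len(p) %in% idx_inf,
        d_true = d_true,
        baseline_log2 = mu,
        dropout = q
      ),
      subjects = tibble::tibble(
        subject_id = subject_id,
        group = group,
        severity = severity,
        library_size = lib
      ),
      design = design
    ),
    class = "mir_sim"
  )
}

#' Simulate subject metadata with Vineland-like behavior scores
#'
#' Attaches age, sex, an ADOS-like severity score (cases only) and four
#' adaptive-behavior scores (communication, socialization, daily living,
#' composite) to the subjects of a simulated cohort. Each score is
#' `group_mean + group_sd * (-coupling * severity + sqrt(1 - coupling^2) * e)`
#' with independent standard-normal `e`, where `severity` is the latent
#' severity recorded by [sim_counts()]. With positive coupling, subjects
#' whose up-regulated informative miRNAs deviate upward therefore score
#' lower, so screen-stage Spearman correlations are non-null; with
#' `coupling = 1` the scores are a deterministic decreasing function of
#' severity.
#'
#' @param bdesign A [behavior_design()] object.
#' @param sim A `mir_sim` object from [sim_counts()].
#' @param seed Integer seed for the score noise.
#'
#' @return Tibble with columns `subject_id`, `group`, `age_years`, `sex`,
#'   `ados`, `vabs_comm`, `vabs_social`, `vabs_adl`, `vabs_comp`.
#' @export
sim_behavior <- function(bdesign = behavior_design(), sim, seed = 1L) {
  stopifnot(inherits(bdesign, "mir_behavior_design"),
            inherits(sim, "mir_sim"))
  subj <- sim$subjects
  n <- nrow(subj)
  is_case <- subj$group == "case"
  cpl <- bdesign$coupling
  noise_w <- sqrt(1 - cpl^2)

  score_for <- function(cm, cs, am, as_, e) {
    m <- ifelse(is_case, am, cm)
    s <- ifelse(is_case, as_, cs)
    m + s * (-cpl * subj$severity + noise_w * e)
  }

  withr::with_seed(seed, {
    age <- pmin(14, pmax(4, rnorm(n, ifelse(is_case, 9.1, 9.2),
                                  ifelse(is_case, 2.4, 2.5))))
    sex <- ifelse(runif(n) < ifelse(is_case, 19 / 24, 16 / 21), "M", "F")
    ados <- ifelse(is_case,
                   round(pmin(26, pmax(1, rnorm(n, 10.6, 4.1)))), NA_real_)
    sub <- bdesign$subscales
    e <- matrix(rnorm(n * (nrow(sub) + 1L)), n)
    scores <- lapply(seq_len(nrow(sub)), function(j) {
      score_for(sub$control_mean[j], sub$control_sd[j],
                sub$case_mean[j], sub$case_sd[j], e[, j])
    })
    names(scores) <- sub$measure
    comp <- score_for(bdesign$control_mean, bdesign$control_sd,
                      bdesign$case_mean, bdesign$case_sd, e[, nrow(sub) + 1L])
  })

  tibble::tibble(
    subject_id = subj$subject_id,
    group = subj$group,
    age_years = round(age, 1),
    sex = sex,
    ados = ados,
    vabs_comm = scores$vabs_comm,
    vabs_social = scores$vabs_social,
    vabs_adl = scores$vabs_adl,
    vabs_comp = comp
  )
}

#' Simulate a miRNA-to-mRNA target-prediction table
#'
#' Builds a prediction table in the style of a target database export:
#' one row per predicted interaction with a confidence score. The table
#' contains `length(mirnas) * targets_per_mirna` rows over a set of
#' distinct genes chosen so that a fraction `share_rate` of them is
#' targeted by two different miRNAs (the study observed roughly 10%
#' multi-targeting: 7764 interactions over about 7000 distinct genes).
#'
#' @param mirnas Character vector of miRNA identifiers.
#' @param n_genes Size of the gene universe identifiers are drawn from.
#' @param targets_per_mirna Average number of predicted targets per miRNA.
#' @param share_rate Fraction of distinct target genes hit by two miRNAs.
#' @param score_range Range of the uniform prediction scores.
#' @param seed Integer seed.
#'
#' @return Tibble with columns `mirna`, `gene`, `score`.
#' @export
sim_target_db <- function(mirnas, n_genes = 20000, targets_per_mirna = 555,
                          share_rate = 0.1, score_range = c(50, 100),
                          seed = 1L) {
  k <- length(mirnas)
  stopifnot(k >= 1)
  total <- k * targets_per_mirna
  if (k == 1L && share_rate > 0) {
    warn("A single miRNA cannot share targets; setting `share_rate = 0`.")
    share_rate <- 0
  }
  n_distinct <- round(total / (1 + share_rate))
  n_shared <- total - n_distinct
  if (n_distinct > n_genes) {
    abort("Gene universe too small for the requested number of targets.")
  }
  withr::with_seed(seed, {
    genes <- sample(sprintf("GENE%05d", seq_len(n_genes)), n_distinct)
    shared <- sample(genes, n_shared)
    single <- setdiff(genes, shared)
    rows <- dplyr::bind_rows(
      tibble::tibble(mirna = sample(mirnas, length(single), replace = TRUE),
                     gene = single),
      purrr::map_dfr(shared, function(g) {
        tibble::tibble(mirna = sample(mirnas, 2L), gene = g)
      })
    )
    rows$score <- runif(nrow(rows), score_range[1], score_range[2])
  })
  dplyr::arrange(rows, .data$mirna, dplyr::desc(.data$score))
}

#' Simulate a candidate gene set with controlled enrichment
#'
#' Samples a gene set of exact size `set_size` from the universe such that
#' its odds of containing a high-confidence target (a member of the top
#' `fraction` of `targets` after [top_fraction_filter()]) versus a
#' non-target are `enrichment_factor` times the background odds. The
#' downstream [fisher_enrichment()] odds ratio therefore estimates
#' `enrichment_factor` (up to sampling error), and `enrichment_factor = 1`
#' yields a null overlap.
#'
#' @param n_genes_universe Gene universe size (must be >= `set_size`).
#' @param set_size Number of genes in the candidate set.
#' @param enrichment_factor Target odds ratio (> 0).
#' @param targets Prediction table from [sim_target_db()].
#' @param fraction Top-score fraction defining high-confidence targets.
#' @param seed Integer seed.
#'
#' @return Character vector of gene identifiers (length `set_size`).
#' @export
sim_gene_set <- function(n_genes_universe = 20000, set_size = 740,
                         enrichment_factor = 2.4, targets,
                         fraction = 0.2, seed = 1L) {
  if (set_size > n_genes_universe) {
    abort("`set_size` cannot exceed the gene universe.")
  }
  stopifnot(enrichment_factor > 0)
  hi <- unique_targets(top_fraction_filter(targets, fraction))
  universe <- sprintf("GENE%05d", seq_len(n_genes_universe))
  if (!all(hi %in% universe)) {
    abort("Target genes fall outside the stated universe.")
  }
  m <- length(hi)
  N <- n_genes_universe
  f <- enrichment_factor
  # Membership probabilities p1 (targets) and p0 (non-targets) with odds
  # ratio f and expected set size K: solve K = m*p1 + (N-m)*p0.
  K <- set_size
  g <- function(p0) {
    p1 <- f * p0 / (1 + (f - 1) * p0)
    m * p1 + (N - m) * p0 - K
  }
  p0 <- stats::uniroot(g, c(1e-12, min(1 - 1e-12, K / (N - m))))$root
  p1 <- f * p0 / (1 + (f - 1) * p0)
  withr::with_seed(seed, {
    a <- rbinom(1L, m, p1)
    a <- min(a, K)
    inside <- sample(hi, a)
    outside <- sample(setdiff(universe, hi), K - a)
  })
  sort(c(inside, outside))
}

#' Simulate a complete analysis-ready dataset
#'
#' Convenience wrapper generating counts, metadata, a target-prediction
#' table for the informative miRNAs, and a candidate gene set in one call.
#'
#' @inheritParams sim_counts
#' @param bdesign A [behavior_design()].
#' @param n_genes Gene universe size for the enrichment stage.
#' @param enrichment_factor Configured odds ratio of the gene set.
#' @return List with `counts`, `metadata`, `targets`, `gene_set`, `truth`
#'   (the `mir_sim` object), and `universe` (gene universe size).
#' @export
sim_dataset <- function(design = sim_design(),
                        bdesign = behavior_design(),
                        n_genes = 20000,
                        enrichment_factor = 2.4,
                        seed = NULL) {
  sim <- sim_counts(design, seed = seed)
  seeds <- derive_seeds(sim$design$seed, 3L)
  metadata <- sim_behavior(bdesign, sim, seed = seeds[1])
  inf <- sim$features$mirna_id[sim$features$informative]
  if (length(inf) == 0) inf <- sim$features$mirna_id[1:2]
  targets <- sim_target_db(inf, n_genes = n_genes, seed = seeds[2])
  gene_set <- sim_gene_set(n_genes, 740, enrichment_factor, targets,
                           seed = seeds[3])
  list(counts = sim$counts, metadata = metadata, targets = targets,
       gene_set = gene_set, truth = sim, universe = n_genes)
}
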