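test_that("fixed seeds reproduce every generated artifact exactly", {
  a <- sim_counts(sim_design(seed = 99))
  b <- sim_counts(sim_design(seed = 99))
  expect_identical(a, b)
  meta_a <- sim_behavior(behavior_design(), a, seed = 5)
  meta_b <- sim_behavior(behavior_design(), b, seed = 5)
  expect_identical(meta_a, meta_b)
  tg <- sim_target_db(c("m1", "m2"), n_genes = 500, targets_per_mirna = 30,
                      seed = 8)
  expect_identical(tg, sim_target_db(c("m1", "m2"), n_genes = 500,
                                     targets_per_mirna = 30, seed = 8))
})

test_that("the default design is study-shaped", {
  sim <- sim_counts(sim_design())
  expect_equal(dim(sim$counts), c(246, 46))  # id column + 45 subjects
  expect_equal(sum(sim$features$informative), 14)
  expect_equal(sort(sim$features$d_true[sim$features$informative]),
               sort(default_effects()))
  expect_equal(table(sim$subjects$group)[["case"]], 24)
  expect_equal(table(sim$subjects$group)[["control"]], 21)
  m <- counts_to_matrix(sim$counts)
  expect_true(all(m >= 0) && all(m == round(m)))
  # dropout leaves a tail of poorly detected features for the filter
  expect_lt(nrow(detection_filter(sim$counts)), 246)
  zero_frac <- mean(m == 0)
  expect_gt(zero_frac, 0.08)
  expect_lt(zero_frac, 0.30)
  # without dropout essentially everything is detected everywhere
  m0 <- counts_to_matrix(sim_counts(sim_design(dropout_rate = 0))$counts)
  expect_lt(mean(m0 == 0), 0.01)
})

test_that("a null design carries no group signal", {
  sim <- sim_counts(sim_design(n_case = 40, n_control = 40, n_features = 60,
                               informative_effects = numeric(0), seed = 21))
  expect_false(any(sim$features$informative))
  an <- sim_analysis_matrix(sim)
  d <- apply(an$m, 1, function(v) {
    suppressWarnings(effect_sizes(v[an$y == "case"],
                                  v[an$y == "control"])$d)
  })
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.1)
})

test_that("configured effect sizes are recovered on the expression scale", {
  # one informative feature with d = 2: mean log2 case-control difference
  # approaches d * log_sd at n = 500/group
  des <- sim_design(n_case = 500, n_control = 500, n_features = 20,
                    informative_effects = 2, log_sd = 1, dropout_rate = 0)
  diffs <- vapply(1:5, function(s) {
    sim <- sim_counts(des, seed = s)
    m <- counts_to_matrix(sim$counts)
    expr <- log2(sweep(m, 2, 1e6 / sim$subjects$library_size, "*") + 1)
    f <- sim$features$mirna_id[sim$features$informative]
    grp <- sim$subjects$group
    mean(expr[f, grp == "case"]) - mean(expr[f, grp == "control"])
  }, numeric(1))
  expect_equal(mean(diffs), 2, tolerance = 0.05)
})

test_that("behavior scores match the configured group moments and coupling", {
  des <- sim_design(n_case = 400, n_control = 400, n_features = 30,
                    informative_effects = c(1, -1), seed = 3)
  sim <- sim_counts(des)
  meta <- sim_behavior(behavior_design(), sim, seed = 6)
  is_case <- meta$group == "case"
  expect_lt(abs(mean(meta$vabs_comp[!is_case]) - 105.3), 2.5)
  expect_lt(abs(mean(meta$vabs_comp[is_case]) - 70.7), 2.5)
  expect_lt(abs(sd(meta$vabs_comp[!is_case]) - 12.7), 2)
  expect_lt(abs(sd(meta$vabs_comp[is_case]) - 10.2), 2)
  expect_true(all(is.na(meta$ados[!is_case])))
  expect_false(anyNA(meta$ados[is_case]))
  # composite correlates with latent severity at -coupling within group
  r <- cor(meta$vabs_comp[is_case], sim$subjects$severity[is_case])
  expect_equal(r, -0.5, tolerance = 0.1)

  # coupling = 0: no association between features and scores
  meta0 <- sim_behavior(behavior_design(coupling = 0), sim, seed = 6)
  r0 <- cor(meta0$vabs_comp[is_case], sim$subjects$severity[is_case])
  expect_lt(abs(r0), 0.15)

  # coupling = 1, single up-regulated informative feature: scores are a
  # deterministic decreasing function of that feature -> Spearman rho = -1
  des1 <- sim_design(n_case = 20, n_control = 20, n_features = 10,
                     informative_effects = 1.5, seed = 9)
  sim1 <- sim_counts(des1)
  meta1 <- sim_behavior(behavior_design(coupling = 1), sim1, seed = 2)
  f <- sim1$features$mirna_id[sim1$features$informative]
  v <- counts_to_matrix(sim1$counts)[f, ]
  expr <- log2(1e6 * v / sim1$subjects$library_size + 1)
  is_case1 <- meta1$group == "case"
  expect_equal(spearman_cor(expr[is_case1], meta1$vabs_comp[is_case1])$rho,
               -1)
})

test_that("target tables have the configured interaction structure", {
  mirnas <- sprintf("miR-%02d", 1:14)
  tg <- sim_target_db(mirnas, n_genes = 20000, targets_per_mirna = 555,
                      seed = 12)
  expect_equal(nrow(tg), 14 * 555)  # ~7764 published total interactions
  expect_equal(length(unique(tg$gene)), round(14 * 555 / 1.1))  # ~7000
  shared <- sum(table(tg$gene) > 1) / length(unique(tg$gene))
  expect_lt(abs(shared - 0.1), 0.005)
  expect_true(all(tg$score >= 50 & tg$score <= 100))
  # no miRNA targets the same gene twice
  expect_equal(anyDuplicated(paste(tg$mirna, tg$gene)), 0)
})

test_that("gene sets reproduce a configured null enrichment", {
  mirnas <- sprintf("miR-%02d", 1:6)
  tg <- sim_target_db(mirnas, n_genes = 5000, targets_per_mirna = 300,
                      seed = 2)
  ors <- vapply(1:10, function(s) {
    gs <- sim_gene_set(5000, 400, enrichment_factor = 1, tg, seed = s)
    hi <- unique_targets(top_fraction_filter(tg, 0.2))
    fisher_enrichment(hi, gs, 5000)$odds_ratio
  }, numeric(1))
  expect_equal(mean(ors), 1, tolerance = 0.15)
  expect_error(sim_gene_set(100, 200, 2, tg), "exceed")
})
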