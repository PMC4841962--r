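test_that("top-fraction filter keeps ceil(fraction * n) per miRNA, deterministically", {
  tg <- tibble::tibble(
    mirna = rep(c("m1", "m2"), c(10, 7)),
    gene = sprintf("g%02d", 1:17),
    score = c(10:1, 7:1)
  )
  f <- top_fraction_filter(tg, 0.2)
  expect_equal(sum(f$mirna == "m1"), 2)    # ceil(0.2 * 10)
  expect_equal(sum(f$mirna == "m2"), 2)    # ceil(0.2 * 7) = ceil(1.4)
  expect_equal(f$score[f$mirna == "m1"], c(10, 9))
  # fraction 1 is the identity up to row order
  expect_equal(nrow(top_fraction_filter(tg, 1)), nrow(tg))
  # exact size law on random tables
  set.seed(97)
  tg2 <- tibble::tibble(
    mirna = sample(paste0("m", 1:5), 200, replace = TRUE),
    gene = sprintf("g%03d", 1:200),
    score = runif(200)
  )
  f2 <- top_fraction_filter(tg2, 0.3)
  expect_equal(nrow(f2),
               sum(ceiling(0.3 * table(tg2$mirna))))
  # boundary ties resolved by gene id ascending
  tie <- tibble::tibble(mirna = "m", gene = c("gB", "gA", "gC"),
                        score = c(5, 5, 5))
  expect_equal(top_fraction_filter(tie, 1 / 3)$gene, "gA")
  expect_error(top_fraction_filter(tibble::tibble(mirna = "m", gene = "g",
                                                  score = NA)), "Missing")
})

test_that("unique_targets deduplicates across miRNAs", {
  tg <- tibble::tibble(mirna = c("m1", "m1", "m2", "m2"),
                       gene = c("g1", "g2", "g2", "g3"), score = 1:4)
  expect_setequal(unique_targets(tg), c("g1", "g2", "g3"))
  no_share <- tibble::tibble(mirna = c("m1", "m2"), gene = c("a", "b"),
                             score = 1:2)
  expect_length(unique_targets(no_share), 2)
})

test_that("Fisher enrichment builds the 2x2 table per its invariants", {
  # targets 10, set 20, universe 100, overlap 5:
  # a=5 b=5 c=15 d=75 -> OR = (5*75)/(5*15) = 5, fold = (5/10)/(20/100)
  enr <- fisher_enrichment(sprintf("t%02d", 1:10),
                           c(sprintf("t%02d", 1:5), sprintf("s%02d", 1:15)),
                           100)
  expect_equal(unname(enr$table), c(5, 5, 15, 75))
  expect_equal(sum(enr$table), 100)
  expect_equal(enr$odds_ratio, 5)
  expect_equal(enr$fold_enrichment, 2.5)
  expect_equal(enr$ci_low, exp(log(5) - 1.96 * sqrt(1 / 5 + 1 / 5 + 1 / 15 + 1 / 75)))
  ref <- fisher.test(matrix(c(5, 5, 15, 75), 2, byrow = TRUE))
  expect_equal(enr$fisher_p, ref$p.value, tolerance = 1e-12)
  expect_error(fisher_enrichment(sprintf("t%d", 1:30),
                                 sprintf("s%d", 1:30), 40), "universe")
})

test_that("Fisher p matches hypergeometric enumeration for small universes", {
  set.seed(99)
  for (i in 1:15) {
    N <- sample(20:200, 1)
    nt <- sample(2:(N / 2), 1)
    ns <- sample(2:(N / 2), 1)
    univ <- sprintf("g%03d", seq_len(N))
    targets <- sample(univ, nt)
    gset <- sample(univ, ns)
    enr <- fisher_enrichment(targets, gset, N)
    a <- enr$table["a"]
    # independent oracle: enumerate all possible overlap counts
    ks <- 0:min(nt, ns)
    dens <- choose(nt, ks) * choose(N - nt, ns - ks) / choose(N, ns)
    p_or <- sum(dens[dens <= dens[ks == a] * (1 + 1e-7)])
    expect_equal(enr$fisher_p, min(1, p_or), tolerance = 1e-10)
    ref <- fisher.test(matrix(c(a, nt - a, ns - a, N - nt - ns + a), 2,
                              byrow = TRUE))
    expect_equal(enr$fisher_p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("a zero cell triggers the flagged Haldane correction", {
  enr <- fisher_enrichment(c("a", "b"), c("c", "d"), 50)
  expect_true(enr$haldane)
  expect_equal(enr$odds_ratio, (0.5 * 46.5) / (2.5 * 2.5))
})

test_that("fold enrichment approaches the odds ratio for rare sets", {
  set.seed(103)
  univ <- sprintf("g%05d", 1:50000)
  targets <- sample(univ, 120)
  gset <- c(sample(targets, 1), sample(setdiff(univ, targets), 99))
  enr <- fisher_enrichment(targets, gset, 50000)
  expect_equal(enr$fold_enrichment / enr$odds_ratio, 1, tolerance = 0.05)
})
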