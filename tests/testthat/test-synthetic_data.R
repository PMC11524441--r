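test_that("sim_config validates parameter ranges", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(mixing = 1.2), class = "oasig_config_error")
  expect_error(sim_config(frac_de = -0.1), class = "oasig_config_error")
  expect_error(sim_config(n_related = 10, n_datasets = 10),
               class = "oasig_config_error")
  expect_error(sim_config(target_rho = 1.5), class = "oasig_config_error")
  expect_error(sim_config(dropout_max = 1), class = "oasig_config_error")
})

test_that("generators replay identically under the same config and seed", {
  cfg <- sim_config(seed = 99, n_genes = 300, n_datasets = 12, n_related = 3)
  g1 <- generate_compendium(cfg); g2 <- generate_compendium(cfg)
  expect_identical(g1, g2)
  t1 <- generate_linked_de_tables(cfg); t2 <- generate_linked_de_tables(cfg)
  expect_identical(t1, t2)
  bg <- t1$table_a$gene
  acfg <- sim_config(seed = 99, n_genes = 300, n_datasets = 12, n_related = 3,
                     n_protective = 60, n_detrimental = 50, n_ambiguous = 10,
                     target_set_size = 20)
  a1 <- generate_annotation_and_targets(acfg, bg[1:50], bg[51:80], bg[1:250])
  a2 <- generate_annotation_and_targets(acfg, bg[1:50], bg[51:80], bg[1:250])
  expect_identical(a1, a2)
  # different seeds diverge
  g3 <- generate_compendium(sim_config(seed = 100, n_genes = 300,
                                       n_datasets = 12, n_related = 3))
  expect_false(identical(g1$query$values, g3$query$values))
})

test_that("generator sub-streams are independent of call order", {
  cfg <- sim_config(seed = 7, n_genes = 200, n_datasets = 8, n_related = 2)
  comp_first <- generate_compendium(cfg)
  tables_after <- generate_linked_de_tables(cfg)
  tables_alone <- generate_linked_de_tables(cfg)
  expect_identical(tables_after, tables_alone)
  comp_again <- generate_compendium(cfg)
  expect_identical(comp_first, comp_again)
})

test_that("noise-free full mixing makes related datasets copies of the signature", {
  cfg <- sim_config(seed = 1, n_genes = 200, n_datasets = 6, n_related = 2,
                    mixing = 1, noise_sd = 0, dropout_max = 0)
  g <- generate_compendium(cfg)
  for (id in g$related_ids) {
    r <- cosine_similarity(g$query$values, g$compendium$profiles[[id]]$values)
    expect_equal(r$cosine, 1, tolerance = 1e-12)
  }
})

test_that("unmixed compendia show only null-level similarity to the query", {
  # mean |cosine| for independent vectors scales like 1/sqrt(n_shared)
  n_genes <- 500
  mean_abs <- vapply(1:20, function(s) {
    g <- generate_compendium(sim_config(seed = s, n_genes = n_genes,
                                        n_datasets = 10, n_related = 2,
                                        mixing = 0))
    mean(vapply(g$compendium$profiles, function(p)
      abs(cosine_similarity(g$query$values, p$values)$cosine), numeric(1)))
  }, numeric(1))
  expect_lt(mean(mean_abs), 3 / sqrt(n_genes))
})

test_that("mean rank of planted datasets falls as signature mixing rises", {
  mean_rank <- vapply(c(0, 0.05, 0.1, 0.2), function(mx) {
    ranks <- unlist(lapply(1:20, function(s) {
      g <- generate_compendium(sim_config(seed = s, n_genes = 400,
                                          n_datasets = 60, n_related = 5,
                                          mixing = mx))
      res <- compendium_search(g$query, g$compendium, min_shared = 50)
      res$rank[match(g$related_ids, res$dataset_id)]
    }))
    mean(ranks)
  }, numeric(1))
  expect_true(all(diff(mean_rank) < 0))
})

test_that("null compendium searches are calibrated", {
  # z-scores are standardised per query; the top rank should hit a planted
  # dataset only at chance rate when nothing is planted (mixing 0)
  top_planted <- vapply(1:200, function(s) {
    g <- generate_compendium(sim_config(seed = s, n_genes = 200,
                                        n_datasets = 40, n_related = 5,
                                        mixing = 0))
    res <- compendium_search(g$query, g$compendium, min_shared = 50)
    res$dataset_id[1] %in% g$related_ids
  }, logical(1))
  # chance = 5/40; allow 3.5 sd above
  expect_lte(mean(top_planted), 5 / 40 + 3.5 * sqrt(0.125 * 0.875 / 200))
  g <- generate_compendium(sim_config(seed = 1, n_genes = 200,
                                      n_datasets = 40, n_related = 5,
                                      mixing = 0))
  res <- compendium_search(g$query, g$compendium, min_shared = 50)
  expect_lt(abs(mean(res$zscore)), 1e-12)
  expect_equal(sd(res$zscore), 1, tolerance = 1e-12)
})

test_that("coupled tables honour exact and degenerate targets", {
  cfg <- sim_config(seed = 3, n_genes = 1000, target_rho = 1, discordance = 0)
  g <- generate_linked_de_tables(cfg)
  de <- g$truth$de_genes
  fa <- fold_changes(g$table_a); fb <- fold_changes(g$table_b)
  expect_identical(fa[de], fb[de])   # noise-free coupling: identical log2fc
  cc <- concordance(g$table_a, g$table_b)
  expect_equal(cc$spearman_rho, 1, tolerance = 1e-6)
  expect_equal(cc$discordant_fraction, 0)

  expect_error(generate_linked_de_tables(
    sim_config(seed = 1, n_genes = 1000, target_rho = 0.3, discordance = 0.01)),
    class = "oasig_config_error")
})

test_that("without planted effects BH keeps tables empty of discoveries", {
  empty <- vapply(1:20, function(s) {
    g <- generate_linked_de_tables(sim_config(seed = s, n_genes = 2000,
                                              frac_de = 0))
    sets <- significant_sets(g$table_a, fold_threshold = 1)
    length(sets$up) + length(sets$down) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.95)
})

test_that("planted discordance rate is recovered", {
  disc <- vapply(1:10, function(s) {
    g <- generate_linked_de_tables(sim_config(seed = s, n_genes = 2000,
                                              discordance = 0.05))
    concordance(g$table_a, g$table_b)$discordant_fraction
  }, numeric(1))
  expect_lt(abs(mean(disc) - 0.05), 0.02)
})

test_that("generator BH agrees with the brute-force step-up procedure", {
  set.seed(23)
  for (i in 1:20) {
    p <- runif(sample(1:100, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), oracle_bh(p),
                 tolerance = 1e-12)
  }
})

test_that("annotation and target planting respects sizes and feasibility", {
  cfg <- sim_config(seed = 5, n_genes = 2000)
  bg <- sprintf("G%05d", 1:2000)
  set.seed(1); up <- sample(bg, 300); down <- sample(setdiff(bg, up), 200)
  at <- generate_annotation_and_targets(cfg, up, down, bg)
  expect_equal(sum(at$annotation == "Protective"), cfg$n_protective)
  expect_equal(sum(at$annotation == "Detrimental"), cfg$n_detrimental)
  expect_equal(sum(at$annotation == "Ambiguous"), cfg$n_ambiguous)
  expect_length(at$targets$genes, cfg$target_set_size)
  expect_true(all(at$targets$genes %in% bg))
  expect_equal(at$truth$annotation_odds_ratio, cfg$annotation_odds_ratio)

  expect_error(generate_annotation_and_targets(cfg, up, down, bg[1:100]),
               class = "oasig_config_error")
})

test_that("unplanted annotations yield null-distributed enrichment odds", {
  # with odds ratio 1 the protective and detrimental in-up rates match
  ors <- vapply(1:40, function(s) {
    cfg <- sim_config(seed = s, n_genes = 2000, annotation_odds_ratio = 1)
    bg <- sprintf("G%05d", 1:2000)
    set.seed(s)
    up <- sample(bg, 300)
    at <- generate_annotation_and_targets(cfg, up, character(), bg)
    directional_enrichment(up, bg, at$annotation)$odds_ratio
  }, numeric(1))
  expect_equal(median(ors), 1, tolerance = 0.25)
})
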