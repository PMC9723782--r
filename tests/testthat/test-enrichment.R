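test_that("Dirichlet CLR instances are positive, seeded and well-centred", {
  ct <- toy_counts(matrix(c(0, 5, 20, 3, 0, 40), 3, 2))
  mc <- dirichlet_clr_instances(ct, n_mc = 16, seed = 3)
  expect_identical(dim(mc), c(3L, 2L, 16L))
  expect_true(all(is.finite(mc)))   # prior keeps zero counts positive
  mc2 <- dirichlet_clr_instances(ct, n_mc = 16, seed = 3)
  expect_identical(mc, mc2)
  expect_false(identical(mc, dirichlet_clr_instances(ct, n_mc = 16,
                                                     seed = 4)))
  expect_error(dirichlet_clr_instances(ct, n_mc = 1), "n_mc")

  # instance means approach the CLR of posterior-mean proportions for
  # well-observed counts
  big <- toy_counts(matrix(20 + stats::rpois(12, 100), 4, 3))
  mcl <- dirichlet_clr_instances(big, n_mc = 1024, seed = 1)
  post <- sweep(unclass(big) + 0.5, 2, colSums(unclass(big) + 0.5), "/")
  expect_lt(max(abs(apply(mcl, 1:2, mean) - clr_transform(post))), 0.05)
})

test_that("effect sizes are antisymmetric in group order", {
  ds <- generate_dataset(small_scenario(seed = 5))
  ct <- ds$counts$bacteria
  g <- ds$truth$regime
  e1 <- enrichment_contrast(ct, g, levels = c("highT", "lowT"), n_mc = 32,
                            seed = 9)
  e2 <- enrichment_contrast(ct, g, levels = c("lowT", "highT"), n_mc = 32,
                            seed = 9)
  expect_lt(max(abs(e1$effect + e2$effect)), 0.35)  # MC pairing noise only
  expect_gt(stats::cor(e1$effect, -e2$effect), 0.98)
  expect_error(effect_size(dirichlet_clr_instances(ct, 4, seed = 1),
                           c("a", rep("b", ncol(ct) - 1))), ">= 2 samples")
})

test_that("exchangeable groups rarely reach the enrichment criterion", {
  ds <- generate_dataset(scenario_config(
    n_samples = 10, sequencing_depth = 1e4, n_enriched_per_regime = 0,
    n_proportional_cliques = 0, seed = 31))
  fx <- enrichment_contrast(ds$counts$bacteria, ds$truth$regime,
                            levels = c("highT", "lowT"), seed = 31)
  expect_lt(mean(abs(fx$effect) >= 1), 0.10)
  expect_identical(sign(fx$effect), sign(fx$diff_btw))
})

test_that("planted 8-fold enrichment is recovered with the right sign", {
  ds <- generate_dataset(scenario_config(
    n_samples = 10, sequencing_depth = 1e4, n_proportional_cliques = 0,
    seed = 32))
  fx <- enrichment_contrast(ds$counts$bacteria, ds$truth$regime,
                            levels = c("highT", "lowT"), seed = 32)
  enr <- ds$truth$enriched
  bac <- names(enr)[grepl("^bac", names(enr))]
  sgn <- ifelse(enr[bac] == "highT", 1, -1)
  expect_gte(mean(sgn * fx$effect[match(bac, fx$taxon)] >= 1), 0.9)
})

test_that("effects are stable under per-sample depth rescaling", {
  ds <- generate_dataset(small_scenario(seed = 6))
  ct <- ds$counts$bacteria
  g <- ds$truth$regime
  e1 <- enrichment_contrast(ct, g, levels = c("highT", "lowT"), seed = 2)
  e10 <- enrichment_contrast(count_table(unclass(ct) * 10, "bacteria"), g,
                             levels = c("highT", "lowT"), seed = 2)
  expect_gt(stats::cor(e1$effect, e10$effect), 0.95)
})

test_that("threshold and intersection filters apply the stated rules", {
  eff <- data.frame(taxon = c("a", "b", "c"),
                    effect = c(1.2, -0.4, -1.6),
                    contrast = "x_vs_y")
  hits <- enriched_features(eff)
  expect_identical(hits$taxon, c("a", "c"))
  expect_identical(hits$direction, c("up", "down"))
  expect_identical(nrow(enriched_features(eff, threshold = Inf)), 0L)

  vs_grab <- data.frame(taxon = c("a", "b"), effect = c(1.5, 2),
                        direction = "up")
  vs_bk <- data.frame(taxon = "b", effect = 1.2, direction = "up")
  expect_identical(confirm_fluid_enrichment(vs_grab, vs_bk)$taxon, "b")
})
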