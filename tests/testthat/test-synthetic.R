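test_that("generation is bit-reproducible under a fixed seed", {
  a <- generate_dataset(small_scenario(seed = 42))
  b <- generate_dataset(small_scenario(seed = 42))
  expect_identical(a$counts, b$counts)
  expect_identical(a$fractions, b$fractions)
  expect_identical(a$truth, b$truth)
  c2 <- generate_dataset(small_scenario(seed = 43))
  expect_false(identical(a$counts, c2$counts))
})

test_that("column sums equal the configured depth before zero inflation", {
  ds <- generate_dataset(small_scenario(seed = 2, zero_inflation = 0))
  expect_true(all(colSums(unclass(ds$counts$bacteria)) == 5000))
  expect_true(all(colSums(unclass(ds$counts$meiofauna)) == 300))
  dz <- generate_dataset(small_scenario(seed = 2, zero_inflation = 0.3))
  expect_true(all(colSums(unclass(dz$counts$bacteria)) <= 5000))
})

test_that("configuration invariants are enforced", {
  expect_error(scenario_config(t_threshold = 50), "inside temperature_range")
  expect_error(scenario_config(zero_inflation = 1), "zero_inflation")
  expect_error(scenario_config(n_taxa_per_domain = c(bacteria = 5)),
               "missing")
  expect_error(scenario_config(latent_sd = NaN), "non-finite")
  expect_error(generate_dataset(
    small_scenario(seed = 1, base_log_override = c(nope = 2))), "unknown")
})

test_that("ground truth is internally consistent", {
  ds <- generate_dataset(scenario_config(seed = 8))
  expect_equal(unname(rowSums(ds$truth$domain_fractions)),
               rep(1, nrow(ds$truth$domain_fractions)), tolerance = 1e-9)
  members <- unlist(ds$truth$cliques)
  expect_identical(anyDuplicated(members), 0L)   # each taxon in one clique
  expect_true(all(ds$truth$enriched %in% c("highT", "lowT")))
  expect_identical(sort(unique(unname(ds$truth$regime))),
                   c("highT", "lowT"))
  # regime matches the threshold rule
  expect_identical(unname(ds$truth$regime),
                   unname(ifelse(ds$truth$temperature > 25, "highT",
                                 "lowT")))
})

test_that("a taxon spiked 1000-fold dominates nearly every sample", {
  cfg <- small_scenario(seed = 12, zero_inflation = 0,
                        n_enriched_per_regime = 0,
                        n_proportional_cliques = 0,
                        base_log_override = c(bac001 = log(1000)))
  ds <- generate_dataset(cfg)
  m <- unclass(ds$counts$bacteria)
  top <- apply(m, 2, function(col) rownames(m)[which.max(col)])
  expect_gte(mean(top == "bac001"), 0.95)
})

test_that("a planted low-noise clique yields near-unit proportionality", {
  cfg <- scenario_config(
    n_taxa_per_domain = c(bacteria = 30, archaea = 10, microeukarya = 10,
                          meiofauna = 8, macrofauna = 8),
    n_enriched_per_regime = 0, n_proportional_cliques = 1, clique_size = 3,
    latent_sd = 0.05, zero_inflation = 0, sequencing_depth = 1e5,
    seed = 17)
  ds <- generate_dataset(cfg)
  cl <- ds$truth$cliques[[1]]
  merged <- do.call(rbind, lapply(ds$counts[c("bacteria", "archaea",
                                              "microeukarya")], unclass))
  clr <- clr_transform(replace_zeros_czm(merged))
  r <- rho_proportionality(clr)
  within <- r[cl, cl][upper.tri(diag(length(cl)))]
  expect_true(all(within > 0.9))
})

test_that("datasets round-trip through their plain-text representation", {
  ds <- generate_dataset(small_scenario(seed = 3))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(unclass(back$counts$bacteria),
               unclass(ds$counts$bacteria), ignore_attr = TRUE)
  expect_identical(back$metadata$sample_id, ds$metadata$sample_id)
  expect_equal(back$fractions, ds$fractions, tolerance = 1e-12)
  expect_identical(sort(as.vector(back$truth$cliques[[1]])),
                   sort(as.vector(ds$truth$cliques[[1]])))
  expect_identical(attr(back$truth$cliques[[1]], "regime"),
                   attr(ds$truth$cliques[[1]], "regime"))
})
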