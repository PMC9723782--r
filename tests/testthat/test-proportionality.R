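test_that("taxonomic aggregation merges byte-identical lineages only", {
  ct <- toy_counts(matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2),
                   taxa = c("o1", "o2", "o3", "o4"))
  tax <- c(o1 = "Bacteria;P;C;O;F;Arcobacter",
           o2 = "Bacteria;P;C;O;F;Arcobacter",
           o3 = "Bacteria;P;C;O;F;arcobacter",   # case differs: kept apart
           o4 = "Bacteria;P;C;O;Lentimicrobiaceae")
  agg <- aggregate_by_taxonomy(ct, tax)
  expect_identical(nrow(agg), 3L)
  expect_equal(as.numeric(agg["B_Arcobacter", ]), c(1 + 2, 5 + 6))
  expect_true("B_arcobacter" %in% rownames(agg))
  expect_true("B_fa_Lentimicrobiaceae" %in% rownames(agg))
  expect_identical(attr(agg, "members")[["B_Arcobacter"]], c("o1", "o2"))

  distinct <- toy_counts(matrix(1:4, 2, 2), taxa = c("x", "y"))
  agg2 <- aggregate_by_taxonomy(distinct, c(x = "Bacteria;A", y = "Bacteria;B"))
  expect_identical(nrow(agg2), 2L)
  expect_error(aggregate_by_taxonomy(ct, tax[1:3]), "missing lineage.*o4")
})

test_that("prefix labels encode domain letter and classification depth", {
  ct <- toy_counts(matrix(1:10, 5, 2), taxa = paste0("o", 1:5),
                   domain = c("archaea", "bacteria", "microeukarya",
                              "meiofauna", "macrofauna"))
  tax <- c(o1 = "Archaea", o2 = "Bacteria;Phy", o3 = "Eukaryota;P;C;Ord",
           o4 = "Animalia;P;C;O;F;Copepod_sp", o5 = "Animalia;P;C;O;F;Limpet")
  agg <- aggregate_by_taxonomy(ct, tax)
  expect_setequal(rownames(agg),
                  c("A_do_Archaea", "B_ph_Phy", "E_or_Ord",
                    "m_Copepod_sp", "M_Limpet"))
})

test_that("prevalence filter drops taxa under-observed in enough samples", {
  m <- rbind(c(0, 0, 0, 0, 0, 1, 1, 5, 9),   # 7 of 9 below 2 -> drop
             c(0, 0, 0, 0, 0, 0, 2, 2, 2),   # 6 below 2 -> keep
             rep(3, 9))
  ct <- toy_counts(m)
  out <- prevalence_filter(ct)
  expect_identical(rownames(out), c("t02", "t03"))
})

test_that("rho matches the brute-force covariance-ratio oracle", {
  set.seed(13)
  for (rep in 1:5) {
    clr <- clr_transform(replace_zeros_czm(random_counts(6, 9,
                                                         seed = rep)))
    expect_equal(rho_proportionality(clr), rho_brute(clr),
                 tolerance = 1e-10)
  }
})

test_that("rho hits its algebraic extremes and masks degenerate taxa", {
  set.seed(14)
  base <- stats::rnorm(8)
  clr <- rbind(a = base, b = base, c = -base)
  r <- rho_proportionality(clr)
  expect_equal(unname(r["a", "b"]), 1)
  expect_equal(unname(r["a", "c"]), -1)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r, t(r))

  flat <- rbind(a = base, z = rep(0.3, 8))
  expect_warning(r2 <- rho_proportionality(flat), "zero-variance.*z")
  expect_true(all(is.na(r2["z", ])))
  expect_error(rho_proportionality(clr[, 1:2]), ">= 3 samples")
})

test_that("rho is invariant to per-sample scaling of the composition", {
  x <- unclass(random_counts(5, 8, seed = 15)) + 1
  scaled <- sweep(x, 2, c(1, 10, 2, 5, 1, 3, 7, 2), "*")
  r1 <- rho_proportionality(clr_transform(sweep(x, 2, colSums(x), "/")))
  r2 <- rho_proportionality(clr_transform(sweep(scaled, 2,
                                                colSums(scaled), "/")))
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("edge thresholding is strict and keeps signs", {
  r <- diag(3)
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  r["a", "b"] <- r["b", "a"] <- 0.75     # boundary: excluded
  r["a", "c"] <- r["c", "a"] <- -0.9
  r["b", "c"] <- r["c", "b"] <- 0.80
  e <- threshold_edges(r, 0.75)
  expect_identical(nrow(e), 2L)
  expect_identical(e$sign[e$from == "a" & e$to == "c"], "negative")
  expect_identical(nrow(threshold_edges(r, cutoff = 1)), 0L)
})
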