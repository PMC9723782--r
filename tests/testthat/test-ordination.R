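embeddable_points <- function(seed = 4, n = 10) {
  set.seed(seed)
  p <- matrix(stats::rnorm(2 * n), n, 2,
              dimnames = list(paste0("s", seq_len(n)), NULL))
  p
}

test_that("NMDS recovers exactly embeddable configurations and is seeded", {
  p <- embeddable_points()
  d <- stats::dist(p)
  fit <- nmds(d, k = 2, n_starts = 10, seed = 5)
  expect_lt(fit$stress, 0.01)
  fit2 <- nmds(d, k = 2, n_starts = 10, seed = 5)
  expect_identical(fit$scores, fit2$scores)
  expect_error(nmds(stats::dist(p[1:2, ]), k = 2), "k \\+ 1")
})

test_that("hierarchical clustering matches a hand-worked average linkage", {
  # pairs (a,b) at 1, (c,d) at 2; cross distances 8, 9, 7, 8 (mean 8)
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- 1; dm["c", "d"] <- 2
  dm["a", "c"] <- 8; dm["a", "d"] <- 9; dm["b", "c"] <- 7; dm["b", "d"] <- 8
  dm <- dm + t(dm)
  hc <- hierarchical_cluster(stats::as.dist(dm), "average")
  expect_equal(hc$height, c(1, 2, 8))
  expect_identical(sort(unname(stats::cutree(hc, 2)[c("a", "b")])),
                   c(1L, 1L))
  expect_error(hierarchical_cluster(stats::as.dist(dm), "fancy"),
               "arg")
})

test_that("ANOSIM equals the rank-arithmetic oracle and binds its range", {
  # fully separated groups: every between distance exceeds every within
  p <- rbind(matrix(stats::rnorm(6, 0, 0.01), 3, 2),
             matrix(stats::rnorm(6, 50, 0.01), 3, 2))
  d <- stats::dist(p)
  g <- rep(c("x", "y"), each = 3)
  res <- anosim_test(d, g, n_perm = 99, seed = 1)
  expect_equal(res$R, 1)
  expect_gte(res$p, 1 / 100)

  set.seed(9)
  d2 <- stats::dist(matrix(stats::rnorm(12), 6, 2))
  g2 <- rep(c("x", "y"), 3)
  expect_equal(anosim_test(d2, g2, n_perm = 9, seed = 1)$R,
               anosim_brute(d2, g2), tolerance = 1e-12)

  # exchangeable labels: R centred on zero
  set.seed(11)
  groupings <- replicate(200, sample(g2))
  rs <- apply(groupings, 2, function(g)
    anosim_test(d2, g, n_perm = 1)$R)
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(anosim_test(d2, c("x", rep("y", 5)), seed = 1), ">= 2")
})

test_that("envfit recovers perfectly aligned variables and rejects constants", {
  p <- embeddable_points(seed = 6)
  ord <- list(scores = p)
  ev <- envfit_ordination(ord, p[, 1], n_perm = 99, seed = 1)
  expect_gt(ev$r2, 0.999)
  expect_lte(ev$p, 0.05)

  grp <- ifelse(p[, 1] > 0, "right", "left")
  far <- p; far[grp == "right", 1] <- far[grp == "right", 1] + 100
  ev2 <- envfit_ordination(list(scores = far), grp, n_perm = 99, seed = 1)
  expect_gt(ev2$r2, 0.95)
  expect_error(envfit_ordination(ord, rep(1, nrow(p))), "constant")
})

test_that("symmetric Procrustes is rotation- and reflection-blind", {
  x <- embeddable_points(seed = 8)
  th <- 0.9
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pr <- procrustes_fit(x, x %*% rot)
  expect_equal(pr$m2, 0, tolerance = 1e-10)
  expect_equal(pr$correlation, 1, tolerance = 1e-10)
  refl <- x %*% diag(c(1, -1))
  expect_equal(procrustes_fit(x, refl)$correlation, 1, tolerance = 1e-10)
  # symmetric mode: congruence does not depend on argument order
  set.seed(3)
  y <- embeddable_points(seed = 12)
  expect_equal(procrustes_fit(x, y)$correlation,
               procrustes_fit(y, x)$correlation, tolerance = 1e-10)
  expect_error(procrustes_fit(x[1:2, ], y[1:2, ]), ">= 3")
})

test_that("protest p-values are exact at the ceiling and uniform under null", {
  x <- embeddable_points(seed = 10, n = 9)
  th <- 0.4
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pr <- protest_test(x, x %*% rot, n_perm = 999, seed = 2)
  expect_equal(pr$p, 1 / 1000)
  expect_error(protest_test(x, x, n_perm = 0), "n_perm")

  # independent configurations: rejection rate at alpha=0.05 is ~0.05
  set.seed(21)
  hits <- replicate(400, {
    a <- matrix(stats::rnorm(18), 9, 2)
    b <- matrix(stats::rnorm(18), 9, 2)
    protest_test(a, b, n_perm = 199, seed = sample.int(1e6, 1))$p <= 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})
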