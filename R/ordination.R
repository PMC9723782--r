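#' Nonmetric multidimensional scaling on a distance matrix
#'
#' Best-of-several-starts NMDS (Kruskal stress-1) on a precomputed distance
#' matrix, typically Aitchison distances from [aitchison_from_counts()].
#' No community autotransforms are applied: the input is already a distance.
#'
#' @param d a [stats::dist] object
#' @param k target dimensionality (default 2)
#' @param n_starts random starts; the best configuration is kept
#' @param max_iter iteration cap per start
#' @param tol stress-ratio convergence tolerance within a run
#' @param seed optional integer seed for reproducible starts; NULL
#'   leaves the RNG state untouched
#' @return list with `scores` (samples x k), `stress` (stress-1, in
#'   \[0, 1\]), `converged` and `n_starts`
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 300, tol = 1e-7,
                 seed = NULL) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (n < k + 1) stop("need at least k + 1 samples for k-dimensional NMDS")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                        maxit = max_iter, sratmax = 1 - tol,
                        autotransform = FALSE, wascores = FALSE,
                        trace = 0)
  scores <- fit$points
  colnames(scores) <- paste0("NMDS", seq_len(k))
  list(scores = scores, stress = fit$stress, converged = fit$converged > 0,
       n_starts = n_starts)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering on a distance matrix.  Average linkage (UPGMA)
#' by default.
#'
#' @param d a [stats::dist] object
#' @param linkage one of "average", "complete", "single", "ward.D2"
#' @return an [stats::hclust] tree
#' @export
hierarchical_cluster <- function(d, linkage = "average") {
  linkage <- match.arg(linkage, c("average", "complete", "single", "ward.D2"))
  stats::hclust(d, method = linkage)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group distances exceed within-group
#' distances: `R = (mean_between_rank - mean_within_rank) / (M/4)` with
#' `M = n(n-1)/2`; R near 1 means complete separation, near 0 none.  The
#' permutation p uses the add-one estimator, so p >= 1/(1+n_perm).
#'
#' @param d a [stats::dist] object
#' @param grouping factor/character of group labels, one per sample; every
#'   group needs >= 2 members
#' @param n_perm permutations (default 999)
#' @param seed optional integer seed (NULL: RNG untouched)
#' @return list with `R`, `p` and `n_permutations`
#' @export
anosim_test <- function(d, grouping, n_perm = 999, seed = NULL) {
  grouping <- as.factor(grouping)
  if (nlevels(droplevels(grouping)) < 2) stop("need >= 2 groups")
  if (any(table(grouping) < 2)) stop("every group needs >= 2 members")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(d, grouping, permutations = n_perm)
  list(R = unname(fit$statistic), p = fit$signif, n_permutations = n_perm)
}

#' Fit an environmental variable onto an ordination
#'
#' Continuous variables: r-squared of the least-squares projection of the
#' variable onto the ordination scores (arrow fitting).  Categorical
#' variables: r-squared from the within-centroid decomposition of the score
#' sum of squares.  Significance by permutation of the variable.
#'
#' @param ord result of [nmds()] (or any list with a `scores` matrix)
#' @param variable numeric vector or factor/character, one value per
#'   ordinated sample
#' @param n_perm permutations (default 999)
#' @param seed optional integer seed (NULL: RNG untouched)
#' @return list with `r2`, `p`, `type` ("vector" or "factor") and either
#'   `direction` (unit arrow) or `centroids`
#' @export
envfit_ordination <- function(ord, variable, n_perm = 999, seed = NULL) {
  scores <- ord$scores
  if (length(variable) != nrow(scores))
    stop("variable must have one value per ordinated sample")
  if (length(unique(variable)) < 2) stop("constant variable: r2 undefined")
  is_num <- is.numeric(variable)
  env <- data.frame(v = if (is_num) variable else as.factor(variable))
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::envfit(scores, env, permutations = n_perm)
  if (is_num) {
    list(r2 = unname(fit$vectors$r), p = unname(fit$vectors$pvals),
         type = "vector",
         direction = drop(fit$vectors$arrows))
  } else {
    list(r2 = unname(fit$factors$r), p = unname(fit$factors$pvals),
         type = "factor",
         centroids = fit$factors$centroids)
  }
}

#' Procrustes superimposition of two ordinations
#'
#' Symmetric Procrustes: both configurations are centred and scaled to unit
#' sum of squares, and the rotation (reflections allowed) minimizing the
#' residual sum of squares m2 is found from the singular decomposition of
#' the cross-product.  Congruence is reported as `correlation =
#' sqrt(1 - m2)`, which is symmetric in the two inputs.
#'
#' @param x,y samples x k score matrices over the same samples (row order
#'   is matched by name when both are named)
#' @return list with `m2`, `correlation`, `residuals` (per sample) and the
#'   underlying [vegan::procrustes] fit
#' @export
procrustes_fit <- function(x, y) {
  xy <- match_score_rows(x, y)
  if (nrow(xy$x) < 3) stop("need >= 3 shared samples")
  fit <- vegan::procrustes(xy$x, xy$y, symmetric = TRUE)
  m2 <- fit$ss
  list(m2 = m2, correlation = sqrt(max(0, 1 - m2)),
       residuals = stats::setNames(stats::residuals(fit), rownames(xy$x)),
       fit = fit)
}

#' Permutation test of Procrustes congruence (protest)
#'
#' Permutes the rows of `y` and recomputes the Procrustes correlation;
#' p = (1 + number of permutations with correlation >= observed) /
#' (1 + n_perm).
#'
#' @inheritParams procrustes_fit
#' @param n_perm permutations (default 1000)
#' @param seed optional integer seed (NULL: RNG untouched)
#' @return list with `correlation`, `m2`, `p` and `n_permutations`
#' @export
protest_test <- function(x, y, n_perm = 1000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  xy <- match_score_rows(x, y)
  if (nrow(xy$x) < 3) stop("need >= 3 shared samples")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::protest(xy$x, xy$y, permutations = n_perm)
  list(correlation = fit$t0, m2 = fit$ss, p = fit$signif,
       n_permutations = n_perm)
}

match_score_rows <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!is.null(rownames(x)) && !is.null(rownames(y))) {
    shared <- intersect(rownames(x), rownames(y))
    x <- x[shared, , drop = FALSE]
    y <- y[shared, , drop = FALSE]
  } else if (nrow(x) != nrow(y)) {
    stop("configurations have different numbers of samples and no names")
  }
  list(x = x, y = y)
}
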