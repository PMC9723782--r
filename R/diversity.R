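#' Remove singleton taxa
#'
#' Drops taxa whose total count across the entire dataset equals 1 (single
#' observed sequence or individual), the usual guard against spurious OTUs.
#'
#' @param counts taxa x samples matrix or [count_table()]
#' @return input with singleton rows removed (class and domain labels kept
#'   for `count_table`s); warns if nothing is left
#' @export
remove_singletons <- function(counts) {
  keep <- rowSums(unclass(as.matrix(counts))) != 1
  if (!any(keep)) warning("all taxa are singletons; empty table returned")
  counts[keep, , drop = FALSE]
}

#' Inverse Simpson diversity
#'
#' `1 / sum(p_i^2)` on relative abundances; ranges from 1 (single taxon) to
#' S (uniform over S taxa).  Scale-invariant, so raw counts are fine.
#'
#' @param abundances non-negative vector, or taxa x samples matrix (one
#'   value per sample)
#' @return numeric diversity value(s)
#' @export
inverse_simpson <- function(abundances) {
  if (is.matrix(abundances) || inherits(abundances, "count_table")) {
    x <- t(unclass(as.matrix(abundances)))
    if (any(rowSums(x) == 0)) stop("all-zero sample")
    return(vegan::diversity(x, index = "invsimpson"))
  }
  if (any(abundances < 0)) stop("negative abundances")
  if (sum(abundances) == 0) stop("all-zero abundance vector")
  vegan::diversity(abundances, index = "invsimpson")
}

#' Expected rarefied richness
#'
#' Analytic expectation of the number of taxa seen in a random subsample of
#' `m` individuals drawn without replacement from one sample:
#' `S_m = sum_i [1 - choose(N - N_i, m) / choose(N, m)]`.
#'
#' @param counts integer count vector for one sample
#' @param m subsample size, `0 <= m <= sum(counts)`
#' @return expected richness at depth `m`
#' @export
rarefaction_expected_richness <- function(counts, m) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (m > n) stop("subsample size m exceeds sample total")
  if (m == 0) return(0)
  as.numeric(vegan::rarefy(t(as.matrix(counts)), sample = m))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided rank-sum comparison of two groups, as used for diversity
#' contrasts between habitat regimes.  The p-value is exact (enumeration)
#' for small untied samples and a tie-corrected normal approximation
#' otherwise.  The reported U is `min(U_A, U_B)`, so identical values are
#' obtained whichever group is listed first.
#'
#' @param values_a,values_b numeric vectors, each non-empty
#' @return list with `U`, `p` and the group sizes
#' @export
mann_whitney <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  u_a <- unname(wt$statistic)
  u_b <- length(values_a) * length(values_b) - u_a
  list(U = min(u_a, u_b), p = wt$p.value,
       n_a = length(values_a), n_b = length(values_b))
}

#' Per-sample diversity table for several assemblage units
#'
#' Computes inverse Simpson diversity for each sample of each unit (a
#' domain, a faunal size class or the balanced assemblage) and attaches the
#' temperature-regime group label.
#'
#' @param units named list of taxa x samples count/abundance matrices
#' @param groups named character vector sample_id -> group label (e.g. from
#'   [classify_temperature()]); samples absent from it get NA
#' @return data.frame with columns unit, sample_id, metric, value, group
#' @export
diversity_table <- function(units, groups = NULL) {
  rows <- lapply(names(units), function(u) {
    x <- unclass(as.matrix(units[[u]]))
    x <- x[, colSums(x) > 0, drop = FALSE]
    data.frame(unit = u, sample_id = colnames(x), metric = "inverse_simpson",
               value = as.numeric(inverse_simpson(x)),
               group = if (is.null(groups)) NA_character_
                       else unname(groups[colnames(x)]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
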