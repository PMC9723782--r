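# shared fixtures and independent brute-force oracles

toy_counts <- function(m, taxa = NULL, samples = NULL,
                       domain = "bacteria") {
  m <- as.matrix(m)
  rownames(m) <- taxa %||% sprintf("t%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  count_table(m, domain)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_counts <- function(n_taxa, n_samples, seed, lambda = 30) {
  set.seed(seed)
  toy_counts(matrix(stats::rpois(n_taxa * n_samples, lambda),
                    n_taxa, n_samples))
}

# elementwise oracle: rho(i,j) = 1 - var(clr_i - clr_j)/(var_i + var_j)
rho_brute <- function(clr) {
  n <- nrow(clr)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    out[i, j] <- 1 - stats::var(clr[i, ] - clr[j, ]) /
      (stats::var(clr[i, ]) + stats::var(clr[j, ]))
  dimnames(out) <- list(rownames(clr), rownames(clr))
  out
}

# elementwise oracle: Euclidean distance between CLR columns (samples)
aitchison_brute <- function(clr) {
  n <- ncol(clr)
  out <- matrix(0, n, n, dimnames = list(colnames(clr), colnames(clr)))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- sqrt(sum((clr[, i] - clr[, j])^2))
  out
}

# ANOSIM R from first principles: rank all pairwise distances (mean ties),
# R = (mean between-group rank - mean within-group rank) / (M/4)
anosim_brute <- function(d, grouping) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  ut <- upper.tri(dm)
  r <- rank(dm[ut])
  same <- outer(grouping, grouping, "==")[ut]
  (mean(r[!same]) - mean(r[same])) / (n * (n - 1) / 4)
}

# a compact scenario for plumbing tests (structure, not calibration)
small_scenario <- function(seed, ...) {
  scenario_config(
    n_taxa_per_domain = c(bacteria = 40, archaea = 15, microeukarya = 15,
                          meiofauna = 10, macrofauna = 8),
    sequencing_depth = 5000, faunal_depth = 300, seed = seed, ...)
}

# map ground-truth OTU ids to aggregated taxon names via the member table
otu_to_agg <- function(filtered, otus) {
  mem <- attr(filtered, "members")
  names(mem)[vapply(mem, function(m) any(m %in% otus), logical(1))]
}
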