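#' Within-domain relative abundances
#'
#' Converts a domain's OTU counts to per-sample proportions within that
#' domain.  Samples whose domain total is zero (or below a read threshold
#' applied upstream) are flagged rather than failing: their columns are set
#' to zero and listed in the `empty_samples` attribute so the balancing step
#' can redistribute that domain's qPCR fraction.
#'
#' @param counts taxa x samples matrix or [count_table()] for one domain
#' @return taxa x samples matrix of proportions (columns sum to 1, or to 0
#'   for flagged empty samples), with attribute `empty_samples`
#' @export
within_domain_relative <- function(counts) {
  x <- unclass(as.matrix(counts))
  tot <- colSums(x)
  empty <- colnames(x)[tot == 0]
  p <- x
  nz <- tot > 0
  p[, nz] <- sweep(x[, nz, drop = FALSE], 2, tot[nz], "/")
  p[, !nz] <- 0
  structure(p, empty_samples = empty)
}

#' Balance microbial domains by qPCR fractions
#'
#' Combines within-domain OTU proportions into one microbial assemblage by
#' scaling each domain's proportions by its qPCR-measured fraction of total
#' 16S/18S copies in that sample, then re-expressing every OTU relative to
#' all OTUs.  Fractions are renormalized per sample over the domains that
#' are actually present (published fraction tables carry rounding; a domain
#' flagged empty in a sample has its fraction redistributed proportionally
#' to the remaining domains).
#'
#' @param proportions named list of within-domain proportion matrices from
#'   [within_domain_relative()], names drawn from bacteria/archaea/
#'   microeukarya; all sharing the same samples in the same order
#' @param fractions sample x domain matrix of qPCR fractions (see
#'   [read_domain_fractions()]); must cover every domain in `proportions`
#' @return list with `abundance` (all OTUs x samples, columns summing to 1),
#'   `domain` (per-OTU domain label) and `fractions_used` (the renormalized
#'   per-sample fractions actually applied)
#' @export
balance_domains <- function(proportions, fractions) {
  doms <- names(proportions)
  if (is.null(doms) || any(!nzchar(doms)))
    stop("proportions must be a named list of domains")
  miss <- setdiff(doms, colnames(fractions))
  if (length(miss))
    stop("domain(s) missing from qPCR fractions: ",
         paste(miss, collapse = ", "))
  samples <- colnames(proportions[[1]])
  for (d in doms)
    if (!identical(colnames(proportions[[d]]), samples))
      stop("domain tables are not sample-aligned; run align_samples() first")
  if (any(!samples %in% rownames(fractions)))
    stop("sample(s) missing from qPCR fractions: ",
         paste(setdiff(samples, rownames(fractions)), collapse = ", "))
  f <- fractions[samples, doms, drop = FALSE]

  # zero out fractions of domains flagged empty in a sample, then renormalize
  for (d in doms) {
    empty <- attr(proportions[[d]], "empty_samples")
    if (length(empty)) f[empty, d] <- 0
  }
  rs <- rowSums(f)
  if (any(rs == 0)) stop("sample(s) with no usable domain: ",
                         paste(samples[rs == 0], collapse = ", "))
  f <- sweep(f, 1, rs, "/")

  blocks <- lapply(doms, function(d)
    sweep(unclass(proportions[[d]]), 2, f[, d], "*"))
  ab <- do.call(rbind, blocks)
  if (anyDuplicated(rownames(ab)))
    stop("taxon ids collide across domains")
  list(abundance = ab,
       domain = rep(doms, vapply(proportions, nrow, integer(1))),
       fractions_used = f)
}

#' Re-express relative abundances as pseudo-counts
#'
#' Count-based downstream stages (zero replacement, Dirichlet Monte-Carlo
#' resampling) need integer counts; the balanced assemblage is relative.
#' This multiplies each sample's relative abundances by a fixed depth and
#' rounds.  The CLR machinery downstream is depth-invariant, so the choice
#' of depth only sets the count resolution.
#'
#' @param abundance taxa x samples matrix of relative abundances (columns
#'   summing to 1)
#' @param depth pseudo-count depth per sample (default 1e5)
#' @return taxa x samples integer-valued matrix
#' @export
pseudo_counts <- function(abundance, depth = 1e5) {
  if (depth < 1) stop("depth must be >= 1")
  round(unclass(as.matrix(abundance)) * depth)
}

#' Exclude shallowly sequenced samples from a domain
#'
#' Samples whose total reads in a domain fall below `min_domain_reads` are
#' treated as missing for that domain (column zeroed); they are picked up as
#' `empty_samples` by [within_domain_relative()] and the domain's qPCR
#' fraction is redistributed by [balance_domains()].
#'
#' @param counts taxa x samples matrix or [count_table()]
#' @param min_domain_reads minimum per-sample read total (default 100)
#' @return matrix with shallow columns zeroed and attribute
#'   `excluded_samples`
#' @export
apply_min_domain_reads <- function(counts, min_domain_reads = 100) {
  x <- unclass(as.matrix(counts))
  shallow <- colnames(x)[colSums(x) < min_domain_reads & colSums(x) > 0]
  x[, shallow] <- 0
  structure(x, excluded_samples = shallow)
}
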