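#' Aggregate OTUs by identical taxonomic assignment
#'
#' OTU-level counts are summed over OTUs carrying byte-identical lineage
#' strings (case-sensitive), collapsing redundant sequence clusters into one
#' taxonomic identity per lineage.  Aggregated taxa are renamed by a
#' domain-letter prefix (B/A/E for bacteria/archaea/microeukarya, M/m for
#' macro/meiofauna) plus a two-letter rank code when classification stops
#' short of genus (do, ph, cl, or, fa for domain, phylum, class, order,
#' family), e.g. `B_fa_Lentimicrobiaceae` for a bacterial lineage resolved
#' only to family.
#'
#' @param counts taxa x samples [count_table()] (or matrix plus `domain`)
#' @param taxonomy named character vector OTU id -> semicolon-delimited
#'   lineage; every OTU in `counts` must be present
#' @param domain per-taxon domain labels; defaults to the table's own
#' @param ranks rank names, outermost first, used to derive the rank code
#' @return [count_table()] of aggregated taxa, with attribute `lineage`
#'   (named lineage per aggregated taxon)
#' @export
aggregate_by_taxonomy <- function(counts, taxonomy,
                                  domain = taxon_domains(counts),
                                  ranks = c("do", "ph", "cl", "or", "fa",
                                            "")) {
  x <- unclass(as.matrix(counts))
  miss <- setdiff(rownames(x), names(taxonomy))
  if (length(miss))
    stop("missing lineage for OTU(s): ", paste(miss, collapse = ", "))
  lin <- unname(taxonomy[rownames(x)])
  key <- paste(domain, lin, sep = "\r")  # never merge across domains
  groups <- split(seq_len(nrow(x)), key)
  agg <- t(vapply(groups, function(i) colSums(x[i, , drop = FALSE]),
                  numeric(ncol(x))))
  colnames(agg) <- colnames(x)
  first <- vapply(groups, `[`, integer(1), 1L)
  dom <- domain[first]
  lins <- lin[first]
  rownames(agg) <- make.unique(
    mapply(taxon_label, dom, lins, MoreArgs = list(ranks = ranks)))
  out <- count_table(agg, dom)
  attr(out, "lineage") <- stats::setNames(lins, rownames(agg))
  attr(out, "members") <- stats::setNames(
    lapply(groups, function(i) rownames(x)[i]), rownames(agg))
  out
}

taxon_label <- function(domain, lineage, ranks) {
  letter <- c(bacteria = "B", archaea = "A", microeukarya = "E",
              meiofauna = "m", macrofauna = "M")[[domain]]
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  depth <- min(length(parts), length(ranks))
  code <- ranks[depth]
  tip <- parts[length(parts)]
  if (nzchar(code)) paste(letter, code, tip, sep = "_")
  else paste(letter, tip, sep = "_")
}

#' Prevalence filter
#'
#' Drops taxa observed at count < `min_count` in `max_below` or more
#' samples; rare, patchily observed taxa are the main source of spurious
#' proportionality at small sample sizes.
#'
#' @param counts taxa x samples matrix or [count_table()]
#' @param min_count per-sample count a taxon must reach (default 2)
#' @param max_below number of below-threshold samples at which the taxon is
#'   excluded (default 7)
#' @return filtered table of the same class
#' @export
prevalence_filter <- function(counts, min_count = 2, max_below = 7) {
  x <- unclass(as.matrix(counts))
  n_below <- rowSums(x < min_count)
  counts[n_below < max_below, , drop = FALSE]
}

#' Symmetric proportionality statistic rho
#'
#' For CLR-transformed taxa i and j observed across samples:
#' `rho(i, j) = 1 - var(clr_i - clr_j) / (var(clr_i) + var(clr_j))
#'            = 2 cov(clr_i, clr_j) / (var(clr_i) + var(clr_j))`.
#' Taxa that rise and fall in constant ratio give rho near 1, antithetic
#' taxa near -1.  Unlike correlation on relative abundances, rho is valid
#' under compositional constraints because it acts on log-ratio
#' coordinates.
#'
#' @param clr taxa x samples CLR matrix (combined microbes + fauna share
#'   one CLR basis)
#' @return symmetric taxa x taxa matrix, unit diagonal; pairs involving a
#'   zero-variance taxon are NA (with a warning)
#' @export
rho_proportionality <- function(clr) {
  x <- unclass(as.matrix(clr))
  if (ncol(x) < 3) stop("need >= 3 samples to estimate rho")
  v <- apply(x, 1, stats::var)
  cv <- stats::cov(t(x))
  denom <- outer(v, v, "+")
  rho <- 2 * cv / denom
  diag(rho) <- 1
  degen <- v == 0
  if (any(degen)) {
    warning("zero-variance taxa masked in rho: ",
            paste(rownames(x)[degen], collapse = ", "))
    rho[degen, ] <- NA_real_
    rho[, degen] <- NA_real_
    diag(rho)[degen] <- NA_real_
  }
  dimnames(rho) <- list(rownames(x), rownames(x))
  rho
}

#' Threshold a rho matrix into an edge list
#'
#' Keeps unordered taxon pairs with `|rho| > cutoff` (strict, so a pair at
#' exactly the cutoff is excluded).
#'
#' @param rho matrix from [rho_proportionality()]
#' @param cutoff absolute rho threshold (default 0.75)
#' @return data.frame with `from`, `to`, `rho`, `sign` ("positive" /
#'   "negative"), `from` < `to` by row order
#' @export
threshold_edges <- function(rho, cutoff = 0.75) {
  idx <- which(upper.tri(rho) & !is.na(rho) & abs(rho) > cutoff,
               arr.ind = TRUE)
  data.frame(from = rownames(rho)[idx[, 1]],
             to = colnames(rho)[idx[, 2]],
             rho = rho[idx],
             sign = ifelse(rho[idx] > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}
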