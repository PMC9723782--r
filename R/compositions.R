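#' Count-zero multiplicative replacement
#'
#' Converts counts to per-sample proportions and imputes a small positive
#' value for every zero so that log-ratio transforms are defined.  For each
#' sample the imputed value is `scale` times the smallest nonzero proportion
#' observed in that sample, and the nonzero parts are shrunk multiplicatively
#' by (1 - total imputed mass) so the sample still sums to exactly 1.
#' Multiplicative shrinkage preserves all ratios among the nonzero parts,
#' which is what makes the replacement compositionally coherent.
#'
#' @param counts taxa x samples matrix (or [count_table()]) of non-negative
#'   counts; each sample needs at least one nonzero count
#' @param scale fraction of the per-sample minimum nonzero proportion used
#'   as the imputed value (default 0.65)
#' @return taxa x samples matrix of strictly positive proportions, columns
#'   summing to 1
#' @examples
#' m <- matrix(c(0, 1, 9), 3, 1, dimnames = list(letters[1:3], "s1"))
#' replace_zeros_czm(m)   # c(0.065, 0.0935, 0.8415)
#' @export
replace_zeros_czm <- function(counts, scale = 0.65) {
  x <- unclass(as.matrix(counts))
  if (any(x < 0)) stop("negative counts")
  if (!(scale > 0 && scale < 1)) stop("scale must be in (0, 1)")
  tot <- colSums(x)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(x)[tot == 0], collapse = ", "))
  p <- sweep(x, 2, tot, "/")
  out <- p
  for (j in seq_len(ncol(p))) {
    z <- p[, j] == 0
    if (!any(z)) next
    imp <- scale * min(p[!z, j])
    out[z, j] <- imp
    out[!z, j] <- p[!z, j] * (1 - imp * sum(z))
  }
  if (any(out <= 0))
    stop("zero replacement failed to produce strictly positive proportions; ",
         "a sample has too many zeros for its minimum nonzero part")
  out
}

#' Centred log-ratio transform
#'
#' Per sample (column): `clr(x)_i = log(x_i) - mean_j log(x_j)`.  The CLR
#' maps strictly positive compositions into a real space where ordinary
#' Euclidean geometry corresponds to Aitchison geometry on the simplex; it
#' is invariant to per-sample rescaling, so sequencing depth drops out.
#'
#' @param compositions taxa x samples matrix of strictly positive values
#'   (zeros must be replaced first, see [replace_zeros_czm()])
#' @return taxa x samples matrix of CLR coordinates; each column sums to 0
#' @export
clr_transform <- function(compositions) {
  x <- unclass(as.matrix(compositions))
  if (any(!is.finite(x)) || any(x <= 0))
    stop("CLR requires strictly positive, finite compositions; ",
         "replace zeros first")
  lx <- log(x)
  sweep(lx, 2, colMeans(lx), "-")
}

#' Aitchison distance between samples
#'
#' Pairwise Euclidean distance between the CLR coordinate vectors of
#' samples.  Equals the Aitchison distance between the underlying
#' compositions.
#'
#' @param clr taxa x samples CLR matrix from [clr_transform()]
#' @return a [stats::dist] object over samples
#' @export
aitchison_distance <- function(clr) {
  x <- unclass(as.matrix(clr))
  if (any(!is.finite(x))) stop("non-finite CLR values")
  stats::dist(t(x))
}

#' Counts to Aitchison distances in one step
#'
#' Convenience wrapper: zero replacement, CLR, pairwise distances.
#'
#' @inheritParams replace_zeros_czm
#' @return a [stats::dist] object over samples
#' @export
aitchison_from_counts <- function(counts, scale = 0.65) {
  aitchison_distance(clr_transform(replace_zeros_czm(counts, scale)))
}
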