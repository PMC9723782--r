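#' Dirichlet Monte-Carlo CLR instances
#'
#' Draws `n_mc` posterior instances of each sample's composition from
#' Dirichlet(counts + prior) and CLR-transforms each instance.  The prior
#' (default 0.5, Jeffreys-like) keeps zero counts strictly positive, and the
#' Monte-Carlo layer propagates counting uncertainty into every downstream
#' effect-size estimate instead of conditioning on a single point
#' composition.
#'
#' @param counts taxa x samples matrix (or [count_table()]) of non-negative
#'   integer counts
#' @param n_mc Monte-Carlo instances (>= 2, default 128)
#' @param prior per-cell Dirichlet prior mass (default 0.5)
#' @param seed integer seed
#' @return array taxa x samples x n_mc of CLR values
#' @export
dirichlet_clr_instances <- function(counts, n_mc = 128, prior = 0.5,
                                    seed = 1) {
  x <- unclass(as.matrix(counts))
  if (n_mc < 2) stop("n_mc must be >= 2")
  if (prior <= 0) stop("prior must be positive")
  n_tax <- nrow(x); n_smp <- ncol(x)
  set.seed(seed)
  out <- array(NA_real_, c(n_tax, n_smp, n_mc),
               dimnames = list(rownames(x), colnames(x), NULL))
  alpha <- x + prior
  for (k in seq_len(n_mc)) {
    g <- matrix(stats::rgamma(n_tax * n_smp, shape = alpha), n_tax, n_smp)
    # Dirichlet draw = normalized gammas; CLR only needs logs minus col mean
    lg <- log(g)
    out[, , k] <- sweep(lg, 2, colMeans(lg), "-")
  }
  out
}

#' Monte-Carlo effect sizes for a two-group contrast
#'
#' The ALDEx2-style standardized difference: within each Monte-Carlo
#' instance, random cross-group sample pairs give between-group CLR
#' differences, random within-group pairs give a dispersion scale (the
#' larger of the two groups' absolute within differences), and the
#' per-draw effect is their ratio.  The reported effect per taxon is the
#' median over all instances and pairings; positive values mean enrichment
#' in the first group of `levels`.
#'
#' @param mc_clr array from [dirichlet_clr_instances()]
#' @param grouping factor/character per sample, two groups, each >= 2
#'   samples
#' @param levels optional length-2 character giving the group order; the
#'   effect sign is positive toward `levels[1]`
#' @param n_pairs random pairings drawn per instance (default 36)
#' @param seed integer seed
#' @param contrast label stored with the result
#' @return data.frame (one row per taxon): `taxon`, `diff_btw` (median
#'   between-group difference, CLR units), `disp_win` (median within
#'   dispersion), `effect`, `sign_agreement` (fraction of draws agreeing
#'   with the majority sign), `contrast`
#' @export
effect_size <- function(mc_clr, grouping, levels = NULL, n_pairs = 36,
                        seed = 1, contrast = "group1_vs_group2") {
  stopifnot(length(dim(mc_clr)) == 3L)
  grouping <- as.character(grouping)
  if (length(grouping) != dim(mc_clr)[2])
    stop("grouping must have one label per sample")
  if (is.null(levels)) levels <- unique(grouping)
  if (length(levels) != 2) stop("exactly two groups required")
  ia <- which(grouping == levels[1])
  ib <- which(grouping == levels[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs >= 2 samples")
  n_mc <- dim(mc_clr)[3]
  n_tax <- dim(mc_clr)[1]
  set.seed(seed)

  pair_idx <- function(idx) {
    # ordered pairs of distinct samples within a group
    p1 <- sample(idx, n_pairs, replace = TRUE)
    off <- sample(length(idx) - 1L, n_pairs, replace = TRUE)
    p2 <- idx[(match(p1, idx) + off - 1L) %% length(idx) + 1L]
    cbind(p1, p2)
  }

  btw <- disp <- eff <- matrix(NA_real_, n_tax, n_mc * n_pairs)
  for (k in seq_len(n_mc)) {
    inst <- mc_clr[, , k, drop = FALSE]
    dim(inst) <- dim(mc_clr)[1:2]
    sa <- sample(ia, n_pairs, replace = TRUE)
    sb <- sample(ib, n_pairs, replace = TRUE)
    pa <- pair_idx(ia); pb <- pair_idx(ib)
    cols <- (k - 1L) * n_pairs + seq_len(n_pairs)
    b <- inst[, sa, drop = FALSE] - inst[, sb, drop = FALSE]
    w <- pmax(abs(inst[, pa[, 1], drop = FALSE] -
                  inst[, pa[, 2], drop = FALSE]),
              abs(inst[, pb[, 1], drop = FALSE] -
                  inst[, pb[, 2], drop = FALSE]))
    btw[, cols] <- b
    disp[, cols] <- w
    eff[, cols] <- b / pmax(w, .Machine$double.eps)
  }

  med <- function(m) apply(m, 1, stats::median)
  pos <- rowMeans(btw > 0)
  data.frame(
    taxon = dimnames(mc_clr)[[1]] %||% paste0("t", seq_len(n_tax)),
    diff_btw = med(btw),
    disp_win = med(disp),
    effect = med(eff),
    sign_agreement = pmax(pos, 1 - pos),
    contrast = contrast,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Taxa passing the enrichment effect-size criterion
#'
#' @param effects data.frame from [effect_size()]
#' @param threshold absolute effect cutoff (default 1)
#' @return data.frame with `taxon`, `effect` and `direction` ("up" =
#'   enriched in the contrast's first group, "down" = second)
#' @export
enriched_features <- function(effects, threshold = 1) {
  hit <- abs(effects$effect) >= threshold
  data.frame(taxon = effects$taxon[hit],
             effect = effects$effect[hit],
             direction = ifelse(effects$effect[hit] > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Run one enrichment contrast from counts
#'
#' Convenience wrapper chaining [dirichlet_clr_instances()] and
#' [effect_size()].
#'
#' @inheritParams dirichlet_clr_instances
#' @inheritParams effect_size
#' @export
enrichment_contrast <- function(counts, grouping, levels = NULL,
                                n_mc = 128, prior = 0.5, n_pairs = 36,
                                seed = 1, contrast = "group1_vs_group2") {
  mc <- dirichlet_clr_instances(counts, n_mc = n_mc, prior = prior,
                                seed = seed)
  effect_size(mc, grouping, levels = levels, n_pairs = n_pairs,
              seed = seed + 1L, contrast = contrast)
}

#' Intersection filter for fluid enrichment
#'
#' A taxon counts as enriched in diffuse fluids only if it is also enriched
#' in diffuse relative to background fluids, so that generic seawater taxa
#' do not masquerade as fluid specialists.
#'
#' @param vs_grabs,vs_background [enriched_features()] outputs for the
#'   diffuse-vs-grab and diffuse-vs-background contrasts
#' @param direction which sign means "enriched in diffuse" in each table
#'   (default "up" for both)
#' @return the `vs_grabs` rows whose taxa are confirmed against background
#' @export
confirm_fluid_enrichment <- function(vs_grabs, vs_background,
                                     direction = c("up", "up")) {
  a <- vs_grabs[vs_grabs$direction == direction[1], , drop = FALSE]
  b <- vs_background$taxon[vs_background$direction == direction[2]]
  a[a$taxon %in% b, , drop = FALSE]
}
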