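#' Scenario configuration for the synthetic assemblage generator
#'
#' Defines the study conditions emulated by [generate_dataset()]: a handful
#' of tubeworm-grab samples spanning a binary basal-temperature regime,
#' three microbial domains plus two faunal size classes, heavy-tailed
#' (log-normal latent) abundances observed through multinomial sequencing
#' with abundant zeros, planted regime-enriched taxa, and planted cliques of
#' proportional taxa spanning size classes.
#'
#' @param n_samples grab samples (default 9)
#' @param n_taxa_per_domain named counts for bacteria, archaea,
#'   microeukarya, meiofauna, macrofauna
#' @param temperature_range min/max basal temperature, degrees C
#' @param t_threshold regime split, degrees C (default 25; must lie inside
#'   the range)
#' @param n_enriched_per_regime planted enriched taxa per regime, allocated
#'   round-robin across size classes (fauna first, so both regimes get
#'   faunal seeds)
#' @param n_proportional_cliques planted cliques of co-varying taxa; cliques
#'   alternate regimes and are built from that regime's enriched fauna and
#'   microbes (topped up with unenriched microbes), each taxon in at most
#'   one clique
#' @param clique_size taxa per clique
#' @param latent_sd per-taxon log-scale noise (default 0.5)
#' @param base_sd log-scale spread of baseline abundances (default 1.5;
#'   makes taxon abundances heavy-tailed)
#' @param regime_log_fc log fold-change added to an enriched taxon's latent
#'   in samples on its regime's side of the threshold (default log(8))
#' @param clique_regime_shift regime-aligned part of the clique signal: a
#'   shared log shift all clique members gain in samples on the clique's
#'   regime side (default log(6)); this is what organizes cliques around
#'   the temperature split, as observed co-occurrence clusters are
#' @param clique_sd standard deviation of the additional per-sample
#'   Gaussian signal shared by a clique's members (default 0.75)
#' @param planted_base_mean,planted_base_sd baseline latent distribution
#'   for planted (enriched or clique) taxa (defaults 0.5, 0.75).  Planted
#'   community members are modelled as moderately abundant, consistently
#'   observed taxa: a planted taxon dominating its domain would cancel its
#'   own signal through compositional closure, and one in the rare tail
#'   would fall below the detection the procedure requires; neither is what
#'   a core-community member looks like
#' @param sequencing_depth multinomial reads per sample per microbial
#'   domain (default 2e4)
#' @param faunal_depth individuals counted per sample per faunal size class
#'   (default 500)
#' @param zero_inflation ceiling probability of independently zeroing an
#'   observed count (default 0.05); the realized dropout probability for a
#'   cell with count c is `zero_inflation * exp(-c / dropout_scale)`, so
#'   low-count cells drop out at close to the ceiling rate while abundant
#'   cells essentially never do — technical dropout is count-dependent,
#'   and biological absence is already produced by the latent regime
#'   effects.  Zeros thus arise from sampling depth and from this
#'   structural mechanism alike
#' @param dropout_scale count scale of the dropout decay (default 25)
#' @param base_log_override optional named numeric added to specific taxa's
#'   baseline latents (used to spike designated taxa)
#' @param seed integer seed
#' @return validated `scenario_config` list
#' @export
scenario_config <- function(n_samples = 9,
                            n_taxa_per_domain = c(bacteria = 80,
                                                  archaea = 40,
                                                  microeukarya = 40,
                                                  meiofauna = 17,
                                                  macrofauna = 14),
                            temperature_range = c(3, 37),
                            t_threshold = 25,
                            n_enriched_per_regime = 10,
                            n_proportional_cliques = 4,
                            clique_size = 4,
                            latent_sd = 0.5,
                            base_sd = 1.5,
                            regime_log_fc = log(8),
                            clique_regime_shift = log(6),
                            clique_sd = 0.75,
                            planted_base_mean = 0.5,
                            planted_base_sd = 0.75,
                            sequencing_depth = 2e4,
                            faunal_depth = 500,
                            zero_inflation = 0.05,
                            dropout_scale = 25,
                            base_log_override = NULL,
                            seed = 1) {
  cfg <- list(n_samples = n_samples, n_taxa_per_domain = n_taxa_per_domain,
              temperature_range = temperature_range,
              t_threshold = t_threshold,
              n_enriched_per_regime = n_enriched_per_regime,
              n_proportional_cliques = n_proportional_cliques,
              clique_size = clique_size, latent_sd = latent_sd,
              base_sd = base_sd, regime_log_fc = regime_log_fc,
              clique_regime_shift = clique_regime_shift,
              clique_sd = clique_sd,
              planted_base_mean = planted_base_mean,
              planted_base_sd = planted_base_sd,
              sequencing_depth = sequencing_depth,
              faunal_depth = faunal_depth, zero_inflation = zero_inflation,
              dropout_scale = dropout_scale,
              base_log_override = base_log_override, seed = seed)
  nums <- c(cfg$n_samples, cfg$n_taxa_per_domain, cfg$temperature_range,
            cfg$t_threshold, cfg$n_enriched_per_regime,
            cfg$n_proportional_cliques, cfg$clique_size, cfg$latent_sd,
            cfg$base_sd, cfg$regime_log_fc, cfg$clique_regime_shift,
            cfg$clique_sd, cfg$planted_base_mean, cfg$planted_base_sd,
            cfg$sequencing_depth, cfg$faunal_depth, cfg$zero_inflation,
            cfg$dropout_scale, cfg$base_log_override)
  if (any(!is.finite(nums)))
    stop("non-finite value in scenario configuration")
  if (n_samples < 4) stop("need at least 4 samples")
  miss <- setdiff(corecomm_domains(), names(n_taxa_per_domain))
  if (length(miss))
    stop("n_taxa_per_domain missing: ", paste(miss, collapse = ", "))
  if (any(n_taxa_per_domain <= 0)) stop("all taxon counts must be > 0")
  if (!(zero_inflation >= 0 && zero_inflation < 1))
    stop("zero_inflation must lie in [0, 1)")
  if (!(t_threshold > temperature_range[1] &&
        t_threshold < temperature_range[2]))
    stop("t_threshold must lie inside temperature_range")
  if (latent_sd < 0 || base_sd < 0 || clique_sd < 0)
    stop("dispersions must be non-negative")
  if (sequencing_depth < 10 || faunal_depth < 10)
    stop("depths must be >= 10")
  if (dropout_scale <= 0) stop("dropout_scale must be positive")
  if (n_proportional_cliques > 0 && clique_size < 2)
    stop("clique_size must be >= 2")
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate a synthetic multi-size-class assemblage dataset
#'
#' Per taxon i and sample s the latent log-abundance is
#' `base_i + regime effect + clique signal + noise`: enriched taxa gain
#' `regime_log_fc` in samples on their regime's side of the temperature
#' threshold, clique members share a per-sample signal, and `latent_sd`
#' Gaussian noise is taxon-and-sample specific.  Counts are multinomial
#' draws of the per-domain depth from the softmax of the domain's latents,
#' then independently zeroed with probability `zero_inflation`.  The
#' clique signal has two parts: a regime-aligned shared shift
#' (`clique_regime_shift`, centred across samples) and a shared Gaussian
#' component (`clique_sd`); co-occurrence clusters in the emulated setting
#' organize around the habitat regime, and a purely regime-independent
#' shared signal would instead act as within-group dispersion and mask the
#' very enrichment it accompanies.  qPCR domain fractions are Dirichlet draws
#' centred on (0.85, 0.08, 0.07), echoing field observations that bacteria
#' dominate 16S/18S copy numbers with archaea and microeukaryotes averaging
#' a few percent each.
#'
#' @param config a [scenario_config()]
#' @return list with `counts` (named list of per-domain [count_table()]s),
#'   `taxonomy` (named lineage vector), `metadata` (sample data.frame),
#'   `fractions` (sample x microbial-domain qPCR matrix) and `truth`
#'   (ground truth: `enriched` taxon -> regime, `cliques` list with regime
#'   attributes, `planted_strong` per regime, `domain_fractions`,
#'   `temperature`)
#' @export
generate_dataset <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  set.seed(cfg$seed)
  doms <- corecomm_domains()
  n_tax <- cfg$n_taxa_per_domain[doms]
  prefix <- c(bacteria = "bac", archaea = "arc", microeukarya = "euk",
              meiofauna = "mei", macrofauna = "mac")
  taxa <- unlist(lapply(doms, function(d)
    sprintf("%s%03d", prefix[[d]], seq_len(n_tax[[d]]))), use.names = FALSE)
  taxon_dom <- rep(doms, n_tax)
  names(taxon_dom) <- taxa
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))

  # temperatures: both regimes always represented, split near half-half
  n_high <- ceiling(cfg$n_samples / 2)
  lo <- cfg$temperature_range[1]; hi <- cfg$temperature_range[2]
  th <- cfg$t_threshold
  temp <- c(stats::runif(n_high, th + 0.1 * (hi - th), hi),
            stats::runif(cfg$n_samples - n_high, lo, th - 0.1 * (th - lo)))
  temp <- round(stats::setNames(sample(temp), samples), 1)
  regime <- ifelse(temp > th, "highT", "lowT")

  # planted enrichment, round-robin over size classes (fauna first)
  rr_doms <- c("macrofauna", "meiofauna", "bacteria", "archaea",
               "microeukarya")
  pools <- lapply(rr_doms, function(d) sample(taxa[taxon_dom == d]))
  names(pools) <- rr_doms
  enriched <- character(0)
  for (r in c("highT", "lowT")) {
    k <- 0L; i <- 0L
    while (k < cfg$n_enriched_per_regime) {
      d <- rr_doms[i %% length(rr_doms) + 1L]; i <- i + 1L
      if (length(pools[[d]]) == 0L) {
        if (all(lengths(pools) == 0L)) stop("not enough taxa to enrich")
        next
      }
      t1 <- pools[[d]][1L]; pools[[d]] <- pools[[d]][-1L]
      enriched[t1] <- r; k <- k + 1L
    }
  }

  # planted cliques: alternate regimes; enriched fauna + microbes first
  cliques <- list()
  in_clique <- character(0)
  if (cfg$n_proportional_cliques > 0) {
    for (ci in seq_len(cfg$n_proportional_cliques)) {
      r <- if (ci %% 2 == 1) "highT" else "lowT"
      enr <- names(enriched)[enriched == r]
      fauna <- setdiff(enr[taxon_dom[enr] %in%
                             c("macrofauna", "meiofauna")], in_clique)
      micro <- setdiff(enr[!taxon_dom[enr] %in%
                             c("macrofauna", "meiofauna")], in_clique)
      filler <- setdiff(taxa[!taxa %in% names(enriched) &
                               !taxon_dom[taxa] %in%
                                 c("macrofauna", "meiofauna")], in_clique)
      members <- c(utils::head(fauna, 2),
                   utils::head(micro, cfg$clique_size))
      members <- utils::head(c(members, sample(filler)), cfg$clique_size)
      if (length(members) < 2) break
      cliques[[ci]] <- structure(members, regime = r)
      in_clique <- c(in_clique, members)
    }
  }

  # latent log-abundances; planted taxa sit in the well-observed mid-range
  base <- stats::rnorm(length(taxa), 0, cfg$base_sd)
  names(base) <- taxa
  planted <- union(names(enriched), unlist(cliques))
  base[planted] <- stats::rnorm(length(planted), cfg$planted_base_mean,
                                cfg$planted_base_sd)
  if (!is.null(cfg$base_log_override)) {
    ov <- cfg$base_log_override
    bad <- setdiff(names(ov), taxa)
    if (length(bad)) stop("base_log_override names unknown: ",
                          paste(bad, collapse = ", "))
    base[names(ov)] <- base[names(ov)] + ov
  }
  lam <- matrix(base, length(taxa), cfg$n_samples,
                dimnames = list(taxa, samples))
  for (t1 in names(enriched)) {
    on_side <- regime == enriched[[t1]]
    lam[t1, on_side] <- lam[t1, on_side] + cfg$regime_log_fc
  }
  for (cl in cliques) {
    r <- attr(cl, "regime")
    ind <- as.numeric(regime == r)
    z <- cfg$clique_regime_shift * (ind - mean(ind)) +
      stats::rnorm(cfg$n_samples, 0, cfg$clique_sd)
    lam[cl, ] <- sweep(lam[cl, , drop = FALSE], 2, z, "+")
  }
  lam <- lam + matrix(stats::rnorm(length(lam), 0, cfg$latent_sd),
                      nrow(lam), ncol(lam))

  # multinomial observation per domain, then zero inflation
  counts <- list()
  for (d in doms) {
    rows <- taxa[taxon_dom == d]
    depth <- if (d %in% c("meiofauna", "macrofauna")) cfg$faunal_depth
             else cfg$sequencing_depth
    m <- vapply(samples, function(s) {
      p <- exp(lam[rows, s] - max(lam[rows, s]))
      as.numeric(stats::rmultinom(1, depth, p / sum(p)))
    }, numeric(length(rows)))
    rownames(m) <- rows
    if (cfg$zero_inflation > 0) {
      p_drop <- cfg$zero_inflation * exp(-m / cfg$dropout_scale)
      m[matrix(stats::runif(length(m)), nrow(m)) < p_drop] <- 0
    }
    counts[[d]] <- count_table(m, d)
  }

  # qPCR domain fractions: Dirichlet centred on (0.85, 0.08, 0.07)
  alpha <- c(bacteria = 0.85, archaea = 0.08, microeukarya = 0.07) * 60
  g <- matrix(stats::rgamma(3 * cfg$n_samples, shape = alpha),
              cfg$n_samples, 3, byrow = TRUE,
              dimnames = list(samples, names(alpha)))
  fractions <- g / rowSums(g)

  taxonomy <- stats::setNames(vapply(taxa, function(t1) {
    d <- taxon_dom[[t1]]
    root <- c(bacteria = "Bacteria", archaea = "Archaea",
              microeukarya = "Eukaryota", meiofauna = "Animalia",
              macrofauna = "Animalia")[[d]]
    paste(root, paste0("Phylum_", d), paste0("Class_", d),
          paste0("Order_", d), paste0("Family_", d), t1, sep = ";")
  }, character(1)), taxa)

  metadata <- data.frame(
    sample_id = samples,
    basal_temperature = unname(temp),
    substratum = sample(c("sulphide", "basalt"), cfg$n_samples,
                        replace = TRUE, prob = c(0.7, 0.3)),
    location = sample(c("Main Endeavour", "Clam Bed", "Middle Valley"),
                      cfg$n_samples, replace = TRUE),
    sample_type = "tubeworm_grab",
    stringsAsFactors = FALSE)

  truth <- list(enriched = enriched, cliques = cliques,
                planted_strong = planted_strong(enriched, cliques,
                                                taxon_dom),
                domain_fractions = fractions,
                temperature = temp, regime = stats::setNames(regime,
                                                             samples))
  list(counts = counts, taxonomy = taxonomy, metadata = metadata,
       fractions = fractions, truth = truth, config = cfg)
}

# microbes that are enriched in a regime AND share a clique with >= 1
# same-regime enriched faunal taxon: these should surface as strong-tier
# core-community members downstream
planted_strong <- function(enriched, cliques, taxon_dom) {
  out <- list(highT = character(0), lowT = character(0))
  for (cl in cliques) {
    r <- attr(cl, "regime")
    fauna <- cl[taxon_dom[cl] %in% c("macrofauna", "meiofauna") &
                  cl %in% names(enriched)[enriched == r]]
    if (length(fauna) == 0) next
    micro <- cl[!taxon_dom[cl] %in% c("macrofauna", "meiofauna") &
                  cl %in% names(enriched)[enriched == r]]
    out[[r]] <- union(out[[r]], micro)
  }
  out
}

#' Write a synthetic dataset to plain-text files
#'
#' Per-domain count TSVs, taxonomy TSV, metadata TSV, qPCR fractions TSV
#' and a ground-truth JSON.
#'
#' @param dataset result of [generate_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(dataset$counts))
    write_count_table(dataset$counts[[d]],
                      file.path(dir, paste0("counts_", d, ".tsv")))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_sample_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_domain_fractions(dataset$fractions,
                         file.path(dir, "qpcr_fractions.tsv"))
  truth <- dataset$truth
  truth$cliques <- lapply(truth$cliques, function(cl)
    list(regime = attr(cl, "regime"), members = as.vector(cl)))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the TSV files
#' @return list shaped like [generate_dataset()] output (without `truth`
#'   unless ground_truth.json is present)
#' @export
read_dataset <- function(dir) {
  counts <- list()
  for (d in corecomm_domains()) {
    f <- file.path(dir, paste0("counts_", d, ".tsv"))
    if (file.exists(f)) counts[[d]] <- read_count_table(f, d)
  }
  if (length(counts) == 0) stop("no count tables found in ", dir)
  out <- list(counts = counts,
              taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
              metadata = read_sample_metadata(file.path(dir,
                                                        "metadata.tsv")),
              fractions = read_domain_fractions(
                file.path(dir, "qpcr_fractions.tsv")))
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) {
    truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
    if (!is.null(truth$cliques) && length(truth$cliques)) {
      cl <- truth$cliques
      truth$cliques <- lapply(seq_along(cl$regime), function(i)
        structure(cl$members[[i]], regime = cl$regime[i]))
    }
    out$truth <- truth
  }
  out
}
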