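#' Pipeline configuration
#'
#' Collects every numeric threshold the analysis uses, with the
#' field-standard defaults: 25 degrees C regime split, CZM scale 0.65,
#' |rho| > 0.75 edges, effect-size cutoff 1, prevalence filter "count < 2
#' in >= 7 samples", 100-read minimum per domain and sample, pseudo-count
#' depth 1e5, 128 Monte-Carlo instances, 999/1000 permutations.
#'
#' @param t_threshold temperature regime split (degrees C)
#' @param czm_scale CZM imputation fraction
#' @param rho_cutoff absolute proportionality threshold for edges
#' @param effect_threshold enrichment effect-size cutoff
#' @param prevalence_min_count,prevalence_max_below prevalence filter: drop
#'   taxa with count < `prevalence_min_count` in >= `prevalence_max_below`
#'   samples
#' @param min_domain_reads minimum reads for a domain to count in a sample
#' @param pseudo_depth pseudo-count depth for the balanced assemblage
#' @param n_mc Dirichlet Monte-Carlo instances
#' @param n_pairs random pairings per instance in the effect size
#' @param prior Dirichlet prior mass per cell
#' @param n_perm permutations for ANOSIM/envfit
#' @param n_perm_protest permutations for protest
#' @param nmds_starts random starts for NMDS
#' @param run_ordination logical; compute the NMDS/ANOSIM/envfit/Procrustes
#'   suite (the community construction itself does not depend on it)
#' @param seed master seed; every stochastic stage derives its seed from it
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(t_threshold = 25, czm_scale = 0.65,
                            rho_cutoff = 0.75, effect_threshold = 1,
                            prevalence_min_count = 2,
                            prevalence_max_below = 7,
                            min_domain_reads = 100, pseudo_depth = 1e5,
                            n_mc = 128, n_pairs = 36, prior = 0.5,
                            n_perm = 999, n_perm_protest = 1000,
                            nmds_starts = 20, run_ordination = TRUE,
                            seed = 1) {
  cfg <- as.list(environment())
  with(cfg, stopifnot(czm_scale > 0, czm_scale < 1, rho_cutoff > 0,
                      effect_threshold > 0, prevalence_min_count > 0,
                      prevalence_max_below > 0, pseudo_depth >= 1,
                      n_mc >= 2, n_pairs >= 1, prior > 0, n_perm >= 1,
                      n_perm_protest >= 1, nmds_starts >= 1))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full core-community pipeline
#'
#' Stage order: ingest and sample alignment; singleton removal; per-domain
#' read-depth exclusion; qPCR balancing into one microbial assemblage
#' (pseudo-counts); temperature classification; diversity and the
#' ordination suite; the highT-vs-lowT enrichment contrast on the combined
#' microbe+fauna table (plus grab-vs-diffuse contrasts when fluid samples
#' exist); taxonomic aggregation and prevalence filtering; proportionality
#' rho and edge thresholding; seeded, tiered core-community construction;
#' network export and a reproducibility manifest.
#'
#' @param dataset list with `counts` (named per-domain [count_table()]s),
#'   `taxonomy`, `metadata`, `fractions` — as produced by
#'   [generate_dataset()] or [read_dataset()]
#' @param config a [pipeline_config()]
#' @param out_dir optional directory; when given, all result tables, the
#'   network files and a manifest are written there
#' @return a results bundle: list with diversity, mann_whitney, ordination,
#'   procrustes, effects (per contrast), seeds, edges, assignments,
#'   subclusters, connectivity, tables used, and the log of stage
#'   dimensions
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  md <- stage("ingest", validate_metadata(dataset$metadata))
  counts <- dataset$counts
  micro_doms <- intersect(c("bacteria", "archaea", "microeukarya"),
                          names(counts))
  fauna_doms <- intersect(c("meiofauna", "macrofauna"), names(counts))
  if (length(micro_doms) == 0) stop("no microbial count tables supplied")

  al <- stage("align", align_samples(counts, md))
  counts <- al$tables
  note("aligned on %d shared samples (dropped: %s)", length(al$samples),
       paste(unlist(al$dropped), collapse = ", "))

  counts[micro_doms] <- stage("singletons",
                              lapply(counts[micro_doms], remove_singletons))
  note("post singleton removal: %s",
       paste(sprintf("%s=%d", micro_doms,
                     vapply(counts[micro_doms], nrow, integer(1))),
             collapse = ", "))

  depth_checked <- stage("min_domain_reads", lapply(
    counts[micro_doms], apply_min_domain_reads,
    min_domain_reads = cfg$min_domain_reads))
  for (d in micro_doms) {
    ex <- attr(depth_checked[[d]], "excluded_samples")
    if (length(ex)) note("domain %s excluded in sample(s): %s", d,
                         paste(ex, collapse = ", "))
  }

  bal <- stage("qpcr_balance", {
    props <- lapply(depth_checked, within_domain_relative)
    balance_domains(props, dataset$fractions)
  })
  balanced_counts <- pseudo_counts(bal$abundance, cfg$pseudo_depth)
  note("balanced assemblage: %d OTUs x %d samples", nrow(balanced_counts),
       ncol(balanced_counts))

  regimes <- stage("temperature", classify_temperature(md,
                                                       cfg$t_threshold))
  grabs <- intersect(al$samples, names(regimes))
  fluid_samples <- setdiff(al$samples, grabs)

  units <- c(list(balanced = balanced_counts),
             lapply(counts[micro_doms], function(x) unclass(as.matrix(x))),
             lapply(counts[fauna_doms], function(x) unclass(as.matrix(x))))
  div <- stage("diversity", diversity_table(units, regimes))
  mw <- stage("mann_whitney", {
    rows <- lapply(unique(div$unit), function(u) {
      d <- div[div$unit == u & !is.na(div$group), , drop = FALSE]
      a <- d$value[d$group == "highT"]; b <- d$value[d$group == "lowT"]
      if (length(a) == 0 || length(b) == 0) return(NULL)
      r <- mann_whitney(a, b)
      data.frame(unit = u, U = r$U, p = r$p, n_highT = r$n_a,
                 n_lowT = r$n_b, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  ord <- proc <- NULL
  if (cfg$run_ordination) {
    ord_units <- units[vapply(units, function(x)
      length(intersect(colnames(x)[colSums(x) > 0], grabs)) >= 4,
      logical(1))]
    fits <- stage("ordination", lapply(ord_units, function(x) {
      x <- x[, intersect(colnames(x), grabs), drop = FALSE]
      x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
      d <- aitchison_from_counts(x, cfg$czm_scale)
      fit <- nmds(d, k = 2, n_starts = cfg$nmds_starts, seed = cfg$seed)
      g <- regimes[labels(d)]
      an <- if (length(unique(g)) == 2 && all(table(g) >= 2))
        anosim_test(d, g, n_perm = cfg$n_perm, seed = cfg$seed)
      else list(R = NA_real_, p = NA_real_)
      tv <- md$basal_temperature[match(rownames(fit$scores),
                                       md$sample_id)]
      ev <- envfit_ordination(fit, tv, n_perm = cfg$n_perm,
                              seed = cfg$seed)
      list(fit = fit, anosim = an, envfit = ev)
    }))
    ord <- data.frame(
      unit = names(fits),
      stress = vapply(fits, function(f) f$fit$stress, numeric(1)),
      anosim_R = vapply(fits, function(f) f$anosim$R, numeric(1)),
      anosim_p = vapply(fits, function(f) f$anosim$p, numeric(1)),
      envfit_r2 = vapply(fits, function(f) f$envfit$r2, numeric(1)),
      envfit_p = vapply(fits, function(f) f$envfit$p, numeric(1)),
      stringsAsFactors = FALSE)
    pairs <- utils::combn(names(fits), 2, simplify = FALSE)
    proc <- stage("procrustes", do.call(rbind, lapply(pairs, function(p) {
      x <- fits[[p[1]]]$fit$scores; y <- fits[[p[2]]]$fit$scores
      if (length(intersect(rownames(x), rownames(y))) < 3) return(NULL)
      pr <- protest_test(x, y, n_perm = cfg$n_perm_protest,
                         seed = cfg$seed)
      data.frame(x = p[1], y = p[2], correlation = pr$correlation,
                 m2 = pr$m2, p = pr$p, stringsAsFactors = FALSE)
    })))
    attr(ord, "fits") <- fits
  }

  # combined microbe + fauna table over grab samples, one composition
  combined <- stage("combine", {
    blocks <- c(list(balanced_counts[, grabs, drop = FALSE]),
                lapply(counts[fauna_doms], function(x)
                  unclass(as.matrix(x))[, grabs, drop = FALSE]))
    m <- do.call(rbind, blocks)
    count_table(m, c(bal$domain,
                     rep(fauna_doms, vapply(counts[fauna_doms], nrow,
                                            integer(1)))))
  })

  agg <- stage("aggregate", aggregate_by_taxonomy(
    combined, dataset$taxonomy,
    domain = taxon_domains(combined)))
  filt <- stage("prevalence_filter", prevalence_filter(
    agg, cfg$prevalence_min_count, cfg$prevalence_max_below))
  note("combined %d taxa -> %d aggregated -> %d after prevalence filter",
       nrow(combined), nrow(agg), nrow(filt))
  filt_dom <- taxon_domains(filt)
  fauna_ids <- rownames(filt)[filt_dom %in% c("meiofauna", "macrofauna")]
  micro_ids <- setdiff(rownames(filt), fauna_ids)

  grp <- regimes[colnames(filt)]
  effects <- list()
  effects$highT_vs_lowT <- stage("enrichment", enrichment_contrast(
    filt, grp, levels = c("highT", "lowT"), n_mc = cfg$n_mc,
    prior = cfg$prior, n_pairs = cfg$n_pairs, seed = cfg$seed,
    contrast = "highT_vs_lowT"))

  diffuse <- md$sample_id[md$sample_type == "diffuse_fluid"]
  diffuse <- intersect(diffuse, colnames(balanced_counts))
  for (r in c("highT", "lowT")) {
    gs <- grabs[regimes[grabs] == r]
    if (length(gs) >= 2 && length(diffuse) >= 2) {
      lab <- paste0(r, "_vs_diffuse")
      sub <- balanced_counts[, c(gs, diffuse), drop = FALSE]
      effects[[lab]] <- stage(lab, enrichment_contrast(
        sub, c(rep("grab", length(gs)), rep("diffuse", length(diffuse))),
        levels = c("grab", "diffuse"), n_mc = cfg$n_mc, prior = cfg$prior,
        n_pairs = cfg$n_pairs, seed = cfg$seed + 7L, contrast = lab))
    }
  }

  rho <- stage("rho", {
    clr <- clr_transform(replace_zeros_czm(filt, cfg$czm_scale))
    rho_proportionality(clr)
  })
  edges <- threshold_edges(rho, cfg$rho_cutoff)
  note("%d edges at |rho| > %g", nrow(edges), cfg$rho_cutoff)

  faunal_fx <- effects$highT_vs_lowT[
    effects$highT_vs_lowT$taxon %in% fauna_ids, , drop = FALSE]
  seeds <- stage("seeds", seed_fauna(faunal_fx, cfg$effect_threshold))
  micro_fx <- effects$highT_vs_lowT[
    effects$highT_vs_lowT$taxon %in% micro_ids, , drop = FALSE]
  dif_fx <- function(lab) {
    e <- effects[[lab]]
    if (is.null(e)) return(NULL)
    e[e$taxon %in% micro_ids, , drop = FALSE]
  }
  flags <- enrichment_flags(micro_fx, dif_fx("highT_vs_diffuse"),
                            dif_fx("lowT_vs_diffuse"),
                            cfg$effect_threshold)
  assignments <- stage("tiers", tier_taxa(edges, seeds, flags, micro_ids))
  subclusters <- stage("subcluster",
                       subcluster_highT(rho, seeds$highT, edges))
  connectivity <- stage("connectivity",
                        connectivity_summary(edges, seeds, fauna_ids))
  note("community: %d strong, %d moderate, %d weak of %d microbial taxa",
       sum(assignments$tier == "strong"),
       sum(assignments$tier == "moderate"),
       sum(assignments$tier == "weak"), length(micro_ids))

  bundle <- list(diversity = div, mann_whitney = mw, ordination = ord,
                 procrustes = proc, effects = effects, rho = rho,
                 edges = edges, seeds = seeds, flags = flags,
                 assignments = assignments, subclusters = subclusters,
                 connectivity = connectivity,
                 tables = list(balanced = balanced_counts,
                               combined = combined, filtered = filt),
                 regimes = regimes, config = cfg, log = log)

  if (!is.null(out_dir)) bundle$files <- write_bundle(bundle, out_dir,
                                                      filt_dom)
  bundle
}

write_bundle <- function(bundle, out_dir, domains) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }
  files <- c(
    wt(bundle$diversity, "diversity.tsv"),
    if (!is.null(bundle$mann_whitney)) wt(bundle$mann_whitney,
                                          "mann_whitney.tsv"),
    if (!is.null(bundle$ordination))
      wt(bundle$ordination, "ordination_stats.tsv"),
    if (!is.null(bundle$procrustes)) wt(bundle$procrustes,
                                        "procrustes.tsv"),
    vapply(names(bundle$effects), function(lab)
      wt(bundle$effects[[lab]], paste0("effects_", lab, ".tsv")),
      character(1)),
    wt(bundle$edges, "edges.tsv"),
    wt(bundle$assignments, "community.tsv"),
    wt(bundle$connectivity, "connectivity.tsv"))
  net <- export_network(bundle$edges, bundle$assignments,
                        stats::setNames(domains,
                                        rownames(bundle$tables$filtered)),
                        file.path(out_dir, "network"),
                        seeds = bundle$seeds,
                        subclusters = bundle$subclusters)
  files <- c(files, net)
  manifest <- list(
    package = "corecomm",
    config = unclass(bundle$config),
    seed = bundle$config$seed,
    log = bundle$log,
    checksums = as.list(tools::md5sum(files)))
  names(manifest$checksums) <- basename(files)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(files, manifest = mf)
}
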