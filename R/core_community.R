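#' Classify grab samples into temperature regimes
#'
#' Samples with basal temperature strictly above the threshold are "highT",
#' the rest "lowT".  A grab sample at exactly the threshold is lowT.
#'
#' @param metadata sample metadata (see [read_sample_metadata()])
#' @param threshold regime split in degrees C (default 25)
#' @return named character vector sample_id -> regime, for tubeworm grab
#'   samples
#' @export
classify_temperature <- function(metadata, threshold = 25) {
  md <- metadata[metadata$sample_type == "tubeworm_grab", , drop = FALSE]
  if (any(is.na(md$basal_temperature)))
    stop("missing basal temperature for grab sample(s): ",
         paste(md$sample_id[is.na(md$basal_temperature)], collapse = ", "))
  stats::setNames(ifelse(md$basal_temperature > threshold, "highT",
                         "lowT"),
                  md$sample_id)
}

#' Seed fauna for community building
#'
#' Faunal species enriched toward a regime (|effect| >= threshold in the
#' highT-vs-lowT contrast) become that regime's seeds, the starting points
#' around which core communities are assembled.
#'
#' @param effects [effect_size()] table for faunal taxa on the
#'   highT-vs-lowT contrast (positive = highT)
#' @param threshold effect cutoff (default 1)
#' @return list with `highT` and `lowT` character vectors of seed species;
#'   warns when both are empty
#' @export
seed_fauna <- function(effects, threshold = 1) {
  seeds <- list(highT = effects$taxon[effects$effect >= threshold],
                lowT = effects$taxon[effects$effect <= -threshold])
  if (length(seeds$highT) == 0 && length(seeds$lowT) == 0)
    warning("no enriched fauna in either regime; community will be empty")
  seeds
}

#' Combine enrichment contrasts into per-taxon regime flags
#'
#' @param vs_opposite [effect_size()] table for the highT-vs-lowT grab
#'   contrast (positive = enriched in highT)
#' @param highT_vs_diffuse,lowT_vs_diffuse optional [effect_size()] tables
#'   for grab-vs-same-regime-diffuse-fluid contrasts (positive = enriched
#'   in grabs); NULL when no fluid samples exist
#' @param threshold effect cutoff (default 1)
#' @return data.frame: taxon, regime, vs_opposite (logical), vs_diffuse
#'   (logical); one row per (taxon, regime) with any enrichment evidence
#' @export
enrichment_flags <- function(vs_opposite, highT_vs_diffuse = NULL,
                             lowT_vs_diffuse = NULL, threshold = 1) {
  rows <- list()
  add <- function(taxa, regime, col) {
    for (t1 in taxa) rows[[length(rows) + 1L]] <<-
      data.frame(taxon = t1, regime = regime,
                 vs_opposite = col == "vs_opposite",
                 vs_diffuse = col == "vs_diffuse",
                 stringsAsFactors = FALSE)
  }
  add(vs_opposite$taxon[vs_opposite$effect >= threshold], "highT",
      "vs_opposite")
  add(vs_opposite$taxon[vs_opposite$effect <= -threshold], "lowT",
      "vs_opposite")
  if (!is.null(highT_vs_diffuse))
    add(highT_vs_diffuse$taxon[highT_vs_diffuse$effect >= threshold],
        "highT", "vs_diffuse")
  if (!is.null(lowT_vs_diffuse))
    add(lowT_vs_diffuse$taxon[lowT_vs_diffuse$effect >= threshold],
        "lowT", "vs_diffuse")
  if (length(rows) == 0)
    return(data.frame(taxon = character(0), regime = character(0),
                      vs_opposite = logical(0), vs_diffuse = logical(0)))
  df <- do.call(rbind, rows)
  stats::aggregate(cbind(vs_opposite, vs_diffuse) ~ taxon + regime, df,
                   any)
}

#' Tiered core-community membership
#'
#' Combines positive proportionality edges to a regime's seed fauna with
#' enrichment evidence into tiers: `strong` = at least one positive faunal
#' edge AND enrichment in a qualifying contrast (vs the opposite regime's
#' grabs, or vs the same regime's diffuse fluids); `moderate` = positive
#' edges to two or more seed fauna without enrichment; `weak` = enrichment
#' only, or a single faunal edge without enrichment.  Only positive edges
#' count as membership evidence; a taxon is assigned to the regime where
#' its evidence is maximal, and ties are reported for both regimes with an
#' ambiguity flag rather than silently resolved.
#'
#' @param edges edge list from [threshold_edges()]
#' @param seeds list from [seed_fauna()]
#' @param flags data.frame from [enrichment_flags()]
#' @param taxa character vector of candidate (microbial) taxon ids to
#'   classify
#' @return data.frame, one row per assigned (taxon, regime):
#'   taxon, regime, tier, n_edges_total, n_edges_to_fauna, mean_rho_fauna,
#'   vs_opposite, vs_diffuse, ambiguous
#' @export
tier_taxa <- function(edges, seeds, flags, taxa) {
  pos <- edges[edges$sign == "positive", , drop = FALSE]
  partner_rows <- function(t1) {
    i <- pos$from == t1 | pos$to == t1
    data.frame(other = ifelse(pos$from[i] == t1, pos$to[i], pos$from[i]),
               rho = pos$rho[i], stringsAsFactors = FALSE)
  }
  tier_rank <- c(strong = 3, moderate = 2, weak = 1, none = 0)
  out <- list()
  for (t1 in taxa) {
    pr <- partner_rows(t1)
    cand <- list()
    for (r in c("highT", "lowT")) {
      fa <- pr[pr$other %in% seeds[[r]], , drop = FALSE]
      fl <- flags[flags$taxon == t1 & flags$regime == r, , drop = FALSE]
      vs_opp <- nrow(fl) > 0 && any(fl$vs_opposite)
      vs_dif <- nrow(fl) > 0 && any(fl$vs_diffuse)
      enr <- vs_opp || vs_dif
      n_f <- nrow(fa)
      tier <- if (n_f >= 1 && enr) "strong"
              else if (n_f >= 2) "moderate"
              else if (enr || n_f == 1) "weak"
              else "none"
      cand[[r]] <- data.frame(
        taxon = t1, regime = r, tier = tier,
        n_edges_total = nrow(pr), n_edges_to_fauna = n_f,
        mean_rho_fauna = if (n_f) mean(fa$rho) else NA_real_,
        vs_opposite = vs_opp, vs_diffuse = vs_dif,
        ambiguous = FALSE, stringsAsFactors = FALSE)
    }
    sc <- vapply(cand, function(d)
      tier_rank[[d$tier]] * 1e6 + d$n_edges_to_fauna * 1e3 +
        ifelse(is.na(d$mean_rho_fauna), 0, d$mean_rho_fauna),
      numeric(1))
    if (max(sc) == 0) {
      row <- cand[[1]]
      row$regime <- "none"; row$tier <- "none"
      out[[length(out) + 1L]] <- row
    } else if (sc["highT"] == sc["lowT"]) {
      cand$highT$ambiguous <- cand$lowT$ambiguous <- TRUE
      out[[length(out) + 1L]] <- cand$highT
      out[[length(out) + 1L]] <- cand$lowT
    } else {
      out[[length(out) + 1L]] <- cand[[names(which.max(sc))]]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  stopifnot(all(res$tier != "strong" |
                  (res$n_edges_to_fauna >= 1 &
                     (res$vs_opposite | res$vs_diffuse))),
            all(res$tier != "moderate" | res$n_edges_to_fauna >= 2))
  res
}

#' Sub-cluster the highT community by its fauna
#'
#' Average-linkage clustering of (1 - rho) among the highT seed fauna,
#' cut into two groups; microbial taxa inherit the sub-cluster(s) of the
#' fauna they hold positive edges to ("HighT 1", "HighT 2", or "HighT 1/2"
#' when connected to both).  The group containing the alphabetically first
#' seed is labelled "HighT 1" so labels are deterministic.
#'
#' @param rho rho matrix over at least the highT seed fauna
#' @param seeds_highT character vector of highT seed fauna (>= 2 required
#'   for a split; otherwise everything is "na")
#' @param edges edge list from [threshold_edges()]
#' @return list with `fauna` (named labels for seed fauna) and `taxa`
#'   (named labels for taxa with positive edges to labelled fauna)
#' @export
subcluster_highT <- function(rho, seeds_highT, edges) {
  if (length(seeds_highT) < 2)
    return(list(fauna = stats::setNames(rep("na", length(seeds_highT)),
                                        seeds_highT),
                taxa = character(0)))
  sub <- rho[seeds_highT, seeds_highT, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(1 - sub), method = "average")
  grp <- stats::cutree(hc, k = 2)
  first <- sort(seeds_highT)[1]
  labels <- ifelse(grp == grp[[first]], "HighT 1", "HighT 2")
  names(labels) <- names(grp)
  pos <- edges[edges$sign == "positive", , drop = FALSE]
  others <- setdiff(unique(c(pos$from, pos$to)), seeds_highT)
  taxa <- character(0)
  for (t1 in others) {
    i <- pos$from == t1 | pos$to == t1
    part <- ifelse(pos$from[i] == t1, pos$to[i], pos$from[i])
    hit <- unique(labels[intersect(part, seeds_highT)])
    if (length(hit) == 0) next
    taxa[t1] <- if (length(hit) == 2) "HighT 1/2" else hit
  }
  list(fauna = labels, taxa = taxa)
}

#' Network connectivity of seed fauna, by regime
#'
#' For each regime's seed fauna: mean and sample standard deviation of the
#' number of positive edges per species (total, and to other faunal
#' species).  A single seed reports sd 0 with `n = 1` so degenerate runs
#' stay representable.
#'
#' @param edges edge list from [threshold_edges()]
#' @param seeds list from [seed_fauna()]
#' @param fauna character vector of all faunal taxon ids (used to count
#'   fauna-fauna edges)
#' @return data.frame: regime, n_seeds, mean_total, sd_total, mean_fauna,
#'   sd_fauna
#' @export
connectivity_summary <- function(edges, seeds, fauna) {
  pos <- edges[edges$sign == "positive", , drop = FALSE]
  degree <- function(t1, within = NULL) {
    i <- pos$from == t1 | pos$to == t1
    part <- ifelse(pos$from[i] == t1, pos$to[i], pos$from[i])
    if (is.null(within)) length(part) else sum(part %in% within)
  }
  rows <- lapply(c("highT", "lowT"), function(r) {
    s <- seeds[[r]]
    if (length(s) == 0)
      return(data.frame(regime = r, n_seeds = 0, mean_total = NA_real_,
                        sd_total = NA_real_, mean_fauna = NA_real_,
                        sd_fauna = NA_real_))
    tot <- vapply(s, degree, numeric(1))
    fau <- vapply(s, degree, numeric(1), within = fauna)
    sdv <- function(v) if (length(v) > 1) stats::sd(v) else 0
    data.frame(regime = r, n_seeds = length(s),
               mean_total = mean(tot), sd_total = sdv(tot),
               mean_fauna = mean(fau), sd_fauna = sdv(fau))
  })
  do.call(rbind, rows)
}

#' Export the community network
#'
#' Writes the proportionality network as GraphML (node attributes:
#' size_class, regime, tier, subcluster, seed; edge attributes: rho, sign)
#' and as a SIF edge list.  Strong-tier members and seed fauna map to large
#' nodes, weak to intermediate, in downstream viewers.
#'
#' @param edges edge list from [threshold_edges()]
#' @param assignments data.frame from [tier_taxa()] (may be empty)
#' @param domains named character vector taxon -> size class
#' @param path output path without extension; `<path>.graphml` and
#'   `<path>.sif` are written
#' @param seeds optional list from [seed_fauna()]
#' @param subclusters optional result of [subcluster_highT()]
#' @return named character vector of the files written
#' @export
export_network <- function(edges, assignments, domains, path,
                           seeds = NULL, subclusters = NULL) {
  nodes <- unique(c(edges$from, edges$to, assignments$taxon,
                    unlist(seeds)))
  nodes <- sort(nodes[!is.na(nodes) & nodes != ""])
  seed_set <- unlist(seeds)
  node_attr <- function(n) {
    a <- assignments[assignments$taxon == n, , drop = FALSE]
    sub <- if (!is.null(subclusters)) {
      if (n %in% names(subclusters$fauna)) subclusters$fauna[[n]]
      else if (n %in% names(subclusters$taxa)) subclusters$taxa[[n]]
      else "na"
    } else "na"
    regime <- if (n %in% seed_set)
      names(seeds)[vapply(seeds, function(s) n %in% s, logical(1))][1]
    else if (nrow(a)) paste(a$regime, collapse = "/")
    else "none"
    list(size_class = if (n %in% names(domains)) domains[[n]] else "na",
         regime = regime,
         tier = if (n %in% seed_set) "seed"
                else if (nrow(a)) paste(a$tier, collapse = "/")
                else "none",
         subcluster = sub)
  }

  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="size_class" for="node" attr.name="size_class" attr.type="string"/>',
    '  <key id="regime" for="node" attr.name="regime" attr.type="string"/>',
    '  <key id="tier" for="node" attr.name="tier" attr.type="string"/>',
    '  <key id="subcluster" for="node" attr.name="subcluster" attr.type="string"/>',
    '  <key id="rho" for="edge" attr.name="rho" attr.type="double"/>',
    '  <key id="sign" for="edge" attr.name="sign" attr.type="string"/>',
    '  <graph id="core_community" edgedefault="undirected">')
  for (n in nodes) {
    a <- node_attr(n)
    lines <- c(lines, sprintf('    <node id="%s">', esc(n)),
               sprintf('      <data key="size_class">%s</data>',
                       esc(a$size_class)),
               sprintf('      <data key="regime">%s</data>', esc(a$regime)),
               sprintf('      <data key="tier">%s</data>', esc(a$tier)),
               sprintf('      <data key="subcluster">%s</data>',
                       esc(a$subcluster)),
               "    </node>")
  }
  if (nrow(edges))
    lines <- c(lines, sprintf(
      paste0('    <edge source="%s" target="%s">',
             '<data key="rho">%.10g</data>',
             '<data key="sign">%s</data></edge>'),
      esc(edges$from), esc(edges$to), edges$rho, edges$sign))
  lines <- c(lines, "  </graph>", "</graphml>")
  graphml <- paste0(path, ".graphml")
  writeLines(lines, graphml)

  sif <- paste0(path, ".sif")
  if (nrow(edges)) {
    writeLines(sprintf("%s\t%s\t%s", edges$from,
                       ifelse(edges$sign == "positive", "pp", "nn"),
                       edges$to), sif)
  } else writeLines(character(0), sif)
  c(graphml = graphml, sif = sif)
}

#' Read edges back from a GraphML file written by [export_network()]
#'
#' @param path a `.graphml` file
#' @return data.frame with from, to, rho, sign
#' @export
read_graphml_edges <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  es <- xml2::xml_find_all(doc, ".//g:edge", ns)
  if (length(es) == 0)
    return(data.frame(from = character(0), to = character(0),
                      rho = numeric(0), sign = character(0)))
  data.frame(
    from = xml2::xml_attr(es, "source"),
    to = xml2::xml_attr(es, "target"),
    rho = as.numeric(xml2::xml_text(
      xml2::xml_find_first(es, ".//g:data[@key='rho']", ns))),
    sign = xml2::xml_text(
      xml2::xml_find_first(es, ".//g:data[@key='sign']", ns)),
    stringsAsFactors = FALSE)
}
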