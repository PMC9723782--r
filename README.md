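# corecomm

Distils diverse multi-size-class assemblage data — amplicon OTU tables
for three microbial domains plus meio- and macrofaunal species counts —
into **core communities**: the taxa that are both enriched in a habitat
regime and covary (are *proportional*) with that regime's characteristic
fauna. The package targets surveys like tubeworm-hosted hydrothermal-vent
assemblages, where grab samples split into high- and low-temperature
regimes at ~25 °C basal fluid temperature, but the machinery is generic
to any two-regime, multi-size-class design.

It is written for ecologists who have per-domain OTU count tables, a
taxonomy table, faunal counts, per-sample qPCR domain fractions and
sample metadata, and who want the entire analysis — compositional
transforms through network construction — reproducible from one seed.

## The statistics at the core

* **Compositional footing.** Counts are treated as compositions: zeros
  are imputed by count-zero multiplicative replacement (imputed value =
  0.65 × the sample's smallest nonzero proportion, nonzero parts shrunk
  multiplicatively), then centred-log-ratio transformed,
  clr(x)ᵢ = ln xᵢ − mean(ln x). Sample dissimilarity is the Aitchison
  distance, the Euclidean distance between CLR vectors.
* **qPCR balancing.** Within-domain OTU proportions are scaled by the
  qPCR-measured fraction of 16S/18S copies per domain, yielding one
  balanced microbial assemblage per sample whose domain subtotals equal
  the measured fractions.
* **Enrichment.** For a two-group contrast, per-sample compositions are
  resampled from Dirichlet(counts + 0.5) posteriors (128 instances),
  CLR-transformed, and summarized per taxon by the median of
  (between-group difference) / (largest within-group difference) over
  random sample pairings. |effect| ≥ 1 is the enrichment criterion.
* **Proportionality.** For CLR series of taxa i and j,
  ρ = 1 − var(clrᵢ − clrⱼ)/(var(clrᵢ) + var(clrⱼ)) =
  2·cov(clrᵢ, clrⱼ)/(var(clrᵢ) + var(clrⱼ)); pairs with |ρ| > 0.75 form
  the co-occurrence network.
* **Community tiers.** Faunal species enriched toward a regime seed it;
  microbial taxa become *strong* (positive edge to seed fauna **and**
  enrichment), *moderate* (edges to ≥ 2 seed fauna), or *weak*
  (enrichment only, or a single faunal edge) members.
* **Supporting suite.** Inverse Simpson diversity, expected rarefaction
  richness, Mann–Whitney contrasts, NMDS, ANOSIM, envfit, and symmetric
  Procrustes/protest congruence between size-class ordinations (via
  vegan).

A synthetic-data generator (`generate_dataset()`) plants known enriched
taxa and proportional cliques spanning size classes, so every stage is
testable without any sequence deposit.

## Worked example

```r
library(corecomm)

ds  <- generate_dataset(scenario_config(seed = 1))   # 9 samples, 191 taxa
res <- run_pipeline(ds, pipeline_config(seed = 1))
cat(res$log, sep = "\n")
#> aligned on 9 shared samples (dropped: )
#> post singleton removal: bacteria=80, archaea=40, microeukarya=40
#> balanced assemblage: 160 OTUs x 9 samples
#> combined 191 taxa -> 191 aggregated -> 188 after prevalence filter
#> 532 edges at |rho| > 0.75
#> community: 14 strong, 1 moderate, 22 weak of 159 microbial taxa

asg <- res$assignments
head(asg[asg$tier == "strong",
         c("taxon", "regime", "tier", "n_edges_to_fauna",
           "mean_rho_fauna", "vs_opposite")])
#>     taxon regime   tier n_edges_to_fauna mean_rho_fauna vs_opposite
#>  A_arc006  highT strong                4      0.8936091        TRUE
#>  B_bac040  highT strong                4      0.8679421        TRUE
#>  B_bac044  highT strong                4      0.9152738        TRUE
#>  E_euk009  highT strong                4      0.8286041        TRUE
#>  E_euk016  highT strong                4      0.9427167        TRUE
#>  B_bac025   lowT strong                3      0.8422243        TRUE
```

Each strong-tier row is a microbial taxon holding positive ρ edges
(here to 3–4 seed fauna, average ρ ≈ 0.83–0.94) *and* enrichment toward
its regime — the double evidence that defines core membership. The
bundle also carries the regime separation statistics of the balanced
assemblage:

```r
res$ordination[res$ordination$unit == "balanced", ]
#>      unit       stress anosim_R anosim_p envfit_r2 envfit_p
#>  balanced 9.262821e-05        1    0.012 0.8494935    0.007
```

(ANOSIM R = 1: in this synthetic run the two temperature regimes are
completely separated in Aitchison space; the near-zero stress reflects
the degenerate two-cluster geometry.)

Writing `run_pipeline(..., out_dir = "out")` exports every table as TSV,
the network as GraphML + SIF (Cytoscape-ready, with tier and sub-cluster
node attributes), and a manifest with config, seed and file checksums.
The same pipeline runs from a shell:

```sh
Rscript inst/scripts/corecomm-pipeline.R simulate --out simdata --seed 5
Rscript inst/scripts/corecomm-pipeline.R run --input simdata --out simout --seed 5
Rscript inst/scripts/corecomm-pipeline.R report --input simout
```

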