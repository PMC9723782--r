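---
title: "Distilling multi-size-class assemblages into core communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distilling multi-size-class assemblages into core communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Faunal assemblages hosted by foundation species — here, deep-sea
hydrothermal-vent tubeworm bushes — contain thousands of microbial OTUs
alongside dozens of meiofaunal (64 µm–1 mm) and macrofaunal (>1 mm)
species. Most of that diversity is incidental. The question this package
addresses is how to distil it down to a **core community**: the subset of
taxa that are both *enriched* in a habitat regime and *covary* with the
regime's characteristic fauna, and are therefore the best candidates for
actual interspecies interaction.

The habitat regimes are defined by basal fluid temperature: grab samples
split into "highT" (above 25 °C) and "lowT" (at or below 25 °C). The
split is strict (`> threshold` is highT), so a sample at exactly 25 °C is
lowT.

## The procedure

`run_pipeline()` executes the stages in order:

1. **Ingest and align.** Per-domain OTU tables (bacteria, archaea,
   microeukarya), faunal species tables (meiofauna, macrofauna), sample
   metadata and per-sample qPCR domain fractions are validated and
   restricted to shared samples. All tables are taxa × samples.
2. **Singleton removal.** OTUs with a single sequence dataset-wide are
   dropped (`remove_singletons()`).
3. **Read-depth exclusion.** A domain observed with fewer than
   `min_domain_reads` (default 100) reads in a sample is treated as
   missing there; its qPCR fraction is redistributed proportionally to
   the remaining domains.
4. **qPCR balancing.** Within-domain relative abundances are scaled by
   the qPCR-measured fraction of 16S/18S copies per domain and sample,
   giving one balanced microbial assemblage per sample
   (`balance_domains()`). Because downstream stages are count-based, the
   balanced relative abundances are re-expressed as pseudo-counts at a
   fixed depth (`pseudo_depth`, default 1e5) — the CLR machinery is
   depth-invariant, so this choice only sets count resolution.
5. **Compositional transforms.** Zeros are imputed by count-zero
   multiplicative replacement (`replace_zeros_czm()`), compositions are
   centred-log-ratio transformed (`clr_transform()`), and sample
   dissimilarity is the Aitchison distance (Euclidean distance between
   CLR vectors).
6. **Diversity and ordination.** Inverse Simpson diversity per sample
   and unit, Mann–Whitney contrasts between regimes, NMDS on Aitchison
   distances, ANOSIM for regime separation, `envfit` for temperature,
   and symmetric Procrustes/protest congruence between every pair of
   unit ordinations.
7. **Enrichment.** Dirichlet Monte-Carlo CLR effect sizes
   (`effect_size()`) for the highT-vs-lowT grab contrast on the combined
   microbe + fauna table, and (when fluid samples are present)
   grab-vs-diffuse contrasts per regime. The enrichment criterion is an
   absolute effect size of at least 1; no p-values are involved.
8. **Aggregation, filtering, proportionality.** OTUs with byte-identical
   lineages are aggregated (`aggregate_by_taxonomy()`), taxa with counts
   below 2 in seven or more samples are excluded
   (`prevalence_filter()`), and the symmetric proportionality statistic

   ρ(i, j) = 1 − var(clrᵢ − clrⱼ) / (var(clrᵢ) + var(clrⱼ))

   is computed over the combined table (`rho_proportionality()`).
   Pairs with |ρ| strictly greater than 0.75 become network edges.
9. **Core-community construction.** Faunal species with |effect| ≥ 1
   seed their regime. Each microbial taxon is tiered: **strong** (≥1
   positive edge to seed fauna *and* enrichment in a qualifying
   contrast), **moderate** (positive edges to ≥2 seed fauna, no
   enrichment), **weak** (enrichment only, or exactly one faunal edge).
   Negative edges are exported but never count as membership evidence.
   The highT community is sub-clustered two ways by average-linkage
   clustering of (1 − ρ) among its seed fauna.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `t_threshold` | 25 °C | regime split on basal temperature |
| `czm_scale` | 0.65 | zero imputation as a fraction of the sample's minimum nonzero proportion |
| `rho_cutoff` | 0.75 | absolute proportionality for a network edge (strict) |
| `effect_threshold` | 1 | enrichment criterion on the MC effect size |
| `prevalence_min_count`, `prevalence_max_below` | 2, 7 | drop taxa with count < 2 in ≥ 7 samples |
| `min_domain_reads` | 100 | per-sample read floor for a domain |
| `pseudo_depth` | 1e5 | pseudo-count depth for the balanced assemblage |
| `n_mc`, `prior` | 128, 0.5 | Dirichlet Monte-Carlo instances and per-cell prior |
| `n_perm`, `n_perm_protest` | 999, 1000 | permutations (ANOSIM/envfit, protest) |

Permutation p-values use the add-one estimator
(p = (1 + #{permutations ≥ observed}) / (1 + n)), so p is never zero.
The Mann–Whitney U is reported as min(U_A, U_B), making the statistic
symmetric in group order; p-values are exact for small untied samples
and tie-corrected normal approximations otherwise.

## Design choices where the design was open

* **CZM parameterization.** The count-zero multiplicative method is used
  without a stated detection limit in the source workflow; this package
  imputes `czm_scale` × (smallest nonzero proportion in the sample),
  with 0.65 as the customary default, and shrinks nonzero parts
  multiplicatively so each sample still sums to one. Rank order among
  nonzero parts is provably preserved.
* **Joint CLR basis for ρ.** Proportionality between microbes and fauna
  requires a common log-ratio frame, so the balanced microbial
  pseudo-counts and the faunal counts enter one combined composition
  before CZM/CLR. ρ is computed on point CLR estimates, not averaged
  over Dirichlet instances.
* **Pseudo-count depth.** Count-based stages need integers but balanced
  abundances are relative; 1e5 keeps quantization error below the CZM
  imputation scale. Results are insensitive to this knob because every
  downstream statistic is scale-invariant.
* **Effect-size internals.** 128 Dirichlet instances, prior 0.5, and 36
  random pairings per instance: the published defaults of the
  Monte-Carlo effect-size estimator family this reimplements. The
  per-draw effect is (between-group difference) / (largest within-group
  difference), and the reported effect is the median over all draws.
* **ANOSIM convention.** R = (mean between-group rank − mean
  within-group rank) / (M/4), M = n(n−1)/2.
* **Dendrogram linkage.** Average (UPGMA) by default; alternatives are
  exposed. Sub-clustering of the highT fauna uses a 2-way cut of
  average-linkage clustering on (1 − ρ); the cluster containing the
  alphabetically first seed is labelled "HighT 1" so labels are
  deterministic.
* **Ties in regime assignment.** A taxon with equal evidence for both
  regimes is reported twice with an `ambiguous` flag rather than
  silently resolved.
* **Mean ρ with fauna** is averaged over the positive edges that were
  counted, not over all faunal pairs.

## The synthetic-data generator

`generate_dataset()` makes the whole pipeline verifiable with known
ground truth. Its latent model is log-normal with multinomial
observation: taxon i in sample s has latent log-abundance

    base_i + regime effect + clique signal + N(0, latent_sd)

* **Scenario dimensions.** 9 grab samples; 80/40/40 bacterial, archaeal
  and microeukaryal taxa; 17 meiofaunal and 14 macrofaunal species
  (matching the filtered faunal richness of the kind of survey this
  emulates); 2×10⁴ reads per microbial domain and 500 individuals per
  faunal size class per sample.
* **Enrichment.** `n_enriched_per_regime` (default 10) taxa per regime
  gain `regime_log_fc` (default log 8) on their regime's side of the
  threshold, allocated round-robin across size classes with fauna first
  so both regimes always have faunal seeds.
* **Cliques.** Planted cliques alternate regimes and are assembled from
  that regime's enriched fauna and microbes. The clique signal has two
  parts: a regime-aligned shared shift (`clique_regime_shift`, default
  log 6, centred across samples) and a shared Gaussian component
  (`clique_sd`, default 0.75). The regime-aligned part is what organizes
  co-occurrence clusters around the habitat split, as observed
  multi-size-class networks are; a purely regime-independent shared
  signal would instead inflate within-group dispersion and mask the very
  enrichment it accompanies.
* **Planted baselines.** Enriched and clique taxa draw their baseline
  latents from N(0.5, 0.75) rather than the heavy-tailed N(0, 1.5) used
  for the background. Core-community members are moderately abundant,
  consistently observed taxa: a planted taxon dominating its domain
  cancels its own signal through compositional closure, and one in the
  rare tail falls below the detection the procedure requires.
* **Zeros.** Sampling zeros arise from finite depth; structural zeros
  from count-dependent dropout with probability
  `zero_inflation · exp(−count / dropout_scale)` (defaults 0.05 and 25),
  so rare cells drop out near the ceiling rate while abundant cells
  essentially never do — the count-dependence mirrors technical dropout
  in amplicon libraries, while biological absence is already produced by
  the latent regime effects.
* **qPCR fractions** are Dirichlet draws centred on (0.85, 0.08, 0.07),
  echoing surveys in which bacteria dominate 16S/18S copies with archaea
  and microeukaryotes averaging a few percent.

What the generator does **not** emulate: OTU-clustering error and
chimeras, copy-number variation of rRNA genes, regime-dependent qPCR
fractions, spatial or temporal autocorrelation between samples, and
fluid (diffuse/background) sample types — the grab-vs-diffuse contrasts
therefore only run on real datasets that include fluid samples. Passing
tests consequently demonstrate that the statistical machinery recovers
planted structure under a faithful compositional count model, not that
any particular field system behaves like the model.

## Problem sizes used by the test suite

The package chooses desk-scale defaults so the whole verification runs
in minutes: effect-size calibration uses 50 null and 50 planted datasets
at 5 samples per group and 10⁴ reads per domain; end-to-end community
recovery uses 20 replicate scenarios at the generator defaults;
oracle-equivalence checks (ρ against the brute-force covariance ratio,
Aitchison against elementwise Euclidean distances) use 50 random tables
each. `scripts/acceptance.R` re-runs the same kinds of computation from
scratch and writes the resulting rates and statistics as JSON.

## Known limitations

* With around nine samples, ρ estimates carry substantial sampling
  noise; the 0.75 threshold is a screening device, not an inferential
  boundary, and the false-discovery behaviour is controlled only through
  the prevalence filter and the planted-structure calibration.
* The Dirichlet MC effect size, like the estimator family it follows,
  has a null spread of roughly ±0.5 at n = 5 per group; effects below 1
  should not be interpreted.
* qPCR balancing inherits the multi-copy bias of rRNA genes; the package
  (deliberately) does not attempt copy-number correction.
* Procrustes congruence between ordinations of strongly separated
  samples can be trivially high, because both configurations degenerate
  into two clusters; the protest permutation p guards against reading
  structure into that.
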