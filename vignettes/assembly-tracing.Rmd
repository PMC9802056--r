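---
title: "Tracing lake community assembly from paired rDNA/rRNA tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing lake community assembly from paired rDNA/rRNA tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblytrace)
```

## The model

`assemblytrace` treats a lake bacterial community as the outcome of taxa
travelling an ordered habitat continuum (river → vegetated habitat → lake)
and asks, per OTU and per sampling campaign, four questions:

1. **Where did it come from?** The source is the most upstream habitat where
   the OTU is detected in DNA. This is an operational definition: detection
   at routine sequencing depth, not true absence. The `retrace_in_reference()`
   operation exists precisely to probe how often "new" downstream taxa are
   in fact present upstream below the detection limit, using a
   deep-sequenced reference sample.
2. **Did its abundance shift?** Relative abundance in the lake is compared
   with its abundance in the source habitat; strictly more than ten-fold in
   either direction counts as shifting. Lake-origin OTUs have no upstream
   reference and are stable by definition.
3. **Where does it sit in the rank-abundance structure?** Dominant (> 1%),
   subdominant (1%–0.1%) or rare (< 0.1%) — the conventional rare-biosphere
   cut-offs.
4. **Is it reactive?** The per-OTU RNA:DNA read ratio is a proxy for
   ribosomal content. Along the continuum from source to lake: consistently
   positive → *active*; consistently zero → *inactive*; switching between
   zero and positive → *seed*. The activity threshold is 0 — any detectable
   transcript counts — deliberately conservative relative to the historical
   threshold of 1, which is known to overcount dormancy. The inference rests
   on the 0 / > 0 distinction, so uncalibrated transcript counts suffice;
   multiplying RNA counts by any positive calibration factor changes
   nothing.

Assumptions worth keeping in mind: reads are exchangeable within a sample
(multinomial sampling of an underlying composition); the DNA↔RNA pair of a
site was drawn from the same water; and a habitat's sites are replicates of
one habitat-level composition, so averaging site profiles into "one value
per habitat" is meaningful.

## Pipeline order and the sentinel rules

Raw integer tables are rarefied first (mean of repeated rarefaction), then
paired, then filtered and classified. Three rules interlock:

- **Phantom exclusion** is per campaign: an OTU with RNA but zero DNA in
  *every* sample of the campaign has no spatial abundance pattern and is
  removed. An OTU can be phantom in one campaign and valid in another.
- **Sentinels**: within a retained OTU, an individual sample pair can still
  have DNA = 0. Its undefined ratio is replaced by 100 (RNA detected) or 0
  (neither detected). Sentinels *do* enter the habitat-mean ratio — that is
  the averaging rule the classification depends on, and 100 is chosen to be
  far above any plausible real ratio so that "RNA seen somewhere" cannot be
  averaged down to zero — but the habitat mean is flagged
  (`ratio_has_sentinel`) and flagged profiles are excluded from the binned
  trend and boxplot statistics, where 100 would be an artifact, not a value.
- **Detection after mean-rarefaction** means mean count > 0: one read in one
  of the 100 repetitions counts. Rounding the mean table would silently
  delete rare OTUs, which are the object of study.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `rarefaction depth` | 10,114 | reads/sample | the study depth this package follows; also the observed minimum sample total |
| `repetitions` | 100 | draws | averages out subsampling noise; column sums stay exactly at depth by integer accumulation |
| `sentinel_rna_only` | 100 | ratio | must dominate any real ratio in a site mean |
| `dominant_threshold` | 0.01 | fraction | rare-biosphere convention, strict (`> 1%`) |
| `rare_threshold` | 0.001 | fraction | boundary values fall to the lower tier (`rare` iff `<= 0.1%`) |
| `shift_fold` | 10 | fold | strict: exactly ten-fold is stable |
| `activity_threshold` | 0 | ratio | any detectable transcript is activity |

Boundary assignment deserves emphasis: the verbal rules "> 1%" and "< 0.1%"
leave the boundary values unassigned, and this package sends ties to the
lower tier — `classify_tier(0.01)` is subdominant, `classify_tier(0.001)`
is rare — preserving the strict ">" phrasing exactly. Likewise "more than
ten-fold" is strict on both sides.

## Design choices where the design was open

- **Activity over partial continua.** The active/inactive/seed definitions
  speak of "all three environments", but OTUs recruited in the vegetated
  habitat or the lake span fewer. Decision: evaluate activity over the
  habitats from the source habitat downstream where the OTU is detected in
  DNA. A single-habitat (lake-only) OTU is therefore active or inactive,
  never seed — a seed requires an observed transition. An OTU detected in
  river and lake but not the vegetated habitat in between is judged on the
  two detected habitats and flagged `continuity_gap = TRUE`, so users can
  audit such records; the undetected habitat's ratio is a sentinel, not
  evidence.
- **Relative abundance per sample, then averaged** across a habitat's sites
  (not pooled counts). With equal rarefaction depths the two conventions
  coincide; per-sample-first keeps each site equally weighted when a sample
  is dropped.
- **Cross-campaign averages weight campaigns equally**, and SD is the sample
  (n − 1) convention — with four campaigns the choice matters and is
  asserted in tests on a hand-computed two-campaign fixture.
- **Equal-count trend bins** are assigned by rank with ties broken by OTU
  id, making the 13-bin trend deterministic.
- **Per-sample random streams.** Every rarefaction draw seeds a stream
  derived from (seed, sample id, repetition) via a string hash, so dropping
  one sample never perturbs another sample's draws, and the whole mean
  table is bit-reproducible.
- **Small-category display pooling** (< 0.1% of lake OTUs → "other")
  affects only the `display` block of the summary; full-resolution data are
  always retained. The proportion denominator is lake-detected, non-phantom
  OTUs, with the phantom count reported alongside.
- **Exact vs asymptotic rank tests**: pairwise Wilcoxon p-values switch to
  the exact distribution only when every group has fewer than 50
  observations; the choice is logged.
- **Config files are JSON**, not YAML: no YAML parser is available in the
  supported dependency set, and `jsonlite` is already required for the
  summary export. The keys mirror the function arguments.

## What the synthetic generator emulates — and what it does not

`generate_scenario()` builds a stated world: ~2,000 lake OTUs across three
source pools (river 800, vegetated 600, lake 600), four campaigns, 1/5/5
sites per habitat, and per-sample read depths drawn uniformly from
50,000–109,706 — the observed per-sample range of the study design (average
77,643), excluding its single low outlier of 10,114 which survives as the
rarefaction depth. The lake composition is assembled per tier: 1% dominant
OTUs carrying 57.5% of reads, 5% subdominant carrying 29.5%, 94% rare
carrying 13% — the reported tier read-contributions — with lognormal
within-tier spread, giving the characteristic skewed rank-abundance curve.
Activity is planted at 56% active / 28% inactive / 16% seeds (inactive OTUs
preferentially of lake origin; dominants and subdominants always active),
and 11% of upstream-origin OTUs shift, at a planted fold of 20, entirely
within the rare biosphere or the rare↔subdominant range. RNA:DNA ratios are
lognormal with higher mean and dispersion toward the rare tail, and seeds
run lower than actives. RNA expectations are DNA composition × ratio,
renormalised — read-level modelling, not per-cell ribosome mechanics,
because the pipeline consumes read tables.

Deliberate departures from real data:

- **The rare tail is truncated** at a lake relative abundance of 3 × 10⁻⁵.
  Real rare tails extend far below the detection limit; an untruncated tail
  would make planted source labels unrecoverable in principle (a taxon
  whose river abundance implies 0.2 expected reads cannot be attributed),
  and the recovery criterion would measure the tail shape, not the
  classifier. Detection-margin loss still occurs near the floor — that is
  intended — but it is bounded.
- **Composition is constant across campaigns**; campaigns differ only by
  independent multinomial draws. Seasonal drift, environmental covariates
  and transient river/vegetated taxa that never reach the lake are not
  simulated.
- **No overdispersion between sites** beyond multinomial noise.

A green planted-recovery test therefore establishes that the pipeline's
inference chain (rarefaction → pairing → phantom/sentinel handling →
profiles → four-way classification → aggregation) correctly inverts the
generative model at realistic depths and effect sizes. It does not
establish robustness to compositional overdispersion, seasonal turnover,
or rare tails below the detection floor. Truth labels are derived from the
final normalised composition and ratio matrices with the classifier's own
threshold rules, so the noiseless expected-value check
(`expected_value_tables()`) separates logic errors (would fail exactly)
from detection-margin loss (appears only with sampling noise).

## Numerical notes and degenerate inputs

- Mean-rarefied column sums equal the depth *exactly*: integer draws are
  accumulated and divided once (`sum = repetitions × depth` is exact in
  doubles far below 2⁵³).
- Proportion families (composite categories, tier contributions) are
  asserted to sum to 1 within 1e-9; diversity closed forms hold to 1e-12.
- Empty inputs refuse loudly: empty metadata cannot be paired, a habitat
  without samples cannot be profiled, an empty ratio sequence cannot be
  classified, a sample below depth names itself in the error.
- A Kruskal–Wallis statistic on all-tied copy numbers is NaN; it is
  reported as p = 1 (no evidence of difference), which is what a degenerate
  "identical distributions" input means.
- Unmatched DNA/RNA pairs are excluded with a warning rather than failing
  the run — field datasets routinely lose one member of a pair.

## Known limitations

- The RNA:DNA ratio is a reactivity proxy, not a growth rate; taxa differ
  in ribosome-per-activity scaling, and some lineages are active at low
  ribosome counts. The package's claims are confined to the 0 / > 0
  transition structure.
- The single river site makes river profiles noisier than the five-site
  habitats; no variance correction is attempted, matching the sampling
  design it emulates.
- Source attribution is detection-limited; use `retrace_in_reference()`
  with deep-sequenced references to quantify that limit on real data.
- Conditionally-rare-taxon temporal dynamics, ordination of community
  structure, and environmental-variable statistics are out of scope.
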