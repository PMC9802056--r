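# assemblytrace

Reconstructing how a lake bacterial community assembles from its upstream
sources, using paired 16S rRNA gene (DNA) and transcript (RNA, sequenced as
cDNA) amplicon OTU tables.

## The problem

Freshwater lakes fed by a single inflow receive their microbes through a
well-defined habitat continuum — here a river that crosses a
macrophyte-dominated vegetated habitat before reaching open water. A
snapshot of the lake community alone cannot distinguish taxa that are
selected and growing from taxa that are merely washed in (mass effects), nor
dormant seed-bank members from dead or maladapted cells. Tracing each OTU
*upstream* — where it was first detected, how its relative abundance changed
in transit, and whether its ribosomal activity switched on or off — makes
these mechanisms separable.

`assemblytrace` operationalises that reconstruction for anyone with paired
DNA/RNA OTU count tables from an ordered habitat chain sampled over repeated
campaigns.

## The method

For each campaign, after equalising sequencing effort by repeated
rarefaction (mean of 100 random subsamples without replacement at a common
depth, 10,114 reads by default):

- **RNA:DNA ratio** per OTU and sample pair: `r = n_RNA / n_DNA`. When
  `n_DNA = 0` the ratio is undefined and a sentinel stands in: 100 if RNA
  was detected (DNA missed), 0 if neither molecule was seen. OTUs with RNA
  but *never* DNA in a campaign ("phantom taxa") are excluded.
- **Habitat profiles**: per-sample relative abundance and ratio are averaged
  over a habitat's sites, giving one value per OTU per habitat.
- **Source**: the most upstream habitat (river → vegetated → lake) where the
  OTU is detected in DNA.
- **Tier** in the lake: dominant (> 1% relative abundance), subdominant
  (1%–0.1%), rare (< 0.1%).
- **Shift**: lake abundance differing from the source-habitat abundance by
  strictly more than ten-fold, in either direction.
- **Activity**: along the continuum from source to lake, ratio > 0
  everywhere → *active*; ratio = 0 everywhere → *inactive*; a mix →
  *seed* (the taxon activated or inactivated in transit).

Category proportions are averaged across campaigns (mean ± sample SD), with
per-tier read contributions, abundance-binned ratio trends (13 equal-count
bins, sentinels excluded), rrnDB-style 16S copy-number contrasts
(Kruskal–Wallis + pairwise Wilcoxon, Bonferroni), alpha diversity, and a
flow-cytometry absolute-abundance cross-check of the shift rule.

A first-class synthetic generator (`generate_scenario()`) builds paired
DNA/RNA tables over the three-habitat, four-campaign design with planted,
recoverable truth for every label family — the package's own test bed.

## Worked example

```r
library(assemblytrace)
sc  <- generate_scenario(scenario_config(seed = 1))
run <- run_pipeline(sc$dna, sc$rna, sc$info,
                    rarefaction_config(depth = 10114, repetitions = 100, seed = 1))
print(run)
```

```
<assembly_summary> 4 campaign(s): lateJuly, midJuly, October, September
Marginal composition (mean +/- sd across campaigns, % of lake OTUs):
 shift: shifting 7.4% +/- 0.1; stable 92.6% +/- 0.1
 tier: dominant 1.0% +/- 0.0; rare 94.0% +/- 0.0; subdominant 5.0% +/- 0.0
 activity: active 56.0% +/- 0.1; inactive 28.1% +/- 0.1; seed 15.9% +/- 0.1
 source: lake 30.0% +/- 0.0; river 38.4% +/- 0.6; vegetated 31.6% +/- 0.6
phantom taxa excluded: lateJuly=0, midJuly=0, October=0, September=0
```

Most lake OTUs are stable and rare; activity splits into roughly 56% active,
28% inactive and 16% seeds — the proportions this scenario planted. Checking
recovery against the generator's truth:

```r
tc <- truth_confusion(run$classifications, sc$truth)
sapply(tc[c("source", "tier", "shift", "activity")], function(f) f$accuracy)
#>   source     tier    shift activity
#>    0.984    1.000    0.996    0.997

round(run$tier_contribution$mean, 3)
#>    dominant subdominant        rare
#>       0.546       0.280       0.173
```

The 1% of dominant OTUs carry ~55% of the community's reads; the rare tail
(94% of OTUs) carries ~17%. The binned trend (`run$trend`) shows the mean
RNA:DNA ratio falling as abundance rises — rare taxa run hotter:

```
  bin   n   mean_abund mean_ratio  se_ratio
1   1 482 2.413769e-05   2.808385 0.1703901
2   2 482 3.178044e-05   2.264107 0.1278665
3   3 482 3.758358e-05   2.167546 0.1487655
4   4 482 4.355370e-05   2.095924 0.1167605
```

Real data enter through `read_count_table()`, `read_sample_info()` (TSV;
see `?read_sample_info` for the schema) and flow into the same
`run_pipeline()` call; `write_run()` exports all derived tables as TSV plus
a JSON summary.

A command-line wrapper is installed under `exec/`:

```sh
assemblytrace simulate --seed 5 --out sim/
assemblytrace run --dna sim/dna.tsv --rna sim/rna.tsv --meta sim/meta.tsv \
    --depth 10114 --repetitions 100 --seed 2 --out out/
```

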