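# Shared builders and the independent classifier oracle.

cmat <- function(values, otus = NULL, samples = NULL) {
  m <- matrix(values, nrow = length(otus) %||% nrow(values))
  if (is.null(otus)) otus <- paste0("OTU_", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(otus, samples)
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# One-campaign metadata: 1 river, n_veg vegetated, n_lake lake sites,
# DNA + RNA columns named <pair>_DNA / <pair>_RNA.
toy_info <- function(campaign = "c1", n_veg = 5, n_lake = 5) {
  rows <- list()
  add <- function(h, s) {
    pair <- paste(campaign, h, s, sep = "_")
    for (mol in c("DNA", "RNA"))
      rows[[paste(pair, mol)]] <<- data.frame(
        sample_id = paste(pair, mol, sep = "_"), habitat = h,
        campaign = campaign, site_index = s, pair_id = pair, molecule = mol)
  }
  add("river", 1)
  for (s in seq_len(n_veg)) add("vegetated", s)
  for (s in seq_len(n_lake)) add("lake", s)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Build a paired view directly from per-habitat DNA/RNA matrices
# (single campaign). `dna`/`rna` are lists keyed by habitat.
toy_paired <- function(dna, rna, campaign = "c1") {
  habitats <- habitat_levels()
  pairs <- do.call(rbind, lapply(habitats, function(h) {
    n <- ncol(dna[[h]])
    data.frame(pair_id = paste(campaign, h, seq_len(n), sep = "_"),
               campaign = campaign,
               habitat = factor(h, habitats, ordered = TRUE),
               site_index = seq_len(n),
               dna_sample = paste(campaign, h, seq_len(n), "DNA", sep = "_"),
               rna_sample = paste(campaign, h, seq_len(n), "RNA", sep = "_"))
  }))
  d <- do.call(cbind, dna[habitats]); colnames(d) <- pairs$pair_id
  r <- do.call(cbind, rna[habitats]); colnames(r) <- pairs$pair_id
  structure(list(dna = d, rna = r, pairs = pairs, habitats = habitats),
            class = "paired_tables")
}

# Single-OTU profile frame across the three habitats.
toy_profiles <- function(abund, ratio, otu = "OTU_X", campaign = "c1") {
  data.frame(otu_id = otu, campaign = campaign,
             habitat = habitat_levels(),
             mean_rel_abund = abund, mean_ratio = ratio,
             detected_dna = abund > 0,
             ratio_has_sentinel = FALSE, n_sites = 1)
}

# Independent straight-line transcription of the four textual rules for a
# single OTU; deliberately naive, no shared code with the package logic.
# det/ab/ratio are length-3 vectors ordered river, vegetated, lake.
oracle_classify <- function(det, ab, ratio) {
  if (!det[3]) return(NULL)                       # not a lake OTU
  src <- if (det[1]) 1 else if (det[2]) 2 else 3
  tier_of <- function(x) {
    if (x > 0.01) "dominant" else if (x > 0.001) "subdominant" else "rare"
  }
  shift <- if (src == 3) "stable" else {
    f <- ab[3] / ab[src]
    if (f > 10 || f < 1 / 10) "shifting" else "stable"
  }
  rs <- ratio[src:3][det[src:3]]                  # detected habitats only
  act <- if (all(rs > 0)) "active" else if (all(rs == 0)) "inactive" else "seed"
  list(source = c("river", "vegetated", "lake")[src],
       tier = tier_of(ab[3]), shift = shift, activity = act)
}

# A deliberately small but fully featured scenario for fast tests.
small_scenario_config <- function(seed = 42, ...) {
  scenario_config(
    n_river = 240, n_vegetated = 120, n_lake = 120,
    tier_fractions = c(dominant = 0.02, subdominant = 0.05, rare = 0.93),
    tier_mass = c(dominant = 0.5, subdominant = 0.2, rare = 0.3),
    rank_sdlog = c(dominant = 0.2, subdominant = 0.2, rare = 0.6),
    rare_band = c(2e-4, 9e-4),
    campaigns = c("c1", "c2"),
    depth_range = c(30000L, 60000L),
    seed = seed, ...)
}
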