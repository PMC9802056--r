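#' Run the full assembly-tracing pipeline
#'
#' Rarefies the raw DNA and RNA tables (mean of repeated rarefactions),
#' aligns them into pair columns, then per campaign: excludes phantom taxa,
#' computes per-habitat OTU profiles (mean relative abundance and RNA:DNA
#' ratio), and classifies every lake-detected OTU by source, tier, shift
#' and activity. Finally aggregates across campaigns.
#'
#' @param dna,rna Raw [count_table()] objects.
#' @param info Sample metadata (see [read_sample_info()]).
#' @param rare_cfg A [rarefaction_config()]; applied to both molecules
#'   (set `rare_cfg_rna` to rarefy RNA differently).
#' @param ratio_cfg A [ratio_config()].
#' @param tier_cfg A [tier_config()].
#' @param rare_cfg_rna Optional separate config for the RNA table.
#' @param habitats Ordered habitat chain.
#' @return List of class `assembly_run`: `profiles` (all campaigns, all
#'   habitats), `classifications`, `summary`, `tier_contribution`,
#'   `phantoms` (per campaign), `trend` (lake ratio-abundance bins, when
#'   enough OTUs), and the configs used.
#' @export
run_pipeline <- function(dna, rna, info,
                         rare_cfg = rarefaction_config(),
                         ratio_cfg = ratio_config(),
                         tier_cfg = tier_config(),
                         rare_cfg_rna = rare_cfg,
                         habitats = habitat_levels()) {
  message(sprintf("rarefaction: depth=%s, repetitions=%d, seed=%d",
                  rare_cfg$depth %||% "min column sum",
                  rare_cfg$repetitions, rare_cfg$seed))
  message(sprintf("thresholds: dominant>%g, rare<=%g, shift fold>%g, activity>%g",
                  tier_cfg$dominant_threshold, tier_cfg$rare_threshold,
                  tier_cfg$shift_fold, tier_cfg$activity_threshold))
  dna_m <- rarefy_mean(dna, rare_cfg)
  rna_m <- rarefy_mean(rna, rare_cfg_rna)
  paired <- align_pairs(dna_m, rna_m, info, habitats)
  campaigns <- unique(paired$pairs$campaign)

  profiles <- list(); classifications <- list(); phantoms <- list()
  for (cp in campaigns) {
    sub <- subset_campaign(paired, cp)
    ph <- exclude_phantoms(sub)
    phantoms[[cp]] <- ph$phantoms
    prof <- campaign_profiles(ph$paired, ratio_cfg, habitats)
    profiles[[cp]] <- prof
    classifications[[cp]] <- classify_campaign(prof, tier_cfg, habitats)
  }
  profiles <- do.call(rbind, profiles)
  cls <- do.call(rbind, classifications)
  rownames(profiles) <- rownames(cls) <- NULL

  lake <- habitats[length(habitats)]
  lake_prof <- profiles[profiles$habitat == lake, , drop = FALSE]
  trend <- tryCatch(trend_statistics(lake_prof, 13L, ratio_cfg),
                    error = function(e) NULL)
  structure(list(profiles = profiles,
                 classifications = cls,
                 summary = summarize_assembly(cls),
                 tier_contribution = tier_read_contribution(lake_prof, cls),
                 phantoms = phantoms,
                 trend = trend,
                 rarefied = list(dna = dna_m, rna = rna_m),
                 configs = list(rarefaction = rare_cfg, ratio = ratio_cfg,
                                tier = tier_cfg)),
            class = "assembly_run")
}

#' @export
print.assembly_run <- function(x, ...) {
  cat("<assembly_run>\n")
  print(x$summary)
  cat(sprintf("phantom taxa excluded: %s\n",
              paste(sprintf("%s=%d", names(x$phantoms),
                            lengths(x$phantoms)), collapse = ", ")))
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Emits `profiles.tsv`, `classifications.tsv`, `trend.tsv` (if computed),
#' `summary.json` and `phantoms.tsv`.
#'
#' @param run An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(run$profiles, "profiles.tsv")
  tsv(run$classifications, "classifications.tsv")
  if (!is.null(run$trend)) tsv(run$trend, "trend.tsv")
  ph <- data.frame(campaign = rep(names(run$phantoms),
                                  lengths(run$phantoms)),
                   otu_id = unlist(run$phantoms, use.names = FALSE))
  tsv(ph, "phantoms.tsv")
  write_summary_json(run$summary, file.path(dir, "summary.json"),
                     tiers = run$tier_contribution)
  invisible(dir)
}

#' Write a synthetic scenario to a directory
#'
#' Emits `dna.tsv`, `rna.tsv`, `meta.tsv` and `truth.tsv`.
#'
#' @param scenario A [generate_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(scenario$dna, file.path(dir, "dna.tsv"))
  write_count_table(scenario$rna, file.path(dir, "rna.tsv"))
  write_sample_info(scenario$info, file.path(dir, "meta.tsv"))
  utils::write.table(scenario$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
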