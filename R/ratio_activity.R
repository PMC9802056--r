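#' RNA:DNA ratio configuration
#'
#' Sentinel values stand in for undefined ratios: an OTU detected in RNA but
#' not in DNA in a given sample gets `sentinel_rna_only` (100); one absent
#' from both gets `sentinel_absent` (0). Sentinels enter habitat averages
#' (flagged), but are dropped from trend and boxplot statistics because they
#' record the absence of a value, not a value.
#'
#' @param sentinel_rna_only Ratio assigned when DNA = 0 and RNA > 0
#'   (default 100; must exceed any plausible real ratio).
#' @param sentinel_absent Ratio assigned when DNA = 0 and RNA = 0 (default 0).
#' @param exclude_sentinels_from_trend Logical (default `TRUE`).
#' @return A list of class `ratio_config`.
#' @export
ratio_config <- function(sentinel_rna_only = 100, sentinel_absent = 0,
                         exclude_sentinels_from_trend = TRUE) {
  if (sentinel_rna_only <= 1)
    stop("sentinel_rna_only must exceed plausible real ratios")
  structure(list(sentinel_rna_only = sentinel_rna_only,
                 sentinel_absent = sentinel_absent,
                 exclude_sentinels_from_trend = exclude_sentinels_from_trend),
            class = "ratio_config")
}

#' Exclude phantom taxa from a campaign's paired tables
#'
#' A phantom taxon is detected in RNA somewhere in the campaign while its
#' DNA count is zero in every sample of the campaign; no spatial pattern can
#' be inferred for it and it is removed. OTUs absent from both tables
#' everywhere are dropped at the same time.
#'
#' @param paired A `paired_tables` view restricted to one campaign
#'   (see [subset_campaign()]).
#' @return List with `paired` (the filtered view), `phantoms` (excluded
#'   RNA-only OTU ids) and `absent` (ids absent from both tables).
#' @export
exclude_phantoms <- function(paired) {
  stopifnot(inherits(paired, "paired_tables"))
  if (length(unique(paired$pairs$campaign)) > 1)
    stop("phantom exclusion is per campaign; subset first")
  dna_any <- rowSums(paired$dna) > 0
  rna_any <- rowSums(paired$rna) > 0
  phantoms <- rownames(paired$dna)[!dna_any & rna_any]
  absent <- rownames(paired$dna)[!dna_any & !rna_any]
  keep <- dna_any
  out <- structure(list(dna = paired$dna[keep, , drop = FALSE],
                        rna = paired$rna[keep, , drop = FALSE],
                        pairs = paired$pairs, habitats = paired$habitats),
                   class = "paired_tables")
  list(paired = out, phantoms = phantoms, absent = absent)
}

#' Per-sample RNA:DNA ratio with sentinel semantics
#'
#' cDNA reads divided by DNA reads when DNA is detected; otherwise the
#' configured sentinel (100 when RNA alone is detected, 0 when neither is).
#' Vectorised over both count arguments.
#'
#' @param dna_count,rna_count Non-negative counts (post-rarefaction reals
#'   are fine).
#' @param cfg A [ratio_config()].
#' @return Numeric vector of ratios.
#' @examples
#' sample_ratio(10, 5)    # 0.5
#' sample_ratio(0, 3)     # sentinel 100
#' sample_ratio(0, 0)     # sentinel 0
#' @export
sample_ratio <- function(dna_count, rna_count, cfg = ratio_config()) {
  if (any(dna_count < 0) || any(rna_count < 0))
    stop("counts must be non-negative")
  ifelse(dna_count > 0, rna_count / dna_count,
         ifelse(rna_count > 0, cfg$sentinel_rna_only, cfg$sentinel_absent))
}

#' Per-OTU habitat profile for one campaign and habitat
#'
#' Averages over the habitat's sites: per-sample DNA relative abundance
#' (count over column sum) and per-sample RNA:DNA ratio, yielding one value
#' per OTU per habitat. Sentinel ratios are included in the mean, as the
#' averaging rule requires, and flagged via `ratio_has_sentinel`.
#'
#' @param paired A phantom-filtered `paired_tables` view for one campaign.
#' @param habitat Habitat label present in the view.
#' @param cfg A [ratio_config()].
#' @return Data frame: `otu_id`, `campaign`, `habitat`, `mean_rel_abund`,
#'   `mean_ratio`, `detected_dna`, `ratio_has_sentinel`, `n_sites`.
#' @export
habitat_profile <- function(paired, habitat, cfg = ratio_config()) {
  stopifnot(inherits(paired, "paired_tables"))
  campaign <- unique(paired$pairs$campaign)
  if (length(campaign) > 1) stop("profiles are per campaign; subset first")
  sel <- paired$pairs$habitat == habitat
  if (!any(sel)) stop("no sample pairs for habitat '", habitat, "'")
  d <- paired$dna[, sel, drop = FALSE]
  r <- paired$rna[, sel, drop = FALSE]
  cs <- colSums(d)
  if (any(cs <= 0)) stop("DNA column with zero total in habitat '", habitat, "'")
  rel <- sweep(d, 2, cs, "/")
  ratios <- matrix(sample_ratio(as.vector(d), as.vector(r), cfg),
                   nrow = nrow(d), dimnames = dimnames(d))
  sentinel <- d == 0            # both sentinel kinds arise from DNA = 0
  data.frame(otu_id = rownames(d),
             campaign = campaign,
             habitat = habitat,
             mean_rel_abund = rowMeans(rel),
             mean_ratio = rowMeans(ratios),
             detected_dna = rowMeans(rel) > 0,
             ratio_has_sentinel = rowSums(sentinel) > 0,
             n_sites = sum(sel),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Habitat profiles for every habitat of one campaign
#'
#' @inheritParams habitat_profile
#' @param habitats Habitat chain to profile (default: all habitats present).
#' @return Row-bound [habitat_profile()] frames, one block per habitat.
#' @export
campaign_profiles <- function(paired, cfg = ratio_config(),
                              habitats = NULL) {
  if (is.null(habitats))
    habitats <- intersect(paired$habitats,
                          as.character(unique(paired$pairs$habitat)))
  do.call(rbind, lapply(habitats, function(h) habitat_profile(paired, h, cfg)))
}

#' Abundance-binned RNA:DNA ratio trend
#'
#' Orders lake OTU profiles by relative abundance, cuts them into
#' `n_bins` equal-count bins (ties broken by OTU id for determinism) and
#' returns per-bin means and standard errors of the ratio - the summary
#' behind the ratio-versus-abundance scatter trend. Sentinel-bearing
#' profiles are removed first when the config says so.
#'
#' @param profiles Lake habitat profiles (possibly several campaigns,
#'   row-bound); only rows with `detected_dna` are used.
#' @param n_bins Number of equal-count bins (the reference analysis uses 13).
#' @param cfg A [ratio_config()].
#' @return Data frame: `bin`, `n`, `mean_abund`, `mean_ratio`, `se_ratio`.
#' @export
trend_statistics <- function(profiles, n_bins = 13L, cfg = ratio_config()) {
  p <- profiles[profiles$detected_dna, , drop = FALSE]
  if (isTRUE(cfg$exclude_sentinels_from_trend))
    p <- p[!p$ratio_has_sentinel, , drop = FALSE]
  n <- nrow(p)
  if (n < n_bins)
    stop("fewer OTU profiles (", n, ") than bins (", n_bins, ")")
  ord <- order(p$mean_rel_abund, p$otu_id, if (!is.null(p$campaign)) p$campaign)
  p <- p[ord, , drop = FALSE]
  bin <- ceiling(seq_len(n) * n_bins / n)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  data.frame(bin = seq_len(n_bins),
             n = as.vector(table(factor(bin, levels = seq_len(n_bins)))),
             mean_abund = as.vector(tapply(p$mean_rel_abund, bin, mean)),
             mean_ratio = as.vector(tapply(p$mean_ratio, bin, mean)),
             se_ratio = as.vector(tapply(p$mean_ratio, bin, se)),
             row.names = NULL)
}
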