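#' Tier / shift / activity thresholds
#'
#' Dominance tiers follow the rare-biosphere convention: dominant above 1%
#' relative abundance, rare at or below 0.1%, subdominant between. The
#' thresholds are strict on the dominant side (`> 1%`), and boundary values
#' fall to the lower tier. A lake OTU whose lake abundance differs from its
#' source-habitat abundance by strictly more than `shift_fold` (10) in
#' either direction is "shifting". Activity uses a conservative threshold
#' of 0 on the RNA:DNA ratio: any detectable transcript counts as activity.
#'
#' @param dominant_threshold Fraction above which an OTU is dominant
#'   (default 0.01).
#' @param rare_threshold Fraction at or below which an OTU is rare
#'   (default 0.001).
#' @param shift_fold Fold change beyond which abundance has shifted
#'   (default 10, strict).
#' @param activity_threshold Ratio above which an OTU counts as active in a
#'   habitat (default 0; the historical threshold of 1 overcounts dormancy).
#' @return A list of class `tier_config`.
#' @export
tier_config <- function(dominant_threshold = 0.01, rare_threshold = 0.001,
                        shift_fold = 10, activity_threshold = 0) {
  if (!(rare_threshold > 0 && rare_threshold < dominant_threshold &&
        dominant_threshold < 1))
    stop("need 0 < rare_threshold < dominant_threshold < 1")
  if (shift_fold <= 1) stop("shift_fold must exceed 1")
  if (activity_threshold < 0) stop("activity_threshold must be >= 0")
  structure(list(dominant_threshold = dominant_threshold,
                 rare_threshold = rare_threshold,
                 shift_fold = shift_fold,
                 activity_threshold = activity_threshold),
            class = "tier_config")
}

#' Source habitat: most upstream detection
#'
#' Scans the habitat chain from upstream down and returns the first habitat
#' where the OTU is detected in DNA.
#'
#' @param detected Logical vector of DNA detection flags, one per habitat,
#'   named or ordered along the continuum (upstream first).
#' @param habitats Habitat chain matching `detected`.
#' @return The source habitat label.
#' @export
attribute_source <- function(detected, habitats = habitat_levels()) {
  if (length(detected) != length(habitats))
    stop("one detection flag per habitat required")
  if (!detected[length(detected)])
    stop("OTU not detected in the terminal (lake) habitat: not part of the lake community")
  habitats[which(detected)[1]]
}

#' Dominance tier of a relative abundance
#'
#' @param rel_abund Fraction(s) in `[0, 1]`.
#' @param cfg A [tier_config()].
#' @return Character vector: `"dominant"`, `"subdominant"` or `"rare"`.
#' @examples
#' classify_tier(c(0.02, 0.005, 0.001))
#' @export
classify_tier <- function(rel_abund, cfg = tier_config()) {
  if (any(rel_abund < 0 | rel_abund > 1)) stop("relative abundance outside [0, 1]")
  ifelse(rel_abund > cfg$dominant_threshold, "dominant",
         ifelse(rel_abund > cfg$rare_threshold, "subdominant", "rare"))
}

#' Ten-fold abundance shift between source and lake
#'
#' Strictly more than `shift_fold` up or down counts as shifting; exactly
#' ten-fold is stable.
#'
#' @param source_abund,lake_abund Positive fractions (the source habitat is
#'   by construction a habitat of detection).
#' @param cfg A [tier_config()].
#' @return `"shifting"` or `"stable"` (vectorised).
#' @export
classify_shift <- function(source_abund, lake_abund, cfg = tier_config()) {
  if (any(source_abund <= 0) || any(lake_abund <= 0))
    stop("shift classification needs positive abundances on both ends")
  fold <- lake_abund / source_abund
  ifelse(fold > cfg$shift_fold | fold < 1 / cfg$shift_fold,
         "shifting", "stable")
}

#' Activity state along the continuum
#'
#' Takes the habitat-mean RNA:DNA ratios from the OTU's source habitat down
#' to the lake (habitats upstream of first detection carry no information)
#' and calls the OTU `active` when every ratio exceeds the activity
#' threshold, `inactive` when none does, and `seed` when the sequence mixes
#' detectable and undetectable transcript - the signature of a taxon able to
#' activate or inactivate along the flow path. The RNA-only sentinel (100)
#' is by construction above the threshold, i.e. detectable RNA counts as
#' activity. A single-habitat OTU can be active or inactive, never seed: a
#' seed requires an observed transition.
#'
#' @param ratios Numeric vector of habitat-mean ratios, ordered upstream to
#'   downstream, restricted to habitats from the source onward (detected
#'   habitats only).
#' @param cfg A [tier_config()].
#' @return `"active"`, `"inactive"` or `"seed"`.
#' @examples
#' classify_activity(c(0.3, 0.1, 0.5))  # active
#' classify_activity(c(0, 0, 0))        # inactive
#' classify_activity(c(0, 0.4, 0.2))    # seed
#' @export
classify_activity <- function(ratios, cfg = tier_config()) {
  if (!length(ratios)) stop("empty ratio sequence")
  pos <- ratios > cfg$activity_threshold
  if (all(pos)) "active" else if (!any(pos)) "inactive" else "seed"
}

#' Classify every lake OTU of one campaign
#'
#' Combines the four sub-classifications - source habitat, lake dominance
#' tier, ten-fold shift, activity state - into one record per lake-detected
#' OTU. Input profiles must cover every habitat of the chain and have
#' phantoms excluded. Activity is evaluated over the habitats from the
#' source habitat downstream where the OTU is detected in DNA; an OTU absent
#' from an intermediate habitat is flagged `continuity_gap`.
#'
#' @param profiles Campaign profiles from [campaign_profiles()], one block
#'   per habitat of the chain.
#' @param cfg A [tier_config()].
#' @param habitats Ordered habitat chain (upstream first, terminal habitat
#'   last); the terminal habitat is the community being classified.
#' @return Data frame with one row per lake-detected OTU: `otu_id`,
#'   `campaign`, `source`, `tier`, `source_tier`, `shift`, `activity`,
#'   `lake_rel_abund`, `lake_ratio`, `source_rel_abund`, `continuity_gap`.
#' @export
classify_campaign <- function(profiles, cfg = tier_config(),
                              habitats = habitat_levels()) {
  miss <- setdiff(habitats, unique(profiles$habitat))
  if (length(miss))
    stop("profiles missing habitat(s): ", paste(miss, collapse = ", "))
  campaign <- unique(profiles$campaign)
  if (length(campaign) != 1) stop("classification is per campaign")
  lake <- habitats[length(habitats)]

  otus <- sort(unique(profiles$otu_id))
  grab <- function(col) {
    m <- matrix(NA_real_, length(otus), length(habitats),
                dimnames = list(otus, habitats))
    for (h in habitats) {
      ph <- profiles[profiles$habitat == h, , drop = FALSE]
      m[match(ph$otu_id, otus), h] <- ph[[col]]
    }
    if (anyNA(m)) stop("profiles incomplete: every OTU needs a row per habitat")
    m
  }
  abund <- grab("mean_rel_abund")
  ratio <- grab("mean_ratio")
  det <- abund > 0

  in_lake <- det[, lake]
  otus <- otus[in_lake]
  abund <- abund[in_lake, , drop = FALSE]
  ratio <- ratio[in_lake, , drop = FALSE]
  det <- det[in_lake, , drop = FALSE]
  if (!length(otus)) stop("no lake-detected OTUs to classify")

  src_idx <- apply(det, 1, function(d) which(d)[1])
  source <- habitats[src_idx]
  lake_ab <- abund[, lake]
  src_ab <- abund[cbind(seq_along(otus), src_idx)]

  res <- data.frame(otu_id = otus, campaign = campaign,
                    source = source,
                    tier = classify_tier(lake_ab, cfg),
                    source_tier = classify_tier(src_ab, cfg),
                    shift = ifelse(source == lake, "stable",
                                   classify_shift(pmax(src_ab, 0), lake_ab, cfg)),
                    activity = NA_character_,
                    lake_rel_abund = lake_ab,
                    lake_ratio = ratio[, lake],
                    source_rel_abund = src_ab,
                    continuity_gap = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_along(otus)) {
    span <- src_idx[i]:length(habitats)
    here <- span[det[i, span]]
    res$activity[i] <- classify_activity(ratio[i, here], cfg)
    res$continuity_gap[i] <- any(!det[i, span])
  }
  res
}

#' Retrace an OTU set in a deep-sequenced reference sample
#'
#' Fraction of the given OTU identifiers with a positive count in a
#' (typically deep-sequenced, single-sample) reference table - used to test
#' whether taxa first detected downstream were in fact present upstream
#' below the routine detection limit.
#'
#' @param otu_set Character vector of OTU ids (non-empty).
#' @param reference A [count_table()] (single sample, or counts summed over
#'   columns).
#' @return Fraction in `[0, 1]` of `otu_set` detected in the reference.
#' @export
retrace_in_reference <- function(otu_set, reference) {
  if (!length(otu_set)) stop("empty OTU set")
  stopifnot(inherits(reference, "count_table"))
  present <- rownames(reference)[rowSums(reference) > 0]
  mean(otu_set %in% present)
}
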