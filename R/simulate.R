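#' Synthetic scenario configuration
#'
#' Describes a three-habitat, multi-campaign paired DNA/RNA world with
#' planted ground truth. Defaults emulate the boreal-lake study design this
#' package follows: one river site, five vegetated and five lake sites,
#' four campaigns, ~2,000 lake OTUs with a highly skewed rank-abundance
#' distribution (about 1% dominants carrying ~57.5% of reads, 5%
#' subdominants carrying ~29.5%, a long rare tail carrying ~13%), roughly
#' 56% active / 28% inactive / 16% seed OTUs, 11% of upstream-origin OTUs
#' shifting more than ten-fold, and read depths spanning the study's
#' 10,114-109,706 range. RNA:DNA ratios rise and disperse toward the rare
#' tail.
#'
#' @param n_river,n_vegetated,n_lake OTUs recruited first in each habitat.
#' @param tier_fractions Named fractions of lake OTUs per tier
#'   (dominant/subdominant/rare), summing to 1.
#' @param tier_mass Named read-mass fractions per tier, summing to 1.
#' @param rank_sdlog Named lognormal sdlog of within-tier abundance spread.
#' @param activity_fractions Named fractions (active/inactive/seed),
#'   summing to 1.
#' @param shifting_fraction Fraction of upstream-origin lake OTUs planted as
#'   shifting.
#' @param shift_fold Planted fold change for shifting OTUs (default 20,
#'   comfortably past the ten-fold rule yet estimable from single-site
#'   source habitats).
#' @param rare_band Lake relative-abundance band for the rare tail; the
#'   floor sits near the single-sample detection limit so planted labels
#'   stay recoverable (real rare tails extend further down; see vignette).
#' @param ratio_meanlog,ratio_sdlog Named per-tier lognormal parameters of
#'   the RNA:DNA ratio for active OTUs.
#' @param seed_ratio_meanlog meanlog of the ratio in a seed OTU's active
#'   habitats (seeds run lower than actives).
#' @param ratio_jitter_sdlog Per-habitat lognormal jitter on an OTU's ratio.
#' @param depth_range Integer range of per-sample read depths.
#' @param sites Named integer vector of sites per habitat.
#' @param campaigns Campaign labels.
#' @param seed Integer master seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_river = 800L, n_vegetated = 600L, n_lake = 600L,
                            tier_fractions = c(dominant = 0.01,
                                               subdominant = 0.05,
                                               rare = 0.94),
                            tier_mass = c(dominant = 0.575,
                                          subdominant = 0.295,
                                          rare = 0.13),
                            rank_sdlog = c(dominant = 0.3,
                                           subdominant = 0.3,
                                           rare = 0.8),
                            activity_fractions = c(active = 0.56,
                                                   inactive = 0.28,
                                                   seed = 0.16),
                            shifting_fraction = 0.11,
                            shift_fold = 20,
                            rare_band = c(3e-5, 9e-4),
                            ratio_meanlog = c(dominant = log(0.4),
                                              subdominant = log(0.8),
                                              rare = log(1.6)),
                            ratio_sdlog = c(dominant = 0.3,
                                            subdominant = 0.45,
                                            rare = 0.6),
                            seed_ratio_meanlog = log(0.8),
                            ratio_jitter_sdlog = 0.2,
                            depth_range = c(50000L, 109706L),
                            sites = c(river = 1L, vegetated = 5L, lake = 5L),
                            campaigns = c("midJuly", "lateJuly",
                                          "September", "October"),
                            seed = 1L) {
  stopifnot(abs(sum(tier_fractions) - 1) < 1e-9,
            abs(sum(tier_mass) - 1) < 1e-9,
            abs(sum(activity_fractions) - 1) < 1e-9,
            shifting_fraction >= 0, shifting_fraction < 1,
            shift_fold > 1, all(depth_range >= 1),
            length(sites) == 3, all(sites >= 1))
  n_total <- n_river + n_vegetated + n_lake
  if (round(tier_fractions[["dominant"]] * n_total) < 1)
    stop("infeasible plant: dominant fraction x OTU count < 1")
  if (round((tier_fractions[["dominant"]] + tier_fractions[["subdominant"]]) *
            n_total) > n_river)
    stop("river pool too small to host all dominant and subdominant OTUs")
  structure(as.list(environment()), class = "scenario_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw within-tier abundance values summing to `mass`, clamped to stay
# strictly inside the tier's band after whole-community normalisation.
tier_abundances <- function(n, mass, sdlog, lo, hi) {
  w <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
  clamp(w / sum(w) * mass, lo, hi)
}

#' Generate a synthetic paired-table scenario with planted truth
#'
#' Builds true per-habitat composition and RNA:DNA ratio matrices from the
#' scenario configuration, then draws raw DNA and RNA read tables
#' multinomially per sample. River-pool OTUs are present from the river
#' onward, vegetated-pool OTUs from the vegetated habitat onward, and
#' lake-pool OTUs in the lake only. Shifting OTUs carry the configured fold
#' change between their source habitat and the lake (with a geometric-mean
#' intermediate for river-origin OTUs); inactive OTUs have zero RNA
#' expectation everywhere; seeds have zero expectation in a proper nonempty
#' subset of their habitats. The underlying composition is held fixed
#' across campaigns: campaigns differ by independent read sampling only.
#' Truth labels are derived from the final normalised compositions and
#' ratio matrices with exactly the classifier's rules, so noiseless tables
#' recover them identically. DNA and RNA seeds are derived independently
#' from the master seed.
#'
#' @param cfg A [scenario_config()].
#' @return List of class `scenario`: `dna`, `rna` (raw [count_table()]s),
#'   `info` (sample metadata with molecule column), `truth` (one row per
#'   OTU per campaign: source, tier, shift, activity, per-habitat true
#'   abundance and ratio), `composition` and `ratios` (OTU x habitat
#'   matrices), and `config`.
#' @export
generate_scenario <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  habitats <- habitat_levels()
  n_total <- cfg$n_river + cfg$n_vegetated + cfg$n_lake
  otus <- sprintf("OTU_%04d", seq_len(n_total))
  pool <- rep(habitats, times = c(cfg$n_river, cfg$n_vegetated, cfg$n_lake))

  set.seed(sample_seed(cfg$seed, "scenario-structure"))

  ## --- tiers: dominants and subdominants live in the river pool ---------
  n_dom <- max(1L, round(cfg$tier_fractions[["dominant"]] * n_total))
  n_sub <- round(cfg$tier_fractions[["subdominant"]] * n_total)
  river_idx <- which(pool == "river")
  dom_idx <- sample(river_idx, n_dom)
  sub_idx <- sample(setdiff(river_idx, dom_idx), n_sub)
  tier <- rep("rare", n_total)
  tier[dom_idx] <- "dominant"
  tier[sub_idx] <- "subdominant"

  lake_comp <- numeric(n_total)
  lake_comp[dom_idx] <- tier_abundances(n_dom, cfg$tier_mass[["dominant"]],
                                        cfg$rank_sdlog[["dominant"]],
                                        0.012, 0.2)
  lake_comp[sub_idx] <- tier_abundances(n_sub, cfg$tier_mass[["subdominant"]],
                                        cfg$rank_sdlog[["subdominant"]],
                                        0.0012, 0.0090)
  rare_idx <- which(tier == "rare")
  lake_comp[rare_idx] <- tier_abundances(length(rare_idx),
                                         cfg$tier_mass[["rare"]],
                                         cfg$rank_sdlog[["rare"]],
                                         cfg$rare_band[1], cfg$rare_band[2])

  ## --- shift plant: rare upstream-origin OTUs only ----------------------
  ## Up-shifters land in the upper rare band so that their (lake / fold)
  ## source abundance stays above the detection margin; down-shifters keep
  ## their source below the dominant threshold. The paper-world pattern:
  ## ten-fold shifts happen within the rare biosphere or rare<->subdominant.
  upstream <- which(pool != "lake")
  n_shift <- round(cfg$shifting_fraction * length(upstream))
  shift_pool <- intersect(rare_idx, upstream)
  n_up <- floor(n_shift / 2)
  up <- sample(shift_pool, n_up)
  lake_comp[up] <- stats::runif(n_up, 0.55 * cfg$rare_band[2], cfg$rare_band[2])
  down_ok <- setdiff(shift_pool[lake_comp[shift_pool] * cfg$shift_fold < 0.009],
                     up)
  down <- sample(down_ok, min(n_shift - n_up, length(down_ok)))
  direction <- rep(0, n_total)                 # log-fold source -> lake
  direction[up] <- log(cfg$shift_fold)         # rose into the lake
  direction[down] <- -log(cfg$shift_fold)      # fell into the lake
  lake_comp <- lake_comp / sum(lake_comp)

  ## --- per-habitat intensities ------------------------------------------
  intensity <- matrix(0, n_total, 3, dimnames = list(otus, habitats))
  intensity[, "lake"] <- lake_comp
  src_int <- lake_comp / exp(direction)        # intensity in the source
  riv <- pool == "river"; veg <- pool == "vegetated"
  intensity[riv, "river"] <- src_int[riv]
  # river-origin OTUs pass through the vegetated habitat mid-transition
  intensity[riv, "vegetated"] <- sqrt(src_int[riv] * lake_comp[riv])
  intensity[veg, "vegetated"] <- src_int[veg]
  composition <- apply(intensity, 2, function(x) x / sum(x))

  ## --- activity plant ----------------------------------------------------
  n_seed <- round(cfg$activity_fractions[["seed"]] * n_total)
  n_inact <- round(cfg$activity_fractions[["inactive"]] * n_total)
  eligible_seed <- setdiff(intersect(rare_idx, upstream), integer(0))
  seed_idx <- sample(eligible_seed, min(n_seed, length(eligible_seed)))
  lake_rare <- setdiff(intersect(rare_idx, which(pool == "lake")), seed_idx)
  n_inact_lake <- min(length(lake_rare), round(0.6 * n_inact))
  inact_idx <- sample(lake_rare, n_inact_lake)
  remaining <- setdiff(setdiff(rare_idx, seed_idx), inact_idx)
  inact_idx <- c(inact_idx, sample(remaining, n_inact - n_inact_lake))
  activity <- rep("active", n_total)
  activity[seed_idx] <- "seed"
  activity[inact_idx] <- "inactive"
  # dominants and subdominants stay active by construction
  stopifnot(all(activity[c(dom_idx, sub_idx)] == "active"))

  ratios <- matrix(0, n_total, 3, dimnames = list(otus, habitats))
  src_col <- match(pool, habitats)
  for (i in seq_len(n_total)) {
    span <- src_col[i]:3
    if (activity[i] == "inactive") next
    base_meanlog <- if (activity[i] == "seed") cfg$seed_ratio_meanlog
                    else cfg$ratio_meanlog[[tier[i]]]
    base <- stats::rlnorm(1, base_meanlog, cfg$ratio_sdlog[[tier[i]]])
    r <- base * stats::rlnorm(length(span), 0, cfg$ratio_jitter_sdlog)
    if (activity[i] == "seed") {
      if (length(span) < 2) { activity[i] <- "active" }
      else {
        n_zero <- sample(seq_len(length(span) - 1), 1)
        r[sample(seq_along(span), n_zero)] <- 0
      }
    }
    ratios[i, span] <- r
  }

  ## --- truth labels, derived from the final matrices --------------------
  tcfg <- tier_config(shift_fold = 10)
  true_tier <- classify_tier(composition[, "lake"], tcfg)
  true_shift <- ifelse(pool == "lake", "stable",
                       classify_shift(composition[cbind(seq_len(n_total), src_col)],
                                      composition[, "lake"], tcfg))
  true_activity <- vapply(seq_len(n_total), function(i) {
    classify_activity(ratios[i, src_col[i]:3], tcfg)
  }, character(1))

  ## --- sampling ----------------------------------------------------------
  info <- list(); dna_cols <- list(); rna_cols <- list()
  for (cp in cfg$campaigns) {
    for (h in habitats) {
      comp_h <- composition[, h]
      w <- comp_h * ratios[, h]
      w <- w / sum(w)
      for (s in seq_len(cfg$sites[[h]])) {
        pair <- paste(cp, h, s, sep = "_")
        for (mol in c("DNA", "RNA")) {
          sid <- paste(pair, mol, sep = "_")
          set.seed(sample_seed(cfg$seed, paste0("depth:", sid)))
          depth <- sample(cfg$depth_range[1]:cfg$depth_range[2], 1)
          set.seed(sample_seed(cfg$seed, paste0("reads:", sid)))
          p <- if (mol == "DNA") comp_h else w
          cnt <- as.vector(stats::rmultinom(1, depth, p))
          if (mol == "DNA") dna_cols[[sid]] <- cnt else rna_cols[[sid]] <- cnt
          info[[sid]] <- data.frame(sample_id = sid, habitat = h,
                                    campaign = cp, site_index = s,
                                    pair_id = pair, molecule = mol,
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  info <- do.call(rbind, info); rownames(info) <- NULL
  dna <- count_table(matrix(unlist(dna_cols), nrow = n_total,
                            dimnames = list(otus, names(dna_cols))), "DNA")
  rna <- count_table(matrix(unlist(rna_cols), nrow = n_total,
                            dimnames = list(otus, names(rna_cols))), "RNA")

  truth1 <- data.frame(otu_id = otus, source = pool, tier = true_tier,
                       shift = true_shift, activity = true_activity,
                       abund_river = composition[, "river"],
                       abund_vegetated = composition[, "vegetated"],
                       abund_lake = composition[, "lake"],
                       ratio_river = ratios[, "river"],
                       ratio_vegetated = ratios[, "vegetated"],
                       ratio_lake = ratios[, "lake"],
                       stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(cfg$campaigns, function(cp)
    cbind(campaign = cp, truth1)))
  rownames(truth) <- NULL

  structure(list(dna = dna, rna = rna, info = info, truth = truth,
                 composition = composition, ratios = ratios, config = cfg),
            class = "scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d OTUs, %d campaigns, %d sample pairs\n",
              nrow(x$dna), length(x$config$campaigns),
              nrow(x$info) / 2))
  invisible(x)
}

#' Noiseless expected-value paired view of a scenario
#'
#' Replaces multinomial sampling by the exact expected compositions: one
#' site per habitat, real-valued "counts" equal to composition times depth.
#' Feeding these tables to the classifier recovers the planted labels
#' exactly for OTUs away from tier and shift boundaries - the sanity anchor
#' separating detection-margin loss from logic errors.
#'
#' @param scenario A [generate_scenario()] result.
#' @param campaign Campaign label to stamp on the view (default first).
#' @param depth Nominal depth scaling the expectations (default 10114).
#' @return A `paired_tables` view.
#' @export
expected_value_tables <- function(scenario, campaign = NULL, depth = 10114) {
  stopifnot(inherits(scenario, "scenario"))
  campaign <- campaign %||% scenario$config$campaigns[1]
  habitats <- habitat_levels()
  comp <- scenario$composition
  d <- comp * depth
  w <- comp * scenario$ratios
  r <- apply(w, 2, function(x) x / sum(x)) * depth
  ids <- paste(campaign, habitats, 1, sep = "_")
  colnames(d) <- colnames(r) <- ids
  pairs <- data.frame(pair_id = ids, campaign = campaign,
                      habitat = factor(habitats, levels = habitats,
                                       ordered = TRUE),
                      site_index = 1L,
                      dna_sample = paste0(ids, "_DNA"),
                      rna_sample = paste0(ids, "_RNA"),
                      stringsAsFactors = FALSE)
  structure(list(dna = d, rna = r, pairs = pairs, habitats = habitats),
            class = "paired_tables")
}

#' Confusion matrices against planted truth
#'
#' Compares pipeline classifications with the scenario's truth labels, per
#' label family, over the OTUs the pipeline classified (OTUs lost to the
#' detection margin are reported, not scored).
#'
#' @param classifications [classify_campaign()] frames, row-bound.
#' @param truth The `truth` element of a [generate_scenario()] result.
#' @return List per family (`source`, `tier`, `shift`, `activity`):
#'   `confusion` (truth rows x called columns) and `accuracy`; plus
#'   `n_scored` and `n_unclassified`.
#' @export
truth_confusion <- function(classifications, truth) {
  cls <- if (is.data.frame(classifications)) classifications
         else do.call(rbind, classifications)
  key_c <- paste(cls$otu_id, cls$campaign)
  key_t <- paste(truth$otu_id, truth$campaign)
  if (!all(key_c %in% key_t))
    stop("classification ids not present in truth")
  t_m <- truth[match(key_c, key_t), ]
  fam <- function(col) {
    levs <- sort(unique(c(t_m[[col]], cls[[col]])))
    cm <- table(truth = factor(t_m[[col]], levs),
                called = factor(cls[[col]], levs))
    list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm))
  }
  out <- lapply(c(source = "source", tier = "tier",
                  shift = "shift", activity = "activity"), fam)
  out$n_scored <- nrow(cls)
  out$n_unclassified <- sum(!key_t %in% key_c)
  out
}
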