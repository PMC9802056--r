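category_label <- function(source, shift, tier, activity) {
  paste(source, shift, tier, activity, sep = "|")
}

props_by <- function(f, levels_all) {
  tab <- table(factor(f, levels = levels_all))
  as.numeric(tab) / length(f)
}

#' Aggregate per-campaign classifications into an assembly summary
#'
#' Computes, per campaign, the proportion of lake OTUs in every composite
#' category (source x shift x tier x activity) and in each marginal family,
#' then averages across campaigns with equal weight (sample SD, n-1). This
#' is the multilayer-pie composition of the lake community: how many OTUs
#' arrived from each source, how many shifted more than ten-fold, which
#' dominance tier they occupy, and their activity state.
#'
#' @param classifications Data frame of [classify_campaign()] results,
#'   row-bound across campaigns (or a list of such frames).
#' @param display_threshold Mean proportion below which a composite category
#'   is pooled into `"other"` in the `display` block (default 0.001, i.e.
#'   0.1% of lake OTUs). Full-resolution data are always retained.
#' @return List of class `assembly_summary`: `campaigns`; `n_lake_otus`
#'   per campaign; `categories` (composite proportions per campaign with
#'   cross-campaign mean and sd); marginal families `by_source`, `by_shift`,
#'   `by_tier`, `by_activity`; `source_counts` (OTU counts per source with
#'   mean and sd); and `display` (pooled view).
#' @export
summarize_assembly <- function(classifications, display_threshold = 0.001) {
  cls <- if (is.data.frame(classifications)) classifications
         else do.call(rbind, classifications)
  if (!nrow(cls)) stop("no classifications to summarise")
  campaigns <- unique(cls$campaign)
  cls$category <- category_label(cls$source, cls$shift, cls$tier, cls$activity)

  family_block <- function(col) {
    levs <- sort(unique(cls[[col]]))
    per <- sapply(campaigns, function(cp)
      props_by(cls[[col]][cls$campaign == cp], levs))
    per <- matrix(per, nrow = length(levs),
                  dimnames = list(levs, campaigns))
    data.frame(level = levs,
               per_campaign = I(lapply(seq_along(levs), function(i) per[i, ])),
               mean = rowMeans(per),
               sd = apply(per, 1, function(x) if (length(x) > 1) stats::sd(x) else 0),
               row.names = NULL, stringsAsFactors = FALSE)
  }

  categories <- family_block("category")
  counts <- sapply(campaigns, function(cp) {
    src <- cls$source[cls$campaign == cp]
    table(factor(src, levels = sort(unique(cls$source))))
  })
  counts <- matrix(counts, nrow = length(sort(unique(cls$source))),
                   dimnames = list(sort(unique(cls$source)), campaigns))
  source_counts <- data.frame(source = rownames(counts),
                              per_campaign = I(lapply(seq_len(nrow(counts)),
                                                      function(i) counts[i, ])),
                              mean = rowMeans(counts),
                              sd = apply(counts, 1, function(x)
                                if (length(x) > 1) stats::sd(x) else 0),
                              row.names = NULL, stringsAsFactors = FALSE)

  pooled <- categories$mean < display_threshold
  display <- categories[!pooled, c("level", "mean", "sd")]
  if (any(pooled))
    display <- rbind(display,
                     data.frame(level = "other",
                                mean = sum(categories$mean[pooled]),
                                sd = NA_real_))
  structure(list(campaigns = campaigns,
                 n_lake_otus = stats::setNames(
                   as.numeric(table(factor(cls$campaign, levels = campaigns))),
                   campaigns),
                 categories = categories,
                 by_source = family_block("source"),
                 by_shift = family_block("shift"),
                 by_tier = family_block("tier"),
                 by_activity = family_block("activity"),
                 source_counts = source_counts,
                 display = display),
            class = "assembly_summary")
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat(sprintf("<assembly_summary> %d campaign(s): %s\n",
              length(x$campaigns), paste(x$campaigns, collapse = ", ")))
  cat("Marginal composition (mean +/- sd across campaigns, % of lake OTUs):\n")
  for (fam in c("by_shift", "by_tier", "by_activity", "by_source")) {
    b <- x[[fam]]
    cat(" ", sub("by_", "", fam), ": ",
        paste(sprintf("%s %.1f%% +/- %.1f", b$level, 100 * b$mean, 100 * b$sd),
              collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Read contribution of each dominance tier
#'
#' Sums the lake-habitat mean relative abundance over the OTUs of each tier:
#' what fraction of the community's reads the dominant, subdominant and rare
#' tiers carry, per campaign and averaged across campaigns.
#'
#' @param lake_profiles Lake habitat profiles row-bound across campaigns.
#' @param classifications Matching classification frames (for the tiers).
#' @return List: `per_campaign` (tier x campaign matrix of fractions, each
#'   column summing to 1) and `mean` (cross-campaign mean per tier).
#' @export
tier_read_contribution <- function(lake_profiles, classifications) {
  cls <- if (is.data.frame(classifications)) classifications
         else do.call(rbind, classifications)
  campaigns <- unique(cls$campaign)
  tiers <- c("dominant", "subdominant", "rare")
  per <- sapply(campaigns, function(cp) {
    c_cp <- cls[cls$campaign == cp, ]
    p_cp <- lake_profiles[lake_profiles$campaign == cp, ]
    ab <- p_cp$mean_rel_abund[match(c_cp$otu_id, p_cp$otu_id)]
    if (anyNA(ab)) stop("classified OTU missing from lake profiles")
    mass <- tapply(ab, factor(c_cp$tier, levels = tiers), sum, default = 0)
    mass / sum(mass)
  })
  per <- matrix(per, nrow = length(tiers), dimnames = list(tiers, campaigns))
  list(per_campaign = per, mean = rowMeans(per))
}

#' Gene copy number by category, with rank tests
#'
#' Joins rrnDB-style 16S copy-number estimates onto the classifications and
#' contrasts tiers (dominant / subdominant / rare) with a Kruskal-Wallis
#' omnibus test plus pairwise Wilcoxon rank-sum tests under Bonferroni
#' correction; the same contrast is repeated for shifting versus stable.
#' OTUs without an estimate are excluded; coverage is reported.
#'
#' @param classifications Classification frame(s).
#' @param copies Named numeric vector of copy numbers (see
#'   [read_copy_numbers()]).
#' @return List per contrast (`tier`, `shift`): group means and n,
#'   `kruskal` (htest), `pairwise` (pairwise.htest or NULL), plus overall
#'   `coverage` (fraction of classified OTUs with an estimate).
#' @export
copy_number_by_tier <- function(classifications, copies) {
  cls <- if (is.data.frame(classifications)) classifications
         else do.call(rbind, classifications)
  cls <- cls[!duplicated(cls$otu_id), ]    # one estimate per OTU
  cov <- mean(cls$otu_id %in% names(copies))
  cls <- cls[cls$otu_id %in% names(copies), ]
  cls$copies <- copies[cls$otu_id]

  contrast <- function(group) {
    g <- factor(cls[[group]])
    n <- table(g)
    if (nlevels(g) < 2 || any(n < 2)) {
      warning("contrast '", group, "' skipped: a group has < 2 covered OTUs")
      return(list(means = c(tapply(cls$copies, g, mean)), n = n,
                  kruskal = NULL, pairwise = NULL))
    }
    kw <- stats::kruskal.test(cls$copies, g)
    if (is.nan(kw$p.value)) kw$p.value <- 1   # all observations tied
    exact <- all(n < 50)
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(cls$copies, g, p.adjust.method = "bonferroni",
                                  exact = exact))
    message(sprintf("copy-number contrast '%s': %s Wilcoxon p-values (min n = %d)",
                    group, if (exact) "exact" else "asymptotic", min(n)))
    list(means = c(tapply(cls$copies, g, mean)), n = n, kruskal = kw, pairwise = pw)
  }
  list(tier = contrast("tier"), shift = contrast("shift"), coverage = cov)
}

#' Per-sample alpha diversity
#'
#' Richness (OTUs with count > 0), Shannon entropy `H = -sum p log p`
#' (natural log, over detected OTUs) and the Gini-Simpson index
#' `1 - sum p^2`, for each sample column of a (rarefied) table.
#'
#' @param table A [count_table()].
#' @return Data frame: `sample_id`, `richness`, `shannon`, `gini_simpson`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "count_table"))
  cs <- colSums(table)
  if (any(cs <= 0)) stop("empty sample column(s): ",
                         paste(colnames(table)[cs <= 0], collapse = ", "))
  one <- function(x) {
    p <- x[x > 0] / sum(x)
    c(richness = sum(x > 0),
      shannon = -sum(p * log(p)),
      gini_simpson = 1 - sum(p^2))
  }
  res <- t(apply(unclass(table), 2, one))
  data.frame(sample_id = colnames(table), res,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-check the shift classification on absolute abundances
#'
#' Relative read fractions can shift without any change in absolute
#' abundance when total cell density differs between habitats. Given
#' flow-cytometry total cell counts per DNA sample, this converts each
#' OTU's per-sample read fraction into cells (cells x fraction), averages
#' per habitat, re-runs the ten-fold shift rule on the absolute scale, and
#' reports both shifting proportions. With habitat-equal cell counts the
#' common factor cancels and the two classifications agree OTU-for-OTU.
#'
#' @param paired Phantom-filtered `paired_tables` for one campaign.
#' @param cells Named numeric vector of total cell counts keyed by DNA
#'   sample id (must cover every DNA sample of the campaign).
#' @param classifications [classify_campaign()] output for the campaign.
#' @param cfg A [tier_config()].
#' @return List: `per_otu` (frame with relative and absolute shift calls for
#'   upstream-origin OTUs), `prop_shifting_relative`,
#'   `prop_shifting_absolute`.
#' @export
absolute_abundance_check <- function(paired, cells, classifications,
                                     cfg = tier_config()) {
  stopifnot(inherits(paired, "paired_tables"))
  pr <- paired$pairs
  missing_cells <- setdiff(pr$dna_sample, names(cells))
  if (length(missing_cells))
    stop("missing cell counts for sample(s): ",
         paste(missing_cells, collapse = ", "))
  habitats <- paired$habitats
  lake <- habitats[length(habitats)]
  rel <- sweep(paired$dna, 2, colSums(paired$dna), "/")
  abs_ab <- sweep(rel, 2, cells[pr$dna_sample], "*")
  hab_mean <- sapply(habitats, function(h)
    rowMeans(abs_ab[, pr$habitat == h, drop = FALSE]))

  ups <- classifications[classifications$source != lake, , drop = FALSE]
  if (!nrow(ups))
    return(list(per_otu = ups, prop_shifting_relative = 0,
                prop_shifting_absolute = 0))
  src_abs <- hab_mean[cbind(match(ups$otu_id, rownames(hab_mean)),
                            match(ups$source, habitats))]
  lake_abs <- hab_mean[match(ups$otu_id, rownames(hab_mean)),
                       match(lake, habitats)]
  ok <- src_abs > 0 & lake_abs > 0
  if (!all(ok)) stop("absolute abundance vanished for classified OTU(s)")
  per_otu <- data.frame(otu_id = ups$otu_id,
                        shift_relative = ups$shift,
                        shift_absolute = classify_shift(src_abs, lake_abs, cfg),
                        stringsAsFactors = FALSE)
  list(per_otu = per_otu,
       prop_shifting_relative = mean(per_otu$shift_relative == "shifting"),
       prop_shifting_absolute = mean(per_otu$shift_absolute == "shifting"))
}

#' Export an assembly summary as JSON
#'
#' Flat schema: campaigns, per-category proportions with per-campaign
#' values, marginal families, source counts and the pooled display block.
#'
#' @param summary An [summarize_assembly()] result.
#' @param path Output path (`.json`).
#' @param tiers Optional [tier_read_contribution()] result to embed.
#' @param copy_number Optional [copy_number_by_tier()] result; p-values and
#'   means are embedded.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, tiers = NULL, copy_number = NULL) {
  block <- function(df) {
    out <- lapply(seq_len(nrow(df)), function(i)
      list(per_campaign = as.numeric(df$per_campaign[[i]]),
           mean = df$mean[i], sd = df$sd[i]))
    names(out) <- df$level %||% df$source
    out
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  payload <- list(
    campaigns = summary$campaigns,
    n_lake_otus = as.list(summary$n_lake_otus),
    categories = block(summary$categories),
    by_source = block(summary$by_source),
    by_shift = block(summary$by_shift),
    by_tier = block(summary$by_tier),
    by_activity = block(summary$by_activity),
    source_counts = block(summary$source_counts),
    display = summary$display)
  if (!is.null(tiers))
    payload$tier_contribution <- list(per_campaign = as.data.frame(tiers$per_campaign),
                                      mean = as.list(tiers$mean))
  if (!is.null(copy_number))
    payload$copy_number <- list(
      coverage = copy_number$coverage,
      tier_means = as.list(copy_number$tier$means),
      tier_kruskal_p = if (!is.null(copy_number$tier$kruskal))
        copy_number$tier$kruskal$p.value else NULL,
      shift_means = as.list(copy_number$shift$means),
      shift_kruskal_p = if (!is.null(copy_number$shift$kruskal))
        copy_number$shift$kruskal$p.value else NULL)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
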