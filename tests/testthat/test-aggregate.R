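mk_cls <- function(campaign, n, shift_stable = n, tier = "rare",
                   source = "river", activity = "active") {
  data.frame(otu_id = sprintf("%s_o%03d", campaign, 1:n), campaign = campaign,
             source = source, tier = tier,
             source_tier = tier,
             shift = rep(c("stable", "shifting"),
                         c(shift_stable, n - shift_stable)),
             activity = activity,
             lake_rel_abund = 1 / n, lake_ratio = 0.5,
             source_rel_abund = 1 / n, continuity_gap = FALSE)
}

test_that("single-campaign proportions and zero SD", {
  s <- summarize_assembly(mk_cls("c1", 10, shift_stable = 9))
  stable <- s$by_shift[s$by_shift$level == "stable", ]
  expect_equal(stable$mean, 0.9)
  expect_equal(stable$sd, 0)
  expect_equal(s$n_lake_otus[["c1"]], 10)
})

test_that("two-campaign mean and sample SD match hand computation", {
  cls <- rbind(mk_cls("c1", 100, shift_stable = 88),
               mk_cls("c2", 100, shift_stable = 92))
  s <- summarize_assembly(cls)
  stable <- s$by_shift[s$by_shift$level == "stable", ]
  expect_equal(stable$mean, 0.90)
  expect_equal(stable$sd, sd(c(0.88, 0.92)))            # n-1 convention
  expect_equal(stable$sd, 0.02 * sqrt(2), tolerance = 1e-12)
  # campaign order does not affect the summary
  s_rev <- summarize_assembly(cls[rev(seq_len(nrow(cls))), ])
  expect_equal(s_rev$by_shift[s_rev$by_shift$level == "stable", "mean"],
               stable$mean)
  # proportion families sum to one per campaign
  for (fam in c("categories", "by_shift", "by_tier", "by_activity"))
    for (i in seq_along(s$campaigns))
      expect_equal(sum(vapply(s[[fam]]$per_campaign, `[`, numeric(1), i)), 1,
                   tolerance = 1e-9)
})

test_that("small categories pool into 'other' for display only", {
  cls <- rbind(mk_cls("c1", 2000), mk_cls("c1", 1, tier = "dominant"))
  cls$otu_id <- sprintf("o%05d", seq_len(nrow(cls)))
  s <- summarize_assembly(cls)
  expect_true("other" %in% s$display$level)     # 1/2001 < 0.1%
  expect_equal(nrow(s$categories), 2)           # full data retained
  expect_equal(sum(s$categories$mean), 1)
})

test_that("source counts average across campaigns", {
  cls <- rbind(mk_cls("c1", 6, source = "river"),
               mk_cls("c1", 4, source = "lake"),
               mk_cls("c2", 8, source = "river"),
               mk_cls("c2", 2, source = "lake"))
  cls$otu_id <- sprintf("o%03d_%s", seq_len(nrow(cls)), cls$campaign)
  s <- summarize_assembly(cls)
  river <- s$source_counts[s$source_counts$source == "river", ]
  expect_equal(river$mean, 7)
  expect_equal(river$sd, sd(c(6, 8)))
})

test_that("tier read contributions sum to one and place the mass", {
  prof <- data.frame(otu_id = c("dom", paste0("r", 1:4)), campaign = "c1",
                     habitat = "lake",
                     mean_rel_abund = c(0.6, rep(0.1, 4)),
                     mean_ratio = 1, detected_dna = TRUE,
                     ratio_has_sentinel = FALSE, n_sites = 5)
  cls <- data.frame(otu_id = prof$otu_id, campaign = "c1",
                    tier = c("dominant", rep("rare", 4)))
  tc <- tier_read_contribution(prof, cls)
  expect_equal(unname(tc$mean), c(0.6, 0, 0.4))
  expect_equal(sum(tc$per_campaign[, 1]), 1)
  cls$tier <- "rare"
  expect_equal(unname(tier_read_contribution(prof, cls)$mean[3]), 1)
})

test_that("copy-number contrasts behave on degenerate and separated input", {
  cls <- mk_cls("c1", 400)
  cls$tier <- rep(c("dominant", "rare"), each = 200)
  same <- setNames(rep(2, 400), cls$otu_id)
  # the all-stable fixture legitimately warns on the skipped shift contrast
  res <- suppressWarnings(suppressMessages(copy_number_by_tier(cls, same)))
  expect_equal(unname(res$tier$means), c(2, 2))
  expect_gt(res$tier$kruskal$p.value, 0.9)
  expect_equal(res$coverage, 1)

  set.seed(13)
  apart <- setNames(c(rnorm(200, 1.8, 1), rnorm(200, 2.6, 1)), cls$otu_id)
  res2 <- suppressWarnings(suppressMessages(copy_number_by_tier(cls, apart)))
  expect_lt(res2$tier$kruskal$p.value, 0.01)
  expect_lt(res2$tier$pairwise$p.value["rare", "dominant"], 0.01)

  # a group with < 2 covered OTUs is skipped with a warning
  cls$shift <- c("shifting", rep("stable", 399))
  expect_warning(suppressMessages(copy_number_by_tier(cls, apart)), "skipped")
})

test_that("alpha diversity matches closed forms and the vegan oracle", {
  u <- count_table(cmat(rep(5, 100), otus = sprintf("o%03d", 1:100),
                        samples = "s"), "DNA")
  div <- alpha_diversity(u)
  expect_equal(div$shannon, log(100), tolerance = 1e-12)
  expect_equal(div$gini_simpson, 1 - 1 / 100, tolerance = 1e-12)
  expect_equal(div$richness, 100)

  single <- count_table(cmat(c(9, 0), otus = c("a", "b"), samples = "s"), "DNA")
  expect_equal(unlist(alpha_diversity(single)[, -1]),
               c(richness = 1, shannon = 0, gini_simpson = 0))

  two <- count_table(cmat(c(9, 1), otus = c("a", "b"), samples = "s"), "DNA")
  expect_equal(alpha_diversity(two)$shannon,
               -(0.9 * log(0.9) + 0.1 * log(0.1)))

  set.seed(8)
  m <- cmat(rpois(80, 20), otus = paste0("o", 1:20))
  m[, colSums(m) == 0] <- 1
  got <- alpha_diversity(count_table(m, "DNA"))
  expect_equal(got$shannon, unname(vegan::diversity(t(m), "shannon")))
  expect_equal(got$gini_simpson, unname(vegan::diversity(t(m), "simpson")))

  empty <- count_table(cmat(c(0, 0), otus = c("a", "b"), samples = "s"),
                       "DNA", raw = FALSE)
  expect_error(alpha_diversity(empty), "empty sample")
})

test_that("absolute-abundance cross-check cancels equal cell counts", {
  set.seed(17)
  n <- 30
  mats <- lapply(c(river = 1, vegetated = 2, lake = 3), function(h) {
    set.seed(h)
    cmat(rpois(n * 2, 50) + 1, otus = paste0("o", 1:n))
  })
  rna <- lapply(mats, function(m) m)   # ratios all 1, irrelevant here
  paired <- toy_paired(mats, rna)
  cls <- classify_campaign(campaign_profiles(paired))
  cells_eq <- setNames(rep(1e6, nrow(paired$pairs)), paired$pairs$dna_sample)
  chk <- absolute_abundance_check(paired, cells_eq, cls)
  expect_identical(chk$per_otu$shift_absolute, chk$per_otu$shift_relative)
  expect_equal(chk$prop_shifting_absolute, chk$prop_shifting_relative)
  expect_error(absolute_abundance_check(paired, cells_eq[-1], cls), "missing")
})

test_that("habitat-dependent cell counts can flip a near-threshold shift", {
  # OTU at 9-fold relative increase river->lake; lake holds 2x the cells
  d <- function(x) cmat(c(x, 1000 - x), otus = c("o", "bulk"))
  paired <- toy_paired(
    dna = list(river = d(10)[, 1, drop = FALSE], vegetated = d(10),
               lake = d(90)),
    rna = list(river = d(10)[, 1, drop = FALSE], vegetated = d(10),
               lake = d(90)))
  cls <- classify_campaign(campaign_profiles(paired))
  o <- cls[cls$otu_id == "o", ]
  expect_equal(o$shift, "stable")                     # 9 < 10
  cells <- setNames(ifelse(paired$pairs$habitat == "lake", 2e6, 1e6),
                    paired$pairs$dna_sample)
  chk <- absolute_abundance_check(paired, cells, cls)
  expect_equal(chk$per_otu$shift_absolute[chk$per_otu$otu_id == "o"],
               "shifting")                            # 18 > 10
})

test_that("summary JSON export is complete and machine-readable", {
  cls <- rbind(mk_cls("c1", 50, shift_stable = 45),
               mk_cls("c2", 50, shift_stable = 44))
  s <- summarize_assembly(cls)
  path <- withr::local_tempfile(fileext = ".json")
  write_summary_json(s, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$by_shift$stable$mean,
               s$by_shift$mean[s$by_shift$level == "stable"])
  expect_named(back, c("campaigns", "n_lake_otus", "categories", "by_source",
                       "by_shift", "by_tier", "by_activity", "source_counts",
                       "display"), ignore.order = TRUE)
})
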