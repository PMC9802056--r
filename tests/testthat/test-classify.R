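test_that("source attribution takes the most upstream detection", {
  expect_equal(attribute_source(c(TRUE, TRUE, TRUE)), "river")
  expect_equal(attribute_source(c(FALSE, TRUE, TRUE)), "vegetated")
  expect_equal(attribute_source(c(FALSE, FALSE, TRUE)), "lake")
  expect_equal(attribute_source(c(TRUE, FALSE, TRUE)), "river")
  expect_error(attribute_source(c(TRUE, TRUE, FALSE)), "lake")
})

test_that("tier thresholds are strict with boundaries going down-tier", {
  expect_equal(classify_tier(c(0.02, 0.005, 0.0005)),
               c("dominant", "subdominant", "rare"))
  expect_equal(classify_tier(0.01), "subdominant")  # exactly 1% is not > 1%
  expect_equal(classify_tier(0.001), "rare")        # exactly 0.1% is rare
  expect_error(classify_tier(1.2), "outside")
  expect_error(tier_config(dominant_threshold = 0.0001), "rare_threshold")
})

test_that("ten-fold shift rule is strict in both directions", {
  expect_equal(classify_shift(0.0005, 0.006), "shifting")   # 12x up
  expect_equal(classify_shift(0.004, 0.0042), "stable")
  expect_equal(classify_shift(0.02, 0.002), "stable")       # exactly 10x
  expect_equal(classify_shift(0.02, 0.0019), "shifting")
  expect_error(classify_shift(0, 0.1), "positive")
})

test_that("activity states follow the zero / positive ratio pattern", {
  expect_equal(classify_activity(c(0.3, 0.1, 0.5)), "active")
  expect_equal(classify_activity(c(0, 0, 0)), "inactive")
  expect_equal(classify_activity(c(0, 0.4, 0.2)), "seed")
  expect_equal(classify_activity(c(0.4, 0, 0)), "seed")     # inactivation
  expect_equal(classify_activity(c(0.2, 100, 0.1)), "active") # sentinel = RNA seen
  expect_equal(classify_activity(0.5), "active")            # single habitat
  expect_equal(classify_activity(0), "inactive")
  expect_error(classify_activity(numeric(0)), "empty")
})

test_that("a toy campaign of six OTUs matches hand evaluation", {
  profs <- rbind(
    toy_profiles(c(0.020, 0.021, 0.019), c(0.3, 0.2, 0.4), "dom_river"),
    toy_profiles(c(0.0005, 0.0006, 0.0004), c(0, 0, 0), "rare_inactive"),
    toy_profiles(c(0, 0.0004, 0.006), c(0, 0.5, 0.3), "veg_riser"),
    toy_profiles(c(0, 0, 0.0008), c(0, 0, 0.2), "lake_only"),
    toy_profiles(c(0.0002, 0.0002, 0.0002), c(0, 0.1, 0.2), "river_seed"),
    toy_profiles(c(0.004, 0, 0.0003), c(0.5, 0, 0.1), "gap_faller"))
  cls <- classify_campaign(profs)
  rownames(cls) <- cls$otu_id
  expect_equal(unname(unlist(cls["dom_river", c("source", "tier", "shift", "activity")])),
               c("river", "dominant", "stable", "active"))
  expect_equal(unname(unlist(cls["rare_inactive", c("source", "tier", "shift", "activity")])),
               c("river", "rare", "stable", "inactive"))
  expect_equal(unname(unlist(cls["veg_riser", c("source", "tier", "shift", "activity")])),
               c("vegetated", "subdominant", "shifting", "active"))
  expect_equal(unname(unlist(cls["lake_only", c("source", "tier", "shift", "activity")])),
               c("lake", "rare", "stable", "active"))
  expect_equal(unname(unlist(cls["river_seed", c("source", "tier", "shift", "activity")])),
               c("river", "rare", "stable", "seed"))
  # detected river + lake, absent from the vegetated habitat in between:
  # the undetected habitat carries no ratio information, so activity is
  # judged on river and lake only (both positive -> active), flagged
  expect_equal(unname(unlist(cls["gap_faller", c("source", "shift", "activity")])),
               c("river", "shifting", "active"))
  expect_true(cls["gap_faller", "continuity_gap"])
  expect_false(any(cls[c("dom_river", "veg_riser"), "continuity_gap"]))
  # exhaustive and exclusive labels for every lake-detected OTU
  expect_equal(nrow(cls), 6)
  expect_true(all(cls$activity %in% c("active", "inactive", "seed")))
})

test_that("classifier agrees with the straight-line oracle on random grids", {
  set.seed(21)
  for (i in 1:200) {
    det <- c(sample(c(TRUE, FALSE), 2, replace = TRUE), TRUE)
    ab <- ifelse(det, sample(c(0.0005, 0.005, 0.05), 3, replace = TRUE), 0)
    ratio <- ifelse(det, sample(c(0, 0.5, 100), 3, replace = TRUE),
                    sample(c(0, 100), 3, replace = TRUE))
    got <- classify_campaign(toy_profiles(ab, ratio))
    want <- oracle_classify(det, ab, ratio)
    expect_equal(got$source, want$source)
    expect_equal(got$tier, want$tier)
    expect_equal(got$shift, want$shift)
    expect_equal(got$activity, want$activity)
  }
})

test_that("classification is invariant to a global count rescaling", {
  set.seed(31)
  n <- 40
  mk <- function(scale) {
    lapply(c(river = 1, vegetated = 2, lake = 3), function(h) {
      set.seed(h * 100)
      cmat(round(scale * (rpois(n * 2, 60) + 1)), otus = paste0("o", 1:n))
    })
  }
  rna <- lapply(c(river = 4, vegetated = 5, lake = 6), function(h) {
    set.seed(h * 100)
    cmat(rpois(n * 2, 20) * rbinom(n * 2, 1, 0.8), otus = paste0("o", 1:n))
  })
  base <- classify_campaign(campaign_profiles(toy_paired(mk(1), rna)))
  big <- classify_campaign(campaign_profiles(toy_paired(mk(7), rna)))
  expect_equal(base[c("otu_id", "source", "tier", "shift", "activity")],
               big[c("otu_id", "source", "tier", "shift", "activity")])
})

test_that("tier never moves toward rare as lake abundance grows", {
  ab <- sort(runif(200, 0, 1))
  tiers <- factor(classify_tier(ab), c("rare", "subdominant", "dominant"),
                  ordered = TRUE)
  expect_true(all(diff(as.integer(tiers)) >= 0))
})

test_that("retrace_in_reference returns detection fractions", {
  ref <- count_table(cmat(c(4, 0, 1), otus = c("A", "X", "Y"),
                          samples = "deep"), "DNA")
  expect_equal(retrace_in_reference(c("A", "B", "C", "D"), ref), 0.25)
  expect_equal(retrace_in_reference(c("A", "Y"), ref), 1.0)
  expect_equal(retrace_in_reference("X", ref), 0)   # zero count = absent
  expect_error(retrace_in_reference(character(0), ref), "empty")
})

test_that("planted retrace overlap is recovered within binomial error", {
  set.seed(77)
  n_set <- 400; p_overlap <- 0.05
  lake_set <- sprintf("lake_%03d", seq_len(n_set))
  planted <- sample(lake_set, round(p_overlap * n_set))
  deep_otus <- c(planted, sprintf("river_%03d", 1:600))
  ref <- count_table(cmat(rpois(length(deep_otus), 5) + 1, otus = deep_otus,
                          samples = "deep"), "DNA")
  got <- retrace_in_reference(lake_set, ref)
  expect_lt(abs(got - p_overlap), 3 * sqrt(p_overlap * 0.95 / n_set))
})
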