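test_that("normalised activity is the firefly/Renilla ratio with guards", {
  expect_equal(normalized_activity(500, 100), 5)
  expect_equal(normalized_activity(0, 100), 0)
  expect_equal(normalized_activity(c(500, 0), c(100, 50)), c(5, 0))
  expect_error(normalized_activity(500, 0), "viability/measurement failure")
  expect_error(normalized_activity(500, NA), "viability/measurement failure")
})

test_that("percent inhibition is 100 minus percent of control mean", {
  expect_equal(percent_inhibition(5, c(5, 5)), 0)
  expect_equal(percent_inhibition(500 / 100, 1000 / 100), 50)
  # activation is retained as negative inhibition, never clipped
  expect_equal(percent_inhibition(20, 10), -100)
  expect_lte(max(percent_inhibition(runif(50, 0, 100), c(2, 3))), 100)
  expect_error(percent_inhibition(1, numeric(0)), "no valid")
  expect_error(percent_inhibition(1, c(1, 0)), "positive")
})

test_that("replicate aggregation gives mean, sample SD, and count", {
  expect_equal(aggregate_replicates(c(60, 60)), list(mean = 60, sd = 0, n = 2L))
  a <- aggregate_replicates(c(80, 90))
  expect_equal(a$mean, 85)
  expect_equal(a$sd, sqrt(50), tolerance = 1e-12)  # 7.0710678...
  single <- aggregate_replicates(63.0)
  expect_equal(single$mean, 63.0)
  expect_true(is.na(single$sd))
  expect_equal(single$n, 1L)
})

test_that("plate factors cancel exactly in the noiseless dual-reporter screen", {
  cfg <- simulation_config(n_genes = 12, amplicons_per_gene = 2,
                           plate_format = 96, noise_cv = 0,
                           plate_effect_sd = 0.8,  # large, to make leakage obvious
                           fraction_true_hits = 0.5, hit_effect = 0.7,
                           fraction_viability = 0, measure_renilla = TRUE,
                           seed = 4)
  sim <- simulate_screen(cfg)
  summ <- score_dual_reporter(sim$dataset, sim$annotation)
  truth <- sim$truth
  expected <- ifelse(truth$class == "hif_regulator", 100 * truth$knockdown, 0)
  got <- summ$mean_inhibition[match(truth$gene_id, summ$gene_id)]
  expect_equal(got, expected, tolerance = 1e-9)
  expect_true(all(summ$sd_inhibition < 1e-9))      # replicates agree exactly
})

test_that("percent inhibition is invariant to rescaling a plate's two channels", {
  sim <- simulate_screen(simulation_config(n_genes = 15, amplicons_per_gene = 2,
                                           plate_format = 96, noise_cv = 0.2,
                                           measure_renilla = TRUE, seed = 8))
  base <- score_dual_reporter(sim$dataset, sim$annotation)
  ds <- sim$dataset
  p1 <- ds$wells$plate_id == ds$wells$plate_id[1]
  ds$wells$firefly[p1] <- ds$wells$firefly[p1] * 37.5
  ds$wells$renilla[p1] <- ds$wells$renilla[p1] * 37.5
  expect_equal(score_dual_reporter(ds, sim$annotation), base)
})

test_that("secondary and tertiary classification follow the strict thresholds", {
  # printed per-amplicon means: Reptin, Clipper, Snr1, CG4849
  expect_equal(classify_secondary(amp_summary("Reptin", c(80.3, 74.6)))$label,
               "group_A")
  expect_equal(classify_secondary(amp_summary("Clipper", 63.0))$label,
               "group_B")
  expect_equal(classify_secondary(amp_summary("x", c(50, 50)))$label,
               "non_hit")                           # strict at 50
  expect_equal(classify_secondary(amp_summary("x", c(75, 40)))$label,
               "group_B")                           # strict at 75
  expect_equal(classify_tertiary(amp_summary("Snr1", c(38.0, 28.2)))$label,
               "negative")
  expect_equal(classify_tertiary(amp_summary("CG4849", c(83.3, 42.0)))$label,
               "positive")
})

test_that("labels are monotone in inhibition, and group A implies tertiary positive", {
  set.seed(12)
  for (i in 1:50) {
    m <- runif(2, -20, 100)
    sec <- classify_secondary(amp_summary("g", m))$label
    ter <- classify_tertiary(amp_summary("g", m))$label
    # consistency across stages on identical inputs
    if (sec != "non_hit") expect_equal(ter, "positive")
    if (sec == "group_A") expect_equal(ter, "positive")
    # raising any amplicon never lowers the severity
    bumped <- classify_secondary(amp_summary("g", m + c(10, 0)))$label
    severity <- c(non_hit = 0, group_B = 1, group_A = 2)
    expect_gte(severity[[bumped]], severity[[sec]])
  }
})

test_that("strong planted knockdowns classify as group A across seeds", {
  # knockdown 0.9 at noise CV 0.2: expect group A in >= 95% of gene-seed draws
  labels <- unlist(lapply(1:20, function(s) {
    cfg <- simulation_config(n_genes = 20, amplicons_per_gene = 2,
                             plate_format = 96, fraction_true_hits = 0.3,
                             hit_effect = 0.9, fraction_viability = 0,
                             noise_cv = 0.2, measure_renilla = TRUE, seed = s)
    sim <- simulate_screen(cfg)
    calls <- classify_secondary(score_dual_reporter(sim$dataset,
                                                    sim$annotation))
    planted <- sim$truth$gene_id[sim$truth$class == "hif_regulator"]
    calls$label[calls$gene_id %in% planted]
  }))
  expect_gte(mean(labels == "group_A"), 0.95)
})
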