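test_that("the noiseless, effect-free screen is exactly baseline x induction", {
  cfg <- simulation_config(n_genes = 30, noise_cv = 0, plate_effect_sd = 0,
                           fraction_true_hits = 0, fraction_viability = 0,
                           baseline_firefly = 1000, induction_fold = 10,
                           seed = 1)
  sim <- simulate_screen(cfg)
  smp <- sim$dataset$wells[sim$dataset$wells$role == "sample", ]
  expect_true(all(smp$firefly == 1000 * 10))
  # positive controls carry the fixed 0.9 knockdown exactly
  pos <- sim$dataset$wells[sim$dataset$wells$role == "positive_control", ]
  expect_equal(pos$firefly, rep(1000 * 10 * 0.1, nrow(pos)))
})

test_that("the generator is seed-deterministic", {
  cfg <- function(s) simulation_config(n_genes = 40, seed = s,
                                       measure_renilla = TRUE)
  a <- simulate_screen(cfg(42))
  b <- simulate_screen(cfg(42))
  c <- simulate_screen(cfg(43))
  expect_identical(a$dataset$wells, b$dataset$wells)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$dataset$wells$firefly, c$dataset$wells$firefly))
})

test_that("every gene appears amplicons x replicates times among sample wells", {
  cfg <- simulation_config(n_genes = 37, amplicons_per_gene = 2,
                           n_replicates = 3, plate_format = 96, seed = 9)
  sim <- simulate_screen(cfg)
  smp <- sim$dataset$wells[sim$dataset$wells$role == "sample", ]
  gene <- sim$annotation$target_gene_id[match(smp$reagent_id,
                                              sim$annotation$reagent_id)]
  expect_true(all(table(gene) == 2 * 3))
  expect_setequal(unique(gene), sim$truth$gene_id)
})

test_that("neutral genes score near zero on the Z scale", {
  # >= 5000 neutral sample wells: 2600 genes x 2 replicates, no planted effects
  cfg <- simulation_config(n_genes = 2600, fraction_true_hits = 0,
                           fraction_viability = 0, seed = 21)
  sim <- simulate_screen(cfg)
  z <- plate_zscores(sim$dataset)
  zs <- z$z[z$role == "sample"]
  expect_gte(length(zs), 5000)
  expect_lt(abs(mean(zs)), 0.1)
})

test_that("replicate correlation rises to 1 as well noise vanishes", {
  r_at <- function(cv, seed) {
    cfg <- simulation_config(n_genes = 120, fraction_true_hits = 0.2,
                             fraction_viability = 0, hit_effect = c(0.5, 0.95),
                             noise_cv = cv, seed = seed)
    sim <- simulate_screen(cfg)
    z <- plate_zscores(sim$dataset)
    s <- z[z$role == "sample", ]
    z1 <- s$z[s$replicate == 1][order(s$reagent_id[s$replicate == 1])]
    z2 <- s$z[s$replicate == 2][order(s$reagent_id[s$replicate == 2])]
    replicate_correlation(z1, z2)
  }
  for (seed in 1:5) {
    expect_equal(r_at(0, seed), 1, tolerance = 1e-9)
    expect_gt(r_at(0.1, seed), r_at(0.6, seed))
  }
})

test_that("a plate budget too small for the library is refused", {
  cfg <- simulation_config(n_genes = 500, amplicons_per_gene = 2,
                           plate_format = 96, n_plates = 2, seed = 1)
  expect_error(simulate_screen(cfg), "plate capacity exceeded")
  expect_error(simulate_screen(cfg), "12 plate")  # suggests the needed count
})

test_that("the packaged tertiary-screen table matches its printed source", {
  tbl <- make_table1_fixture()
  expect_equal(nrow(tbl), 35L)
  sima <- tbl[tbl$gene_id == "Sima", ]
  expect_equal(c(sima$inhibition_amp1_mean, sima$inhibition_amp2_mean),
               c(92.3, 89.3))
  snr1 <- tbl[tbl$gene_id == "Snr1", ]
  expect_equal(c(snr1$inhibition_amp1_mean, snr1$inhibition_amp2_mean),
               c(38.0, 28.2))
  clipper <- tbl[tbl$gene_id == "Clipper", ]
  expect_equal(clipper$inhibition_amp1_mean, 63.0)
  expect_true(is.na(clipper$inhibition_amp2_mean))  # second amplicon not tested

  long <- table1_amplicon_summaries(tbl)
  expect_equal(nrow(long), 35L + sum(!is.na(tbl$inhibition_amp2_mean)))
  expect_false(anyNA(long$mean_inhibition))
})
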