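test_that("delta-Ct averages replicates on the cycle scale", {
  expect_equal(delta_ct(25.0, 20.0), 5.0)
  expect_equal(delta_ct(c(25.0, 25.2, 24.8), c(20.0, 20.0, 20.0)), 5.0)
  expect_equal(delta_ct(22.5, 22.5), 0.0)
  expect_error(delta_ct(numeric(0), 20), "target")
  expect_error(delta_ct(25, NA), "reference")
})

test_that("fold induction follows the comparative-Ct formula", {
  expect_equal(fold_induction(5, 5), 1.0)
  expect_equal(fold_induction(2, 5), 8.0)    # delta-delta-Ct of -3
  expect_equal(fold_induction(6, 5), 0.5)    # delta-delta-Ct of +1
})

test_that("reciprocal identity and Ct-drift invariance hold to 1e-12", {
  set.seed(31)
  for (i in 1:50) {
    a <- runif(1, -8, 8); b <- runif(1, -8, 8)
    expect_equal(fold_induction(a, b) * fold_induction(b, a), 1,
                 tolerance = 1e-12)
    ct_t <- runif(3, 18, 30); ct_r <- runif(3, 15, 25); drift <- runif(1, -3, 3)
    expect_equal(delta_ct(ct_t + drift, ct_r + drift), delta_ct(ct_t, ct_r),
                 tolerance = 1e-12)
  }
})

test_that("fold-induction tables normalise every sample to the control", {
  ct <- data.frame(
    sample_id = rep(c("gfp_normoxia", "gfp_hypoxia"), each = 6),
    gene = rep(rep(c("ldh", "tubulin"), each = 3), 2),
    replicate = rep(1:3, 4),
    ct = c(28.0, 28.2, 27.8, 20.0, 20.1, 19.9,    # normoxic: dCt = 8
           25.0, 25.1, 24.9, 20.0, 20.0, 20.0))   # hypoxic:  dCt = 5
  folds <- fold_induction_table(ct, reference_gene = "tubulin",
                                control_sample = "gfp_normoxia")
  expect_equal(folds$fold[folds$sample_id == "gfp_normoxia"], 1)
  expect_equal(folds$fold[folds$sample_id == "gfp_hypoxia"], 8)  # 2^3
  expect_error(fold_induction_table(ct[ct$gene != "tubulin", ],
                                    control_sample = "gfp_normoxia"),
               "lacks reference gene")
})

test_that("beta-gal activity is the background-corrected slope per ug protein", {
  t <- c(10, 30, 60, 120, 180)
  bg <- rep(0.05, 5)
  # exact line: corrected OD = 0.001 * t, 20 ug protein
  res <- bgal_activity(t, 0.001 * t + bg, bg, protein_ug = 20)
  expect_equal(res$activity, 5e-5, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_false(res$linearity_flagged)

  # flat series: zero slope, zero activity, undefined R^2, no flag
  flat <- bgal_activity(t, bg, bg, protein_ug = 20)
  expect_equal(flat$activity, 0)
  expect_true(is.na(flat$r_squared))
  expect_false(flat$linearity_flagged)

  # two points: fitted slope equals the closed-form two-point slope
  two <- bgal_activity(c(10, 30), c(0.12, 0.31), c(0.02, 0.03),
                       protein_ug = 10)
  expect_equal(two$slope, ((0.31 - 0.03) - (0.12 - 0.02)) / (30 - 10),
               tolerance = 1e-12)

  # saturating (non-linear) series gets flagged, not refused
  sat <- bgal_activity(t, 1 - exp(-t / 15), rep(0, 5), protein_ug = 20)
  expect_true(sat$linearity_flagged)
  expect_lt(sat$r_squared, 0.9)
})

test_that("mismatched time grids are a hard error", {
  expect_error(
    bgal_activity(c(10, 30, 60), c(0.1, 0.2, 0.3), c(0, 0, 0),
                  protein_ug = 20, time_background = c(10, 30, 120)),
    "different time grid")
  expect_error(bgal_activity(c(10, 30), c(0.1, 0.2), c(0, 0), protein_ug = 0),
               "protein")
})
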