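make_plate_ds <- function(firefly, roles = rep("sample", length(firefly))) {
  screen_dataset(data.frame(
    plate_id = "P1",
    row = rep(LETTERS[1:8], length.out = length(firefly)),
    col = rep(1:12, each = 8)[seq_along(firefly)],
    reagent_id = paste0("r", seq_along(firefly)),
    role = roles, firefly = firefly, stringsAsFactors = FALSE),
    plate_format = 96)
}

test_that("plate Z-scores match hand arithmetic and a brute-force oracle", {
  # hand case: {100, 200, 300}, sample SD 100
  z <- plate_zscores(make_plate_ds(c(100, 200, 300)))
  expect_equal(z$z, c(-1, 0, 1))

  # brute-force two-pass oracle on random small plates
  two_pass <- function(x) {
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))
    (x - m) / s
  }
  set.seed(101)
  for (i in 1:25) {
    x <- rlnorm(sample(3:10, 1), meanlog = 7, sdlog = 0.5)
    expect_equal(plate_zscores(make_plate_ds(x))$z, two_pass(x),
                 tolerance = 1e-12)
  }
})

test_that("Z-scores are invariant to affine rescaling of the plate signal", {
  set.seed(7)
  x <- rlnorm(96, meanlog = 8, sdlog = 0.3)
  z0 <- plate_zscores(make_plate_ds(x))$z
  for (ab in list(c(3.7, 0), c(1, 250), c(0.02, 11))) {
    z1 <- plate_zscores(make_plate_ds(ab[1] * x + ab[2]))$z
    expect_equal(z1, z0, tolerance = 1e-9)
  }
  # and within a plate the scores themselves have mean 0, SD 1
  expect_equal(mean(z0), 0, tolerance = 1e-9)
  expect_equal(sd(z0), 1, tolerance = 1e-9)
})

test_that("degenerate plates are refused", {
  expect_error(plate_zscores(make_plate_ds(c(100, 100, 100))), "zero plate SD")
  expect_error(plate_zscores(make_plate_ds(c(100, 200))), "fewer than 3")
})

test_that("control handling and SD denominator are explicit flags", {
  x <- c(100, 200, 300, 5000)      # last well a wild control
  roles <- c("sample", "sample", "sample", "negative_control")
  ds <- make_plate_ds(x, roles)
  with_ctrl <- plate_zscores(ds, include_controls = TRUE)
  no_ctrl <- plate_zscores(ds, include_controls = FALSE)
  # control excluded from statistics but still scored
  expect_equal(no_ctrl$z[1:3], c(-1, 0, 1))
  expect_equal(nrow(no_ctrl), 4L)
  expect_false(isTRUE(all.equal(with_ctrl$z[1:3], no_ctrl$z[1:3])))

  pop <- plate_zscores(make_plate_ds(c(100, 200, 300)), sd_denom = "n")
  expect_equal(pop$z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
})

test_that("threshold hit calling honours the replicate rule and is strict", {
  gz <- data.frame(
    gene_id = rep(c("sima", "boundary", "split"), each = 2),
    replicate = rep(1:2, 3),
    z = c(-6.4, -6.4,   # far below the cut-off in both replicates
          -2.5, -2.5,   # exactly at the cut-off
          -3.0, -1.0))  # below in one replicate only (mean -2.0)
  any_rule <- call_primary_hits(gz, cutoff = -2.5, replicate_rule = "any")
  mean_rule <- call_primary_hits(gz, cutoff = -2.5, replicate_rule = "mean")
  get <- function(calls, g) calls$label[calls$gene_id == g]
  expect_equal(get(any_rule, "sima"), "hit")
  expect_equal(get(mean_rule, "sima"), "hit")
  expect_equal(get(any_rule, "boundary"), "non_hit")   # strict inequality
  expect_equal(get(mean_rule, "boundary"), "non_hit")
  expect_equal(get(any_rule, "split"), "hit")
  expect_equal(get(mean_rule, "split"), "non_hit")
  expect_equal(any_rule$z_rep1[any_rule$gene_id == "split"], -3.0)
  expect_equal(any_rule$z_mean[any_rule$gene_id == "split"], -2.0)
})

test_that("gene scores take the strongest amplicon within each replicate", {
  ztab <- data.frame(plate_id = "P1", row = "A", col = 1:4,
                     reagent_id = c("g1_a1", "g1_a2", "g2_a1", "g2_a2"),
                     role = "sample", replicate = 1L,
                     z = c(-3, -1, 0.5, 0.2), stringsAsFactors = FALSE)
  gz <- gene_zscores(ztab, toy_annotation(c("g1", "g2"), amplicons = 2L))
  expect_equal(gz$z[gz$gene_id == "g1"], -3)
  expect_equal(gz$z[gz$gene_id == "g2"], 0.2)
  expect_true(all(gz$n_amplicons == 2L))
})

test_that("replicate correlation is the Pearson coefficient with its guards", {
  x <- c(1, 2, 3, 4)
  expect_equal(replicate_correlation(x, x), 1)
  expect_equal(replicate_correlation(x, -x), -1)
  expect_equal(replicate_correlation(x, c(2, 1, 4, 3)), 0.6)  # hand arithmetic
  expect_error(replicate_correlation(x, c(5, 5, 5, 5)), "zero variance")
  expect_error(replicate_correlation(1:2, 1:2), "at least 3")
  expect_error(replicate_correlation(1:4, 1:3), "paired")
})
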