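test_that("Rif-resistance frequency follows the dilution model", {
  expect_equal(rifr_frequency(50, 1, 100), 5)
  expect_equal(rifr_frequency(0, 1, 100), 0)
  expect_error(rifr_frequency(50, 1, 0), "viable")
  expect_error(rifr_frequency(-1, 1, 10), "nonnegative")

  # linear in rif_cfu, inverse-linear in viable_cfu, dilution-corrected
  expect_equal(rifr_frequency(100, 1, 100), 2 * rifr_frequency(50, 1, 100))
  expect_equal(rifr_frequency(50, 1, 200), rifr_frequency(50, 1, 100) / 2)
  expect_equal(rifr_frequency(5, 0.1, 100), rifr_frequency(50, 1, 100))
})

test_that("plate choice prefers the countable 30-300 plate, else undiluted", {
  plates <- tibble::tibble(
    group_id = "g", culture_id = c("c1", "c1", "c2", "c2"),
    rif_cfu = c(500, 50, 12, 1), rif_dilution = c(1, 0.1, 1, 0.1),
    viable_cfu = 20
  )
  chosen <- choose_plate(plates)
  expect_equal(nrow(chosen), 2)
  # c1: undiluted 500 uncountable, diluted 50 countable -> diluted
  expect_equal(chosen$rif_dilution[chosen$culture_id == "c1"], 0.1)
  # c2: neither countable -> undiluted
  expect_equal(chosen$rif_dilution[chosen$culture_id == "c2"], 1)

  freqs <- assay_frequencies(plates)
  expect_equal(freqs$frequency[freqs$culture_id == "c1"],
               rifr_frequency(50, 0.1, 20))
})

test_that("bootstrap median CI handles degenerate and tiny inputs", {
  b <- median_ci(c(7, 7, 7, 7), n_boot = 1000, seed = 1)
  expect_equal(b$median, 7)
  expect_equal(c(b$ci_low, b$ci_high), c(7, 7))
  expect_equal(median_ci(c(1, 2, 3), n_boot = 1000, seed = 1)$median, 2)
  expect_error(median_ci(c(1, 2), seed = 1), ">= 3")
  expect_error(median_ci(1:5, n_boot = 10, seed = 1), "n_boot")
})

test_that("bootstrap is seed-reproducible and level-monotone", {
  x <- c(101, 88, 150, 40, 95, 120, 99, 101, 77, 130)
  b1 <- median_ci(x, n_boot = 2000, seed = 42)
  b2 <- median_ci(x, n_boot = 2000, seed = 42)
  expect_identical(b1$boot_medians, b2$boot_medians)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  b3 <- median_ci(x, n_boot = 2000, seed = 43)
  expect_false(identical(b1$boot_medians, b3$boot_medians))

  wide <- median_ci(x, n_boot = 2000, seed = 42, level = 0.99)
  expect_lte(wide$ci_low, b1$ci_low)
  expect_gte(wide$ci_high, b1$ci_high)
  expect_lte(b1$ci_low, b1$median)
  expect_gte(b1$ci_high, b1$median)

  # calling median_ci must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(median_ci(x, n_boot = 1000, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("native percentile CI agrees with the boot package on the same data", {
  skip_if_not_installed("boot")
  set.seed(8)
  x <- rlnorm(30, log(50), 0.5)
  ours <- median_ci(x, n_boot = 5000, seed = 1)
  bt <- boot::boot(x, function(d, i) stats::median(d[i]), R = 5000)
  ci <- boot::boot.ci(bt, type = "perc", conf = 0.95)
  expect_equal(ours$median, stats::median(x))
  # different RNG streams: intervals agree to bootstrap noise, not bitwise
  expect_lt(abs(ours$ci_low - ci$percent[4]) / ci$percent[4], 0.15)
  expect_lt(abs(ours$ci_high - ci$percent[5]) / ci$percent[5], 0.15)
})

test_that("group comparison: fold changes and CI-overlap significance", {
  set.seed(2)
  freqs <- tibble::tibble(
    group_id = rep(c("null", "EcMutY", "twin"), each = 24),
    culture_id = paste0("c", 1:72),
    frequency = c(101 * exp(0.3 * rnorm(24)),
                  12 * exp(0.3 * rnorm(24)),
                  12 * exp(0.3 * rnorm(24)))
  )
  cmp <- compare_groups(freqs, reference = "EcMutY", n_boot = 2000, seed = 7)
  expect_s3_class(cmp, "rifr_comparison")
  ec <- cmp[cmp$group_id == "EcMutY", ]
  expect_equal(ec$fold_change, 1)
  expect_false(ec$significant_vs_reference)
  nl <- cmp[cmp$group_id == "null", ]
  expect_true(nl$significant_vs_reference)
  expect_false(nl$significant_vs_null)
  expect_gt(nl$fold_change, 4)
  tw <- cmp[cmp$group_id == "twin", ]
  expect_false(tw$significant_vs_reference)  # same distribution as reference
  expect_true(tw$significant_vs_null)

  expect_error(compare_groups(freqs, reference = "missing"), "missing")

  g <- glance(cmp)
  expect_equal(g$n_groups, 3)

  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
})

test_that("tidy and glance expose bootstrap results as tibbles", {
  b <- median_ci(c(5, 6, 7, 8, 9), n_boot = 1000, seed = 3)
  td <- tidy(b)
  expect_equal(td$median, 7)
  expect_equal(td$n, 5)
  expect_equal(glance(b)$n_boot, 1000L)
})
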