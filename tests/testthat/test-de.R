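# Dye-swap alignment, variance exclusion and the pooled-variance paired
# t-test with Bonferroni control.

make_ratio_table <- function(values, n_pairs) {
  G <- nrow(values)  # values: genes x replicates "true" signal
  ratios <- matrix(NA_real_, G, 2 * n_pairs)
  ids <- character(2 * n_pairs); ori <- character(2 * n_pairs)
  rep_id <- character(2 * n_pairs)
  for (p in seq_len(n_pairs)) {
    ratios[, 2 * p - 1] <- values[, p]
    ratios[, 2 * p] <- -values[, p]
    ids[c(2 * p - 1, 2 * p)] <- sprintf("A%02d_%s", p, c("F", "S"))
    ori[c(2 * p - 1, 2 * p)] <- c("forward", "swapped")
    rep_id[c(2 * p - 1, 2 * p)] <- sprintf("R%02d", p)
  }
  dimnames(ratios) <- list(rownames(values), ids)
  list(ratios = ratios,
       arrays = data.frame(array_id = ids, replicate_id = rep_id,
                           orientation = ori))
}

test_that("dye-swap alignment recovers signal and cancels dye bias", {
  ratios <- matrix(c(1, -1), nrow = 1,
                   dimnames = list("g1", c("A01_F", "A01_S")))
  arrays <- data.frame(array_id = c("A01_F", "A01_S"),
                       replicate_id = "R01",
                       orientation = c("forward", "swapped"))
  expect_equal(unname(align_dye_swaps(ratios, arrays)[1, 1]), 1.0)

  biased <- matrix(c(1, 1), nrow = 1,
                   dimnames = list("g1", c("A01_F", "A01_S")))
  expect_equal(unname(align_dye_swaps(biased, arrays)[1, 1]), 0.0)
})

test_that("alignment equals the (forward - swapped)/2 oracle on random tables", {
  set.seed(41)
  ratios <- matrix(rnorm(600), 100, 6,
                   dimnames = list(sprintf("g%03d", 1:100),
                                   c(t(outer(sprintf("A%02d", 1:3),
                                             c("F", "S"), paste, sep = "_")))))
  arrays <- data.frame(array_id = colnames(ratios),
                       replicate_id = rep(sprintf("R%02d", 1:3), each = 2),
                       orientation = rep(c("forward", "swapped"), 3))
  got <- align_dye_swaps(ratios, arrays)
  for (p in 1:3) {
    oracle <- (ratios[, 2 * p - 1] - ratios[, 2 * p]) / 2
    expect_equal(unname(got[, p]), unname(oracle), tolerance = 1e-15)
  }
})

test_that("unpaired swapped arrays are a named hard error", {
  ratios <- matrix(rnorm(4), 2, 2,
                   dimnames = list(c("g1", "g2"), c("A01_S", "A02_S")))
  arrays <- data.frame(array_id = c("A01_S", "A02_S"),
                       replicate_id = c("R01", "R01"),
                       orientation = c("swapped", "swapped"))
  expect_error(align_dye_swaps(ratios, arrays), "R01")
})

test_that("extreme-variance exclusion removes only distribution tails", {
  set.seed(42)
  aligned <- matrix(rnorm(3000), 1000, 3,
                    dimnames = list(sprintf("g%04d", 1:1000), NULL))
  mask <- exclude_extreme_variance(aligned, de_config())
  n_excl <- attr(mask, "n_excluded")
  expect_gte(n_excl, 0); expect_lte(n_excl, 8)  # expectation 2 of 1000

  spiked <- aligned
  spiked[17, ] <- spiked[17, ] * sqrt(1e6 / stats::median(apply(aligned, 1, var)))
  mask2 <- exclude_extreme_variance(spiked, de_config())
  expect_false(mask2[["g0017"]])

  all_in <- exclude_extreme_variance(aligned,
    de_config(variance_exclusion_quantiles = c(0, 1)))
  expect_identical(attr(all_in, "n_excluded"), 0L)
})

test_that("pooled test reproduces the closed-form normal tail", {
  a <- sqrt(0.1875)  # mean 1, pooled s2 = 0.25 over n = 4 replicates
  aligned <- matrix(c(1 - a, 1 + a, 1 - a, 1 + a), nrow = 1,
                    dimnames = list("g1", NULL))
  tab <- pooled_paired_test(aligned)
  expect_equal(attr(tab, "s2"), 0.25, tolerance = 1e-12)
  expect_equal(tab$t_stat, 4.0, tolerance = 1e-12)
  expect_equal(tab$p_raw, 2 * pnorm(-4), tolerance = 1e-12)
  expect_equal(tab$p_raw, 6.334248e-05, tolerance = 1e-4)
})

test_that("degenerate and invalid inputs are handled per contract", {
  zeros <- matrix(0, 5, 3, dimnames = list(paste0("g", 1:5), NULL))
  tab <- pooled_paired_test(zeros)
  expect_true(all(tab$p_raw == 1))
  expect_true(all(tab$call == "unchanged"))

  one_rep <- matrix(rnorm(5), 5, 1, dimnames = list(paste0("g", 1:5), NULL))
  expect_error(pooled_paired_test(one_rep), "2 replicates")
})

test_that("Bonferroni is monotone, bounded and call-stable under reordering", {
  set.seed(43)
  sim <- gen_two_color(two_color_spec(300, 3, de_fraction = 0.1, effect = 1,
                                      sigma = 0.3, rng_seed = 44))
  tab <- de_test(sim$ratios, sim$arrays)
  expect_true(all(tab$p_bonferroni >= tab$p_raw - 1e-15))
  expect_true(all(tab$p_bonferroni <= 1))
  ord <- order(tab$p_raw)
  expect_true(all(diff(tab$p_bonferroni[ord]) >= -1e-15))

  perm <- sample(nrow(sim$ratios))
  tab2 <- de_test(sim$ratios[perm, ], sim$arrays)
  expect_identical(setNames(tab2$call, tab2$gene_id)[tab$gene_id],
                   setNames(tab$call, tab$gene_id))
})

test_that("calls require both significance and a matching sign", {
  sim <- gen_two_color(two_color_spec(500, 3, de_fraction = 0.1, effect = -2,
                                      sigma = 0.3, rng_seed = 45))
  tab <- de_test(sim$ratios, sim$arrays)
  expect_true(all(tab$mean_log_ratio[tab$call == "down"] < 0))
  expect_true(all(tab$mean_log_ratio[tab$call == "up"] > 0))
  de <- sim$truth$is_de
  expect_gte(mean(tab$call[de] == "down"), 0.9)
})

test_that("power: 3 sigma / sqrt(n) effects are recovered with high sensitivity", {
  n <- 3; sigma <- 0.5
  eff <- 3 * sigma / sqrt(n)
  sim <- gen_two_color(two_color_spec(1000, n, de_fraction = 0.1, effect = eff,
                                      sigma = sigma, rng_seed = 46))
  tab <- de_test(sim$ratios, sim$arrays)
  de <- sim$truth$is_de
  # raw-p sensitivity (the family-wise Bonferroni call is deliberately
  # stricter and is exercised by the calibration tests)
  sens <- mean(tab$p_raw[de] < 0.05 & tab$mean_log_ratio[de] > 0)
  expect_gte(sens, 0.9)
})
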