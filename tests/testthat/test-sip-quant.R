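test_that("profile normalization returns exact proportions", {
  prof <- data.frame(fraction = 1:3, density_g_ml = c(1.75, 1.74, 1.73),
                     copies = c(10, 10, 20))
  expect_equal(unname(normalize_profile(prof, c(1, 3))),
               c(0.25, 0.25, 0.5))
  uni <- data.frame(fraction = 1:7, density_g_ml = seq(1.76, 1.70, -0.01),
                    copies = rep(3, 7))
  expect_equal(unname(normalize_profile(uni, c(1, 7))), rep(1 / 7, 7))
  zero <- data.frame(fraction = 1:3, density_g_ml = c(1.75, 1.74, 1.73),
                     copies = c(0, 0, 0))
  expect_error(normalize_profile(zero, c(1, 3)), "failed gradient")
})

test_that("fixed heavy window enumerates fractions at or above threshold", {
  proto <- gradient_protocol(noise_cv = 0)
  tr <- label_truth(0.5, 1, 0.5, 1e6)
  pair <- gradient_pair(simulate_gradient(tr, proto, seed = 1), "AOA")
  win <- define_heavy_window(pair, "fixed", 1.725)
  dens <- fraction_densities(proto)
  manual <- which(dens >= 1.725)
  manual <- manual[manual >= 2 & manual <= 14]
  expect_identical(win, as.integer(manual))
  # hand check: midpoint densities run 1.757667 down by 0.0046667 per
  # fraction, so fractions 2..7 are unambiguously >= 1.725
  expect_true(all(2:7 %in% win))
  expect_false(any(win > 8))
})

test_that("adaptive window is empty without enrichment and finds the labeled peak", {
  same <- manual_pair(list(c(1, 5, 20, 5, 1)), list(c(1, 5, 20, 5, 1)))
  expect_length(define_heavy_window(same, "adaptive"), 0)

  proto <- gradient_protocol(noise_cv = 0)
  tr <- label_truth(0.5, 1, 0.8, 1e6)
  pair <- gradient_pair(simulate_gradient(tr, proto, seed = 1), "AOA")
  win <- define_heavy_window(pair, "adaptive")
  dens <- fraction_densities(proto)
  peak_fraction <- which.min(abs(dens - 1.745))  # labeled peak density
  expect_true(peak_fraction %in% win)
  modal <- which.min(abs(dens - 1.709))          # unlabeled peak density
  expect_false(modal %in% win)
})

test_that("labeled proportion matches hand arithmetic on constructed sums", {
  # window sum S12 = 0.10, S13 = 0.55
  pair <- manual_pair(list(c(10, 90, 0)), list(c(55, 45, 0)))
  est_n <- labeled_proportion(pair, window = 1, n_boot = 0)
  expect_equal(est_n$p_hat, 0.45 / 0.90)
  est_r <- labeled_proportion(pair, window = 1, estimator = "raw_excess",
                              n_boot = 0)
  expect_equal(est_r$p_hat, 0.45)
  # identical profiles: both estimators give zero
  same <- manual_pair(list(c(10, 90, 0)), list(c(10, 90, 0)))
  expect_equal(labeled_proportion(same, 1, n_boot = 0)$p_hat, 0)
  expect_equal(labeled_proportion(same, 1, "raw_excess", n_boot = 0)$p_hat, 0)
})

test_that("p-hat is scale invariant and normalized >= raw under excess", {
  pair <- manual_pair(list(c(10, 90, 0)), list(c(55, 45, 0)))
  scaled <- manual_pair(list(c(10, 90, 0) * 7.3), list(c(55, 45, 0)))
  expect_equal(labeled_proportion(pair, 1, n_boot = 0)$p_hat,
               labeled_proportion(scaled, 1, n_boot = 0)$p_hat)
  for (s13 in c(0.2, 0.5, 0.9)) {
    p <- manual_pair(list(c(10, 90, 0)), list(c(s13, 1 - s13, 0) * 100))
    raw <- labeled_proportion(p, 1, "raw_excess", n_boot = 0)$p_hat
    nrm <- labeled_proportion(p, 1, "normalized_excess", n_boot = 0)$p_hat
    expect_gte(nrm, raw)
  }
})

test_that("empty and saturated windows are flagged, never errors", {
  pair <- manual_pair(list(c(10, 90, 0)), list(c(55, 45, 0)))
  est <- labeled_proportion(pair, integer(0), n_boot = 0)
  expect_equal(est$p_hat, 0)
  expect_equal(est$flag, "empty_window")
  sat <- manual_pair(list(c(100, 0, 0)), list(c(100, 0, 0)))
  est <- labeled_proportion(sat, 1, n_boot = 0)
  expect_equal(est$p_hat, 0)
  expect_equal(est$flag, "window_saturated")
  expect_error(labeled_proportion(pair, 99, n_boot = 0), "analysis fraction")
})

test_that("noise-free recovery is exact within the quadrature tail error", {
  proto <- gradient_protocol(noise_cv = 0)
  for (p_true in c(0, 0.25, 0.5, 0.8, 1)) {
    tr <- label_truth(0.5, 1, p_true, 1e6)
    pair <- gradient_pair(simulate_gradient(tr, proto, seed = 1), "AOA")
    win <- define_heavy_window(pair, "adaptive")
    est <- labeled_proportion(pair, win, n_boot = 0)
    expect_lt(abs(est$p_hat - p_true), 0.02)
  }
})

test_that("p-hat is non-decreasing in the true proportion without noise", {
  proto <- gradient_protocol(noise_cv = 0)
  ps <- seq(0, 1, by = 0.1)
  est <- vapply(ps, function(p) {
    pair <- gradient_pair(simulate_gradient(label_truth(0.5, 1, p, 1e6),
                                            proto, seed = 1), "AOA")
    labeled_proportion(pair, define_heavy_window(pair, "adaptive"),
                       n_boot = 0)$p_hat
  }, numeric(1))
  expect_true(all(diff(est) >= -1e-12))
})

test_that("bootstrap CI brackets the point estimate and is seeded", {
  proto <- gradient_protocol(noise_cv = 0.05)
  tr <- label_truth(0.5, 1, 0.6, 1e6)
  pair <- gradient_pair(simulate_gradient(tr, proto, seed = 8), "AOA")
  win <- define_heavy_window(pair, "adaptive")
  e1 <- labeled_proportion(pair, win, n_boot = 200, seed = 5)
  e2 <- labeled_proportion(pair, win, n_boot = 200, seed = 5)
  expect_identical(e1, e2)
  expect_lte(e1$ci_low, e1$p_hat)
  expect_gte(e1$ci_high, e1$p_hat)
})

test_that("labeled abundance is the exact product of proportion and total", {
  expect_equal(labeled_abundance(0, 1e6), 0)
  expect_equal(labeled_abundance(0.5, 2e6), 1e6)
  expect_equal(labeled_abundance(0.803, 1e5), 8.03e4)
})

test_that("enrichment significance is a t-test on heavy-window sums", {
  # strong planted enrichment -> small p
  proto <- gradient_protocol(noise_cv = 0.05)
  tr <- label_truth(0.5, 1, 0.8, 1e6)
  pair <- gradient_pair(simulate_gradient(tr, proto, seed = 2), "AOA")
  win <- define_heavy_window(pair, "adaptive")
  expect_lt(enrichment_significance(pair, win)$p_value, 0.05)
  # degenerate zero-variance identical replicates -> p = 1 with flag
  same <- manual_pair(list(c(10, 90, 0), c(10, 90, 0)),
                      list(c(10, 90, 0), c(10, 90, 0)))
  res <- enrichment_significance(same, 1)
  expect_equal(res$p_value, 1)
  expect_equal(res$flag, "zero_variance")
  # single replicates are refused
  single <- manual_pair(list(c(10, 90, 0)), list(c(55, 45, 0)))
  expect_error(enrichment_significance(single, 1), "replicates")
})

test_that("significance test is powered and calibrated on simulated pairs", {
  proto <- gradient_protocol(noise_cv = 0.05)
  pvals_for <- function(p_true, seeds) {
    vapply(seeds, function(s) {
      g <- simulate_gradient(label_truth(0.5, 1, p_true, 1e6), proto,
                             seed = s)
      pair <- gradient_pair(g, "AOA")
      win <- define_heavy_window(pair, "fixed", 1.725)
      enrichment_significance(pair, win)$p_value
    }, numeric(1))
  }
  power <- mean(pvals_for(0.8, 1:500) < 0.05)
  expect_gte(power, 0.95)
  typeI <- mean(pvals_for(0, 1:2000) < 0.05)
  expect_lt(abs(typeI - 0.05), 0.02)
})

test_that("quantify_labeling assembles estimates for every gene", {
  tr <- label_truth(c(AOA = 0.4, AOB = 0.5, comammox = 0.55), 1,
                    c(AOA = 0.8, AOB = 0.2, comammox = 0.6),
                    c(AOA = 1e6, AOB = 2e6, comammox = 5e5))
  g <- simulate_gradient(tr, gradient_protocol(noise_cv = 0.05), seed = 10)
  totals <- data.frame(gene = c("AOA", "AOB", "comammox"),
                       copies_per_g = c(1e6, 2e6, 5e5))
  est <- quantify_labeling(g, totals, n_boot = 50, seed = 1)
  expect_setequal(est$gene, c("AOA", "AOB", "comammox"))
  expect_equal(est$labeled_abundance, est$p_hat * est$total_copies)
  expect_true(all(est$p_hat >= 0 & est$p_hat <= 1))
})

test_that("gradient pair construction enforces its contracts", {
  tr <- label_truth(0.5, 1, 0.5, 1e6)
  g <- simulate_gradient(tr, gradient_protocol(), seed = 1)
  expect_error(gradient_pair(g, "nosZ"), "not present")
  only13 <- g[g$isotope == "13C", ]
  expect_error(gradient_pair(only13, "AOA"), "both 12C and 13C")
  shifted <- g
  shifted$density_g_ml[shifted$replicate == 2] <-
    shifted$density_g_ml[shifted$replicate == 2] + 0.001
  expect_error(gradient_pair(shifted, "AOA"), "grids do not match")
})
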