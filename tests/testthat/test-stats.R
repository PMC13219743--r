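test_that("one-way ANOVA matches the hand-computed table and aov", {
  av <- one_way_anova(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(av$F, 27)
  expect_equal(av$df_between, 2)
  expect_equal(av$df_within, 6)
  expect_equal(av$MSE, 1)
  expect_equal(av$p, pf(27, 2, 6, lower.tail = FALSE))
  # oracle: base R aov on random data
  set.seed(42)
  g <- list(a = rnorm(4), b = rnorm(5, 1), c = rnorm(3, 2))
  av <- one_way_anova(g)
  d <- data.frame(y = unlist(g), grp = rep(names(g), lengths(g)))
  ref <- summary(aov(y ~ grp, d))[[1]]
  expect_equal(av$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(av$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(av$MSE, ref$`Mean Sq`[2], tolerance = 1e-10)
})

test_that("ANOVA degenerate cases are explicit", {
  av <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(av$F, 0)
  expect_equal(av$p, 1)
  expect_equal(av$flag, "zero_within_variance")
  av <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_equal(av$F, Inf)
  expect_equal(av$p, 0)
  expect_error(one_way_anova(list(a = 1:3)), ">= 2 groups")
  expect_error(one_way_anova(list(a = 1, b = 1:2)), ">= 2 values")
})

test_that("with two groups F equals the squared pooled t statistic", {
  set.seed(7)
  x <- rnorm(5); y <- rnorm(6, 0.5)
  av <- one_way_anova(list(x = x, y = y))
  tt <- two_sample_t(x, y, "student")
  expect_equal(av$F, tt$t^2, tolerance = 1e-12)
  expect_equal(av$p, tt$p, tolerance = 1e-12)
})

test_that("t statistics match hand computation and t.test", {
  tt <- two_sample_t(c(1, 2, 3), c(2, 3, 4), "student")
  expect_equal(tt$t, -1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  eq <- two_sample_t(c(1, 2), c(1, 2))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  set.seed(11)
  x <- rnorm(6); y <- rnorm(9, 1, 2)
  for (mode in c("student", "welch")) {
    mine <- two_sample_t(x, y, mode)
    ref <- t.test(x, y, var.equal = (mode == "student"))
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
  # Satterthwaite df never exceeds the pooled df; equal when balanced
  expect_lte(two_sample_t(x, y, "welch")$df,
             two_sample_t(x, y, "student")$df)
  expect_equal(two_sample_t(c(1, 2, 3), c(4, 5, 6), "welch")$df, 4)
  # zero-variance degenerate cases
  z <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(z$p, 1)
  expect_equal(z$flag, "zero_variance")
  expect_equal(two_sample_t(c(1, 1), c(2, 2))$p, 0)
})

test_that("studentized range quantiles match the reference distribution", {
  # normal limit: q(0.95, 2, Inf) = sqrt(2) * z_0.975
  expect_equal(studentized_range_quantile(0.95, 2, Inf),
               sqrt(2) * qnorm(0.975), tolerance = 1e-4)
  # published-table oracle (base R's qtukey implements the standard tables)
  cases <- expand.grid(prob = c(0.95, 0.99), k = c(2, 3, 5), df = c(5, 10, 30))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], expect_equal(
      studentized_range_quantile(prob, k, df), qtukey(prob, k, df),
      tolerance = 1e-4))
  }
  expect_equal(studentized_range_quantile(0.95, 3, 10), 3.877,
               tolerance = 1e-3)
  # monotone in the number of groups
  qs <- vapply(2:6, studentized_range_quantile, numeric(1), prob = 0.95,
               df = 12)
  expect_true(all(diff(qs) > 0))
  expect_error(studentized_range_quantile(1.2, 3, 10), "prob")
})

test_that("Duncan separates the classic fixture and handles identity", {
  set.seed(3)
  g <- list(g1 = 1 + rnorm(3, 0, 0.2), g2 = 1.1 + rnorm(3, 0, 0.2),
            g3 = 5 + rnorm(3, 0, 0.2), g4 = 9 + rnorm(3, 0, 0.2))
  d <- duncan_mrt(g, 0.05)
  lt <- setNames(d$display$letters, d$display$group)
  # {1, 1.1} share a letter; 5 and 9 are isolated
  expect_true(any(strsplit(lt[["g1"]], "")[[1]] %in%
                    strsplit(lt[["g2"]], "")[[1]]))
  expect_false(any(strsplit(lt[["g3"]], "")[[1]] %in%
                     c(strsplit(lt[["g1"]], "")[[1]],
                       strsplit(lt[["g2"]], "")[[1]],
                       strsplit(lt[["g4"]], "")[[1]])))
  expect_false(any(strsplit(lt[["g4"]], "")[[1]] %in%
                     strsplit(lt[["g3"]], "")[[1]]))
  # identical groups share one letter
  same <- duncan_mrt(list(a = c(1, 1, 1), b = c(1, 1, 1),
                          c = c(1, 1, 1)))
  expect_true(all(same$display$letters == "a"))
})

test_that("two-group Duncan decisions equal the pooled t-test", {
  for (s in 1:25) {
    set.seed(s)
    x <- rnorm(3); y <- rnorm(3, runif(1, 0, 3))
    d <- duncan_mrt(list(x = x, y = y), 0.05)
    tt <- two_sample_t(x, y, "student")
    expect_identical(unname(d$significant[1, 2]), tt$p < 0.05)
  }
})

test_that("Duncan decisions agree with the brute-force range rule", {
  for (s in 1:30) {
    set.seed(s)
    k <- sample(3:5, 1)
    g <- lapply(seq_len(k), function(i) rnorm(3, runif(1, 0, 4)))
    names(g) <- paste0("g", seq_len(k))
    d <- duncan_mrt(g, 0.05)
    ms <- d$display$mean
    oracle <- oracle_duncan_pairs(ms, d$ranges)
    expect_identical(unname(d$significant), oracle)
    # compact letter display is consistent with the decision matrix
    share <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
      any(strsplit(d$display$letters[i], "")[[1]] %in%
            strsplit(d$display$letters[j], "")[[1]])
    }))
    expect_identical(!share & !diag(k), d$significant & !diag(k),
                     ignore_attr = TRUE)
  }
})

test_that("ANOVA is calibrated and Duncan exceeds its nominal level", {
  n_sim <- 5000
  reject_anova <- logical(n_sim)
  any_duncan <- logical(n_sim)
  set.seed(123)
  for (i in seq_len(n_sim)) {
    g <- list(a = rnorm(3), b = rnorm(3), c = rnorm(3), d = rnorm(3))
    av <- one_way_anova(g)
    reject_anova[i] <- av$p < 0.05
    d <- duncan_mrt(g, 0.05, anova = av)
    any_duncan[i] <- any(d$significant)
  }
  expect_lt(abs(mean(reject_anova) - 0.05), 0.01)
  # Duncan's protection levels make the familywise error exceed alpha
  expect_gt(mean(any_duncan), 0.04)
})

test_that("compare_groups wraps ANOVA and letters for a data frame", {
  set.seed(9)
  d <- data.frame(y = c(rnorm(3, 1), rnorm(3, 1.1), rnorm(3, 10)),
                  grp = rep(c("A", "B", "C"), each = 3))
  res <- compare_groups(d, "y", "grp")
  expect_equal(nrow(res$table), 3)
  expect_equal(res$table$group[1], "C")  # sorted by descending mean
  expect_error(compare_groups(d, "nope", "grp"), "must exist")
  dlog <- d; dlog$y <- abs(dlog$y)
  expect_silent(compare_groups(dlog, "y", "grp", log_transform = TRUE))
})
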