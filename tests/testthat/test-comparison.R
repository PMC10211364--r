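test_that("classic ANOVA reproduces hand-computed sums of squares", {
  res <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4),
                            c = c(4, 5, 6)))
  expect_equal(res$statistic, 7)       # SSB = 14, SSW = 6
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
  expect_equal(res$variant, "classic")

  same <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$statistic, 0)

  g <- list(a = c(1.2, 3.4, 2.2), b = c(5.5, 4.4, 6.1))
  shifted <- lapply(g, `+`, 100)
  expect_equal(one_way_anova(shifted)$statistic,
               one_way_anova(g)$statistic, tolerance = 1e-9)
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("Welch ANOVA relates to the classic F by its exact correction", {
  expect_error(welch_anova(list(a = c(1, 1, 1), b = c(2, 2, 2))),
               "zero-variance")

  # equal sizes and equal sample variances: the Welch numerator equals the
  # classic F and the denominator is the Welch-Satterthwaite correction
  x <- c(0.4, 1.9, -0.7, 1.1, 0.3, -1.2, 0.8, 1.6)
  groups <- list(a = x, b = x + 1, c = x + 2.5)
  k <- 3; n <- length(x)
  lambda <- k * (1 - 1 / k)^2 / (n - 1)
  corr <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  cl <- one_way_anova(groups)
  we <- welch_anova(groups)
  expect_equal(we$statistic, cl$statistic / corr, tolerance = 1e-9)
  expect_equal(we$df1, 2)
  expect_lte(we$df2, cl$df2)
  expect_false(we$df2 == round(we$df2) && we$df2 == cl$df2)

  # with generous replication the two agree within 5% on average under
  # equal population variances (per-draw sample variances still differ)
  rel <- vapply(1:40, function(seed) {
    big <- withr::with_seed(seed, lapply(1:3, function(i) stats::rnorm(100)))
    names(big) <- letters[1:3]
    abs(welch_anova(big)$statistic / one_way_anova(big)$statistic - 1)
  }, numeric(1))
  expect_lt(mean(rel), 0.05)
})

test_that("Levene's test is calibrated under H0 and detects spread shifts", {
  p0 <- vapply(1:60, function(seed) {
    g <- withr::with_seed(seed, lapply(1:3, function(i) stats::rnorm(30)))
    names(g) <- letters[1:3]
    levene_test(g)$p_value
  }, numeric(1))
  expect_gt(mean(p0), 0.4)  # uniform p-values have mean 0.5 under H0

  hits <- vapply(1:30, function(seed) {
    g <- withr::with_seed(1000 + seed, list(
      a = stats::rnorm(50), b = stats::rnorm(50), c = stats::rnorm(50, sd = 10)
    ))
    levene_test(g)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  expect_error(levene_test(list(a = c(1, 1), b = c(2, 2))), "constant")
  res <- levene_test(list(a = c(1, 5, 2), b = c(2, 2, 9)), center = "mean")
  expect_identical(res$center, "mean")
})

test_that("Shapiro-Wilk behaves on normal, skewed and degenerate input", {
  x <- withr::with_seed(5, stats::rnorm(500))
  res <- shapiro_wilk(x)
  expect_gt(res$statistic, 0.98)

  hits <- vapply(1:40, function(seed) {
    shapiro_wilk(withr::with_seed(seed, stats::rexp(100)))$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)), "identical")
})

test_that("Tukey HSD: null pairs, strong effects and t-test dominance", {
  same <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$p_adj, 1, tolerance = 1e-9)

  g <- withr::with_seed(8, list(a = stats::rnorm(10), b = stats::rnorm(10),
                                c = stats::rnorm(10, mean = 10)))
  tk <- tukey_hsd(g)
  lt <- attr(tk, "letters")
  expect_false(lt[["c"]] %in% lt[c("a", "b")])
  expect_identical(lt[["a"]], lt[["b"]])

  # adjusted p never undercuts the unadjusted pairwise t-test
  for (seed in 1:8) {
    g <- withr::with_seed(seed, lapply(1:4, function(i) stats::rnorm(6)))
    names(g) <- letters[1:4]
    tk <- tukey_hsd(g)
    for (r in seq_len(nrow(tk))) {
      praw <- stats::t.test(g[[tk$group1[r]]], g[[tk$group2[r]]],
                            var.equal = TRUE)$p.value
      expect_gte(tk$p_adj[r], praw - 1e-9)
    }
  }

  # adjusted p grows monotonically as the mean difference shrinks to 0
  x <- withr::with_seed(21, stats::rnorm(8))
  p_at <- vapply(c(3, 1.5, 0.5, 0), function(delta) {
    tukey_hsd(list(a = x, b = x + delta, c = x - 1))$p_adj[1]
  }, numeric(1))
  expect_true(all(diff(p_at) >= -1e-9))
  expect_equal(p_at[4], 1, tolerance = 1e-9)
})

test_that("Games-Howell matches Tukey when assumptions hold and stays
           calibrated when they fail", {
  same <- games_howell(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$p_adj, 1, tolerance = 1e-9)
  expect_equal(same$df, 4)  # Welch-Satterthwaite df for equal pair
  expect_error(games_howell(list(a = c(1, 1), b = c(1, 2))),
               "zero-variance")

  for (seed in 1:6) {
    g <- withr::with_seed(seed, lapply(1:3, function(i) stats::rnorm(30)))
    names(g) <- letters[1:3]
    gh <- games_howell(g)
    tk <- tukey_hsd(g)
    expect_lt(max(abs(gh$p_adj - tk$p_adj)), 0.1)
  }

  # type-I error with a 100-fold variance ratio stays near nominal
  rejections <- vapply(1:2000, function(seed) {
    g <- withr::with_seed(seed, list(a = stats::rnorm(10, sd = 1),
                                     b = stats::rnorm(10, sd = 10)))
    games_howell(g)$p_adj < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.075)
})

test_that("assumption gating routes on Levene and records the path", {
  homo <- withr::with_seed(2, lapply(1:4, function(i) stats::rnorm(8)))
  names(homo) <- paste0("s", 1:4)
  r1 <- route_comparison(homo)
  expect_identical(r1$route, "classic+tukey")
  expect_identical(r1$omnibus$variant, "classic")

  hetero <- withr::with_seed(3, list(
    s1 = stats::rnorm(20), s2 = stats::rnorm(20),
    s3 = stats::rnorm(20), s4 = stats::rnorm(20, sd = 25)
  ))
  r2 <- route_comparison(hetero)
  expect_identical(r2$route, "welch+games-howell")
  expect_identical(r2$omnibus$variant, "welch")
  expect_identical(nrow(r2$posthoc), 6L)
  expect_true(all(r2$posthoc$p_adj >= 0 & r2$posthoc$p_adj <= 1))

  # full per-plot pipeline on a simulated chronosequence
  ch <- simulate_chronosequence(paperlike_config(seed = 23))
  cmp <- compare_metric(ch, "richness")
  expect_s3_class(cmp, "group_comparison")
  expect_identical(nrow(cmp$posthoc), 6L)
  expect_identical(sort(unique(c(cmp$posthoc$group1, cmp$posthoc$group2))),
                   sort(site_labels(ch)))
  expect_identical(cmp$omnibus$df1, 3)
  pm <- plot_metrics(ch)
  expect_identical(nrow(pm), 16L)
  expect_true(all(is.finite(pm$a_index)))
})
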