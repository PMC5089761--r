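brute_force_auc <- function(cases, controls) {
  wins <- outer(cases, controls, ">")
  ties <- outer(cases, controls, "==")
  (sum(wins) + 0.5 * sum(ties)) / (length(cases) * length(controls))
}

test_that("roc_auc matches hand-computable cases", {
  expect_identical(roc_auc(c(5, 6, 7), c(1, 2, 3))$auc, 1)
  expect_identical(roc_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)  # midrank ties
  expect_identical(roc_auc(c(3, 1), c(2, 0))$auc, 0.75)       # 3 wins of 4 pairs
  expect_error(roc_auc(numeric(0), c(1)), class = "msrisk_validation_error")
})

test_that("roc_auc equals the brute-force pairwise statistic on random instances", {
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(2:50, 1); n0 <- sample(2:50, 1)
    cases <- sample(round(rnorm(n1, 0.5, 1), 1))     # rounding induces ties
    controls <- sample(round(rnorm(n0, 0, 1), 1))
    r <- roc_auc(cases, controls)
    expect_equal(r$auc, brute_force_auc(cases, controls), tolerance = 1e-12)
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  }
})

test_that("the DeLong interval matches the reference implementation", {
  set.seed(33)
  cases <- rnorm(40, 1); controls <- rnorm(55)
  r <- roc_auc(cases, controls)
  pr <- pROC::roc(c(rep(1, 40), rep(0, 55)), c(cases, controls),
                  quiet = TRUE, direction = "<")
  ci <- pROC::ci.auc(pr, method = "delong")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  expect_equal(r$ci_low, as.numeric(ci[1]), tolerance = 1e-10)
  expect_equal(r$ci_high, as.numeric(ci[3]), tolerance = 1e-10)
})

test_that("the Hanley-McNeil interval is available and sane", {
  set.seed(34)
  r <- roc_auc(rnorm(30, 1), rnorm(30), ci_method = "hanley")
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_true(r$ci_low >= 0 && r$ci_high <= 1)
})

test_that("compare_groups runs ANOVA, Welch pairs with Bonferroni, and normality", {
  d <- tibble::tibble(
    score = c(0, 1, 2, 1, 0, 2, 2, 1, 0),
    group = rep(c("MS", "SIB", "HC"), each = 3)
  )
  cg <- compare_groups(d)                      # identical group means
  expect_equal(cg$anova$f, 0, tolerance = 1e-12)
  expect_equal(cg$pairwise$p_adjusted, pmin(1, 3 * cg$pairwise$p_value),
               tolerance = 1e-12)

  set.seed(55)
  d2 <- tibble::tibble(
    score = c(rnorm(30, 0, 0.1), rnorm(30, 5, 0.1), rnorm(30, 10, 0.1)),
    group = rep(c("HC", "SIB", "MS"), each = 30)
  )
  cg2 <- compare_groups(d2)
  # per-group summaries agree with direct computation
  expect_equal(cg2$groups$mean,
               unname(c(tapply(d2$score, d2$group, mean)[cg2$groups$group])),
               tolerance = 1e-12)
  expect_lt(cg2$anova$p, 1e-10)
  expect_true(all(cg2$pairwise$p_adjusted < 1e-10))
  expect_identical(nrow(cg2$groups), 3L)
  expect_false(anyNA(cg2$groups$shapiro_p))

  expect_error(compare_groups(tibble::tibble(score = 1:4, group = "A")),
               class = "msrisk_validation_error")
})

test_that("tidy and glance methods return the documented shapes", {
  set.seed(56)
  d <- tibble::tibble(score = rnorm(60), group = rep(c("MS", "SIB", "HC"), 20))
  cg <- compare_groups(d)
  expect_identical(nrow(tidy(cg)), 3L)
  expect_named(glance(cg), c("statistic", "df_between", "df_within", "p_value"))
  r <- roc_auc(rnorm(10, 1), rnorm(10))
  expect_identical(nrow(tidy(r)), 1L)
  sp <- septile_partition(rnorm(100))
  expect_identical(nrow(tidy(sp)), 7L)
  expect_equal(sum(tidy(sp)$count), 100L)
})

test_that("septile partitioning uses mean +/- 0.25, 0.75, 1.25 SD", {
  x <- c(-3, -2, -1, 0, 1, 2, 3)
  sp <- septile_partition(x)
  expect_identical(sp$counts, rep(1L, 7))          # symmetric data, symmetric counts
  expect_equal(sp$cutpoints,
               mean(x) + c(-1.25, -0.75, -0.25, 0.25, 0.75, 1.25) * sd(x),
               tolerance = 1e-12)
  # boundary: a score equal to a cutpoint falls in the lower category
  # cutpoints at center 0, scale 8 are -10,-6,-2,2,6,10; 10 == top cutpoint -> 6
  sp2 <- septile_partition(c(0, 10), center = 0, scale = 8)
  expect_identical(sp2$category, c(4L, 6L))
  expect_error(septile_partition(rep(1, 5)), class = "msrisk_validation_error")
  expect_error(septile_partition(1), class = "msrisk_validation_error")
})

test_that("septile categories are invariant under positive affine maps", {
  set.seed(77)
  x <- rnorm(300)
  a <- septile_partition(x)$category
  b <- septile_partition(2.5 * x + 7)$category
  expect_identical(a, b)
})

test_that("the top septile of a Gaussian sample approaches the normal tail mass", {
  set.seed(99)
  sp <- septile_partition(rnorm(100000))
  expect_lt(abs(sp$top_fraction - pnorm(-1.25)), 0.004)
})

test_that("the pooled-null two-proportion formula reproduces the planned n", {
  expect_identical(two_proportion_sample_size(0.15, 0.04, 0.05, 0.8), 111L)
  expect_error(two_proportion_sample_size(0.2, 0.2), class = "msrisk_validation_error")
  expect_error(two_proportion_sample_size(1.2, 0.4), class = "msrisk_validation_error")
})

test_that("sample size is monotone in effect size and power", {
  n_base <- two_proportion_sample_size(0.5, 0.1)
  expect_gte(two_proportion_sample_size(0.4, 0.1), n_base)   # smaller gap
  expect_gte(two_proportion_sample_size(0.5, 0.2), n_base)
  expect_gte(two_proportion_sample_size(0.5, 0.1, power = 0.9), n_base)
  expect_gte(two_proportion_sample_size(0.5, 0.1, alpha = 0.01), n_base)
})

test_that("the returned n achieves the target power under exact binomial enumeration", {
  p1 <- 0.5; p2 <- 0.1
  n <- two_proportion_sample_size(p1, p2, 0.05, 0.8)
  zcrit <- qnorm(0.975)
  pow <- 0
  for (x1 in 0:n) {
    d1 <- dbinom(x1, n, p1)
    for (x2 in 0:n) {
      pp <- (x1 + x2) / (2 * n)
      se <- sqrt(pp * (1 - pp) * 2 / n)
      z <- if (se == 0) 0 else (x1 / n - x2 / n) / se
      if (abs(z) > zcrit) pow <- pow + d1 * dbinom(x2, n, p2)
    }
  }
  expect_gte(pow, 0.8)
})

test_that("the enrolled-cohort bookkeeping reproduces the published composition", {
  cohort <- reference_cohort()
  summ <- cohort_summary(cohort)
  expect_identical(attr(summ, "total_n"), 302L)
  expect_identical(summ$n[summ$group == "MS"], 78L)
  expect_identical(summ$pct_female[summ$group == "MS"], 89.7)
  expect_identical(summ$pct_female[summ$group == "SIB"], 68.6)
  expect_identical(summ$pct_female[summ$group == "HC"], 68)
})
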