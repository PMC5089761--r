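#' Rank-based ROC AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney statistic with midrank ties:
#' `U / (n_cases * n_controls)`, i.e. the probability that a random case
#' scores above a random control (ties counting one half). The confidence
#' interval uses the DeLong placement variance by default
#' (Hanley-McNeil available as an alternative) and is truncated to `[0, 1]`.
#'
#' @param case_scores,control_scores Numeric score vectors; both non-empty.
#' @param ci_method `"delong"` (default) or `"hanley"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `ms_roc`: list with `auc`, `ci_low`, `ci_high`,
#'   `se`, `n_cases`, `n_controls`, `ci_method`, `conf_level`, and the score
#'   vectors (for plotting).
#' @examples
#' roc_auc(c(3, 1), c(2, 0))  # AUC 0.75
#' @export
roc_auc <- function(case_scores, control_scores,
                    ci_method = c("delong", "hanley"), conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  case_scores <- case_scores[!is.na(case_scores)]
  control_scores <- control_scores[!is.na(control_scores)]
  n1 <- length(case_scores); n0 <- length(control_scores)
  if (n1 == 0L || n0 == 0L) abort_validation("both groups must be non-empty.")

  r <- rank(c(case_scores, control_scores))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  if (ci_method == "delong") {
    # placement values: V10_i = P(case_i > random control) with midrank ties
    v10 <- vapply(case_scores, function(x) {
      (sum(x > control_scores) + 0.5 * sum(x == control_scores)) / n0
    }, 1.0)
    v01 <- vapply(control_scores, function(y) {
      (sum(case_scores > y) + 0.5 * sum(case_scores == y)) / n1
    }, 1.0)
    s10 <- if (n1 > 1) var(v10) else 0
    s01 <- if (n0 > 1) var(v01) else 0
    se <- sqrt(s10 / n1 + s01 / n0)
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      auc = auc,
      ci_low = max(0, auc - z * se),
      ci_high = min(1, auc + z * se),
      se = se,
      n_cases = n1, n_controls = n0,
      ci_method = ci_method, conf_level = conf_level,
      case_scores = case_scores, control_scores = control_scores
    ),
    class = "ms_roc"
  )
}

#' @export
print.ms_roc <- function(x, ...) {
  cat(sprintf("ROC AUC: %.3f (%d%% CI %.3f-%.3f, %s), %d cases vs %d controls\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$ci_method, x$n_cases, x$n_controls))
  invisible(x)
}

#' Compare risk scores between cohort groups
#'
#' Classical one-way ANOVA across groups, Welch two-sample t-tests for every
#' pair with Bonferroni adjustment (`min(1, n_pairs * p)`), and a
#' Shapiro-Wilk normality check within each group.
#'
#' @param data Data frame of scores.
#' @param score,group Columns of `data` holding the numeric score and the
#'   group label (tidy evaluation; defaults `score` and `group`).
#' @return An object of class `ms_group_comparison`: list with `groups`
#'   (n/mean/sd/shapiro_p per group), `anova` (F, df, p), and `pairwise`
#'   (estimate, raw and Bonferroni-adjusted p per pair).
#' @examples
#' coh <- simulate_cohort(n_probands = 30, n_siblings = 30, n_controls = 30,
#'                        seed = 2)
#' score_cohort(coh$phenotypes, coh$genotypes) %>% compare_groups()
#' @export
compare_groups <- function(data, score = score, group = group) {
  score <- dplyr::pull(data, {{ score }})
  group <- as.character(dplyr::pull(data, {{ group }}))
  ok <- !is.na(score) & !is.na(group)
  score <- score[ok]; group <- group[ok]
  levels_ <- unique(group)
  if (length(levels_) < 2L) abort_validation("need at least 2 groups to compare.")
  sizes <- table(group)
  if (any(sizes < 2L)) abort_validation("every group needs >= 2 observations.")

  by_group <- split(score, factor(group, levels = levels_))
  groups <- tibble::tibble(
    group = levels_,
    n = unname(vapply(by_group, length, 1L)),
    mean = unname(vapply(by_group, mean, 1.0)),
    sd = unname(vapply(by_group, sd, 1.0)),
    shapiro_p = unname(vapply(by_group, function(x) {
      if (length(x) >= 3L && length(x) <= 5000L && sd(x) > 0) {
        shapiro.test(x)$p.value
      } else NA_real_
    }, 1.0))
  )

  fit <- aov(score ~ factor(group))
  an <- summary(fit)[[1]]
  anova_res <- list(
    f = an[["F value"]][1],
    df_between = an[["Df"]][1],
    df_within = an[["Df"]][2],
    p = an[["Pr(>F)"]][1]
  )

  pairs <- utils::combn(levels_, 2L)
  n_pairs <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tt <- t.test(score[group == a], score[group == b])
    tibble::tibble(
      group1 = a, group2 = b,
      estimate = unname(diff(rev(tt$estimate))),
      statistic = unname(tt$statistic),
      p_value = tt$p.value,
      p_adjusted = min(1, n_pairs * tt$p.value)
    )
  })

  structure(list(groups = groups, anova = anova_res, pairwise = pairwise),
            class = "ms_group_comparison")
}

#' @export
print.ms_group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$f, x$anova$p))
  print(x$groups)
  cat("Pairwise Welch t-tests (Bonferroni-adjusted):\n")
  print(x$pairwise)
  invisible(x)
}

#' Partition scores into septiles around the mean
#'
#' Splits a score distribution into 7 categories at the six cutpoints
#' `mean + c(-1.25, -0.75, -0.25, 0.25, 0.75, 1.25) * sd` (sample SD, n-1);
#' a score equal to a cutpoint falls in the lower category. Category 7 is the
#' high-risk tail; for a Gaussian score its expected occupancy is
#' `pnorm(-1.25)`, about 10.6%.
#'
#' @param scores Numeric vector, `n >= 2`, positive SD.
#' @param center,scale Optional externally supplied mean and SD (e.g. to
#'   partition one group on another group's distribution); default: computed
#'   from `scores`.
#' @return An object of class `ms_septiles`: list with `cutpoints` (6),
#'   `category` (integer 1..7 per score), `counts`, `top_fraction`, `mean`,
#'   `sd`.
#' @export
septile_partition <- function(scores, center = NULL, scale = NULL) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2L) abort_validation("need at least 2 scores.")
  m <- center %||% mean(scores)
  s <- scale %||% sd(scores)
  if (!is.finite(s) || s <= 0) abort_validation("score SD must be positive.")
  cutpoints <- m + c(-1.25, -0.75, -0.25, 0.25, 0.75, 1.25) * s
  category <- as.integer(cut(scores, c(-Inf, cutpoints, Inf), right = TRUE,
                             labels = FALSE))
  structure(
    list(
      cutpoints = cutpoints,
      category = category,
      counts = tabulate(category, nbins = 7L),
      top_fraction = mean(category == 7L),
      mean = m, sd = s, n = length(scores)
    ),
    class = "ms_septiles"
  )
}

#' @export
print.ms_septiles <- function(x, ...) {
  cat(sprintf("Septile partition (mean %.3f, SD %.3f, n %d)\n", x$mean, x$sd, x$n))
  cat("counts:", x$counts, "\n")
  cat(sprintf("top-septile fraction: %.4f\n", x$top_fraction))
  invisible(x)
}

#' Two-proportion sample size (pooled-null normal approximation)
#'
#' Per-group sample size for detecting a difference between two proportions
#' with a two-sided z test: pooled variance under the null, unpooled under
#' the alternative,
#' `n = (z_{1-a/2} * sqrt(2 pbar (1-pbar)) + z_{power} * sqrt(p1(1-p1) + p2(1-p2)))^2 / (p1-p2)^2`,
#' rounded up.
#'
#' @param p1,p2 The two proportions, both in (0, 1) and distinct.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @return Integer sample size per group.
#' @examples
#' two_proportion_sample_size(0.15, 0.04)  # 111
#' @export
two_proportion_sample_size <- function(p1, p2, alpha = 0.05, power = 0.8) {
  for (v in list(p1 = p1, p2 = p2, alpha = alpha, power = power)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1) {
      abort_validation("p1, p2, alpha and power must all lie strictly in (0, 1).")
    }
  }
  if (p1 == p2) abort_validation("p1 and p2 must differ (sample size undefined).")
  z_a <- qnorm(1 - alpha / 2)
  z_b <- qnorm(power)
  pbar <- (p1 + p2) / 2
  n <- ((z_a * sqrt(2 * pbar * (1 - pbar)) +
           z_b * sqrt(p1 * (1 - p1) + p2 * (1 - p2))) / (p1 - p2))^2
  as.integer(ceiling(n))
}

#' Study cohort composition
#'
#' `reference_cohort()` expands the shipped per-group male/female counts of
#' the enrolled study population (78 probands with MS, 121 unaffected
#' siblings, 103 healthy controls) into a participant-level table;
#' `cohort_summary()` recomputes group sizes and female percentages from any
#' participant-level table with `group` and `sex` columns.
#'
#' @return `reference_cohort()`: a tibble with `participant_id`, `group`,
#'   `sex` (one row per enrolled participant). `cohort_summary()`: a tibble
#'   with `group`, `n`, `n_female`, `pct_female` plus an attribute
#'   `total_n`.
#' @export
reference_cohort <- function() {
  comp <- jsonlite::fromJSON(msrisk_extdata("study_cohort_composition.json"))$groups
  rows <- purrr::pmap_dfr(comp, function(group, n_male, n_female) {
    tibble::tibble(group = group, sex = c(rep("M", n_male), rep("F", n_female)))
  })
  dplyr::mutate(rows,
                participant_id = sprintf("%s%03d", .data$group, dplyr::row_number()),
                .by = "group") %>%
    dplyr::select("participant_id", "group", "sex")
}

#' @param data Participant-level data frame with `group` and `sex` columns.
#' @rdname reference_cohort
#' @export
cohort_summary <- function(data) {
  out <- data %>%
    dplyr::summarise(
      n = dplyr::n(),
      n_female = sum(.data$sex == "F"),
      .by = "group"
    ) %>%
    dplyr::mutate(pct_female = round(100 * .data$n_female / .data$n, 1))
  attr(out, "total_n") <- sum(out$n)
  out
}
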