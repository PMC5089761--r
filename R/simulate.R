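#' Default exposure model for the cohort simulator
#'
#' Prevalences and distributional parameters for the simulated environmental
#' exposures: female fraction 0.5; infectious mononucleosis history 6%;
#' ever-smoking 40% (30% of ever-smokers currently smoking, with cotinine
#' well above the 3.08 ng/ml cut-off); uniform birth months; anti-EBNA-1 IgG
#' titre lognormal(meanlog log(50), sdlog 1.2) with an assay limit of
#' detection of 5 units; serum 25-OHvD with an annual cosinor (mesor 70
#' nmol/l, amplitude 15, residual SD 15).
#'
#' @return A named list of exposure parameters.
#' @export
exposure_defaults <- function() {
  list(
    p_female = 0.5,
    p_im = 0.06,
    p_smoke_ever = 0.4,
    p_current_given_ever = 0.3,
    month_probs = rep(1 / 12, 12L),
    ebna_meanlog = log(50), ebna_sdlog = 1.2, ebna_lod = 5,
    vitd_mesor = 70, vitd_amplitude = 15, vitd_sd = 15,
    cotinine_smoker_meanlog = log(150), cotinine_smoker_sdlog = 0.5,
    cotinine_nonsmoker_rate = 2
  )
}

# named weight-lookup vectors for fast vectorised truth scoring
env_weight_vectors <- function(weights) {
  vec <- function(factor_id) {
    sub <- weights[weights$factor_id == factor_id, ]
    setNames(sub$weight, sub$level)
  }
  list(
    sex = vec("sex"), month = vec("birth_month"), im = vec("im_history"),
    smoking = vec("smoking"), ebna = vec("ebna1"), vitd = vec("vitd"),
    hla = vec("hla_drb1_1501")
  )
}

draw_environment <- function(n, exposure) {
  if (n == 0L) return(draw_environment(1L, exposure)[0L, ])
  e <- exposure
  sex <- ifelse(runif(n) < e$p_female, "F", "M")
  birth_month <- sample.int(12L, n, replace = TRUE, prob = e$month_probs)
  im <- runif(n) < e$p_im
  smoke_report <- runif(n) < e$p_smoke_ever
  current <- smoke_report & runif(n) < e$p_current_given_ever
  cotinine <- ifelse(
    current,
    rlnorm(n, e$cotinine_smoker_meanlog, e$cotinine_smoker_sdlog),
    stats::rexp(n, rate = e$cotinine_nonsmoker_rate)
  )
  sample_day <- sample.int(365L, n, replace = TRUE)
  vitd_base <- pmax(1, rnorm(n, e$vitd_mesor, e$vitd_sd))     # deseasonalised truth
  vitd <- pmax(1, vitd_base + e$vitd_amplitude * sin(2 * pi * sample_day / 365.25))
  ebna <- rlnorm(n, e$ebna_meanlog, e$ebna_sdlog)

  ebna_cuts <- stats::qlnorm(c(0.2, 0.4, 0.6, 0.8), e$ebna_meanlog, e$ebna_sdlog)
  ebna_level <- as.character(cut(ebna, c(-Inf, ebna_cuts, Inf),
                                 labels = paste0("Q", 1:5), right = TRUE))
  ebna_level[ebna < e$ebna_lod] <- "undetectable"

  tibble::tibble(
    sex = sex, birth_month = birth_month, im_history = im,
    smoking_self_report = smoke_report, cotinine_ng_ml = round(cotinine, 2),
    ebna1_titre = round(ebna, 1), vitd_nmol_l = round(vitd, 1),
    sample_day = sample_day,
    sex_level = sex,
    month_level = as.character(birth_month),
    im_level = ifelse(im, "yes", "no"),
    smoking_level = ifelse(smoke_report | cotinine > 3.08, "ever", "never"),
    ebna_level = ebna_level,
    vitd_level = assign_vitd_quintile(vitd_base)
  )
}

env_truth_score <- function(env, wv, include_vitd = TRUE) {
  s <- unname(wv$sex[env$sex_level]) +
    unname(wv$month[env$month_level]) +
    unname(wv$im[env$im_level]) +
    unname(wv$smoking[env$smoking_level]) +
    unname(wv$ebna[env$ebna_level])
  if (include_vitd) s <- s + unname(wv$vitd[env$vitd_level])
  s
}

draw_founder_genotypes <- function(n, freqs) {
  matrix(rbinom(n * length(freqs), 2L, rep(freqs, each = n)),
         nrow = n, ncol = length(freqs), dimnames = list(NULL, names(freqs)))
}

transmit <- function(mother, father) {
  # one allele from each parent, Mendelian
  dims <- dim(mother)
  child <- rbinom(prod(dims), 1L, as.vector(mother) / 2) +
    rbinom(prod(dims), 1L, as.vector(father) / 2)
  matrix(child, nrow = dims[1], dimnames = dimnames(mother))
}

# SNP effect sizes are taken from the weights ledger (so a modified or nulled
# ledger changes the generative model), falling back to the panel's own
# weights for rsIDs the ledger does not carry
snp_weight_vector <- function(weights, panel) {
  snps <- panel$snp_id[!panel$is_hla_tag]
  w <- setNames(panel$weight[match(snps, panel$snp_id)], snps)
  in_ledger <- weights$category == "snp_panel"
  hit <- intersect(snps, weights$factor_id[in_ledger])
  w[hit] <- weights$weight[in_ledger][match(hit, weights$factor_id[in_ledger])]
  w
}

genetic_truth_score <- function(geno, wv, snp_w, dosage_model,
                                genetic_scope = "full_genetic") {
  tag <- hla_tag_snp()
  copies <- geno[, tag]
  s <- ifelse(copies == 1, unname(wv$hla["heterozygote"]),
              ifelse(copies == 2, unname(wv$hla["homozygote"]), 0))
  if (genetic_scope == "full_genetic") {
    g <- geno[, names(snp_w), drop = FALSE]
    dose <- if (dosage_model == "carriage") (g >= 1) + 0 else g
    s <- s + as.vector(dose %*% snp_w)
  }
  s
}

calibrate_baseline <- function(liab_sample, target_prevalence) {
  f <- function(b) mean(plogis(b + liab_sample)) - target_prevalence
  uniroot(f, c(-60, 20), tol = 1e-10)$root
}

#' Simulate a proband/sibling/control cohort
#'
#' Generates a three-group family cohort under the additive log10-odds model
#' itself: environmental exposures are drawn independently at configured
#' prevalences; founder genotypes are drawn binomial(2, freq) per SNP
#' (Hardy-Weinberg); each proband and their siblings inherit genotypes by
#' Mendelian transmission from a shared simulated parent pair. Disease status
#' follows the logistic model `P(MS) = plogis(baseline + ln(10) * score)`, so
#' the generative odds ratios equal the ledger's odds ratios. Probands are
#' sampled conditional on being affected (rejection sampling), siblings and
#' controls conditional on being unaffected.
#'
#' @param n_probands,n_siblings,n_controls Group sizes (defaults: the
#'   enrolled study sizes 78 / 121 / 103).
#' @param weights An `ms_weight_table` used as the generative effect model.
#' @param panel An [snp_panel()].
#' @param allele_freqs Named vector of risk-allele frequencies for the panel
#'   SNPs; `NULL` (default) uses 0.15 for the HLA tag and draws the others
#'   from Uniform(0.2, 0.8) under the run's RNG.
#' @param exposure Exposure model, see [exposure_defaults()].
#' @param target_prevalence Population disease probability used to calibrate
#'   the baseline (default 0.005); ignored when `baseline_log_odds` is given.
#' @param baseline_log_odds Baseline natural-log odds of disease; `NULL`
#'   (default) calibrates it to `target_prevalence` by Monte Carlo.
#' @param dosage_model `"carriage"` or `"additive"` SNP dosage in the
#'   generative score.
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called so
#'   runs are reproducible.
#' @param max_batches Safety bound on rejection-sampling batches; exceeded
#'   (e.g. prevalence numerically 0) raises an error.
#' @return An object of class `ms_cohort`: list with `phenotypes` (schema of
#'   [read_phenotypes()] plus `family_id`), `genotypes` (`participant_id` +
#'   one column per panel SNP), and `truth` (per-participant true score,
#'   liability and disease probability; true encoded levels; allele
#'   frequencies; baseline; exposure model; dosage model).
#' @examples
#' coh <- simulate_cohort(n_probands = 15, n_siblings = 15, n_controls = 15,
#'                        seed = 42)
#' dplyr::count(coh$phenotypes, group)
#' @export
simulate_cohort <- function(n_probands = 78, n_siblings = 121, n_controls = 103,
                            weights = risk_weight_table(), panel = snp_panel(),
                            allele_freqs = NULL,
                            exposure = exposure_defaults(),
                            target_prevalence = 0.005,
                            baseline_log_odds = NULL,
                            dosage_model = c("carriage", "additive"),
                            seed = NULL, max_batches = 2000L) {
  dosage_model <- match.arg(dosage_model)
  if (n_probands < 1 && n_siblings > 0) {
    abort_validation("siblings require at least one proband family.")
  }
  if (!is.null(seed)) set.seed(seed)
  wv <- env_weight_vectors(weights)

  if (is.null(allele_freqs)) {
    allele_freqs <- setNames(runif(nrow(panel), 0.2, 0.8), panel$snp_id)
    allele_freqs[hla_tag_snp()] <- 0.15
  }
  if (is.null(names(allele_freqs)) ||
      !all(panel$snp_id %in% names(allele_freqs))) {
    abort_validation("`allele_freqs` must be named with every panel rsID.")
  }
  if (any(allele_freqs <= 0 | allele_freqs >= 1)) {
    abort_validation("allele frequencies must lie strictly in (0, 1).")
  }
  allele_freqs <- allele_freqs[panel$snp_id]

  snp_w <- snp_weight_vector(weights, panel)
  total_score <- function(env, geno) {
    env_truth_score(env, wv, include_vitd = TRUE) +
      genetic_truth_score(geno, wv, snp_w, dosage_model)
  }

  if (is.null(baseline_log_odds)) {
    ncal <- 20000L
    env <- draw_environment(ncal, exposure)
    geno <- draw_founder_genotypes(ncal, allele_freqs)
    baseline_log_odds <- calibrate_baseline(
      log(10) * total_score(env, geno), target_prevalence
    )
  }
  b <- baseline_log_odds

  # --- probands: rejection-sample affected children of simulated parent pairs
  acc_env <- list(); acc_geno <- list(); acc_mother <- list(); acc_father <- list()
  got <- 0L; batches <- 0L
  while (got < n_probands) {
    batches <- batches + 1L
    if (batches > max_batches) {
      abort_validation("conditional proband sampling infeasible at this prevalence.")
    }
    need <- n_probands - got
    bsz <- as.integer(min(50000, max(500, ceiling(1.5 * need / max(target_prevalence, 1e-6)))))
    mother <- draw_founder_genotypes(bsz, allele_freqs)
    father <- draw_founder_genotypes(bsz, allele_freqs)
    child <- transmit(mother, father)
    env <- draw_environment(bsz, exposure)
    p <- plogis(b + log(10) * total_score(env, child))
    hit <- which(runif(bsz) < p)
    if (length(hit)) {
      hit <- hit[seq_len(min(length(hit), need))]
      acc_env[[batches]] <- env[hit, ]
      acc_geno[[batches]] <- child[hit, , drop = FALSE]
      acc_mother[[batches]] <- mother[hit, , drop = FALSE]
      acc_father[[batches]] <- father[hit, , drop = FALSE]
      got <- got + length(hit)
    }
  }
  if (n_probands > 0) {
    pro_env <- dplyr::bind_rows(acc_env)
    pro_geno <- do.call(rbind, acc_geno)
    mothers <- do.call(rbind, acc_mother)
    fathers <- do.call(rbind, acc_father)
  } else {
    pro_env <- draw_environment(0L, exposure)
    pro_geno <- mothers <- fathers <- draw_founder_genotypes(0L, allele_freqs)
  }

  # --- siblings: Mendelian transmission from the proband's parents, unaffected
  if (n_siblings > 0) {
    fam <- rep_len(seq_len(n_probands), n_siblings)
    sib_env <- NULL; sib_geno <- NULL
    pending <- seq_len(n_siblings)
    sib_env_acc <- vector("list", n_siblings)
    sib_geno_acc <- vector("list", n_siblings)
    tries <- 0L
    while (length(pending)) {
      tries <- tries + 1L
      if (tries > 100L) {
        abort_validation("conditional sibling sampling infeasible.")
      }
      idx <- fam[pending]
      child <- transmit(mothers[idx, , drop = FALSE], fathers[idx, , drop = FALSE])
      env <- draw_environment(length(pending), exposure)
      p <- plogis(b + log(10) * total_score(env, child))
      keep <- runif(length(pending)) >= p      # unaffected
      for (k in which(keep)) {
        sib_env_acc[[pending[k]]] <- env[k, ]
        sib_geno_acc[[pending[k]]] <- child[k, , drop = FALSE]
      }
      pending <- pending[!keep]
    }
    sib_env <- dplyr::bind_rows(sib_env_acc)
    sib_geno <- do.call(rbind, sib_geno_acc)
  } else {
    fam <- integer(0)
    sib_env <- draw_environment(0L, exposure)
    sib_geno <- draw_founder_genotypes(0L, allele_freqs)
  }

  # --- controls: unrelated founders, unaffected
  acc_env <- list(); acc_geno <- list(); got <- 0L; batches <- 0L
  while (got < n_controls) {
    batches <- batches + 1L
    if (batches > max_batches) {
      abort_validation("conditional control sampling infeasible.")
    }
    need <- n_controls - got
    bsz <- as.integer(min(50000, max(500, ceiling(1.1 * need))))
    geno <- draw_founder_genotypes(bsz, allele_freqs)
    env <- draw_environment(bsz, exposure)
    p <- plogis(b + log(10) * total_score(env, geno))
    hit <- which(runif(bsz) >= p)
    hit <- hit[seq_len(min(length(hit), need))]
    if (length(hit)) {
      acc_env[[batches]] <- env[hit, ]
      acc_geno[[batches]] <- geno[hit, , drop = FALSE]
      got <- got + length(hit)
    }
  }
  hc_env <- dplyr::bind_rows(acc_env)
  hc_geno <- do.call(rbind, acc_geno)

  env_all <- dplyr::bind_rows(pro_env, sib_env, hc_env)
  geno_all <- rbind(pro_geno, sib_geno, hc_geno)
  group <- c(rep("MS", n_probands), rep("SIB", n_siblings), rep("HC", n_controls))
  ids <- c(sprintf("MS%04d", seq_len(n_probands)),
           sprintf("SIB%04d", seq_len(n_siblings)),
           sprintf("HC%04d", seq_len(n_controls)))
  family_id <- c(sprintf("FAM%04d", seq_len(n_probands)),
                 sprintf("FAM%04d", fam),
                 rep(NA_character_, n_controls))

  score_true <- total_score(env_all, geno_all)
  eta <- b + log(10) * score_true

  phenotypes <- dplyr::bind_cols(
    tibble::tibble(participant_id = ids, group = group, family_id = family_id),
    env_all[, c("sex", "birth_month", "im_history", "smoking_self_report",
                "cotinine_ng_ml", "ebna1_titre", "vitd_nmol_l", "sample_day")]
  )
  genotypes <- dplyr::bind_cols(
    tibble::tibble(participant_id = ids),
    tibble::as_tibble(geno_all)
  )
  truth <- list(
    participants = tibble::tibble(
      participant_id = ids, group = group, family_id = family_id,
      score = score_true, liability = eta, prob_disease = plogis(eta)
    ),
    encoded = dplyr::bind_cols(
      tibble::tibble(participant_id = ids),
      env_all[, c("sex_level", "month_level", "im_level", "smoking_level",
                  "ebna_level", "vitd_level")]
    ),
    allele_freqs = allele_freqs,
    baseline_log_odds = b,
    target_prevalence = target_prevalence,
    exposure = exposure,
    dosage_model = dosage_model
  )
  structure(list(phenotypes = phenotypes, genotypes = genotypes, truth = truth),
            class = "ms_cohort")
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat("Simulated MS family cohort:",
      paste(dplyr::count(x$phenotypes, .data$group)$n,
            dplyr::count(x$phenotypes, .data$group)$group, collapse = ", "),
      "\n")
  cat(sprintf("baseline log-odds %.3f (target prevalence %.4g)\n",
              x$truth$baseline_log_odds, x$truth$target_prevalence))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `phenotypes.csv` (phenotype schema + `family_id`),
#' `genotypes.tsv` (dosage TSV readable by [read_genotypes()]), and
#' `truth.json` (generative parameters and per-participant latent values).
#'
#' @param cohort An `ms_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   progress = FALSE)
  geno <- cohort$genotypes
  readr::write_tsv(geno, file.path(dir, "genotypes.tsv"), progress = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(
      baseline_log_odds = truth$baseline_log_odds,
      target_prevalence = truth$target_prevalence,
      dosage_model = truth$dosage_model,
      allele_freqs = as.list(truth$allele_freqs),
      exposure = truth$exposure,
      participants = truth$participants
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Recover generative effects from a simulated cohort
#'
#' Validation harness: fits a logistic regression of disease status (proband
#' vs healthy control; siblings are excluded because their genotypes are
#' correlated with their proband's) on indicator variables for every
#' non-reference factor level and on SNP carriage/dosage indicators, and
#' compares each estimated natural-log odds ratio with its generative value
#' `ln(10) * weight`. Under case-control sampling the slope estimates are
#' consistent (only the intercept absorbs the sampling fractions).
#'
#' @param cohort An `ms_cohort` from [simulate_cohort()].
#' @param weights The generative `ms_weight_table` (defaults to the shipped
#'   ledger).
#' @param panel An [snp_panel()].
#' @param conf_level Wald confidence level (default 0.95).
#' @return A tibble with one row per modelled factor: `term`,
#'   `weight_log10`, `generative` (natural-log scale), `estimate`, `se`,
#'   `conf_low`, `conf_high`, `covered`, `separation`.
#' @export
recover_parameters <- function(cohort, weights = risk_weight_table(),
                               panel = snp_panel(), conf_level = 0.95) {
  keep <- cohort$phenotypes$group %in% c("MS", "HC")
  enc <- cohort$truth$encoded[keep, ]
  geno <- cohort$genotypes[keep, ]
  y <- as.integer(cohort$phenotypes$group[keep] == "MS")
  if (length(unique(y)) < 2L) {
    abort_validation("parameter recovery needs both probands and controls.")
  }

  wv <- env_weight_vectors(weights)
  X <- list(
    sex_F = as.integer(enc$sex_level == "F"),
    im_yes = as.integer(enc$im_level == "yes"),
    smoking_ever = as.integer(enc$smoking_level == "ever"),
    month_4 = as.integer(enc$month_level == "4"),
    month_5 = as.integer(enc$month_level == "5"),
    month_10 = as.integer(enc$month_level == "10"),
    month_11 = as.integer(enc$month_level == "11"),
    ebna_undetectable = as.integer(enc$ebna_level == "undetectable"),
    ebna_Q3 = as.integer(enc$ebna_level == "Q3"),
    ebna_Q4 = as.integer(enc$ebna_level == "Q4"),
    ebna_Q5 = as.integer(enc$ebna_level == "Q5"),
    vitd_Q5 = as.integer(enc$vitd_level == "Q5"),
    hla_het = as.integer(geno[[hla_tag_snp()]] == 1),
    hla_hom = as.integer(geno[[hla_tag_snp()]] == 2)
  )
  gen_w <- c(
    wv$sex["F"], wv$im["yes"], wv$smoking["ever"],
    wv$month["4"], wv$month["5"], wv$month["10"], wv$month["11"],
    wv$ebna["undetectable"], wv$ebna["Q3"], wv$ebna["Q4"], wv$ebna["Q5"],
    wv$vitd["Q5"], wv$hla["heterozygote"], wv$hla["homozygote"]
  )
  snp_w <- snp_weight_vector(weights, panel)
  snps <- names(snp_w)
  dm <- cohort$truth$dosage_model
  for (s in snps) {
    X[[s]] <- if (dm == "carriage") as.integer(geno[[s]] >= 1) else geno[[s]]
  }
  gen_w <- c(gen_w, unname(snp_w))

  df <- as.data.frame(X)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  terms <- names(X)
  est <- sm[terms, "Estimate"]
  se <- sm[terms, "Std. Error"]
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = terms,
    weight_log10 = unname(gen_w),
    generative = log(10) * unname(gen_w),
    estimate = unname(est),
    se = unname(se),
    conf_low = unname(est - z * se),
    conf_high = unname(est + z * se),
    covered = .data$conf_low <= .data$generative & .data$generative <= .data$conf_high,
    separation = unname(se) > 10 | abs(unname(est)) > 15
  )
}
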