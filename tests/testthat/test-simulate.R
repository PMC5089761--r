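test_that("simulation is fully reproducible under a seed", {
  a <- simulate_cohort(n_probands = 10, n_siblings = 15, n_controls = 12, seed = 123)
  b <- simulate_cohort(n_probands = 10, n_siblings = 15, n_controls = 12, seed = 123)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth$participants, b$truth$participants)
})

test_that("family structure links every sibling to exactly one proband", {
  coh <- simulate_cohort(n_probands = 10, n_siblings = 25, n_controls = 5, seed = 6)
  ph <- coh$phenotypes
  sib_fams <- ph$family_id[ph$group == "SIB"]
  pro_fams <- ph$family_id[ph$group == "MS"]
  expect_true(all(sib_fams %in% pro_fams))
  expect_true(all(is.na(ph$family_id[ph$group == "HC"])))
  expect_identical(anyDuplicated(pro_fams), 0L)
})

test_that("founder genotype frequencies match the configured allele frequencies", {
  pan <- snp_panel()
  freqs <- setNames(rep(0.3, nrow(pan)), pan$snp_id)
  coh <- simulate_cohort(n_probands = 2, n_siblings = 0, n_controls = 600,
                         allele_freqs = freqs, seed = 14)
  geno <- as.matrix(coh$genotypes[coh$phenotypes$group == "HC", pan$snp_id])
  obs <- colMeans(geno) / 2
  # binomial SE at n=600, 2 alleles each: sqrt(.3*.7/1200) ~ 0.013
  expect_true(all(abs(obs - 0.3) < 0.055))
})

test_that("proband-sibling genotype correlation reflects 50% allele sharing", {
  coh <- simulate_cohort(n_probands = 120, n_siblings = 120, n_controls = 2,
                         seed = 15)
  ph <- coh$phenotypes
  pro <- ph$participant_id[ph$group == "MS"]
  sib <- ph$participant_id[ph$group == "SIB"]
  fam_of <- setNames(ph$family_id, ph$participant_id)
  pro_by_fam <- setNames(pro, fam_of[pro])
  pan <- snp_panel()
  gm <- as.matrix(coh$genotypes[, pan$snp_id])
  rownames(gm) <- coh$genotypes$participant_id
  cors <- vapply(pan$snp_id, function(s) {
    x <- gm[pro_by_fam[fam_of[sib]], s]
    y <- gm[sib, s]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }, 1.0)
  expect_equal(mean(cors, na.rm = TRUE), 0.5, tolerance = 0.08)
})

test_that("a null effect model yields indistinguishable groups", {
  wt <- risk_weight_table()
  null_wt <- wt
  null_wt$weight <- 0
  coh <- simulate_cohort(n_probands = 2000, n_siblings = 0, n_controls = 2000,
                         weights = null_wt, seed = 16)
  sc <- suppressWarnings(score_cohort(coh$phenotypes, coh$genotypes, ebna_lod = 5))
  r <- roc_auc(sc$score[sc$group == "MS"], sc$score[sc$group == "HC"])
  expect_lt(abs(r$auc - 0.5), 0.02)
})

test_that("simulated groups are ordered probands > siblings > controls", {
  coh <- simulate_cohort(n_probands = 400, n_siblings = 400, n_controls = 400,
                         seed = 17)
  tr <- coh$truth$participants
  m <- tapply(tr$score, tr$group, mean)
  expect_gt(m[["MS"]], m[["SIB"]])
  expect_gt(m[["SIB"]], m[["HC"]])
})

test_that("logistic recovery centres on the generative effects", {
  coh <- simulate_cohort(n_probands = 1500, n_siblings = 0, n_controls = 1500,
                         seed = 18, target_prevalence = 0.02)
  rec <- recover_parameters(coh)
  expect_gte(mean(rec$covered), 0.85)
  expect_false(any(rec$separation))
  # the HLA heterozygote effect specifically is recovered within its CI
  het <- rec[rec$term == "hla_het", ]
  expect_true(het$conf_low <= het$generative && het$generative <= het$conf_high)
})

test_that("null generative weights give estimates centred on zero", {
  wt <- risk_weight_table()
  wt$weight <- 0
  coh <- simulate_cohort(n_probands = 800, n_siblings = 0, n_controls = 800,
                         weights = wt, seed = 19)
  rec <- recover_parameters(coh, weights = wt)
  expect_gte(mean(rec$covered), 0.85)          # CIs cover 0
  expect_lt(abs(mean(rec$estimate)), 0.1)
})

test_that("confidence-interval width shrinks like one over root n", {
  coh1 <- simulate_cohort(n_probands = 800, n_siblings = 0, n_controls = 800,
                          seed = 20, target_prevalence = 0.02)
  coh2 <- simulate_cohort(n_probands = 1600, n_siblings = 0, n_controls = 1600,
                          seed = 21, target_prevalence = 0.02)
  w1 <- stats::median(recover_parameters(coh1)$se)
  w2 <- stats::median(recover_parameters(coh2)$se)
  expect_equal(w1 / w2, sqrt(2), tolerance = 0.2 * sqrt(2))
})

test_that("infeasible conditional sampling errors after bounded retries", {
  expect_error(
    simulate_cohort(n_probands = 3, n_siblings = 0, n_controls = 0,
                    baseline_log_odds = -200, seed = 22, max_batches = 3L),
    class = "msrisk_validation_error"
  )
})

test_that("cohorts round-trip through the on-disk formats", {
  coh <- simulate_cohort(n_probands = 4, n_siblings = 4, n_controls = 4, seed = 23)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  ph <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  gt <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_identical(ph$participant_id, coh$phenotypes$participant_id)
  expect_identical(as.data.frame(gt), as.data.frame(coh$genotypes))
  sc1 <- suppressWarnings(score_cohort(coh$phenotypes, coh$genotypes, ebna_lod = 5))
  sc2 <- suppressWarnings(score_cohort(ph, gt, ebna_lod = 5))
  expect_equal(sc1$score, sc2$score, tolerance = 1e-12)
})

test_that("adding genetic information to the score increases discrimination", {
  coh <- simulate_cohort(n_probands = 1000, n_siblings = 0, n_controls = 1000,
                         seed = 24)
  sc_full <- suppressWarnings(score_cohort(coh$phenotypes, coh$genotypes, ebna_lod = 5))
  sc_env <- suppressWarnings(score_cohort(coh$phenotypes, genotypes = NULL, ebna_lod = 5))
  auc_full <- roc_auc(sc_full$score[sc_full$group == "MS"],
                      sc_full$score[sc_full$group == "HC"])$auc
  auc_env <- roc_auc(sc_env$score[sc_env$group == "MS"],
                     sc_env$score[sc_env$group == "HC"])$auc
  expect_gt(auc_full, auc_env)
  expect_gt(auc_full, 0.5)
})
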