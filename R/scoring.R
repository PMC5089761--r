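#' The four score variants
#'
#' The score is reported in four variants: genetic scope restricted to
#' HLA-DRB1*1501 zygosity only or extended to the full SNP panel, each with
#' and without the serum 25-OHvD contribution (vitamin D status is heavily
#' confounded by supplementation in cases, so the score is also evaluated
#' without it).
#'
#' @return A tibble with columns `variant`, `genetic_scope`, `include_vitd`.
#' @export
score_variants <- function() {
  tidyr::expand_grid(
    genetic_scope = c("hla_only", "full_genetic"),
    include_vitd = c(TRUE, FALSE)
  ) %>%
    dplyr::mutate(variant = paste0(
      .data$genetic_scope,
      ifelse(.data$include_vitd, "", "_no_vitd")
    )) %>%
    dplyr::select("variant", "genetic_scope", "include_vitd")
}

resolve_level <- function(weights, factor_id, levels) {
  sub <- weights[weights$factor_id == factor_id, ]
  i <- match(as.character(levels), sub$level)
  if (anyNA(i)) {
    bad <- unique(as.character(levels)[is.na(i)])
    abort_validation(paste0("level(s) ", paste(bad, collapse = ", "),
                            " of factor '", factor_id,
                            "' do not resolve in the weight table."))
  }
  sub$weight[i]
}

#' Score one participant
#'
#' Sums the additive log10-odds contributions for a single participant from
#' encoded factor levels and genotype counts. Absent or missing factors
#' contribute exactly 0.
#'
#' @param encoded One-row tibble (or list) with `sex_level`, `month_level`,
#'   `im_level`, `smoking_level`, `ebna_level`, `vitd_level` as produced by
#'   [encode_phenotypes()].
#' @param hla_copies HLA-DRB1*1501 copies (0/1/2, `NA` scores 0).
#' @param genotypes Optional named vector/one-row tibble of risk-allele
#'   counts for the SNP panel (used when `genetic_scope = "full_genetic"`).
#' @param weights An `ms_weight_table`.
#' @param panel An [snp_panel()].
#' @param genetic_scope `"hla_only"` or `"full_genetic"`.
#' @param include_vitd Include the 25-OHvD contribution (default `TRUE`).
#' @param dosage_model SNP dosage model, `"carriage"` or `"additive"`.
#' @return A list with `score` and `contributions` (tibble of factor_id,
#'   level, weight).
#' @export
compute_score <- function(encoded, hla_copies = NA_integer_, genotypes = NULL,
                          weights = risk_weight_table(), panel = snp_panel(),
                          genetic_scope = c("full_genetic", "hla_only"),
                          include_vitd = TRUE,
                          dosage_model = c("carriage", "additive")) {
  genetic_scope <- match.arg(genetic_scope)
  dosage_model <- match.arg(dosage_model)
  encoded <- as.list(encoded)

  contrib <- tibble::tibble(
    factor_id = c("sex", "birth_month", "im_history", "smoking", "ebna1"),
    level = as.character(c(encoded$sex_level, encoded$month_level,
                           encoded$im_level, encoded$smoking_level,
                           encoded$ebna_level))
  )
  if (include_vitd) {
    contrib <- dplyr::bind_rows(contrib,
      tibble::tibble(factor_id = "vitd", level = as.character(encoded$vitd_level)))
  }
  contrib$weight <- vapply(seq_len(nrow(contrib)), function(i) {
    resolve_level(weights, contrib$factor_id[i], contrib$level[i])
  }, 1.0)

  hla <- tibble::tibble(
    factor_id = "hla_drb1_1501",
    level = c("noncarrier", "heterozygote", "homozygote")[
      ifelse(is.na(hla_copies), 0L, hla_copies) + 1L],
    weight = hla_weight(hla_copies, weights = weights)
  )
  contrib <- dplyr::bind_rows(contrib, hla)

  if (genetic_scope == "full_genetic" && !is.null(genotypes)) {
    g <- as.list(genotypes)
    snps <- intersect(names(g), panel$snp_id[!panel$is_hla_tag])
    if (length(snps)) {
      counts <- vapply(g[snps], function(x) as.integer(x[1]), 1L)
      contrib <- dplyr::bind_rows(contrib, tibble::tibble(
        factor_id = snps,
        level = panel$risk_allele[match(snps, panel$snp_id)],
        weight = snp_contribution(snps, counts, panel = panel,
                                  dosage_model = dosage_model)
      ))
    }
  }
  list(score = sum(contrib$weight), contributions = contrib)
}

#' Score a cohort
#'
#' Encodes a phenotype table, attaches genotypes, and computes the additive
#' risk score for every participant under one variant. Participants missing
#' from the genotype table are scored with genetic contribution 0 (with a
#' warning). Returns one row per participant with the per-factor contribution
#' breakdown; `score` equals the row sum of the contribution columns.
#'
#' @param phenotypes Phenotype tibble (schema of [read_phenotypes()]) or a
#'   path to a phenotype CSV.
#' @param genotypes Genotype tibble from [read_genotypes()], a file path, or
#'   `NULL` for no genetic data.
#' @param weights An `ms_weight_table`.
#' @param panel An [snp_panel()].
#' @param genetic_scope `"full_genetic"` (default) or `"hla_only"`.
#' @param include_vitd Include the 25-OHvD contribution (default `TRUE`).
#' @param dosage_model `"carriage"` or `"additive"`.
#' @param ... Passed to [encode_phenotypes()] (`ebna_reference`,
#'   `vitd_reference`, `ebna_lod`, ...).
#' @return A tibble: `participant_id`, `group`, `variant`, `score`,
#'   `contrib_sex`, `contrib_month`, `contrib_im`, `contrib_smoking`,
#'   `contrib_ebna`, `contrib_vitd`, `contrib_hla`, `contrib_snp`, and
#'   `genotyped` (logical).
#' @examples
#' coh <- simulate_cohort(n_probands = 20, n_siblings = 20, n_controls = 20,
#'                        seed = 1)
#' scores <- score_cohort(coh$phenotypes, coh$genotypes)
#' head(scores)
#' @export
score_cohort <- function(phenotypes, genotypes = NULL,
                         weights = risk_weight_table(), panel = snp_panel(),
                         genetic_scope = c("full_genetic", "hla_only"),
                         include_vitd = TRUE,
                         dosage_model = c("carriage", "additive"), ...) {
  genetic_scope <- match.arg(genetic_scope)
  dosage_model <- match.arg(dosage_model)
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes, panel = panel)

  enc <- encode_phenotypes(phenotypes, ...)

  env_contrib <- tibble::tibble(
    contrib_sex = resolve_level(weights, "sex", enc$sex_level),
    contrib_month = resolve_level(weights, "birth_month", enc$month_level),
    contrib_im = resolve_level(weights, "im_history", enc$im_level),
    contrib_smoking = resolve_level(weights, "smoking", enc$smoking_level),
    contrib_ebna = resolve_level(weights, "ebna1", enc$ebna_level),
    contrib_vitd = if (include_vitd) {
      resolve_level(weights, "vitd", enc$vitd_level)
    } else 0
  )

  n <- nrow(enc)
  hla_copies <- rep(NA_integer_, n)
  snp_total <- rep(0, n)
  genotyped <- rep(FALSE, n)
  if (!is.null(genotypes)) {
    gi <- match(enc$participant_id, genotypes$participant_id)
    genotyped <- !is.na(gi)
    if (any(!genotyped)) {
      warning(sum(!genotyped), " participant(s) missing from the genotype table;",
              " scored with genetic contribution 0.", call. = FALSE)
    }
    if (hla_tag_snp() %in% names(genotypes)) {
      hla_copies[genotyped] <- genotypes[[hla_tag_snp()]][gi[genotyped]]
    }
    if (genetic_scope == "full_genetic") {
      totals <- snp_panel_score(genotypes, panel = panel, dosage_model = dosage_model)
      snp_total[genotyped] <- totals[gi[genotyped]]
    }
  }

  variant_label <- paste0(genetic_scope, ifelse(include_vitd, "", "_no_vitd"))
  out <- dplyr::bind_cols(
    tibble::tibble(
      participant_id = enc$participant_id,
      group = enc$group,
      variant = variant_label
    ),
    env_contrib,
    tibble::tibble(
      contrib_hla = hla_weight(hla_copies, weights = weights),
      contrib_snp = if (genetic_scope == "full_genetic") snp_total else 0,
      genotyped = genotyped
    )
  )
  contrib_cols <- grep("^contrib_", names(out), value = TRUE)
  out$score <- rowSums(out[, contrib_cols])
  dplyr::select(out, "participant_id", "group", "variant", "score",
                dplyr::all_of(contrib_cols), "genotyped")
}

#' Score a cohort under all four variants
#'
#' Convenience wrapper running [score_cohort()] for every row of
#' [score_variants()] and binding the results.
#'
#' @inheritParams score_cohort
#' @return A tibble with one row per participant per variant.
#' @export
score_cohort_all_variants <- function(phenotypes, genotypes = NULL,
                                      weights = risk_weight_table(),
                                      panel = snp_panel(),
                                      dosage_model = c("carriage", "additive"),
                                      ...) {
  dosage_model <- match.arg(dosage_model)
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes, panel = panel)
  purrr::pmap_dfr(score_variants(), function(variant, genetic_scope, include_vitd) {
    score_cohort(phenotypes, genotypes, weights = weights, panel = panel,
                 genetic_scope = genetic_scope, include_vitd = include_vitd,
                 dosage_model = dosage_model, ...)
  })
}
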