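#' Convert a published odds ratio into an additive-model weight
#'
#' The composite risk score is built on base-10 logarithms of published odds
#' ratios. An odds ratio whose 95% confidence interval strictly contains 1 is
#' treated as non-significant and contributes a weight of exactly 0; an
#' interval that merely touches 1 at a bound is kept (its point estimate is
#' still the best available effect size). Weights are rounded to two decimal
#' places, the precision at which the source estimates are reported.
#'
#' @param odds_ratio Positive numeric scalar, the published odds ratio.
#' @param ci Optional numeric length-2 vector `c(low, high)` giving the
#'   confidence interval around `odds_ratio`.
#' @param full_precision If `TRUE`, return the unrounded `log10(odds_ratio)`
#'   (zeroing still applies). Default `FALSE`.
#'
#' @return A numeric scalar weight in log10-odds units.
#' @examples
#' weight_from_or(2.22)                 # 0.35
#' weight_from_or(9.4, c(2.5, 35.4))    # 0.97
#' weight_from_or(0.57, c(0.3, 1.07))   # 0, CI spans 1
#' @export
weight_from_or <- function(odds_ratio, ci = NULL, full_precision = FALSE) {
  if (!is.numeric(odds_ratio) || length(odds_ratio) != 1L || is.na(odds_ratio) ||
      odds_ratio <= 0) {
    abort_validation("`odds_ratio` must be a single positive number.")
  }
  if (!is.null(ci)) {
    if (!is.numeric(ci) || length(ci) != 2L || anyNA(ci) ||
        ci[1] <= 0 || ci[1] > ci[2]) {
      abort_validation("`ci` must be c(low, high) with 0 < low <= high.")
    }
    if (ci[1] < 1 && ci[2] > 1) return(0)
  }
  w <- log10(odds_ratio)
  if (full_precision) w else round(w, 2L)
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "msrisk_validation_error")
}

msrisk_extdata <- function(file) {
  path <- system.file("extdata", file, package = "msrisk", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) abort_validation(paste0("fixture not found: ", file))
  path
}

#' Shipped weight-ledger definitions
#'
#' Reads the odds-ratio definition fixtures shipped with the package: the
#' environmental + HLA ledger (sex, birth month, infectious mononucleosis,
#' anti-EBNA-1 IgG quintiles, 25-OHvD quintiles, smoking, HLA-DRB1*1501
#' zygosity) and the 58-row SNP panel (HLA tag SNP plus 57 non-MHC risk SNPs).
#'
#' @param which One of `"environmental"` (Table of environmental + HLA odds
#'   ratios) or `"snp_panel"`.
#' @return A tibble of odds-ratio definitions. For `"environmental"`:
#'   `factor_id`, `level`, `odds_ratio`, `ci_low`, `ci_high`, `category`,
#'   `source_note`. For `"snp_panel"`: `snp_id`, `gene`, `risk_allele`,
#'   `odds_ratio`.
#' @export
weight_definitions <- function(which = c("environmental", "snp_panel")) {
  which <- match.arg(which)
  file <- switch(which,
    environmental = "environmental_weights.json",
    snp_panel = "snp_panel.json"
  )
  raw <- jsonlite::fromJSON(msrisk_extdata(file), simplifyVector = TRUE)
  if (which == "snp_panel") return(tibble::as_tibble(raw))
  ci <- raw$ci
  if (is.null(ci)) ci <- replicate(nrow(raw), NULL, simplify = FALSE)
  tibble::tibble(
    factor_id = raw$factor_id,
    level = raw$level,
    odds_ratio = raw$odds_ratio,
    ci_low = vapply(ci, function(x) if (is.null(x) || !length(x)) NA_real_ else x[1], 1.0),
    ci_high = vapply(ci, function(x) if (is.null(x) || !length(x)) NA_real_ else x[2], 1.0),
    category = raw$category,
    source_note = raw$source_note
  )
}

# baseline levels that contribute 0 by the absent-factor rule; added to every
# built ledger so that all encoder output resolves to exactly one entry
baseline_entries <- function() {
  tibble::tibble(
    factor_id = c(
      "sex", "im_history", "smoking",
      rep("birth_month", 8L),
      "ebna1", "vitd", "hla_drb1_1501"
    ),
    level = c(
      "M", "no", "never",
      as.character(c(1, 2, 3, 6, 7, 8, 9, 12)),
      "missing", "missing", "noncarrier"
    ),
    odds_ratio = NA_real_,
    ci_low = NA_real_,
    ci_high = NA_real_,
    category = c(
      "environmental", "environmental", "environmental",
      rep("environmental", 8L),
      "environmental", "vitamin_d", "hla"
    ),
    source_note = "baseline: absent factor scores 0"
  )
}

#' Build the additive weight ledger
#'
#' Turns odds-ratio definitions into the full weight ledger used by the
#' scoring functions. Each published entry receives
#' `weight_from_or(odds_ratio, ci)`; SNP-panel rows are keyed by rsID with the
#' risk allele as level; baseline levels (male sex, no mononucleosis, never
#' smoking, unlisted birth months, missing serology, HLA non-carrier) are
#' appended with weight 0 so that every encoded level resolves to exactly one
#' ledger entry.
#'
#' @param environmental Data frame of environmental/HLA definitions as
#'   returned by [weight_definitions("environmental")][weight_definitions];
#'   `NULL` omits them.
#' @param snp_panel Data frame of SNP definitions as returned by
#'   [weight_definitions("snp_panel")][weight_definitions]; the HLA tag SNP is
#'   excluded from the ledger (its signal enters through the HLA zygosity
#'   entries). `NULL` omits the panel.
#' @param full_precision Keep unrounded log10 weights (see [weight_from_or()]).
#' @return A tibble of class `ms_weight_table` with columns `factor_id`,
#'   `level`, `odds_ratio`, `ci_low`, `ci_high`, `weight`, `category`,
#'   `source_note`.
#' @examples
#' wt <- build_weight_table()
#' dplyr::filter(wt, factor_id == "ebna1")
#' @export
build_weight_table <- function(environmental = weight_definitions("environmental"),
                               snp_panel = weight_definitions("snp_panel"),
                               full_precision = FALSE) {
  defs <- list()
  if (!is.null(environmental)) {
    env <- tibble::as_tibble(environmental)
    need <- c("factor_id", "level", "odds_ratio")
    if (!all(need %in% names(env))) {
      abort_validation("environmental definitions need factor_id, level, odds_ratio columns.")
    }
    if (!"ci_low" %in% names(env)) env$ci_low <- NA_real_
    if (!"ci_high" %in% names(env)) env$ci_high <- NA_real_
    if (!"category" %in% names(env)) env$category <- "environmental"
    if (!"source_note" %in% names(env)) env$source_note <- ""
    defs$env <- env[, c("factor_id", "level", "odds_ratio", "ci_low", "ci_high",
                        "category", "source_note")]
  }
  if (!is.null(snp_panel)) {
    pan <- tibble::as_tibble(snp_panel)
    if (!all(c("snp_id", "risk_allele", "odds_ratio") %in% names(pan))) {
      abort_validation("snp panel definitions need snp_id, risk_allele, odds_ratio columns.")
    }
    pan <- dplyr::filter(pan, .data$snp_id != hla_tag_snp())
    defs$snp <- tibble::tibble(
      factor_id = pan$snp_id,
      level = pan$risk_allele,
      odds_ratio = pan$odds_ratio,
      ci_low = NA_real_,
      ci_high = NA_real_,
      category = "snp_panel",
      source_note = if ("gene" %in% names(pan)) pan$gene else ""
    )
  }
  defs <- dplyr::bind_rows(defs)
  if (nrow(defs) == 0L) abort_validation("no weight definitions supplied.")

  key <- paste(defs$factor_id, defs$level, sep = "\r")
  if (anyDuplicated(key)) {
    abort_validation(paste0(
      "duplicate (factor_id, level) keys: ",
      paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", ")
    ))
  }
  for (fac in c("ebna1", "vitd")) {
    if (fac %in% defs$factor_id && !any(defs$factor_id == fac & defs$level == "Q1")) {
      abort_validation(paste0("missing reference level Q1 for factor ", fac, "."))
    }
  }

  defs$weight <- vapply(seq_len(nrow(defs)), function(i) {
    ci <- if (is.na(defs$ci_low[i])) NULL else c(defs$ci_low[i], defs$ci_high[i])
    weight_from_or(defs$odds_ratio[i], ci, full_precision = full_precision)
  }, 1.0)

  out <- dplyr::bind_rows(defs, dplyr::mutate(baseline_entries(), weight = 0))
  out <- out[, c("factor_id", "level", "odds_ratio", "ci_low", "ci_high",
                 "weight", "category", "source_note")]
  # keep only baseline rows for factors actually present
  out <- dplyr::filter(
    out,
    !is.na(.data$odds_ratio) | .data$factor_id %in% defs$factor_id
  )
  new_weight_table(out)
}

new_weight_table <- function(x) {
  structure(tibble::as_tibble(x), class = c("ms_weight_table", class(tibble::tibble())))
}

#' The default shipped weight ledger
#'
#' Convenience wrapper around [build_weight_table()] with the shipped
#' environmental and SNP-panel definitions.
#'
#' @inheritParams build_weight_table
#' @return An `ms_weight_table` tibble.
#' @export
risk_weight_table <- function(full_precision = FALSE) {
  build_weight_table(full_precision = full_precision)
}

#' Look up one weight in a ledger
#'
#' @param weights An `ms_weight_table` from [build_weight_table()].
#' @param factor_id,level Key of the entry.
#' @return Numeric weight; errors (naming the factor) if the key is absent.
#' @export
weight_for <- function(weights, factor_id, level) {
  hit <- weights$factor_id == factor_id & weights$level == as.character(level)
  if (sum(hit) != 1L) {
    abort_validation(paste0(
      "level '", level, "' of factor '", factor_id, "' does not resolve in the weight table."
    ))
  }
  weights$weight[hit]
}

#' Write / read a weight ledger as JSON
#'
#' The on-disk schema is an array of
#' `{factor_id, level, odds_ratio, ci, weight, category, source_note}` with
#' `ci` either `[low, high]` or `null`. A ledger survives a write/read round
#' trip identically.
#'
#' @param weights An `ms_weight_table`.
#' @param path File path.
#' @return `write_weight_table()` returns `path` invisibly;
#'   `read_weight_table()` returns an `ms_weight_table`.
#' @export
write_weight_table <- function(weights, path) {
  recs <- lapply(seq_len(nrow(weights)), function(i) {
    list(
      factor_id = weights$factor_id[i],
      level = weights$level[i],
      odds_ratio = if (is.na(weights$odds_ratio[i])) NULL else weights$odds_ratio[i],
      ci = if (is.na(weights$ci_low[i])) NULL else c(weights$ci_low[i], weights$ci_high[i]),
      weight = weights$weight[i],
      category = weights$category[i],
      source_note = weights$source_note[i]
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(raw)) abort_validation("empty weight-table file.")
  out <- tibble::tibble(
    factor_id = vapply(raw, function(r) r$factor_id, ""),
    level = vapply(raw, function(r) r$level, ""),
    odds_ratio = vapply(raw, function(r) r$odds_ratio %||% NA_real_, 1.0),
    ci_low = vapply(raw, function(r) if (is.null(r$ci)) NA_real_ else r$ci[[1]], 1.0),
    ci_high = vapply(raw, function(r) if (is.null(r$ci)) NA_real_ else r$ci[[2]], 1.0),
    weight = vapply(raw, function(r) r$weight, 1.0),
    category = vapply(raw, function(r) r$category, ""),
    source_note = vapply(raw, function(r) r$source_note %||% "", "")
  )
  new_weight_table(out)
}
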