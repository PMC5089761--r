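#' Adjudicate ever/never smoking from self-report and serum cotinine
#'
#' A participant is coded "ever" smoking if they either report a smoking
#' history or have a serum cotinine strictly above the current-smoker
#' threshold of 3.08 ng/ml; otherwise "never". Missing cotinine contributes no
#' evidence.
#'
#' @param self_report Logical vector, self-reported smoking history.
#' @param cotinine Numeric vector of serum cotinine (ng/ml), `NA` for missing.
#' @param threshold Cotinine cut-off in ng/ml (default 3.08).
#' @return Character vector, `"ever"` or `"never"`.
#' @examples
#' adjudicate_smoking(FALSE, 3.09)  # "ever"
#' adjudicate_smoking(TRUE, 0)      # "ever"
#' adjudicate_smoking(FALSE, 3.08)  # "never": strictly greater than
#' @export
adjudicate_smoking <- function(self_report, cotinine = NA_real_, threshold = 3.08) {
  if (!is.logical(self_report) || anyNA(self_report)) {
    abort_validation("`self_report` must be logical and non-missing.")
  }
  cotinine <- rep_len(as.numeric(cotinine), length(self_report))
  if (any(cotinine < 0, na.rm = TRUE)) {
    abort_validation("cotinine must be non-negative.")
  }
  biochemical <- !is.na(cotinine) & cotinine > threshold
  ifelse(self_report | biochemical, "ever", "never")
}

#' Fit a first-harmonic cosinor to seasonal measurements
#'
#' Least-squares fit of `value ~ mesor + a*sin(2*pi*day/T) + b*cos(2*pi*day/T)`
#' with an annual period `T = 365.25` days.
#'
#' @param value Numeric measurements.
#' @param day Day of year (1--366) for each measurement.
#' @param period Period in days (default 365.25).
#' @return A list with `mesor`, `beta_sin`, `beta_cos`, `amplitude`,
#'   `period`, and `seasonal(day)` -- a function returning the zero-mean
#'   seasonal component at given days.
#' @export
cosinor_fit <- function(value, day, period = 365.25) {
  ok <- complete.cases(value, day)
  value <- value[ok]; day <- day[ok]
  if (length(value) < 2L || length(unique(day)) < 2L) {
    abort_validation("cosinor reference needs measurements on >= 2 distinct days.")
  }
  s <- sin(2 * pi * day / period)
  c_ <- cos(2 * pi * day / period)
  fit <- lm(value ~ s + c_)
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  bs <- unname(cf["s"]); bc <- unname(cf["c_"])
  list(
    mesor = unname(cf["(Intercept)"]),
    beta_sin = bs,
    beta_cos = bc,
    amplitude = sqrt(bs^2 + bc^2),
    period = period,
    seasonal = function(d) bs * sin(2 * pi * d / period) + bc * cos(2 * pi * d / period)
  )
}

#' Deseasonalise serum 25-OHvD to the day of sampling
#'
#' Removes the annual sinusoidal component of serum 25-hydroxyvitamin D:
#' a first-harmonic cosinor is fitted to a reference set of (value, day)
#' pairs and each input value is adjusted by subtracting the fitted seasonal
#' component at its sampling day, re-centring on the reference annual mean
#' (the cosinor mesor). The mean of the deseasonalised reference equals the
#' mesor exactly.
#'
#' @param value Numeric 25-OHvD measurements (nmol/l, > 0).
#' @param day Sampling day of year for each value.
#' @param reference Optional data frame with columns `value` and `day` used to
#'   fit the seasonal model; defaults to the input pairs themselves.
#' @param period Period in days (default 365.25).
#' @return Numeric vector of deseasonalised values (nmol/l).
#' @export
deseasonalise_vitd <- function(value, day, reference = NULL, period = 365.25) {
  if (any(value <= 0, na.rm = TRUE)) {
    abort_validation("25-OHvD values must be positive.")
  }
  if (is.null(reference)) {
    reference <- data.frame(value = value, day = day)
  }
  if (!all(c("value", "day") %in% names(reference))) {
    abort_validation("`reference` must have columns value and day.")
  }
  fit <- cosinor_fit(reference$value, reference$day, period = period)
  value - fit$seasonal(day)
}

#' Assign 25-OHvD quintiles at fixed cutpoints
#'
#' Uses the fixed quintile cutpoints 63.2, 75.3, 84.8 and 99.1 nmol/l
#' (intervals upper-inclusive: a value equal to a cutpoint falls in the lower
#' quintile). Values should be deseasonalised first.
#'
#' @param value Numeric deseasonalised 25-OHvD (nmol/l, > 0); `NA` propagates.
#' @param cutpoints Four increasing cutpoints (nmol/l).
#' @return Character vector `"Q1"`..`"Q5"` (`NA` for missing input).
#' @examples
#' assign_vitd_quintile(c(50, 75.3, 100))  # Q1 Q2 Q5
#' @export
assign_vitd_quintile <- function(value, cutpoints = c(63.2, 75.3, 84.8, 99.1)) {
  if (length(cutpoints) != 4L || is.unsorted(cutpoints, strictly = TRUE)) {
    abort_validation("`cutpoints` must be 4 strictly increasing values.")
  }
  if (any(value <= 0, na.rm = TRUE)) {
    abort_validation("25-OHvD values must be positive.")
  }
  as.character(cut(value, c(-Inf, cutpoints, Inf),
                   labels = paste0("Q", 1:5), right = TRUE))
}

#' Assign anti-EBNA-1 IgG quintiles against a reference distribution
#'
#' Titres below the assay limit of detection are classed `"undetectable"`
#' (a protective level in the ledger). Detectable titres are assigned to
#' quintiles whose cutpoints are the 20/40/60/80th percentiles
#' (linear-interpolation definition, [stats::quantile()] type 7) of the
#' detectable titres in the reference group; a titre equal to a cutpoint
#' falls in the lower quintile.
#'
#' @param titre Numeric titres (assay units); `NA` propagates.
#' @param reference Numeric reference titres (typically the combined healthy
#'   control and sibling titres); needs >= 5 detectable values.
#' @param lod Assay limit of detection (same units); titres strictly below it
#'   are undetectable. Default 0 (nothing undetectable).
#' @return Character vector in `"undetectable"`, `"Q1"`..`"Q5"`.
#' @export
assign_ebna_quintile <- function(titre, reference, lod = 0) {
  if (missing(reference) || !length(reference)) {
    abort_validation("`reference` titres must be supplied and non-empty.")
  }
  detectable <- reference[!is.na(reference) & reference >= lod]
  if (length(detectable) < 5L) {
    abort_validation("reference must contain >= 5 detectable titres.")
  }
  cut_q <- quantile(detectable, probs = c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
  out <- as.character(cut(titre, c(-Inf, cut_q, Inf),
                          labels = paste0("Q", 1:5), right = TRUE))
  out[!is.na(titre) & titre < lod] <- "undetectable"
  out
}

phenotype_schema <- function() {
  c("participant_id", "group", "sex", "birth_month", "im_history",
    "smoking_self_report", "cotinine_ng_ml", "ebna1_titre", "vitd_nmol_l",
    "sample_day")
}

#' Read a phenotype CSV
#'
#' Expects exactly the header `participant_id, group, sex, birth_month,
#' im_history, smoking_self_report, cotinine_ng_ml, ebna1_titre, vitd_nmol_l,
#' sample_day`; empty cells are missing. Extra columns (e.g. `family_id`) are
#' preserved.
#'
#' @param path CSV file path.
#' @return A tibble with one row per participant.
#' @export
read_phenotypes <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(phenotype_schema(), names(dat))
  if (length(missing_cols)) {
    abort_validation(paste0("phenotype file lacks columns: ",
                            paste(missing_cols, collapse = ", ")))
  }
  dat$im_history <- as.logical(dat$im_history)
  dat$smoking_self_report <- as.logical(dat$smoking_self_report)
  validate_phenotypes(dat)
  dat
}

validate_phenotypes <- function(data) {
  if (!all(data$group %in% c("MS", "SIB", "HC"))) {
    abort_validation("`group` must be one of MS, SIB, HC.")
  }
  if (!all(data$sex %in% c("F", "M"))) abort_validation("`sex` must be F or M.")
  if (anyNA(data$birth_month) || !all(data$birth_month %in% 1:12)) {
    abort_validation("`birth_month` must be 1-12 and non-missing.")
  }
  if (any(data$cotinine_ng_ml < 0, na.rm = TRUE)) {
    abort_validation("cotinine must be non-negative.")
  }
  invisible(data)
}

#' Encode raw phenotypes into risk-factor levels
#'
#' Maps each participant's raw measurements to the categorical levels the
#' additive score consumes: sex, birth month, infectious mononucleosis,
#' cotinine-adjudicated smoking status, anti-EBNA-1 IgG quintile (against a
#' reference group, by default the combined healthy-control and sibling
#' titres in `data`), and the quintile of deseasonalised 25-OHvD at fixed
#' cutpoints. Missing serology maps to level `"missing"`, which carries
#' weight 0 downstream.
#'
#' @param data Phenotype tibble in the schema of [read_phenotypes()].
#' @param ebna_reference Optional numeric vector of reference titres;
#'   default: `ebna1_titre` of the SIB and HC rows of `data`.
#' @param vitd_reference Optional data frame (`value`, `day`) used to fit the
#'   seasonal model; default: all non-missing 25-OHvD rows of `data`.
#' @param ebna_lod Assay limit of detection for the EBNA-1 ELISA (default 0).
#' @param vitd_cutpoints Fixed 25-OHvD quintile cutpoints, nmol/l.
#' @param deseasonalise Deseasonalise 25-OHvD before quintile assignment
#'   (default `TRUE`; requires `sample_day`).
#' @return A tibble with `participant_id`, `group`, the level columns
#'   `sex_level`, `month_level`, `im_level`, `smoking_level`, `ebna_level`,
#'   `vitd_level`, and `vitd_deseasonalised` (nmol/l).
#' @export
encode_phenotypes <- function(data,
                              ebna_reference = NULL,
                              vitd_reference = NULL,
                              ebna_lod = 0,
                              vitd_cutpoints = c(63.2, 75.3, 84.8, 99.1),
                              deseasonalise = TRUE) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(phenotype_schema(), names(data))
  if (length(missing_cols)) {
    abort_validation(paste0("phenotype data lacks columns: ",
                            paste(missing_cols, collapse = ", ")))
  }
  validate_phenotypes(data)

  if (is.null(ebna_reference)) {
    ebna_reference <- data$ebna1_titre[data$group %in% c("SIB", "HC")]
    if (sum(!is.na(ebna_reference) & ebna_reference >= ebna_lod) < 5L) {
      ebna_reference <- data$ebna1_titre
    }
  }

  vd <- data$vitd_nmol_l
  if (deseasonalise && any(!is.na(vd))) {
    if (is.null(vitd_reference)) {
      ok <- !is.na(vd) & !is.na(data$sample_day)
      vitd_reference <- data.frame(value = vd[ok], day = data$sample_day[ok])
    }
    vd_adj <- rep(NA_real_, length(vd))
    ok_in <- !is.na(vd) & !is.na(data$sample_day)
    vd_adj[ok_in] <- deseasonalise_vitd(vd[ok_in], data$sample_day[ok_in],
                                        reference = vitd_reference)
  } else {
    vd_adj <- vd
  }
  # adjustment can only be quintiled while positive
  vd_adj_q <- ifelse(!is.na(vd_adj) & vd_adj <= 0, NA_real_, vd_adj)

  have_ebna <- !is.na(data$ebna1_titre)
  ebna_level <- rep("missing", nrow(data))
  if (any(have_ebna)) {
    ebna_level[have_ebna] <- assign_ebna_quintile(
      data$ebna1_titre[have_ebna], reference = ebna_reference, lod = ebna_lod
    )
  }
  vitd_level <- ifelse(is.na(vd_adj_q), "missing", assign_vitd_quintile(vd_adj_q, vitd_cutpoints))

  tibble::tibble(
    participant_id = data$participant_id,
    group = data$group,
    sex_level = data$sex,
    month_level = as.character(data$birth_month),
    im_level = ifelse(data$im_history %in% TRUE, "yes", "no"),
    smoking_level = adjudicate_smoking(
      data$smoking_self_report %in% TRUE, data$cotinine_ng_ml
    ),
    ebna_level = ebna_level,
    vitd_level = vitd_level,
    vitd_deseasonalised = vd_adj
  )
}
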