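#' @keywords internal
hla_tag_snp <- function() "rs1315388"

#' The shipped MS susceptibility SNP panel
#'
#' Reads the 58-row panel of genome-wide significant MS risk SNPs (the
#' HLA-DRB1*1501 tag SNP plus 57 non-MHC SNPs), each with its risk allele and
#' published per-allele odds ratio, and derives the rounded log10 weight used
#' by the additive score. The HLA tag SNP is flagged: its signal is scored
#' through the zygosity-specific HLA weights, never through the SNP loop.
#'
#' @param full_precision Keep unrounded log10 weights.
#' @return A tibble of class `ms_snp_panel` with columns `snp_id`, `gene`,
#'   `risk_allele`, `odds_ratio`, `weight`, `is_hla_tag`; attribute
#'   `hla_tag` holds the tag rsID.
#' @export
snp_panel <- function(full_precision = FALSE) {
  pan <- weight_definitions("snp_panel")
  if (anyDuplicated(pan$snp_id)) abort_validation("panel rsIDs must be unique.")
  pan$weight <- vapply(pan$odds_ratio, weight_from_or,
                       FUN.VALUE = 1.0, full_precision = full_precision)
  pan$is_hla_tag <- pan$snp_id == hla_tag_snp()
  structure(pan, hla_tag = hla_tag_snp(),
            class = c("ms_snp_panel", class(tibble::tibble())))
}

#' Genetic weight for HLA-DRB1*1501 carriage
#'
#' Zygosity at the major MHC class II risk haplotype carries its own pair of
#' odds ratios (heterozygote 3.1, homozygote 6.2) rather than a per-allele
#' dose: 0 copies score 0, 1 copy 0.49, 2 copies 0.79 (log10 units).
#'
#' @param copies Integer vector of risk-haplotype copies (0, 1 or 2; `NA`
#'   scores 0, the absent-factor rule).
#' @param weights Optional `ms_weight_table` to take the zygosity weights
#'   from; defaults to the shipped ledger values.
#' @return Numeric vector of log10-odds weights.
#' @export
hla_weight <- function(copies, weights = NULL) {
  if (is.null(weights)) {
    het <- weight_from_or(3.1)
    hom <- weight_from_or(6.2)
  } else {
    het <- weight_for(weights, "hla_drb1_1501", "heterozygote")
    hom <- weight_for(weights, "hla_drb1_1501", "homozygote")
  }
  bad <- !is.na(copies) & !copies %in% 0:2
  if (any(bad)) abort_validation("HLA copies must be 0, 1 or 2.")
  out <- rep(0, length(copies))
  out[!is.na(copies) & copies == 1] <- het
  out[!is.na(copies) & copies == 2] <- hom
  out
}

#' Weight contribution of one non-MHC panel SNP
#'
#' Under the default carriage (dominant) model a genotype with at least one
#' risk allele contributes the SNP's rounded log10 odds ratio once; under the
#' additive model the weight is multiplied by the allele count. Missing
#' genotypes contribute 0 (the absent-factor rule).
#'
#' @param snp_id Panel rsID (not the HLA tag SNP).
#' @param count Risk-allele count 0/1/2 (`NA` = missing).
#' @param panel An [snp_panel()].
#' @param dosage_model `"carriage"` (default) or `"additive"`.
#' @return Numeric vector of contributions.
#' @examples
#' snp_contribution("rs1335532", 1)                # 0.09
#' snp_contribution("rs1335532", 2, dosage_model = "additive")  # 0.18
#' @export
snp_contribution <- function(snp_id, count, panel = snp_panel(),
                             dosage_model = c("carriage", "additive")) {
  dosage_model <- match.arg(dosage_model)
  i <- match(snp_id, panel$snp_id)
  if (anyNA(i)) {
    abort_validation(paste0("unknown panel SNP: ",
                            paste(snp_id[is.na(i)], collapse = ", ")))
  }
  if (any(panel$is_hla_tag[i])) {
    abort_validation("the HLA tag SNP is scored via hla_weight(), not the SNP loop.")
  }
  bad <- !is.na(count) & !count %in% 0:2
  if (any(bad)) abort_validation("risk-allele counts must be 0, 1 or 2.")
  w <- panel$weight[i]
  cnt <- ifelse(is.na(count), 0L, count)
  if (dosage_model == "carriage") w * (cnt >= 1) else w * cnt
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Read genotypes for the SNP panel
#'
#' Reads either a VCF (GT field, biallelic sites, variant IDs = rsIDs) or a
#' dosage TSV (`participant_id` column followed by one rsID column per SNP
#' holding risk-allele counts 0/1/2, blank = missing) and returns risk-allele
#' counts oriented against the panel's risk alleles. In VCF input the count
#' honours REF/ALT orientation; sites whose rsID is not in the panel are
#' skipped with a warning; sites where neither REF nor ALT equals the panel
#' risk allele are recorded missing with a warning; strand-ambiguous A/T or
#' C/G sites are flagged with a warning, never silently flipped.
#'
#' @param path File path (`.vcf` or `.tsv`), or pass `format` explicitly.
#' @param panel An [snp_panel()].
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A tibble: `participant_id` plus one integer column per panel SNP
#'   found in the file (`NA` = missing/uncalled).
#' @export
read_genotypes <- function(path, panel = snp_panel(),
                           format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) abort_validation(paste0("genotype file not found: ", path))
  switch(format,
    vcf = read_genotypes_vcf(path, panel),
    tsv = read_genotypes_tsv(path, panel)
  )
}

read_genotypes_vcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- if (is.null(dim(fix))) matrix(fix, nrow = 1, dimnames = list(NULL, names(fix))) else fix
  ids <- fix[, "ID"]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(ids, names(gt)))
  samples <- colnames(gt)

  keep <- ids %in% panel$snp_id
  if (any(!keep)) {
    warning("skipping VCF sites not in the panel: ",
            paste(ids[!keep], collapse = ", "), call. = FALSE)
  }
  counts <- matrix(NA_integer_, nrow = length(samples), ncol = sum(keep),
                   dimnames = list(NULL, ids[keep]))
  for (j in which(keep)) {
    id <- ids[j]
    ref <- toupper(fix[j, "REF"]); alt <- toupper(fix[j, "ALT"])
    risk <- panel$risk_allele[match(id, panel$snp_id)]
    if (is_strand_ambiguous(ref, alt)) {
      warning("strand-ambiguous alleles (", ref, "/", alt, ") at ", id,
              "; counts taken at face value.", call. = FALSE)
    }
    if (!risk %in% c(ref, alt)) {
      warning("risk allele ", risk, " for ", id,
              " matches neither REF nor ALT; recording missing.", call. = FALSE)
      next
    }
    risk_code <- if (risk == ref) "0" else "1"
    g <- gt[j, ]
    alleles <- strsplit(ifelse(is.na(g), "", g), "[/|]")
    counts[, id] <- vapply(alleles, function(a) {
      a <- a[nzchar(a)]
      if (!length(a) || any(a == ".")) return(NA_integer_)
      sum(a == risk_code)
    }, 1L)
  }
  dplyr::bind_cols(tibble::tibble(participant_id = samples),
                   tibble::as_tibble(counts))
}

read_genotypes_tsv <- function(path, panel) {
  dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(dat)[1] != "participant_id") {
    abort_validation("dosage TSV must start with a participant_id column.")
  }
  snp_cols <- setdiff(names(dat), "participant_id")
  unknown <- setdiff(snp_cols, panel$snp_id)
  if (length(unknown)) {
    warning("skipping TSV columns not in the panel: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    dat <- dat[, c("participant_id", intersect(snp_cols, panel$snp_id))]
  }
  for (col in setdiff(names(dat), "participant_id")) {
    v <- suppressWarnings(as.integer(dat[[col]]))
    if (any(!is.na(v) & !v %in% 0:2)) {
      abort_validation(paste0("dosages in column ", col, " must be 0, 1 or 2."))
    }
    dat[[col]] <- v
  }
  tibble::as_tibble(dat)
}

#' Total SNP-panel contribution per participant
#'
#' Sums [snp_contribution()] over all non-HLA-tag panel SNPs present in a
#' genotype table (missing genotypes and absent SNP columns contribute 0).
#'
#' @param genotypes Genotype tibble from [read_genotypes()].
#' @param panel An [snp_panel()].
#' @param dosage_model `"carriage"` or `"additive"`.
#' @return Numeric vector, one total per row of `genotypes`.
#' @export
snp_panel_score <- function(genotypes, panel = snp_panel(),
                            dosage_model = c("carriage", "additive")) {
  dosage_model <- match.arg(dosage_model)
  snps <- intersect(names(genotypes), panel$snp_id[!panel$is_hla_tag])
  if (!length(snps)) return(rep(0, nrow(genotypes)))
  contrib <- vapply(snps, function(s) {
    snp_contribution(s, genotypes[[s]], panel = panel, dosage_model = dosage_model)
  }, numeric(nrow(genotypes)))
  if (is.null(dim(contrib))) contrib <- matrix(contrib, nrow = nrow(genotypes))
  rowSums(contrib)
}
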