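# small in-code fixtures shared across test files

tiny_phenotypes <- function() {
  tibble::tibble(
    participant_id = c("P1", "P2", "P3"),
    group = c("MS", "SIB", "HC"),
    sex = c("F", "M", "F"),
    birth_month = c(4L, 6L, 11L),
    im_history = c(TRUE, FALSE, FALSE),
    smoking_self_report = c(TRUE, FALSE, FALSE),
    cotinine_ng_ml = c(120, 0.5, NA),
    ebna1_titre = c(180, 40, NA),
    vitd_nmol_l = c(55, 102, NA),
    sample_day = c(30L, 200L, 100L)
  )
}

# hand-rolled VCF text: variants is a data frame with id, ref, alt and one
# column per sample holding GT strings
write_test_vcf <- function(path, variants, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c("1", as.character(1000 + i), variants$id[i], variants$ref[i],
            variants$alt[i], ".", "PASS", ".", "GT",
            unlist(variants[i, samples])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

# encoded-level list for a participant with no active risk factors
null_encoded <- function() {
  list(sex_level = "M", month_level = "6", im_level = "no",
       smoking_level = "never", ebna_level = "missing", vitd_level = "missing")
}
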