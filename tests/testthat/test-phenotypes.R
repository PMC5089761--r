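test_that("smoking adjudication follows the self-report OR cotinine rule", {
  expect_identical(adjudicate_smoking(FALSE, 3.09), "ever")
  expect_identical(adjudicate_smoking(TRUE, 0), "ever")
  expect_identical(adjudicate_smoking(FALSE, 3.08), "never")  # strictly greater
  expect_identical(adjudicate_smoking(FALSE, NA), "never")
  expect_error(adjudicate_smoking(FALSE, -1), class = "msrisk_validation_error")
})

test_that("smoking adjudication is monotone in both inputs", {
  set.seed(11)
  for (i in 1:50) {
    cot <- runif(1, 0, 10)
    base <- adjudicate_smoking(FALSE, cot)
    # turning on self-report never moves ever -> never
    expect_true(base == "never" || adjudicate_smoking(TRUE, cot) == "ever")
    expect_identical(adjudicate_smoking(TRUE, cot), "ever")
    # raising cotinine never moves ever -> never
    if (base == "ever") {
      expect_identical(adjudicate_smoking(FALSE, cot + runif(1, 0, 5)), "ever")
    }
  }
})

test_that("deseasonalisation is the identity for amplitude-zero references", {
  ref <- data.frame(value = rep(80, 50), day = seq(5, 360, length.out = 50))
  out <- deseasonalise_vitd(c(60, 80, 95), c(10, 180, 300), reference = ref)
  expect_equal(out, c(60, 80, 95), tolerance = 1e-9)
})

test_that("the cosinor recovers a simulated annual cycle", {
  set.seed(42)
  day <- sample.int(365L, 500L, replace = TRUE)
  value <- 80 + 15 * sin(2 * pi * day / 365.25) + rnorm(500)
  fit <- cosinor_fit(value, day)
  expect_lt(abs(fit$amplitude - 15) / 15, 0.10)
  expect_lt(abs(fit$mesor - 80), 1)
  # a sample drawn at the seasonal peak deseasonalises to about the mesor
  peak_day <- 365.25 / 4
  peak_value <- 80 + 15 * sin(2 * pi * peak_day / 365.25)
  des <- deseasonalise_vitd(peak_value, peak_day,
                            reference = data.frame(value = value, day = day))
  expect_equal(des, 80, tolerance = 1)
  # the deseasonalised reference keeps the annual mean (the mesor) exactly
  des_ref <- deseasonalise_vitd(value, day,
                                reference = data.frame(value = value, day = day))
  expect_equal(mean(des_ref), fit$mesor, tolerance = 1e-9)
  # a single measurement sitting on the fitted curve maps to the annual mean
  d0 <- 200
  on_curve <- fit$mesor + fit$seasonal(d0)
  expect_equal(
    deseasonalise_vitd(on_curve, d0, reference = data.frame(value = value, day = day)),
    fit$mesor, tolerance = 1e-9
  )
})

test_that("degenerate seasonal references are rejected", {
  ref <- data.frame(value = c(70, 75, 80), day = c(100, 100, 100))
  expect_error(deseasonalise_vitd(80, 50, reference = ref),
               class = "msrisk_validation_error")
})

test_that("25-OHvD quintiles use the fixed cutpoints, upper-inclusive", {
  expect_identical(assign_vitd_quintile(100), "Q5")
  expect_identical(assign_vitd_quintile(50), "Q1")
  expect_identical(assign_vitd_quintile(75.3), "Q2")   # boundary to the lower side
  expect_identical(assign_vitd_quintile(63.2), "Q1")
  expect_identical(assign_vitd_quintile(99.2), "Q5")
  expect_error(assign_vitd_quintile(-5), class = "msrisk_validation_error")
  # partition: every positive value gets exactly one level
  set.seed(12)
  v <- runif(200, 1, 150)
  lev <- assign_vitd_quintile(v)
  expect_false(anyNA(lev))
  expect_true(all(lev %in% paste0("Q", 1:5)))
})

test_that("EBNA-1 quintiles come from the reference distribution", {
  expect_identical(assign_ebna_quintile(3, reference = c(10, 20, 30, 40, 50), lod = 5),
                   "undetectable")
  expect_identical(assign_ebna_quintile(10, reference = c(10, 20, 30, 40, 50)), "Q1")
  expect_identical(assign_ebna_quintile(50, reference = c(10, 20, 30, 40, 50)), "Q5")
  # ties at a cutpoint go to the lower quintile: 20th percentile of 0..100 is 20
  expect_identical(assign_ebna_quintile(20, reference = 0:100), "Q1")
  expect_identical(assign_ebna_quintile(20.001, reference = 0:100), "Q2")
  expect_error(assign_ebna_quintile(10, reference = numeric(0)),
               class = "msrisk_validation_error")
  expect_error(assign_ebna_quintile(10, reference = c(1, 2, 3)),
               class = "msrisk_validation_error")
})

test_that("quintile occupancy is balanced on a uniform reference", {
  set.seed(7)
  ref <- runif(1000, 1, 100)
  lev <- assign_ebna_quintile(ref, reference = ref)
  counts <- table(factor(lev, levels = paste0("Q", 1:5)))
  expect_true(all(abs(counts - 200) <= 40))
})

test_that("encode_phenotypes composes the component encoders", {
  ph <- tiny_phenotypes()
  ref <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  enc <- encode_phenotypes(ph, ebna_reference = ref, deseasonalise = FALSE)
  # P1: female, April birth, IM+, heavy cotinine smoker, top titre, low vitD
  expect_identical(enc$sex_level[1], "F")
  expect_identical(enc$month_level[1], "4")
  expect_identical(enc$im_level[1], "yes")
  expect_identical(enc$smoking_level[1], "ever")
  expect_identical(enc$ebna_level[1], "Q5")
  expect_identical(enc$vitd_level[1], "Q1")
  # P2: male never-smoker, June birth (weight 0 downstream), vitD > 99.1
  expect_identical(enc$sex_level[2], "M")
  expect_identical(enc$smoking_level[2], "never")
  expect_identical(enc$vitd_level[2], "Q5")
  # P3: fully missing serology
  expect_identical(enc$ebna_level[3], "missing")
  expect_identical(enc$vitd_level[3], "missing")
  expect_identical(enc$smoking_level[3], "never")
})

test_that("phenotype CSV reading enforces the schema", {
  ph <- tiny_phenotypes()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ph, path)
  back <- read_phenotypes(path)
  expect_identical(nrow(back), 3L)
  expect_identical(back$participant_id, ph$participant_id)
  bad <- ph[, -2]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path2)
  expect_error(read_phenotypes(path2), class = "msrisk_validation_error")
})
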