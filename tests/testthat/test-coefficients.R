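# Golden checks of the shipped coefficient set, its serialization, and the
# significance filter.

# every published numeric cell of the default set, as (equation, term, value)
published_cells <- read.table(header = TRUE, text = "
  eq     term              value
  hba1c  constant          3.055
  hba1c  lag               0.526
  hba1c  ln_duration       0.182
  hba1c  year1            -0.144
  hba1c  age_at_diagnosis -0.008
  hba1c  female           -0.034
  hba1c  smoking           0.192
  hba1c  bmi               0.015
  sbp    constant          5.546
  sbp    lag               0.466
  sbp    ln_duration      -0.050
  sbp    age_at_diagnosis  0.021
  sbp    female           -0.064
  sbp    smoking           0.094
  sbp    bmi               0.017
  tchdl  constant          1.647
  tchdl  lag               0.541
  tchdl  ln_duration       0.099
  tchdl  age_at_diagnosis -0.009
  tchdl  female           -0.144
  tchdl  smoking           0.071
  tchdl  bmi               0.021
  ldl    constant          1.938
  ldl    lag               0.352
  ldl    ln_duration      -0.059
  ldl    age_at_diagnosis -0.007
  ldl    female            0.060
  ldl    smoking           0.091
  ldl    bmi               0.018
  ldl    bmi_squared      -0.0003
  bmi    constant          6.832
  bmi    lag               0.811
  bmi    ln_duration       0.106
  bmi    age_at_diagnosis -0.022
  bmi    female            0.134
  bmi    smoking          -0.370
")

get_term <- function(cs, eq, term) {
  e <- cs[[eq]]
  if (term == "constant") e$constant else if (term == "lag") e$lag
  else e$covariates[[term]]
}

test_that("the shipped default reproduces every published coefficient cell", {
  cs <- ndr_table2()
  for (i in seq_len(nrow(published_cells))) {
    row <- published_cells[i, ]
    expect_identical(get_term(cs, row$eq, row$term)$value, row$value,
                     label = paste(row$eq, row$term))
  }
  # footer metadata
  expect_identical(cs$hba1c$meta$n_patients, 4450L)
  expect_identical(cs$bmi$meta$person_years, 25447L)
  expect_equal(cs$hba1c$meta$hansen_p, 0.053)
  # markers: smoking endogenous and unstarred in the HbA1c equation
  expect_identical(cs$hba1c$covariates$smoking$sig, "ns")
  expect_true(isTRUE(cs$hba1c$covariates$smoking$endogenous))
  # first-year indicator exists only in the HbA1c equation
  expect_identical(cs$hba1c$covariates$year1$sig, "10%")
  for (eq in c("sbp", "tchdl", "ldl", "bmi"))
    expect_identical(ndr_table2()[[eq]]$covariates$year1$sig, "ni")
  # BMI squared only carries a value in the LDL equation
  expect_null(cs$hba1c$covariates$bmi_squared$value)
  expect_identical(cs$ldl$covariates$bmi_squared$value, -0.0003)
})

test_that("coefficient sets round-trip through save/load", {
  cs <- ndr_table2()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_coefset(cs, path)
  again <- read_coefset(path)
  expect_identical(unclass(again), unclass(cs))
})

test_that("lag coefficients outside (0,1) are rejected on load", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cs <- ndr_table2()
  cs$hba1c$lag$value <- 1.2
  write_coefset(cs, path)
  expect_error(read_coefset(path), "lag coefficient.*between 0 and 1")
})

test_that("malformed files raise schema errors naming the offending field", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("hba1c:", "  constant: {value: 1.0, sig: '42%'}",
               "  lag: {value: 0.5, sig: '1%'}"), path)
  expect_error(read_coefset(path), "hba1c:constant")
  writeLines(c("hba1c:", "  constant: {value: 1.0, sig: '1%'}",
               "  lag: {value: 0.5, sig: '1%'}",
               "  covariates:", "    bmi: {sig: 'ni', value: 0.1}"), path)
  expect_error(read_coefset(path), "hba1c:bmi")
})

test_that("the 10% filter removes exactly the unstarred coefficients", {
  f <- filter_significant(ndr_table2(), 0.10)
  # unstarred in the published table: filtered out
  expect_null(f$bmi$covariates$female$value)
  expect_null(f$hba1c$covariates$smoking$value)
  expect_null(f$tchdl$covariates$ln_duration$value)
  expect_null(f$sbp$covariates$ln_duration$value)
  # starred at exactly 10%: retained
  expect_identical(f$hba1c$covariates$female$value, -0.034)
  expect_identical(f$sbp$covariates$age_at_diagnosis$value, 0.021)
  expect_identical(f$bmi$constant$value, 6.832)   # constant always kept
  # stricter filters remove the 10% tier too
  f5 <- filter_significant(ndr_table2(), 0.05)
  expect_null(f5$hba1c$covariates$female$value)
  expect_identical(f5$sbp$covariates$female$value, -0.064)
})

test_that("filtering is idempotent and the all-significant case is identity", {
  f1 <- filter_significant(ndr_table2(), 0.10)
  f2 <- filter_significant(f1, 0.10)
  expect_identical(f1, f2)
  # a set where everything is 1%-significant passes through unchanged
  cs <- ndr_table2()
  for (eq in names(cs)) {
    cs[[eq]]$constant$sig <- "1%"
    for (cv in names(cs[[eq]]$covariates))
      if (!is.null(cs[[eq]]$covariates[[cv]]$value))
        cs[[eq]]$covariates[[cv]]$sig <- "1%"
  }
  filtered <- filter_significant(cs, 0.10)
  attr(filtered, "sig_level") <- attr(cs, "sig_level")
  expect_identical(filtered, cs)
  expect_error(filter_significant(ndr_table2(), 0.2), "level must be")
})
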