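test_that("the lookback window is closed on both ends", {
  cs <- codeset("mi", "ICD10CM", "I21", "quan_icd10")
  idx <- as.Date("2018-06-01")
  dx <- function(offset) data.frame(code = "I21", vocabulary = "ICD10CM",
                                    date = idx - offset)
  expect_false(any(detect_conditions(dx(366), idx, cs, "quan_icd10")))
  expect_true(detect_conditions(dx(365), idx, cs, "quan_icd10")[["mi"]])
  expect_true(detect_conditions(dx(0), idx, cs, "quan_icd10")[["mi"]])
  # a diagnosis after index never counts
  expect_false(any(detect_conditions(dx(-1), idx, cs, "quan_icd10")))
  # no diagnoses at all
  empty <- data.frame(code = character(), vocabulary = character(),
                      date = as.Date(character()))
  expect_false(any(detect_conditions(empty, idx, cs, "quan_icd10")))
})

test_that("records in unreadable vocabularies are skipped, not errors", {
  cs <- codeset("mi", "ICD10CM", "I21", "quan_icd10")
  dx <- data.frame(code = c("I21", "410"), vocabulary = c("ICD10CM", "ICD9CM"),
                   date = as.Date("2018-05-01"))
  expect_message(
    flags <- detect_conditions(dx, as.Date("2018-06-01"), cs, "quan_icd10"),
    "skipped 1")
  expect_true(flags[["mi"]])
})

test_that("prefix matching follows the printed Quan list convention", {
  quan <- quan_codesets("ICD10CM")
  idx <- as.Date("2018-06-01")
  dx <- data.frame(code = c("I21.09", "E11.21", "C77.1"),
                   vocabulary = "ICD10CM", date = idx - 10)
  flags <- detect_conditions(dx, idx, quan, "quan_icd10", match = "prefix")
  expect_true(flags[["mi"]])
  expect_true(flags[["diabetes_complicated"]])
  expect_true(flags[["metastatic_tumor"]])
  expect_false(flags[["chf"]])
  # exact matching must not fire on longer codes
  flags_exact <- detect_conditions(dx, idx, quan, "quan_icd10", match = "exact")
  expect_false(any(flags_exact))
})

test_that("weighted scoring applies the severity hierarchy", {
  defs <- cci_definitions()
  expect_equal(sum(defs$weight), 33L)
  base <- setNames(rep(FALSE, nrow(defs)), defs$condition)
  expect_equal(compute_cci(base), 0L)

  f <- base; f[c("mi", "chf")] <- TRUE
  expect_equal(compute_cci(f), 2L)

  f <- base; f[c("malignancy", "metastatic_tumor")] <- TRUE
  expect_equal(compute_cci(f, apply_hierarchy = TRUE), 6L)
  expect_equal(compute_cci(f, apply_hierarchy = FALSE), 8L)

  all_on <- base; all_on[] <- TRUE
  expect_equal(compute_cci(all_on, apply_hierarchy = TRUE), 29L)
  expect_equal(compute_cci(all_on, apply_hierarchy = FALSE), 33L)
})

test_that("hierarchy never increases the score and the gap is exactly the superseded weights", {
  defs <- cci_definitions()
  set.seed(42)
  for (i in 1:50) {
    f <- setNames(runif(nrow(defs)) < 0.4, defs$condition)
    on <- compute_cci(f, apply_hierarchy = TRUE)
    off <- compute_cci(f, apply_hierarchy = FALSE)
    expect_lte(on, off)
    sup <- match(defs$superseded_by, defs$condition)
    dropped <- !is.na(sup) & f[defs$condition] & f[defs$condition[ifelse(is.na(sup), 1L, sup)]]
    expect_equal(off - on, sum(defs$weight[dropped]))
  }
})

test_that("adding a diagnosis never lowers a flag or the score", {
  v <- gen_vocabulary(vocab_spec(seed = 3))
  cl <- gen_claims(claims_spec(n_patients = 60, seed = 3), v)
  co <- build_cohort(cl$bundle, 2018)
  dx <- cl$bundle$condition_occurrences
  r1 <- score_cohort(co, dx, v$quan_codeset, "quan_icd10")
  # add one more matching record for every person
  extra <- data.frame(person_id = co$person_id,
                      code = v$role_codes$code[v$role_codes$role == "clean" &
                                                 v$role_codes$condition == "mi"][1],
                      vocabulary = "ICD10CM",
                      date = co$index_date)
  r2 <- score_cohort(co, rbind(dx, extra), v$quan_codeset, "quan_icd10")
  expect_true(all(r2$score >= r1$score))
  expect_true(all(r2$mi))
  conds <- cci_definitions()$condition
  expect_true(all(as.matrix(r2[conds]) >= as.matrix(r1[conds])))
})

test_that("vectorized cohort scoring matches the per-patient oracle exactly", {
  v <- gen_vocabulary(vocab_spec(seed = 21))
  cl <- gen_claims(claims_spec(n_patients = 500, disc_snomed_only = 0.05,
                               disc_quan_only = 0.02, seed = 21), v)
  co <- build_cohort(cl$bundle, 2018)
  dx <- cl$bundle$condition_occurrences
  for (hier in c(TRUE, FALSE)) {
    res <- score_cohort(co, dx, v$quan_codeset, "quan_icd10",
                        apply_hierarchy = hier)
    want <- oracle_score(co$person_id, as.Date(co$index_date), dx,
                         v$quan_codeset, "ICD10CM", apply_hierarchy = hier)
    expect_equal(res$score, as.integer(want))
  }
  expect_equal(nrow(score_cohort(co[0, ], dx, v$quan_codeset, "quan_icd10")), 0L)
})
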