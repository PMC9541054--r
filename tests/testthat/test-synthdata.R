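test_that("generator specs validate their inputs", {
  expect_error(vocab_spec(n_clean = -1), class = "snomedcci_spec_error")
  expect_error(claims_spec(n_patients = 0), class = "snomedcci_spec_error")
  expect_error(claims_spec(prevalence = c(mi = 1.2)),
               class = "snomedcci_spec_error")
  expect_error(claims_spec(disc_snomed_only = 0.7, disc_quan_only = 0.6),
               class = "snomedcci_spec_error")
})

test_that("identical specs give byte-identical output; seeds change it", {
  s <- vocab_spec(seed = 13)
  v1 <- gen_vocabulary(s)
  v2 <- gen_vocabulary(s)
  expect_identical(lapply(v1[-1], identity), lapply(v2[-1], identity))
  expect_identical(as.data.frame(v1$store$concepts),
                   as.data.frame(v2$store$concepts))

  cs <- claims_spec(n_patients = 150, seed = 8)
  c1 <- gen_claims(cs, v1)
  c2 <- gen_claims(cs, v1)
  expect_identical(c1$truth, c2$truth)
  expect_identical(unclass(c1$bundle), unclass(c2$bundle))
  c3 <- gen_claims(claims_spec(n_patients = 150, seed = 9), v1)
  expect_false(identical(c1$truth, c3$truth))
})

test_that("engineered structures appear in the stated numbers", {
  spec <- vocab_spec(conditions = c("mi", "chf"), n_clean = 1,
                     n_fanout_gain = 2, n_fanout_noise = 1, n_deprecated = 3,
                     n_specificity = 1, worked_examples = FALSE, seed = 1)
  v <- gen_vocabulary(spec)
  # deprecated codes: no maps_to edge, labeled as such
  dep <- v$labels[v$labels$category == "deprecated_unmapped", ]
  expect_equal(nrow(dep), 6L)
  dep_ids <- v$store$concepts$concept_id[
    normalize_code(v$store$concepts$code) %in% dep$code]
  expect_false(any(dep_ids %in% v$store$mappings$source_concept_id))
  # fan-outs: 2 gain + 1 noise per condition
  expect_equal(sum(v$labels$adjudication == "information_gain"), 4L)
  expect_equal(sum(v$labels$adjudication == "added_noise"), 2L)
  # all-zero spec with a single clean mapping: no labels at all
  tiny <- gen_vocabulary(vocab_spec(conditions = "mi", n_clean = 1,
                                    n_fanout_gain = 0, n_fanout_noise = 0,
                                    n_deprecated = 0, n_specificity = 0,
                                    worked_examples = FALSE))
  expect_equal(nrow(tiny$labels), 0L)
  expect_equal(nrow(tiny$store$mappings), 1L)
})

test_that("realized prevalence tracks the spec within binomial error", {
  v <- gen_vocabulary(vocab_spec(seed = 4))
  prev <- c(mi = 0.3, chf = 0.05, renal = 0.5)
  cl <- gen_claims(claims_spec(n_patients = 3000, prevalence = prev, seed = 4), v)
  for (cond in names(prev)) {
    p_hat <- mean(cl$truth[[cond]])
    se <- sqrt(prev[[cond]] * (1 - prev[[cond]]) / 3000)
    expect_lt(abs(p_hat - prev[[cond]]), 3 * se)
  }
  # planted conditions always produce an in-window record for the patient
  flagged <- cl$truth$person_id[cl$truth$mi]
  dx <- cl$bundle$condition_occurrences
  expect_true(all(flagged %in% dx$person_id))
})

test_that("zero discordance makes the two algorithms see identical patients", {
  v <- gen_vocabulary(vocab_spec(seed = 6))
  ad <- adapt_codeset(v$store, v$quan_codeset, v$adjudication)
  cl <- gen_claims(claims_spec(n_patients = 400, seed = 6), v)
  co <- build_cohort(cl$bundle, 2018)
  dx <- cl$bundle$condition_occurrences
  rs <- score_cohort(co, dx, ad$snomed_codeset, "snomed", store = v$store)
  rq <- score_cohort(co, dx, v$quan_codeset, "quan_icd10")
  conds <- cci_definitions()$condition
  expect_identical(as.matrix(rs[conds]), as.matrix(rq[conds]))
  # and both recover the planted truth exactly
  tr <- cl$truth[match(co$person_id, cl$truth$person_id), ]
  expect_identical(unname(as.matrix(rs[conds])), unname(as.matrix(tr[conds])))
  expect_equal(rs$score, tr$true_cci)
})

test_that("mortality honors the logistic model on the true score", {
  v <- gen_vocabulary(vocab_spec(seed = 10))
  # prevalence zero: every CCI is 0 and deaths occur at the intercept rate
  cl <- gen_claims(claims_spec(n_patients = 4000,
                               prevalence = c(mi = 0, chf = 0),
                               mortality_intercept = -2,
                               noise_code_rate = 0, seed = 10), v)
  expect_true(all(cl$truth$true_cci == 0L))
  p <- mean(cl$truth$died)
  expect_lt(abs(p - plogis(-2)), 3 * sqrt(plogis(-2) * (1 - plogis(-2)) / 4000))
  expect_equal(nrow(cl$bundle$condition_occurrences), 0L)
})
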