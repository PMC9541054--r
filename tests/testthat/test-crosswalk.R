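test_that("discrepant-code partition is exact set algebra", {
  p <- find_discrepant_codes(c("a", "b"), c("b", "c"))
  expect_equal(p$both, "B")
  expect_equal(p$quan_only, "A")
  expect_equal(p$snomed_only, "C")

  same <- find_discrepant_codes(c("x", "y"), c("y", "x"))
  expect_length(same$snomed_only, 0)
  expect_length(same$quan_only, 0)

  # partition completeness on random inputs
  for (seed in 1:25) {
    set.seed(seed)
    universe <- sprintf("C%02d", 1:40)
    q <- sample(universe, sample.int(40, 1))
    b <- sample(universe, sample.int(40, 1))
    p <- find_discrepant_codes(q, b)
    expect_length(intersect(p$both, p$snomed_only), 0)
    expect_length(intersect(p$both, p$quan_only), 0)
    expect_equal(sort(c(p$both, p$snomed_only, p$quan_only)),
                 sort(union(toupper(q), toupper(b))))
  }
})

test_that("discrepancy categories are assigned per mapping structure", {
  store <- tiny_fixture_store()
  # extra back-mapped code sharing a standard target with an in-set code
  expect_equal(classify_discrepancy(store, "snomed_only", "A00.9", "ICD10CM"),
               "multiple_icd_to_one_snomed")
  # deprecated code: no maps_to edge at all
  expect_equal(classify_discrepancy(store, "quan_only", "D99.9", "ICD10CM"),
               "deprecated_unmapped")
  # in-set code with an edge whose target was excluded
  expect_equal(classify_discrepancy(store, "quan_only", "A00.1", "ICD10CM"),
               "specificity")
  expect_error(classify_discrepancy(store, "both", "A00.0", "ICD10CM"),
               class = "snomedcci_contract_error")
})

test_that("a perfect crosswalk yields an empty ledger", {
  concepts <- data.frame(concept_id = 1:4,
                         code = c("A1", "A2", "1", "2"),
                         vocabulary = c("ICD10CM", "ICD10CM", "SNOMED", "SNOMED"),
                         name = letters[1:4], valid = TRUE)
  mappings <- data.frame(source_concept_id = 1:2, target_concept_id = 3:4)
  store <- vocab_store(concepts, mappings)
  qs <- codeset("mi", "ICD10CM", c("A1", "A2"), "quan_icd10")
  out <- adapt_codeset(store, qs)
  expect_equal(nrow(out$ledger), 0L)
  expect_equal(sort(out$snomed_codeset$code), c("1", "2"))
  expect_equal(out$overlap$n_both, 2L)
})

test_that("fan-out, exclusion and adjudication reproduce the worked audit cases", {
  v <- gen_vocabulary(vocab_spec(seed = 5))
  out <- adapt_codeset(v$store, v$quan_codeset, v$adjudication)
  led <- out$ledger

  # heart-failure code lost to an over-broad shared target
  hf <- led[led$code == "I132", ]
  expect_equal(hf$side, "quan_only")
  expect_equal(hf$category, "specificity")
  expect_false(any(grepl("I131", out$snomed_codeset$code)))

  # migraine-with-infarction code gained through the shared target, relevant
  mig <- led[led$code == "G4361", ]
  expect_equal(mig$side, "snomed_only")
  expect_equal(mig$category, "multiple_icd_to_one_snomed")
  expect_equal(mig$adjudication, "information_gain")

  # secondary/drug-induced diabetes pulled in as noise, target retained
  noise <- led[led$code %in% c("2494", "E092"), ]
  expect_equal(nrow(noise), 2L)
  expect_setequal(noise$adjudication, "added_noise")
  kidney_target <- unique(noise$via_snomed_ids)
  expect_length(kidney_target, 1L)
  expect_true(kidney_target %in%
                out$snomed_codeset$code[out$snomed_codeset$condition ==
                                          "diabetes_complicated"])
})

test_that("adjudication referencing an unknown concept is rejected", {
  store <- tiny_fixture_store()
  qs <- codeset("mi", "ICD10CM", "A00.0", "quan_icd10")
  adj <- data.frame(key_type = "snomed_id", key = "31415926",
                    decision = "exclude", note = "")
  expect_error(adapt_codeset(store, qs, adj), "31415926",
               class = "snomedcci_lookup_error")
})

test_that("classifier recovers every engineered label on generated stores", {
  for (seed in c(2, 17, 40)) {
    v <- gen_vocabulary(vocab_spec(seed = seed))
    out <- adapt_codeset(v$store, v$quan_codeset, v$adjudication)
    got <- out$ledger[order(out$ledger$condition, out$ledger$code,
                            out$ledger$vocabulary),
                      c("condition", "code", "vocabulary", "side",
                        "category", "adjudication")]
    want <- v$labels[order(v$labels$condition, v$labels$code,
                           v$labels$vocabulary), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("report arithmetic conserves ledger counts and rounds half-up", {
  v <- gen_vocabulary(vocab_spec(seed = 9))
  out <- adapt_codeset(v$store, v$quan_codeset, v$adjudication)
  counts <- ledger_category_counts(out$ledger)
  rep <- diagnostics_report(out$overlap, counts)
  tot <- rep$categories[rep$categories$condition == "TOTAL", ]
  expect_equal(tot$n_information_gain + tot$n_added_noise + tot$n_pending +
                 tot$n_deprecated + tot$n_specificity,
               nrow(out$ledger))
  ov_tot <- rep$overlap[rep$overlap$condition == "TOTAL", ]
  expect_equal(ov_tot$n_snomed_only + ov_tot$n_quan_only, nrow(out$ledger))
  expect_equal(rep$summary[["n_discrepant"]], nrow(out$ledger))

  # empty inputs give an all-zero table
  empty <- diagnostics_report(
    data.frame(condition = character(), vocabulary = character(),
               n_both = integer(), n_snomed_only = integer(),
               n_quan_only = integer()),
    data.frame(condition = character(), n_information_gain = integer(),
               n_added_noise = integer(), n_deprecated = integer(),
               n_specificity = integer()))
  expect_equal(empty$summary[["n_codes"]], 0)
  expect_equal(empty$summary[["pct_discrepant"]], 0)

  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(35.714, 1), 35.7)
})
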