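test_that("loading validates schema and referential integrity", {
  g <- random_vocab_graph(1)
  dir <- withr::local_tempdir()
  write1 <- function(df, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    path
  }
  cp <- write1(g$concepts, "concepts.tsv")
  mp <- write1(g$mappings, "mappings.tsv")
  ap <- write1(g$ancestors, "ancestors.tsv")
  store <- suppressMessages(load_vocabulary(cp, mp, ap, dialect = "compact"))
  expect_s3_class(store, "vocab_store")
  expect_equal(nrow(store$concepts), nrow(g$concepts))
  expect_equal(nrow(store$mappings), nrow(unique(g$mappings)))

  # missing column -> schema error naming the column
  bad <- g$concepts[, setdiff(names(g$concepts), "vocabulary")]
  bp <- write1(bad, "bad_concepts.tsv")
  expect_error(suppressMessages(load_vocabulary(bp, mp, ap, dialect = "compact")),
               "vocabulary", class = "snomedcci_schema_error")

  # dangling edge endpoint -> integrity error naming the id
  dang <- rbind(g$mappings,
                data.frame(source_concept_id = 9999L, target_concept_id = 1L))
  dp <- write1(dang, "dangling.tsv")
  expect_error(suppressMessages(load_vocabulary(cp, dp, ap, dialect = "compact")),
               "9999", class = "snomedcci_integrity_error")
})

test_that("the OMOP dialect maps its columns and keeps only Maps to rows", {
  dir <- withr::local_tempdir()
  concept <- data.frame(
    concept_id = 1:3,
    concept_code = c("I13.2", "123456", "654321"),
    vocabulary_id = c("ICD10CM", "SNOMED", "SNOMED"),
    concept_name = c("icd", "std", "other std"),
    invalid_reason = c("", "", "D"))
  rel <- data.frame(concept_id_1 = c(1L, 1L), concept_id_2 = c(2L, 3L),
                    relationship_id = c("Maps to", "Is a"))
  cp <- file.path(dir, "CONCEPT.csv")
  rp <- file.path(dir, "CONCEPT_RELATIONSHIP.csv")
  write.table(concept, cp, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(rel, rp, sep = "\t", row.names = FALSE, quote = FALSE)
  store <- suppressMessages(load_vocabulary(cp, rp, dialect = "omop"))
  expect_equal(nrow(store$mappings), 1L)
  expect_false(store$concepts[store$concepts$concept_id == 3L, ]$valid)
  fm <- forward_map(store, "I13.2", "ICD10CM")
  expect_equal(fm$snomed_ids, 2L)
})

test_that("forward and reverse mapping follow edge semantics", {
  store <- tiny_fixture_store()
  # empty input is vacuous
  fm0 <- forward_map(store, data.frame(code = character(),
                                       vocabulary = character()))
  expect_identical(fm0$snomed_ids, integer())

  # two codes sharing one target collapse to a single concept
  fm <- forward_map(store, data.frame(code = c("A00.1", "A00.9"),
                                      vocabulary = "ICD10CM"))
  expect_equal(fm$snomed_ids, 6L)

  # deprecated code with no edge lands in the unmapped side-list
  fm2 <- forward_map(store, data.frame(code = c("A00.0", "D99.9"),
                                       vocabulary = "ICD10CM"))
  expect_equal(fm2$snomed_ids, 5L)
  expect_equal(fm2$unmapped$code, "D99.9")

  # reverse of a shared target returns both source codes, normalized
  rv <- reverse_map(store, 6L)
  expect_setequal(rv$code, c("A001", "A009"))

  # dotted and undotted spellings are the same code
  expect_equal(forward_map(store, "a000", "ICD10CM")$snomed_ids,
               forward_map(store, "A00.0", "ICD10CM")$snomed_ids)

  expect_error(reverse_map(store, 424242L), "424242",
               class = "snomedcci_lookup_error")
})

test_that("descendant expansion pulls in codes mapped to child concepts", {
  concepts <- data.frame(
    concept_id = 1:5,
    code = c("A1", "A2", "D1", "10", "11"),
    vocabulary = c(rep("ICD10CM", 3), "SNOMED", "SNOMED"),
    name = letters[1:5], valid = TRUE)
  mappings <- data.frame(source_concept_id = c(1L, 2L, 3L),
                         target_concept_id = c(4L, 4L, 5L))
  ancestors <- data.frame(ancestor_concept_id = 4L,
                          descendant_concept_id = 5L, min_levels = 1L)
  store <- vocab_store(concepts, mappings, ancestors)
  expected_off <- oracle_reverse(concepts, mappings, ancestors, 4L, FALSE)
  expected_on <- oracle_reverse(concepts, mappings, ancestors, 4L, TRUE)
  expect_equal(reverse_map(store, 4L, include_descendants = FALSE)$code,
               expected_off)
  expect_equal(sort(unique(reverse_map(store, 4L)$code)), expected_on)
  expect_true("D1" %in% reverse_map(store, 4L)$code)
})

test_that("round trip containment and monotonicity hold on random graphs", {
  for (seed in 1:30) {
    g <- random_vocab_graph(seed)
    # every ICD code is mapped, so C is contained in reverse(forward(C))
    set.seed(seed + 1000)
    C <- sample(g$icd_codes, sample.int(length(g$icd_codes), 1L))
    fm <- forward_map(g$store, data.frame(code = C, vocabulary = "ICD10CM"))
    expect_equal(nrow(fm$unmapped), 0L)
    back <- reverse_map(g$store, fm$snomed_ids)$code
    expect_true(all(normalize_code(C) %in% back))

    # adding a SNOMED id never shrinks the reverse image
    sn <- g$store$concepts$concept_id[g$store$concepts$vocabulary == "SNOMED"]
    sub <- sample(sn, 2L)
    r_small <- reverse_map(g$store, sub[1L])$code
    r_big <- reverse_map(g$store, sub)$code
    expect_true(all(r_small %in% r_big))

    # agreement with the naive edge-scan oracle
    expect_equal(fm$snomed_ids,
                 oracle_forward(g$concepts, g$mappings, C, "ICD10CM"))
    expect_equal(sort(unique(back)),
                 oracle_reverse(g$concepts, g$mappings, g$ancestors,
                                fm$snomed_ids))
  }
})
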