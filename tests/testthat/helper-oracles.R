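# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own query paths: plain edge scans,
# all-pairs enumeration, and a hand-rolled per-patient scoring loop.

# all-pairs concordance with ties at one half
oracle_c <- function(scores, outcomes) {
  cases <- scores[outcomes == 1]
  controls <- scores[outcomes == 0]
  cmp <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# naive forward map: scan every edge for every code
oracle_forward <- function(concepts, mappings, codes, vocabulary) {
  norm <- function(x) gsub(".", "", toupper(trimws(x)), fixed = TRUE)
  ids <- concepts$concept_id[norm(concepts$code) %in% norm(codes) &
                               concepts$vocabulary == vocabulary]
  sort(unique(mappings$target_concept_id[mappings$source_concept_id %in% ids]))
}

# naive reverse map: optional descendant expansion by direct ancestor rows,
# then scan every edge
oracle_reverse <- function(concepts, mappings, ancestors, snomed_ids,
                           include_descendants = TRUE) {
  ids <- snomed_ids
  if (include_descendants) {
    ids <- unique(c(ids, ancestors$descendant_concept_id[
      ancestors$ancestor_concept_id %in% snomed_ids]))
  }
  src <- mappings$source_concept_id[mappings$target_concept_id %in% ids]
  hit <- concepts[concepts$concept_id %in% src &
                    concepts$vocabulary %in% c("ICD9CM", "ICD10CM"), ]
  norm <- function(x) gsub(".", "", toupper(trimws(x)), fixed = TRUE)
  sort(unique(norm(hit$code)))
}

# random mapping graph: n_icd ICD codes each with >= 1 maps_to edge, n_sn
# SNOMED concepts, a sprinkle of extra fan-out edges and ancestor rows
random_vocab_graph <- function(seed, n_icd = 12L, n_sn = 6L) {
  set.seed(seed)
  sn_ids <- seq_len(n_sn)
  icd_ids <- n_sn + seq_len(n_icd)
  concepts <- data.frame(
    concept_id = c(sn_ids, icd_ids),
    code = c(as.character(sn_ids), sprintf("T%02d.%d", icd_ids, icd_ids %% 10)),
    vocabulary = c(rep("SNOMED", n_sn), rep("ICD10CM", n_icd)),
    name = paste("concept", c(sn_ids, icd_ids)),
    valid = TRUE)
  mappings <- data.frame(
    source_concept_id = icd_ids,
    target_concept_id = sample(sn_ids, n_icd, replace = TRUE))
  extra <- sample(icd_ids, max(1L, n_icd %/% 3L))
  mappings <- rbind(mappings, data.frame(
    source_concept_id = extra,
    target_concept_id = sample(sn_ids, length(extra), replace = TRUE)))
  mappings <- unique(mappings)
  pairs <- expand.grid(ancestor_concept_id = sn_ids,
                       descendant_concept_id = sn_ids)
  pairs <- pairs[pairs$ancestor_concept_id != pairs$descendant_concept_id, ]
  pairs <- pairs[sample.int(nrow(pairs), min(nrow(pairs), n_sn)), ]
  pairs$min_levels <- 1L
  list(concepts = concepts, mappings = mappings, ancestors = pairs,
       store = vocab_store(concepts, mappings, pairs),
       icd_codes = concepts$code[concepts$vocabulary == "ICD10CM"])
}

# hand-rolled per-patient scorer, independent of the engine's vectorized path
oracle_score <- function(person_ids, index_dates, diagnoses, codesets,
                         vocabulary, apply_hierarchy = TRUE) {
  defs <- data.frame(
    condition = c("mi", "chf", "pvd", "cvd", "dementia", "chronic_pulmonary",
                  "rheumatic", "pud", "mild_liver", "diabetes_uncomplicated",
                  "diabetes_complicated", "hemiplegia_paraplegia", "renal",
                  "malignancy", "severe_liver", "metastatic_tumor", "hiv_aids"),
    weight = c(rep(1L, 10L), 2L, 2L, 2L, 2L, 3L, 6L, 6L))
  norm <- function(x) gsub(".", "", toupper(trimws(x)), fixed = TRUE)
  cs <- codesets[codesets$vocabulary == vocabulary, ]
  vapply(seq_along(person_ids), function(i) {
    dx <- diagnoses[diagnoses$person_id == person_ids[i] &
                      diagnoses$vocabulary == vocabulary, ]
    d <- as.Date(dx$date)
    dx <- dx[d >= index_dates[i] - 365 & d <= index_dates[i], ]
    flag <- vapply(defs$condition, function(cond) {
      any(norm(dx$code) %in% norm(cs$code[cs$condition == cond]))
    }, logical(1))
    if (apply_hierarchy) {
      if (flag[["diabetes_complicated"]]) flag[["diabetes_uncomplicated"]] <- FALSE
      if (flag[["severe_liver"]]) flag[["mild_liver"]] <- FALSE
      if (flag[["metastatic_tumor"]]) flag[["malignancy"]] <- FALSE
    }
    sum(defs$weight[flag])
  }, numeric(1))
}

# minimal store used by several crosswalk unit tests: one in-set code whose
# target also back-maps to an out-of-scope code, one deprecated code, one
# clean mapping
tiny_fixture_store <- function() {
  concepts <- data.frame(
    concept_id = 1:7,
    code = c("A00.0", "A00.1", "A00.9", "D99.9", "101", "102", "103"),
    vocabulary = c(rep("ICD10CM", 4), rep("SNOMED", 3)),
    name = c("clean", "in-set broad", "out-of-scope", "deprecated",
             "std clean", "std broad", "std orphan"),
    valid = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  mappings <- data.frame(source_concept_id = c(1L, 2L, 3L),
                         target_concept_id = c(5L, 6L, 6L))
  vocab_store(concepts, mappings)
}
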