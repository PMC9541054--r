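# Charlson comorbidity index: condition detection over a 365-day lookback
# and weighted scoring with the standard condition hierarchy.

#' The 17 Charlson conditions, weights and hierarchy
#'
#' Weights follow the widely used claims convention for the Charlson index:
#' 1 for the first ten conditions; 2 for diabetes with chronic complications,
#' hemiplegia/paraplegia, renal disease and malignancy; 3 for moderate or
#' severe liver disease; 6 for metastatic solid tumor and AIDS/HIV. The
#' hierarchy (`superseded_by`) encodes that a milder condition does not add
#' weight when its severe form is also present: diabetes without chronic
#' complications is superseded by diabetes with chronic complications, mild
#' liver disease by moderate/severe liver disease, and malignancy by
#' metastatic solid tumor. The table is plain data so forks can supply their
#' own weights.
#'
#' @return data.frame with columns `condition`, `label`, `weight`,
#'   `superseded_by` (`NA` when none).
#' @export
cci_definitions <- function() {
  data.frame(
    condition = c("mi", "chf", "pvd", "cvd", "dementia", "chronic_pulmonary",
                  "rheumatic", "pud", "mild_liver", "diabetes_uncomplicated",
                  "diabetes_complicated", "hemiplegia_paraplegia", "renal",
                  "malignancy", "severe_liver", "metastatic_tumor",
                  "hiv_aids"),
    label = c("Myocardial infarction", "Congestive heart failure",
              "Peripheral vascular disease", "Cerebrovascular disease",
              "Dementia", "Chronic pulmonary disease", "Rheumatic disease",
              "Peptic ulcer disease", "Mild liver disease",
              "Diabetes without chronic complications",
              "Diabetes with chronic complications",
              "Hemiplegia or paraplegia", "Renal disease",
              "Malignancy, except skin neoplasms",
              "Moderate or severe liver disease", "Metastatic solid tumor",
              "AIDS/HIV"),
    weight = c(rep(1L, 10L), 2L, 2L, 2L, 2L, 3L, 6L, 6L),
    superseded_by = c(rep(NA_character_, 8L), "severe_liver",
                      "diabetes_complicated", NA, NA, NA, "metastatic_tumor",
                      NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

# algorithm -> the vocabulary of records it can read
#' @noRd
algorithm_vocab <- function(algorithm) {
  switch(algorithm,
         snomed = "SNOMED", quan_icd9 = "ICD9CM", quan_icd10 = "ICD10CM",
         abort_cci(sprintf("unknown algorithm: %s", algorithm),
                   "snomedcci_contract_error"))
}

# per-condition matching sets, normalized (and descendant-expanded for SNOMED)
#' @noRd
condition_code_sets <- function(codesets, algorithm, store = NULL,
                                include_descendants = TRUE) {
  voc <- algorithm_vocab(algorithm)
  cs <- codesets[codesets$vocabulary == voc, , drop = FALSE]
  sets <- split(normalize_code(cs$code), cs$condition)
  if (voc == "SNOMED" && include_descendants && !is.null(store)) {
    sn <- store$concepts[vocabulary == "SNOMED"]
    sets <- lapply(sets, function(codes) {
      ids <- sn[norm_code %in% codes, concept_id]
      desc <- snomed_descendants(store, ids)
      unique(c(codes, sn[concept_id %in% desc, norm_code]))
    })
  }
  lapply(sets, unique)
}

# which (row, condition) pairs match; diagnoses_dt must carry norm_code.
# exact: set membership; prefix: codeset entries are prefixes of record codes
# (the convention for printed Quan-style lists such as "410.x").
#' @noRd
match_condition_rows <- function(norm_codes, sets, match) {
  hits <- lapply(names(sets), function(cond) {
    codes <- sets[[cond]]
    idx <- if (match == "exact") {
      which(norm_codes %in% codes)
    } else {
      lens <- sort(unique(nchar(codes)))
      out <- logical(length(norm_codes))
      for (L in lens) {
        out <- out | (substr(norm_codes, 1L, L) %in% codes[nchar(codes) == L])
      }
      which(out)
    }
    if (length(idx)) data.frame(row = idx, condition = cond) else NULL
  })
  hits <- Filter(Negate(is.null), hits)
  if (length(hits)) do.call(rbind, hits) else
    data.frame(row = integer(), condition = character())
}

#' Detect Charlson conditions for one patient
#'
#' A condition is flagged when at least one diagnosis dated at or within 365
#' days prior to the index date (both ends inclusive) matches the
#' condition's codeset in the vocabulary the chosen algorithm reads.
#' Diagnoses in vocabularies the algorithm cannot read are skipped (their
#' count is reported via `message()`); mixed-vocabulary extracts are
#' expected.
#'
#' @param diagnoses data.frame with columns `code`, `vocabulary`, `date`.
#' @param index_date Index date (`Date` or parseable string).
#' @param codesets Interchange-format codesets covering the algorithm's
#'   vocabulary.
#' @param algorithm `"snomed"`, `"quan_icd9"` or `"quan_icd10"`.
#' @param store Optional [vocab_store()], used by the SNOMED algorithm for
#'   descendant expansion of codeset concepts.
#' @param match `"exact"` (normalized equality) or `"prefix"` (codeset
#'   entries are code prefixes, the convention for the printed Quan lists).
#' @param include_descendants Expand SNOMED codesets to descendants when a
#'   store is supplied (default `TRUE`).
#' @param definitions Condition table, default [cci_definitions()].
#' @param lookback_days Lookback window length in days (default 365).
#' @return Named logical vector, one element per condition.
#' @export
detect_conditions <- function(diagnoses, index_date, codesets,
                              algorithm = c("snomed", "quan_icd9", "quan_icd10"),
                              store = NULL, match = c("exact", "prefix"),
                              include_descendants = TRUE,
                              definitions = cci_definitions(),
                              lookback_days = 365L) {
  algorithm <- match.arg(algorithm)
  match <- match.arg(match)
  assert_cols(diagnoses, c("code", "vocabulary", "date"), "diagnoses")
  index_date <- as_date_safe(index_date, "index_date")
  flags <- stats::setNames(rep(FALSE, nrow(definitions)), definitions$condition)
  if (nrow(diagnoses) == 0L) return(flags)
  d <- as_date_safe(diagnoses$date, "diagnosis date")
  in_window <- d >= index_date - lookback_days & d <= index_date
  voc <- algorithm_vocab(algorithm)
  readable <- diagnoses$vocabulary == voc
  n_skipped <- sum(!readable)
  if (n_skipped > 0L) {
    message(sprintf("detect_conditions: skipped %d diagnosis record(s) in vocabularies the %s algorithm cannot read",
                    n_skipped, algorithm))
  }
  dx <- diagnoses[in_window & readable, , drop = FALSE]
  if (nrow(dx) == 0L) return(flags)
  sets <- condition_code_sets(codesets, algorithm, store, include_descendants)
  hit <- match_condition_rows(normalize_code(dx$code), sets, match)
  flags[unique(hit$condition)] <- TRUE
  flags
}

#' Weighted Charlson score from condition flags
#'
#' With `apply_hierarchy = TRUE` (the standard convention) a condition's
#' weight is not counted when its superseding severe form is also flagged;
#' with `FALSE` the score is the plain weighted sum. The maximum score is 29
#' with the hierarchy, 33 without.
#'
#' @param flags Named logical vector as returned by [detect_conditions()].
#' @param definitions Condition table, default [cci_definitions()].
#' @param apply_hierarchy Apply the supersession rules (default `TRUE`).
#' @return Non-negative integer score.
#' @export
compute_cci <- function(flags, definitions = cci_definitions(),
                        apply_hierarchy = TRUE) {
  missing <- setdiff(definitions$condition, names(flags))
  if (length(missing)) {
    abort_cci(sprintf("flags missing condition(s): %s",
                      paste(missing, collapse = ", ")),
              "snomedcci_contract_error")
  }
  f <- as.logical(flags[definitions$condition])
  count <- f
  if (apply_hierarchy) {
    sup <- match(definitions$superseded_by, definitions$condition)
    dropped <- !is.na(sup) & f & f[ifelse(is.na(sup), 1L, sup)]
    count <- f & !dropped
  }
  as.integer(sum(definitions$weight[count]))
}

#' Score a cohort under one coding algorithm
#'
#' Vectorized detection and scoring: one `CciResult` row per cohort member
#' (condition flags plus weighted score), deterministic given its inputs.
#'
#' @param cohort data.frame with columns `person_id`, `index_date`.
#' @param diagnoses data.frame with columns `person_id`, `code`,
#'   `vocabulary`, `date` (all condition occurrences; the engine applies the
#'   lookback window itself).
#' @param codesets,algorithm,store,match,include_descendants,definitions,lookback_days
#'   As in [detect_conditions()].
#' @param apply_hierarchy Passed to [compute_cci()].
#' @return data.frame with `person_id`, `algorithm`, one logical column per
#'   condition, and `score`; rows ordered as in `cohort`.
#' @export
score_cohort <- function(cohort, diagnoses, codesets,
                         algorithm = c("snomed", "quan_icd9", "quan_icd10"),
                         store = NULL, match = c("exact", "prefix"),
                         include_descendants = TRUE,
                         definitions = cci_definitions(),
                         apply_hierarchy = TRUE, lookback_days = 365L) {
  algorithm <- match.arg(algorithm)
  match <- match.arg(match)
  assert_cols(cohort, c("person_id", "index_date"), "cohort")
  assert_cols(diagnoses, c("person_id", "code", "vocabulary", "date"),
              "diagnoses")
  conds <- definitions$condition
  flag_mat <- matrix(FALSE, nrow(cohort), length(conds),
                     dimnames = list(NULL, conds))
  if (nrow(cohort) > 0L && nrow(diagnoses) > 0L) {
    voc <- algorithm_vocab(algorithm)
    dx <- data.table::as.data.table(diagnoses)[vocabulary == voc]
    if (nrow(dx)) {
      dx[, date := as_date_safe(date, "diagnosis date")]
      idx <- data.table::data.table(person_id = cohort$person_id,
                                    index_date = as_date_safe(cohort$index_date,
                                                              "index_date"),
                                    .row = seq_len(nrow(cohort)))
      dx <- dx[idx, on = "person_id", allow.cartesian = TRUE, nomatch = NULL]
      dx <- dx[date >= index_date - lookback_days & date <= index_date]
      if (nrow(dx)) {
        sets <- condition_code_sets(codesets, algorithm, store,
                                    include_descendants)
        hit <- match_condition_rows(normalize_code(dx$code), sets, match)
        if (nrow(hit)) {
          flag_mat[cbind(dx$.row[hit$row],
                         match(hit$condition, conds))] <- TRUE
        }
      }
    }
  }
  scores <- if (nrow(flag_mat)) {
    apply(flag_mat, 1L, compute_cci, definitions = definitions,
          apply_hierarchy = apply_hierarchy)
  } else integer()
  out <- data.frame(person_id = cohort$person_id,
                    algorithm = rep(algorithm, nrow(cohort)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(flag_mat))
  out$score <- as.integer(if (length(scores)) scores else integer())
  out
}
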