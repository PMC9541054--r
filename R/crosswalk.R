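# Codeset adaptation (ICD -> SNOMED) with back-translation diagnostics.
#
# The adaptation pipeline has three steps: (1) forward-map the ICD codeset to
# SNOMED standard concepts; (2) back-translate the SNOMED set to ICD and
# partition the union of the original and back-translated codes into
# both / snomed_only / quan_only; (3) apply expert adjudication (read from a
# file, never inferred) to retain or exclude SNOMED concepts and to label
# multiple-to-one discrepancies as information gain or added noise. Every
# discrepant code is recorded exactly once in an auditable ledger.

DISCREPANCY_CATEGORIES <- c("multiple_icd_to_one_snomed", "deprecated_unmapped",
                            "specificity")

#' Partition two codesets into both / snomed-only / quan-only
#'
#' A discrepant code is an ICD code captured by exactly one of the two
#' algorithms: present in the original (Quan-style) ICD codeset or in the
#' back-translation of the SNOMED codeset, but not both.
#'
#' @param quan_codes Character vector: the original ICD codeset.
#' @param backmapped_codes Character vector: ICD codes obtained by
#'   back-translating the SNOMED codeset.
#' @return list with sorted normalized code vectors `both`, `snomed_only`,
#'   `quan_only`; the three sets are disjoint and their union is the union of
#'   the normalized inputs.
#' @export
find_discrepant_codes <- function(quan_codes, backmapped_codes) {
  q <- unique(normalize_code(quan_codes))
  b <- unique(normalize_code(backmapped_codes))
  list(both = sort(intersect(q, b)),
       snomed_only = sort(setdiff(b, q)),
       quan_only = sort(setdiff(q, b)))
}

#' Classify one discrepant code
#'
#' Assigns the diagnostic category of a discrepant code:
#' \describe{
#'   \item{multiple_icd_to_one_snomed}{a `snomed_only` code — it was pulled
#'     into the back-translation because its SNOMED target is shared with an
#'     in-set code (two or more ICD codes mapping to one standard concept).}
#'   \item{deprecated_unmapped}{a `quan_only` code with no "maps to" edge in
#'     this vocabulary snapshot (typically a deprecated ICD code).}
#'   \item{specificity}{a `quan_only` code that does have "maps to" edges —
#'     it was lost because its every SNOMED target was excluded for
#'     back-mapping too broadly.}
#' }
#' The categories are exhaustive and mutually exclusive for discrepant codes.
#'
#' @param store A [vocab_store()].
#' @param side `"snomed_only"` or `"quan_only"` (a code on side `"both"` is
#'   not discrepant and raises a contract error).
#' @param code The discrepant code.
#' @param vocabulary Its vocabulary (`"ICD9CM"` or `"ICD10CM"`).
#' @return One of `"multiple_icd_to_one_snomed"`, `"deprecated_unmapped"`,
#'   `"specificity"`.
#' @export
classify_discrepancy <- function(store, side, code, vocabulary) {
  stopifnot_store(store)
  if (!side %in% c("snomed_only", "quan_only")) {
    abort_cci(sprintf("code %s is not discrepant (side = %s)", code, side),
              "snomedcci_contract_error")
  }
  if (side == "snomed_only") return("multiple_icd_to_one_snomed")
  hit <- lookup_concepts(store, code, vocabulary)
  cid <- hit$concept_id[!is.na(hit$concept_id)]
  n_edges <- if (length(cid) == 0L) 0L else
    nrow(store$mappings[source_concept_id %in% cid])
  if (n_edges == 0L) "deprecated_unmapped" else "specificity"
}

# decisions keyed on SNOMED ids / codes, validated against the store
#' @noRd
split_adjudication <- function(store, adjudication) {
  if (is.null(adjudication)) {
    adjudication <- data.frame(key_type = character(), key = character(),
                               decision = character(), note = character())
  }
  assert_cols(adjudication, c("key_type", "key", "decision"), "adjudication")
  by_id <- adjudication[adjudication$key_type == "snomed_id", , drop = FALSE]
  by_code <- adjudication[adjudication$key_type == "code", , drop = FALSE]
  ids <- suppressWarnings(as.integer(by_id$key))
  known <- store$concepts[vocabulary == "SNOMED", concept_id]
  bad <- by_id$key[is.na(ids) | !(ids %in% known)]
  if (length(bad)) {
    abort_cci(sprintf("adjudication references unknown SNOMED concept(s): %s",
                      paste(utils::head(bad, 10), collapse = ", ")),
              "snomedcci_lookup_error")
  }
  list(id_decision = stats::setNames(by_id$decision, as.character(ids)),
       code_decision = stats::setNames(by_code$decision,
                                       normalize_code(by_code$key)))
}

#' Adapt an ICD codeset to SNOMED with discrepancy ledger
#'
#' Runs the full three-step adaptation for each condition in `quan_codeset`:
#' forward-map to SNOMED, drop concepts the adjudication file excludes,
#' back-translate, partition codes, and classify every discrepant code. The
#' result is deterministic given its inputs.
#'
#' @param store A [vocab_store()].
#' @param quan_codeset Interchange-format data.frame (`condition`,
#'   `vocabulary`, `code`, `provenance`) of ICD codes; may span several
#'   conditions.
#' @param adjudication Optional data.frame as read by [read_adjudication()].
#'   `exclude` decisions (keyed by `snomed_id`) remove concepts from the
#'   adapted set; `information_gain` / `added_noise` decisions (keyed by
#'   `snomed_id` or by `code`) label multiple-to-one ledger records.
#'   Unadjudicated multiple-to-one records remain `"pending"`.
#' @param include_descendants Use descendant closure in the back-translation
#'   (default `TRUE`).
#' @return list with
#'   \item{snomed_codeset}{interchange data.frame of retained SNOMED concept
#'     ids (as code strings), provenance `translated` or `curated_in`;}
#'   \item{ledger}{data.frame of `DiscrepancyRecord`s: `condition`, `code`,
#'     `vocabulary`, `side`, `category`, `adjudication`, `via_snomed_ids`
#'     (comma-joined), sorted by (condition, side, code);}
#'   \item{overlap}{per-condition, per-vocabulary counts `n_both`,
#'     `n_snomed_only`, `n_quan_only`.}
#' @export
adapt_codeset <- function(store, quan_codeset, adjudication = NULL,
                          include_descendants = TRUE) {
  stopifnot_store(store)
  assert_cols(quan_codeset, c("condition", "vocabulary", "code"), "quan_codeset")
  if (nrow(quan_codeset) == 0L) {
    abort_cci("quan_codeset is empty", "snomedcci_contract_error")
  }
  if (!all(quan_codeset$vocabulary %in% c("ICD9CM", "ICD10CM"))) {
    abort_cci("quan_codeset vocabularies must be ICD9CM/ICD10CM",
              "snomedcci_contract_error")
  }
  adj <- split_adjudication(store, adjudication)
  excluded_ids <- as.integer(names(adj$id_decision)[adj$id_decision == "exclude"])

  snomed_rows <- list()
  ledger_rows <- list()
  overlap_rows <- list()
  for (cond in unique(quan_codeset$condition)) {
    sub <- quan_codeset[quan_codeset$condition == cond, , drop = FALSE]
    fm <- forward_map(store, sub)
    retained <- setdiff(fm$snomed_ids, excluded_ids)
    back <- if (length(retained)) {
      reverse_map(store, retained, include_descendants = include_descendants)
    } else {
      data.frame(code = character(), vocabulary = character(),
                 snomed_id = integer())
    }
    # ICD code -> implicated SNOMED targets, for ledger via_snomed_ids
    via_of <- if (nrow(back)) {
      via <- stats::aggregate(snomed_id ~ code, data = back,
                              FUN = function(x) paste(sort(unique(x)), collapse = ","))
      stats::setNames(as.character(via$snomed_id), via$code)
    } else {
      character()
    }
    via_get <- function(code) {
      v <- unname(via_of[code])
      if (length(v) == 0L || is.na(v)) "" else v
    }

    for (voc in c("ICD9CM", "ICD10CM")) {
      q <- unique(normalize_code(sub$code[sub$vocabulary == voc]))
      b <- unique(back$code[back$vocabulary == voc])
      if (length(q) == 0L && length(b) == 0L) next
      part <- find_discrepant_codes(q, b)
      overlap_rows[[length(overlap_rows) + 1L]] <- data.frame(
        condition = cond, vocabulary = voc,
        n_both = length(part$both),
        n_snomed_only = length(part$snomed_only),
        n_quan_only = length(part$quan_only))
      for (code in part$snomed_only) {
        dec <- unname(adj$code_decision[code])
        if (length(dec) == 0L || is.na(dec)) {
          tgt <- strsplit(via_get(code), ",")[[1]]
          decs <- adj$id_decision[tgt]
          decs <- decs[!is.na(decs) & decs != "exclude"]
          dec <- if (length(decs)) decs[[1]] else "pending"
        }
        ledger_rows[[length(ledger_rows) + 1L]] <- data.frame(
          condition = cond, code = code, vocabulary = voc,
          side = "snomed_only", category = "multiple_icd_to_one_snomed",
          adjudication = dec, via_snomed_ids = via_get(code))
      }
      for (code in part$quan_only) {
        category <- classify_discrepancy(store, "quan_only", code, voc)
        targets <- integer()
        if (category == "specificity") {
          cid <- lookup_concepts(store, code, voc)$concept_id
          targets <- store$mappings[source_concept_id %in% cid[!is.na(cid)],
                                    target_concept_id]
          if (any(targets %in% retained)) {
            abort_cci(sprintf(
              "code %s is quan_only but target(s) %s are retained: inconsistent partition",
              code, paste(intersect(targets, retained), collapse = ",")),
              "snomedcci_integrity_error")
          }
        }
        ledger_rows[[length(ledger_rows) + 1L]] <- data.frame(
          condition = cond, code = code, vocabulary = voc,
          side = "quan_only", category = category,
          adjudication = "pending",
          via_snomed_ids = paste(sort(unique(targets)), collapse = ","))
      }
    }
    if (length(retained)) {
      retained <- sort(retained)
      prov <- ifelse(as.character(retained) %in% names(adj$id_decision),
                     "curated_in", "translated")
      # codesets carry the concept's vocabulary-native code, not the
      # store-internal id
      codes <- store$concepts[data.table::data.table(concept_id = retained),
                              on = "concept_id", code]
      snomed_rows[[length(snomed_rows) + 1L]] <- data.frame(
        condition = cond, vocabulary = "SNOMED", code = codes,
        provenance = prov)
    }
  }
  ledger <- if (length(ledger_rows)) do.call(rbind, ledger_rows) else
    data.frame(condition = character(), code = character(),
               vocabulary = character(), side = character(),
               category = character(), adjudication = character(),
               via_snomed_ids = character())
  ledger <- ledger[order(ledger$condition, ledger$side, ledger$code), ]
  rownames(ledger) <- NULL
  snomed_codeset <- if (length(snomed_rows)) do.call(rbind, snomed_rows) else
    data.frame(condition = character(), vocabulary = character(),
               code = character(), provenance = character())
  class(snomed_codeset) <- c("cci_codeset", "data.frame")
  overlap <- if (length(overlap_rows)) do.call(rbind, overlap_rows) else
    data.frame(condition = character(), vocabulary = character(),
               n_both = integer(), n_snomed_only = integer(),
               n_quan_only = integer())
  list(snomed_codeset = snomed_codeset, ledger = ledger, overlap = overlap)
}

#' Tally a discrepancy ledger into per-condition category counts
#'
#' @param ledger Ledger data.frame from [adapt_codeset()].
#' @return data.frame with columns `condition`, `n_information_gain`,
#'   `n_added_noise`, `n_deprecated`, `n_specificity` (pending
#'   multiple-to-one records are counted in `n_pending`).
#' @export
ledger_category_counts <- function(ledger) {
  conds <- unique(ledger$condition)
  out <- do.call(rbind, lapply(conds, function(cond) {
    l <- ledger[ledger$condition == cond, , drop = FALSE]
    multi <- l$category == "multiple_icd_to_one_snomed"
    data.frame(
      condition = cond,
      n_information_gain = sum(multi & l$adjudication == "information_gain"),
      n_added_noise = sum(multi & l$adjudication == "added_noise"),
      n_pending = sum(multi & l$adjudication == "pending"),
      n_deprecated = sum(l$category == "deprecated_unmapped"),
      n_specificity = sum(l$category == "specificity"))
  }))
  out %||% data.frame(condition = character(), n_information_gain = integer(),
                      n_added_noise = integer(), n_pending = integer(),
                      n_deprecated = integer(), n_specificity = integer())
}

#' Crosswalk diagnostics report
#'
#' Summarizes code-mapping overlap and discrepancy categories across
#' conditions: per-condition both/only counts with one-decimal percentages,
#' per-condition category counts with the information-gain / added-noise
#' split, row and grand totals, and headline shares (fraction of codes
#' discrepant, share of discrepancies due to multiple-to-one mapping, share
#' of those adjudicated information gain). Percentages use half-up rounding.
#'
#' @param overlap_counts data.frame `condition`, `vocabulary`, `n_both`,
#'   `n_snomed_only`, `n_quan_only` — from [adapt_codeset()]'s `overlap`, or
#'   an external count fixture such as [reference_audit_counts()].
#' @param category_counts data.frame `condition`, `n_information_gain`,
#'   `n_added_noise`, `n_deprecated`, `n_specificity` (optional `n_pending`)
#'   — from [ledger_category_counts()] or an external fixture.
#' @return list with `overlap` (per-row percentages + `TOTAL` row),
#'   `categories` (+ `TOTAL` row) and `summary` (named numerics:
#'   `n_codes`, `n_both`, `n_discrepant`, `pct_both`, `pct_discrepant`,
#'   `n_multiple`, `pct_multiple_of_discrepant`, `n_information_gain`,
#'   `pct_gain_of_multiple`).
#' @export
diagnostics_report <- function(overlap_counts, category_counts) {
  assert_cols(overlap_counts,
              c("condition", "vocabulary", "n_both", "n_snomed_only",
                "n_quan_only"), "overlap_counts")
  assert_cols(category_counts,
              c("condition", "n_information_gain", "n_added_noise",
                "n_deprecated", "n_specificity"), "category_counts")
  ov <- as.data.frame(overlap_counts)
  for (col in c("n_both", "n_snomed_only", "n_quan_only")) {
    ov[[col]] <- as.integer(ov[[col]])
  }
  ov_tot <- data.frame(condition = "TOTAL", vocabulary = "ALL",
                       n_both = sum(ov$n_both),
                       n_snomed_only = sum(ov$n_snomed_only),
                       n_quan_only = sum(ov$n_quan_only))
  ov <- rbind(ov, ov_tot)
  n_row <- ov$n_both + ov$n_snomed_only + ov$n_quan_only
  pct <- function(num, den) round_half_up(ifelse(den > 0, 100 * num / den, 0), 1L)
  ov$pct_both <- pct(ov$n_both, n_row)
  ov$pct_snomed_only <- pct(ov$n_snomed_only, n_row)
  ov$pct_quan_only <- pct(ov$n_quan_only, n_row)

  cat_df <- as.data.frame(category_counts)
  if (!"n_pending" %in% names(cat_df)) cat_df$n_pending <- rep(0L, nrow(cat_df))
  num_cols <- c("n_information_gain", "n_added_noise", "n_pending",
                "n_deprecated", "n_specificity")
  for (col in num_cols) cat_df[[col]] <- as.integer(cat_df[[col]])
  cat_tot <- data.frame(condition = "TOTAL",
                        as.list(colSums(cat_df[num_cols])))
  cat_df <- rbind(cat_df, cat_tot)

  n_codes <- ov_tot$n_both + ov_tot$n_snomed_only + ov_tot$n_quan_only
  n_discrepant <- ov_tot$n_snomed_only + ov_tot$n_quan_only
  n_multiple <- cat_tot$n_information_gain + cat_tot$n_added_noise +
    cat_tot$n_pending
  summary <- c(
    n_codes = n_codes,
    n_both = ov_tot$n_both,
    n_discrepant = n_discrepant,
    pct_both = pct(ov_tot$n_both, n_codes),
    pct_discrepant = pct(n_discrepant, n_codes),
    n_multiple = n_multiple,
    pct_multiple_of_discrepant = pct(n_multiple, n_discrepant),
    n_information_gain = cat_tot$n_information_gain,
    pct_gain_of_multiple = pct(cat_tot$n_information_gain, n_multiple)
  )
  list(overlap = ov, categories = cat_df, summary = summary)
}

#' Bundled reference audit counts
#'
#' Per-condition code-overlap and discrepancy-category counts from a
#' published audit of a Quan-to-SNOMED crosswalk built on the July 2021
#' SNOMED CT International Edition. Useful as a fixture for the report
#' arithmetic; the counts are vocabulary-snapshot dependent and are not a
#' target the toolkit tries to regenerate.
#'
#' @return list with `overlap` and `categories` data.frames in the shapes
#'   [diagnostics_report()] consumes.
#' @export
reference_audit_counts <- function() {
  list(
    overlap = utils::read.csv(system.file(
      "extdata", "reference_overlap_counts.csv", package = "snomedcci",
      mustWork = TRUE), stringsAsFactors = FALSE),
    categories = utils::read.csv(system.file(
      "extdata", "reference_discrepancy_counts.csv", package = "snomedcci",
      mustWork = TRUE), stringsAsFactors = FALSE)
  )
}
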