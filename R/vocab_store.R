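# Vocabulary store: load OMOP-dialect (or compact fixture) vocabulary tables
# and answer forward (ICD -> SNOMED), reverse (SNOMED -> ICD) and
# hierarchy-descendant queries.

KNOWN_VOCABS <- c("ICD9CM", "ICD10CM", "SNOMED")

#' Construct a vocabulary store from in-memory tables
#'
#' A `vocab_store` indexes three tables: concepts, "maps to" edges, and
#' ancestor/descendant hierarchy edges. It is the substrate for codeset
#' translation: forward mapping (source ICD concept to its SNOMED standard
#' concept(s)) and reverse mapping (all ICD codes whose standard target lies
#' in a SNOMED set, optionally expanded to descendants).
#'
#' @param concepts data.frame with columns `concept_id`, `code`,
#'   `vocabulary`, `name`, `valid` (logical; `FALSE` marks a
#'   deprecated/invalid concept in this snapshot).
#' @param mappings data.frame with columns `source_concept_id`,
#'   `target_concept_id`; every target must be a SNOMED concept.
#' @param ancestors data.frame with columns `ancestor_concept_id`,
#'   `descendant_concept_id`, `min_levels`. The reflexive closure (every
#'   concept its own descendant at 0 levels) is added if absent.
#' @return An object of class `vocab_store`.
#' @export
vocab_store <- function(concepts, mappings = NULL, ancestors = NULL) {
  concepts <- data.table::as.data.table(concepts)
  assert_cols(concepts, c("concept_id", "code", "vocabulary", "name", "valid"),
              "concept table")
  concepts[, concept_id := as.integer(concept_id)]
  concepts[, code := as.character(code)]
  concepts[, vocabulary := as.character(vocabulary)]
  concepts[, valid := as.logical(valid)]
  if (any(!nzchar(concepts$code))) {
    abort_cci("concept codes must be non-empty", "snomedcci_value_error")
  }
  if (anyDuplicated(concepts$concept_id)) {
    dup <- unique(concepts$concept_id[duplicated(concepts$concept_id)])
    abort_cci(sprintf("duplicate concept_id(s): %s",
                      paste(utils::head(dup, 5), collapse = ", ")),
              "snomedcci_integrity_error")
  }
  concepts[, norm_code := normalize_code(code)]
  valid_cc <- concepts[valid == TRUE, .N, by = .(norm_code, vocabulary)]
  if (any(valid_cc$N > 1L)) {
    bad <- valid_cc[N > 1L]
    abort_cci(sprintf("duplicate (code, vocabulary) among valid concepts: %s",
                      paste(utils::head(paste0(bad$vocabulary, ":", bad$norm_code), 5),
                            collapse = ", ")),
              "snomedcci_integrity_error")
  }
  concepts[, known_vocab := vocabulary %in% KNOWN_VOCABS]

  if (is.null(mappings) || nrow(mappings) == 0L) {
    mappings <- data.table::data.table(source_concept_id = integer(),
                                       target_concept_id = integer())
  } else {
    mappings <- data.table::as.data.table(mappings)
    assert_cols(mappings, c("source_concept_id", "target_concept_id"),
                "mapping table")
    mappings <- mappings[, .(source_concept_id = as.integer(source_concept_id),
                             target_concept_id = as.integer(target_concept_id))]
    mappings <- unique(mappings)
  }
  if (is.null(ancestors) || nrow(ancestors) == 0L) {
    ancestors <- data.table::data.table(ancestor_concept_id = integer(),
                                        descendant_concept_id = integer(),
                                        min_levels = integer())
  } else {
    ancestors <- data.table::as.data.table(ancestors)
    assert_cols(ancestors,
                c("ancestor_concept_id", "descendant_concept_id", "min_levels"),
                "ancestor table")
    ancestors <- ancestors[, .(ancestor_concept_id = as.integer(ancestor_concept_id),
                               descendant_concept_id = as.integer(descendant_concept_id),
                               min_levels = as.integer(min_levels))]
    ancestors <- unique(ancestors)
  }

  edge_ids <- unique(c(mappings$source_concept_id, mappings$target_concept_id,
                       ancestors$ancestor_concept_id,
                       ancestors$descendant_concept_id))
  dangling <- setdiff(edge_ids, concepts$concept_id)
  if (length(dangling)) {
    abort_cci(sprintf("edge endpoint(s) reference unknown concept_id(s): %s",
                      paste(utils::head(sort(dangling), 10), collapse = ", ")),
              "snomedcci_integrity_error")
  }
  non_snomed_target <- setdiff(
    mappings$target_concept_id,
    concepts[vocabulary == "SNOMED", concept_id]
  )
  if (length(non_snomed_target)) {
    abort_cci(sprintf("maps_to target(s) not in the SNOMED vocabulary: %s",
                      paste(utils::head(sort(non_snomed_target), 10), collapse = ", ")),
              "snomedcci_integrity_error")
  }
  if (nrow(ancestors[ancestor_concept_id == descendant_concept_id & min_levels > 0L])) {
    abort_cci("self ancestor edge with min_levels > 0", "snomedcci_integrity_error")
  }
  # reflexive closure: every concept is its own descendant at 0 levels
  self_missing <- setdiff(concepts$concept_id,
                          ancestors[min_levels == 0L &
                                      ancestor_concept_id == descendant_concept_id,
                                    ancestor_concept_id])
  if (length(self_missing)) {
    ancestors <- rbind(ancestors,
                       data.table::data.table(ancestor_concept_id = self_missing,
                                              descendant_concept_id = self_missing,
                                              min_levels = 0L))
  }

  data.table::setkey(concepts, concept_id)
  data.table::setkey(mappings, source_concept_id)
  data.table::setkey(ancestors, ancestor_concept_id)
  structure(list(concepts = concepts, mappings = mappings, ancestors = ancestors),
            class = "vocab_store")
}

#' @export
print.vocab_store <- function(x, ...) {
  cat(sprintf(
    "<vocab_store> %d concepts (%d SNOMED, %d ICD9CM, %d ICD10CM), %d maps_to edges, %d ancestor edges\n",
    nrow(x$concepts),
    sum(x$concepts$vocabulary == "SNOMED"),
    sum(x$concepts$vocabulary == "ICD9CM"),
    sum(x$concepts$vocabulary == "ICD10CM"),
    nrow(x$mappings), nrow(x$ancestors)))
  invisible(x)
}

#' Load a vocabulary snapshot from delimited files
#'
#' Two dialects are supported. `"omop"` reads OMOP-vocabulary tab-delimited
#' exports: CONCEPT (`concept_id`, `concept_code`, `vocabulary_id`,
#' `concept_name`, `invalid_reason`), CONCEPT_RELATIONSHIP (`concept_id_1`,
#' `concept_id_2`, `relationship_id`; only `"Maps to"` rows are consumed) and
#' CONCEPT_ANCESTOR (`ancestor_concept_id`, `descendant_concept_id`,
#' `min_levels_of_separation`). `"compact"` reads the package's fixture
#' dialect: concepts (`concept_id`, `code`, `vocabulary`, `name`, `valid`),
#' mappings (`source_concept_id`, `target_concept_id`) and ancestors
#' (`ancestor_concept_id`, `descendant_concept_id`, `min_levels`), any
#' delimiter `utils::read.delim` can sniff via `sep`.
#'
#' Concepts in vocabularies other than ICD9CM/ICD10CM/SNOMED are retained but
#' flagged (`known_vocab = FALSE`). Row counts are reported via `message()`.
#'
#' @param concept_path,relationship_path,ancestor_path File paths;
#'   `ancestor_path` may be `NULL` (no hierarchy beyond the reflexive closure).
#' @param dialect `"omop"` or `"compact"`.
#' @param sep Field separator (default tab).
#' @return A [vocab_store()].
#' @export
load_vocabulary <- function(concept_path, relationship_path,
                            ancestor_path = NULL,
                            dialect = c("omop", "compact"), sep = "\t") {
  dialect <- match.arg(dialect)
  for (p in c(concept_path, relationship_path, ancestor_path)) {
    if (!file.exists(p)) {
      abort_cci(sprintf("file not found: %s", p), "snomedcci_io_error")
    }
  }
  read1 <- function(path) {
    utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                      colClasses = "character", quote = "")
  }
  if (dialect == "omop") {
    con <- read1(concept_path)
    assert_cols(con, c("concept_id", "concept_code", "vocabulary_id",
                       "concept_name", "invalid_reason"), "CONCEPT")
    concepts <- data.frame(
      concept_id = as.integer(con$concept_id),
      code = con$concept_code,
      vocabulary = con$vocabulary_id,
      name = con$concept_name,
      valid = !nzchar(trimws(con$invalid_reason)),
      stringsAsFactors = FALSE
    )
    rel <- read1(relationship_path)
    assert_cols(rel, c("concept_id_1", "concept_id_2", "relationship_id"),
                "CONCEPT_RELATIONSHIP")
    rel <- rel[rel$relationship_id == "Maps to", , drop = FALSE]
    mappings <- data.frame(source_concept_id = as.integer(rel$concept_id_1),
                           target_concept_id = as.integer(rel$concept_id_2))
    ancestors <- NULL
    if (!is.null(ancestor_path)) {
      anc <- read1(ancestor_path)
      assert_cols(anc, c("ancestor_concept_id", "descendant_concept_id",
                         "min_levels_of_separation"), "CONCEPT_ANCESTOR")
      ancestors <- data.frame(
        ancestor_concept_id = as.integer(anc$ancestor_concept_id),
        descendant_concept_id = as.integer(anc$descendant_concept_id),
        min_levels = as.integer(anc$min_levels_of_separation)
      )
    }
  } else {
    con <- read1(concept_path)
    assert_cols(con, c("concept_id", "code", "vocabulary", "name", "valid"),
                "concept table")
    concepts <- data.frame(concept_id = as.integer(con$concept_id),
                           code = con$code, vocabulary = con$vocabulary,
                           name = con$name,
                           valid = as.logical(con$valid),
                           stringsAsFactors = FALSE)
    rel <- read1(relationship_path)
    assert_cols(rel, c("source_concept_id", "target_concept_id"),
                "mapping table")
    mappings <- data.frame(source_concept_id = as.integer(rel$source_concept_id),
                           target_concept_id = as.integer(rel$target_concept_id))
    ancestors <- NULL
    if (!is.null(ancestor_path)) {
      anc <- read1(ancestor_path)
      assert_cols(anc, c("ancestor_concept_id", "descendant_concept_id",
                         "min_levels"), "ancestor table")
      ancestors <- data.frame(
        ancestor_concept_id = as.integer(anc$ancestor_concept_id),
        descendant_concept_id = as.integer(anc$descendant_concept_id),
        min_levels = as.integer(anc$min_levels)
      )
    }
  }
  store <- vocab_store(concepts, mappings, ancestors)
  message(sprintf("loaded vocabulary: %d concepts, %d maps_to edges, %d ancestor edges",
                  nrow(store$concepts), nrow(store$mappings), nrow(store$ancestors)))
  store
}

#' @noRd
stopifnot_store <- function(store) {
  if (!inherits(store, "vocab_store")) {
    abort_cci("expected a vocab_store", "snomedcci_contract_error")
  }
}

# concept ids (any vocabulary) for (code, vocabulary) pairs; valid concepts
# preferred, invalid concepts still resolvable (deprecated codes exist in
# snapshots and must be addressable).
#' @noRd
lookup_concepts <- function(store, codes, vocabulary) {
  q <- data.table::data.table(norm_code = normalize_code(codes),
                              vocabulary = as.character(vocabulary))
  store$concepts[q, on = c("norm_code", "vocabulary"),
                 .(concept_id = x.concept_id, code = i.norm_code,
                   vocabulary = i.vocabulary)]
}

#' Forward-map ICD codes to SNOMED standard concepts
#'
#' Applies the "maps to" relationship to each input code and returns the
#' de-duplicated union of SNOMED targets. Codes with no concept or no edge
#' are not errors: they are returned in the `unmapped` side-list (a
#' deprecated code with no "maps to" edge is data the crosswalk diagnostics
#' later classify).
#'
#' @param store A [vocab_store()].
#' @param codes data.frame with columns `code`, `vocabulary`
#'   (ICD9CM/ICD10CM), or a character vector of codes with `vocabulary`
#'   supplied separately.
#' @param vocabulary Optional single vocabulary when `codes` is a vector.
#' @return list with `snomed_ids` (sorted integer vector) and `unmapped`
#'   (data.frame `code`, `vocabulary` of codes contributing no target).
#' @export
forward_map <- function(store, codes, vocabulary = NULL) {
  stopifnot_store(store)
  if (!is.data.frame(codes)) {
    codes <- data.frame(code = as.character(codes),
                        vocabulary = vocabulary %||% "ICD10CM")
  }
  assert_cols(codes, c("code", "vocabulary"), "codes")
  if (nrow(codes) == 0L) {
    return(list(snomed_ids = integer(),
                unmapped = data.frame(code = character(),
                                      vocabulary = character())))
  }
  hit <- lookup_concepts(store, codes$code, codes$vocabulary)
  hit <- cbind(hit, orig_code = codes$code)
  mapped <- store$mappings[hit[!is.na(concept_id)],
                           on = c(source_concept_id = "concept_id"),
                           .(orig_code = i.orig_code, vocabulary = i.vocabulary,
                             target_concept_id = x.target_concept_id)]
  has_target <- mapped[!is.na(target_concept_id)]
  no_target <- unique(rbind(
    hit[is.na(concept_id), .(code = orig_code, vocabulary)],
    mapped[is.na(target_concept_id), .(code = orig_code, vocabulary)]
  ))
  list(snomed_ids = sort(unique(has_target$target_concept_id)),
       unmapped = as.data.frame(no_target))
}

#' SNOMED descendant closure
#'
#' @param store A [vocab_store()].
#' @param snomed_ids Integer SNOMED concept ids.
#' @return Sorted integer vector including the inputs themselves (reflexive).
#' @export
snomed_descendants <- function(store, snomed_ids) {
  stopifnot_store(store)
  snomed_ids <- as.integer(snomed_ids)
  hit <- store$ancestors[data.table::data.table(ancestor_concept_id = snomed_ids),
                         on = "ancestor_concept_id", nomatch = NULL]
  sort(unique(c(snomed_ids, hit$descendant_concept_id)))
}

#' Reverse-map (back-translate) SNOMED concepts to ICD source codes
#'
#' Returns every ICD code whose "maps to" target lies in the input SNOMED
#' set — the back-translation used to audit codeset coverage. With
#' `include_descendants = TRUE` (the default, matching the usual OMOP
#' codeset-expansion convention) the input set is first expanded to its
#' hierarchy descendants.
#'
#' @param store A [vocab_store()].
#' @param snomed_ids Integer SNOMED concept ids; all must exist in the store.
#' @param include_descendants Expand to descendant closure first?
#' @return data.frame with columns `code` (normalized), `vocabulary`,
#'   `snomed_id` (the target that pulled the code in), sorted by
#'   (vocabulary, code, snomed_id) for deterministic serialization.
#' @export
reverse_map <- function(store, snomed_ids, include_descendants = TRUE) {
  stopifnot_store(store)
  snomed_ids <- unique(as.integer(snomed_ids))
  known <- store$concepts[vocabulary == "SNOMED", concept_id]
  unknown <- setdiff(snomed_ids, known)
  if (length(unknown)) {
    abort_cci(sprintf("unknown SNOMED concept id(s): %s",
                      paste(utils::head(sort(unknown), 10), collapse = ", ")),
              "snomedcci_lookup_error")
  }
  targets <- if (include_descendants) snomed_descendants(store, snomed_ids) else snomed_ids
  hits <- store$mappings[target_concept_id %in% targets]
  if (nrow(hits) == 0L) {
    return(data.frame(code = character(), vocabulary = character(),
                      snomed_id = integer()))
  }
  src <- store$concepts[hits, on = c(concept_id = "source_concept_id"),
                        .(code = x.norm_code, vocabulary = x.vocabulary,
                          snomed_id = i.target_concept_id)]
  src <- src[vocabulary %in% c("ICD9CM", "ICD10CM")]
  src <- unique(src)
  data.table::setorder(src, vocabulary, code, snomed_id)
  as.data.frame(src)
}
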