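# Codesets and their interchange format, plus expert-adjudication files.

#' Build a codeset
#'
#' A codeset is a named set of codes in a single vocabulary, each code tagged
#' with its provenance (`quan_icd9`, `quan_icd10`, `translated`, `curated_in`,
#' `curated_out`). Represented as a plain data.frame so codesets round-trip
#' through the delimited interchange format unchanged.
#'
#' @param condition Condition label (e.g. `"CHF"`).
#' @param vocabulary One of `"ICD9CM"`, `"ICD10CM"`, `"SNOMED"`.
#' @param codes Character vector of codes (duplicates dropped).
#' @param provenance Single tag or vector parallel to `codes`.
#' @return data.frame with columns `condition`, `vocabulary`, `code`,
#'   `provenance`, class `c("cci_codeset", "data.frame")`.
#' @export
codeset <- function(condition, vocabulary, codes, provenance = "translated") {
  codes <- as.character(codes)
  if (length(provenance) == 1L) provenance <- rep(provenance, length(codes))
  keep <- !duplicated(codes)
  out <- data.frame(condition = condition, vocabulary = vocabulary,
                    code = codes[keep], provenance = provenance[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("cci_codeset", "data.frame")
  out
}

#' Read codesets from the interchange format
#'
#' The interchange format is a delimited file with columns `condition`,
#' `vocabulary`, `code`, `provenance` (one row per code; several conditions
#' and vocabularies may share a file).
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return data.frame of class `cci_codeset`.
#' @export
read_codesets <- function(path, sep = ",") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  assert_cols(df, c("condition", "vocabulary", "code", "provenance"),
              "codeset file")
  class(df) <- c("cci_codeset", "data.frame")
  df
}

#' Write codesets in the interchange format
#'
#' Rows are sorted by (condition, vocabulary, code) for reproducible diffs.
#'
#' @param codesets data.frame with the interchange columns.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_codesets <- function(codesets, path, sep = ",") {
  assert_cols(codesets, c("condition", "vocabulary", "code", "provenance"),
              "codesets")
  df <- as.data.frame(codesets)
  df <- df[order(df$condition, df$vocabulary, df$code), ]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expert adjudication file
#'
#' Clinical relevance of discrepant codes is never inferred by the toolkit:
#' it is read from an adjudication file produced by clinical subject-matter
#' experts. Columns: `key_type` (`snomed_id` or `code`), `key`, `decision`
#' (`information_gain`, `added_noise`, `exclude`), `note` (free text,
#' optional).
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return data.frame with those columns.
#' @export
read_adjudication <- function(path, sep = ",") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  assert_cols(df, c("key_type", "key", "decision"), "adjudication file")
  if (!"note" %in% names(df)) df$note <- ""
  bad <- setdiff(unique(df$decision),
                 c("information_gain", "added_noise", "exclude"))
  if (length(bad)) {
    abort_cci(sprintf("unknown adjudication decision(s): %s",
                      paste(bad, collapse = ", ")),
              "snomedcci_value_error")
  }
  df
}

#' Bundled Quan comorbidity code lists
#'
#' Returns the enhanced ICD-9-CM and ICD-10 Charlson code lists of Quan and
#' colleagues in the interchange format, as shipped with the package. These
#' lists are printed as code prefixes (e.g. `410.x`); match them with
#' `match = "prefix"` in the scoring engine.
#'
#' @param vocabulary `"ICD9CM"`, `"ICD10CM"`, or `"both"` (default).
#' @return data.frame of class `cci_codeset`.
#' @export
quan_codesets <- function(vocabulary = c("both", "ICD9CM", "ICD10CM")) {
  vocabulary <- match.arg(vocabulary)
  paths <- c(ICD9CM = "quan_icd9.csv", ICD10CM = "quan_icd10.csv")
  want <- if (vocabulary == "both") names(paths) else vocabulary
  out <- do.call(rbind, lapply(want, function(v) {
    read_codesets(system.file("extdata", paths[[v]], package = "snomedcci",
                              mustWork = TRUE))
  }))
  class(out) <- c("cci_codeset", "data.frame")
  out
}
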