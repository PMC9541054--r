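# End-to-end orchestration: adapt -> score -> validate, with delimited
# report outputs shaped like the familiar cohort-study tables and a run
# manifest for reproducibility.

#' Read a claims bundle from delimited files
#'
#' Expects `persons.csv`, `observation_periods.csv`, `visits.csv`,
#' `condition_occurrences.csv`, `deaths.csv` under `dir` (columns as in
#' [claims_bundle()]).
#'
#' @param dir Directory of delimited tables.
#' @param sep Field separator (default comma).
#' @return A [claims_bundle()].
#' @export
read_claims_bundle <- function(dir, sep = ",") {
  rd <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      abort_cci(sprintf("file not found: %s", path), "snomedcci_io_error")
    }
    utils::read.delim(path, sep = sep, stringsAsFactors = FALSE, quote = "")
  }
  claims_bundle(rd("persons"), rd("observation_periods"), rd("visits"),
                rd("condition_occurrences"), rd("deaths"))
}

#' Write a claims bundle as delimited files
#'
#' @param bundle A [claims_bundle()].
#' @param dir Output directory (created if absent).
#' @param sep Field separator.
#' @export
write_claims_bundle <- function(bundle, dir, sep = ",") {
  if (!inherits(bundle, "claims_bundle")) {
    abort_cci("expected a claims_bundle", "snomedcci_contract_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle)) {
    utils::write.table(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                       sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Build a run configuration
#'
#' @param out_dir Output directory for report files.
#' @param calendar_year Index year; 2013-style runs compare against the
#'   ICD-9-CM algorithm, later years against ICD-10-CM.
#' @param seed Top-level seed; all per-stage randomness (generators,
#'   bootstrap) is derived from it.
#' @param vocab A [vocab_spec()] (synthetic vocabulary) — or a pre-built
#'   [gen_vocabulary()] result.
#' @param claims A [claims_spec()] — or a pre-built [gen_claims()] result.
#' @param include_descendants,apply_hierarchy,match Engine flags.
#' @param boot_n Bootstrap resamples for model CIs.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, calendar_year = 2018L, seed = 1L,
                       vocab = vocab_spec(seed = seed),
                       claims = claims_spec(calendar_year = calendar_year,
                                            seed = seed),
                       include_descendants = TRUE, apply_hierarchy = TRUE,
                       match = "exact", boot_n = 500L) {
  structure(list(out_dir = out_dir, calendar_year = as.integer(calendar_year),
                 seed = as.integer(seed), vocab = vocab, claims = claims,
                 include_descendants = include_descendants,
                 apply_hierarchy = apply_hierarchy, match = match,
                 boot_n = as.integer(boot_n)),
            class = "run_config")
}

#' Run the full validation pipeline
#'
#' Adapts the ICD codesets to SNOMED, builds the inpatient cohort with its
#' one-year mortality outcome, scores every patient under the SNOMED and the
#' Quan-style ICD algorithm, and writes: cohort attrition, a balance table
#' (per-condition prevalences and SMDs, plus the CCI itself), the
#' per-condition patient-overlap table, code-mapping overlap and
#' discrepancy-category tables, model performance (intercept, slope,
#' c statistic with bootstrap CI), a plain-text summary and a JSON run
#' manifest. Reruns with the same config are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every computed object (`vocab`, `adapt`,
#'   `cohort`, `results_snomed`, `results_quan`, `balance`, `overlap`,
#'   `diagnostics`, `models`, `files`).
#' @export
run_validation <- function(config) {
  if (!inherits(config, "run_config")) {
    abort_cci("expected a run_config", "snomedcci_contract_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  vocab <- if (inherits(config$vocab, "vocab_spec"))
    gen_vocabulary(config$vocab) else config$vocab
  adapt <- adapt_codeset(vocab$store, vocab$quan_codeset, vocab$adjudication,
                         include_descendants = config$include_descendants)
  claims <- if (inherits(config$claims, "claims_spec"))
    gen_claims(config$claims, vocab) else config$claims

  cohort <- build_cohort(claims$bundle, config$calendar_year)
  cohort <- attach_outcome(cohort, claims$bundle$deaths)

  dx <- claims$bundle$condition_occurrences
  quan_alg <- if (config$calendar_year < 2015L) "quan_icd9" else "quan_icd10"
  res_sn <- score_cohort(cohort, dx, adapt$snomed_codeset, "snomed",
                         store = vocab$store, match = config$match,
                         include_descendants = config$include_descendants,
                         apply_hierarchy = config$apply_hierarchy)
  res_qu <- score_cohort(cohort, dx, vocab$quan_codeset, quan_alg,
                         match = config$match,
                         apply_hierarchy = config$apply_hierarchy)

  balance <- balance_table(res_sn, res_qu)
  overlap <- overlap_table(res_sn, res_qu)
  diagnostics <- diagnostics_report(adapt$overlap,
                                    ledger_category_counts(adapt$ledger))
  outcomes <- cohort$died_within_365
  models <- list(
    snomed = fit_mortality_model(res_sn$score, outcomes, "snomed",
                                 boot_n = config$boot_n,
                                 seed = config$seed * 1000L + 1L),
    quan = fit_mortality_model(res_qu$score, outcomes, quan_alg,
                               boot_n = config$boot_n,
                               seed = config$seed * 1000L + 2L))
  model_df <- do.call(rbind, lapply(models, function(m)
    data.frame(algorithm = m$algorithm, intercept = m$intercept,
               slope = m$slope, c_statistic = m$c_statistic,
               ci_low = m$ci_low, ci_high = m$ci_high, n = m$n,
               n_events = m$n_events)))

  wt <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    path
  }
  files <- c(
    attrition = wt(attr(cohort, "attrition"), "attrition.csv"),
    balance = wt(balance, "balance.csv"),
    patient_overlap = wt(overlap, "patient_overlap.csv"),
    code_overlap = wt(diagnostics$overlap, "code_overlap.csv"),
    categories = wt(diagnostics$categories, "discrepancy_categories.csv"),
    ledger = wt(adapt$ledger, "discrepancy_ledger.csv"),
    models = wt(model_df, "model_performance.csv"),
    snomed_codeset = wt(adapt$snomed_codeset, "snomed_codeset.csv"))

  summary_path <- file.path(config$out_dir, "summary.txt")
  s <- diagnostics$summary
  writeLines(c(
    sprintf("calendar year %d | cohort n = %d | one-year deaths = %d (%.1f%%)",
            config$calendar_year, nrow(cohort), sum(outcomes),
            100 * mean(outcomes)),
    sprintf("mean CCI: snomed %.3f vs %s %.3f (SMD %.4f)",
            mean(res_sn$score), quan_alg, mean(res_qu$score),
            balance$smd[balance$covariate == "cci"]),
    sprintf("codes mapped: %d | discrepant: %d (%.1f%%)",
            s[["n_codes"]], s[["n_discrepant"]], s[["pct_discrepant"]]),
    sprintf("multiple-to-one share of discrepancies: %.1f%% | information gain within multiple-to-one: %.1f%%",
            s[["pct_multiple_of_discrepant"]], s[["pct_gain_of_multiple"]]),
    sprintf("c statistic: snomed %.4f (%.4f-%.4f) vs %s %.4f (%.4f-%.4f)",
            models$snomed$c_statistic, models$snomed$ci_low,
            models$snomed$ci_high, quan_alg, models$quan$c_statistic,
            models$quan$ci_low, models$quan$ci_high)
  ), summary_path)
  files["summary"] <- summary_path

  cfg_json <- jsonlite::toJSON(list(
    calendar_year = config$calendar_year, seed = config$seed,
    include_descendants = config$include_descendants,
    apply_hierarchy = config$apply_hierarchy, match = config$match,
    boot_n = config$boot_n,
    vocab_spec = if (inherits(config$vocab, "vocab_spec"))
      unclass(config$vocab) else "prebuilt",
    claims_spec = if (inherits(config$claims, "claims_spec"))
      unclass(config$claims) else "prebuilt"),
    auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "snomedcci",
    version = as.character(utils::packageVersion("snomedcci")),
    seed = config$seed,
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    config_md5 = unname(tools::md5sum(tmp)))
  unlink(tmp)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files["manifest"] <- manifest_path

  invisible(list(vocab = vocab, adapt = adapt, cohort = cohort,
                 results_snomed = res_sn, results_quan = res_qu,
                 balance = balance, overlap = overlap,
                 diagnostics = diagnostics, models = models, files = files))
}
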