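# Synthetic vocabularies and claims. The vocabulary generator engineers every
# discrepancy category (clean 1:1 mappings, multiple-to-one fan-outs labeled
# gain/noise, deprecated codes, specificity traps) with exact ground-truth
# labels, so the crosswalk classifier can be scored against a known answer.
# The claims generator plants condition flags directly (flags -> codes) and
# draws deaths from a logistic model on the true weighted score, so scoring
# and model-recovery tests also have exact ground truth.

#' @noRd
with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic vocabulary
#'
#' Per-condition counts of engineered mapping structures:
#' \describe{
#'   \item{n_clean}{ICD codes mapping 1:1 to a SNOMED concept that back-maps
#'     only to them (no discrepancy).}
#'   \item{n_fanout_gain / n_fanout_noise}{multiple-to-one fan-outs: a SNOMED
#'     concept targeted by one in-set ICD code plus one extra out-of-set ICD
#'     code, pre-adjudicated information gain / added noise.}
#'   \item{n_deprecated}{in-set ICD codes with no "maps to" edge.}
#'   \item{n_specificity}{in-set ICD codes whose sole SNOMED target also
#'     back-maps to an out-of-scope code and is excluded by adjudication.}
#' }
#'
#' @param conditions Condition labels (default: all 17 from
#'   [cci_definitions()]).
#' @param n_clean,n_fanout_gain,n_fanout_noise,n_deprecated,n_specificity
#'   Per-condition structure counts (recycled across conditions).
#' @param icd_vocabulary Vocabulary of the generated ICD codes
#'   (`"ICD10CM"` default, or `"ICD9CM"`).
#' @param worked_examples Also plant replicas of three canonical audit
#'   cases: a hypertensive heart/kidney specificity trap under `chf`, a
#'   migraine-with-cerebral-infarction information gain under `cvd`, and a
#'   diabetic-kidney-disorder fan-out with secondary/drug-induced diabetes
#'   noise under `diabetes_complicated`.
#' @param seed Seed controlling any sampled structure placement.
#' @return list of class `vocab_spec`.
#' @export
vocab_spec <- function(conditions = cci_definitions()$condition,
                       n_clean = 2L, n_fanout_gain = 1L, n_fanout_noise = 1L,
                       n_deprecated = 1L, n_specificity = 1L,
                       icd_vocabulary = c("ICD10CM", "ICD9CM"),
                       worked_examples = TRUE, seed = 1L) {
  icd_vocabulary <- match.arg(icd_vocabulary)
  counts <- data.frame(
    condition = conditions,
    n_clean = rep_len(as.integer(n_clean), length(conditions)),
    n_fanout_gain = rep_len(as.integer(n_fanout_gain), length(conditions)),
    n_fanout_noise = rep_len(as.integer(n_fanout_noise), length(conditions)),
    n_deprecated = rep_len(as.integer(n_deprecated), length(conditions)),
    n_specificity = rep_len(as.integer(n_specificity), length(conditions)))
  if (any(counts[-1] < 0L)) {
    abort_cci("structure counts must be non-negative", "snomedcci_spec_error")
  }
  structure(list(counts = counts, icd_vocabulary = icd_vocabulary,
                 worked_examples = worked_examples, seed = as.integer(seed)),
            class = "vocab_spec")
}

#' Generate a synthetic vocabulary with labeled discrepancies
#'
#' Builds a miniature vocabulary store, the matching "Quan-style" ICD
#' codeset, a pre-filled adjudication table, and the ground-truth label for
#' every engineered discrepancy. Deterministic for a given spec.
#'
#' @param spec A [vocab_spec()].
#' @return list with:
#'   \item{store}{a [vocab_store()];}
#'   \item{quan_codeset}{interchange data.frame of the in-set ICD codes;}
#'   \item{adjudication}{adjudication data.frame (gain/noise labels and
#'     specificity exclusions), consumable by [adapt_codeset()];}
#'   \item{labels}{ground truth: `condition`, `code`, `vocabulary`, `side`,
#'     `category`, `adjudication` for every engineered discrepant code;}
#'   \item{role_codes}{every generated ICD code with its structural role
#'     (`clean`, `fanout_extra`, `deprecated`, `specificity`) and standard
#'     `snomed_id` (`NA` for deprecated), used by [gen_claims()];}
#'   \item{snomed_codeset}{the expected adapted SNOMED codeset.}
#' @export
gen_vocabulary <- function(spec) {
  if (!inherits(spec, "vocab_spec")) {
    abort_cci("expected a vocab_spec", "snomedcci_spec_error")
  }
  with_seed(spec$seed, {
    icd_voc <- spec$icd_vocabulary
    next_icd <- 0L
    icd_code <- function() {
      next_icd <<- next_icd + 1L
      if (icd_voc == "ICD10CM") {
        sprintf("X%02d.%d", (next_icd - 1L) %/% 10L, (next_icd - 1L) %% 10L)
      } else {
        sprintf("8%02d.%d", (next_icd - 1L) %/% 10L, (next_icd - 1L) %% 10L)
      }
    }
    concepts <- list(); mappings <- list(); ancestors <- list()
    quan <- list(); adjud <- list(); labels <- list(); roles <- list()
    next_cid <- 0L
    add_concept <- function(code, vocabulary, name, valid = TRUE) {
      next_cid <<- next_cid + 1L
      concepts[[length(concepts) + 1L]] <<- data.frame(
        concept_id = next_cid, code = code, vocabulary = vocabulary,
        name = name, valid = valid)
      next_cid
    }
    add_map <- function(src, tgt) {
      mappings[[length(mappings) + 1L]] <<- data.frame(
        source_concept_id = src, target_concept_id = tgt)
    }
    # SNOMED concept codes double as their concept ids in this fixture, so
    # codeset membership, record codes and hierarchy queries all line up on
    # one identifier
    snomed_row <- function(name) {
      code <- as.character(next_cid + 1L)  # force before add_concept increments
      add_concept(code, "SNOMED", name)
    }
    add_quan <- function(cond, code) {
      quan[[length(quan) + 1L]] <<- data.frame(
        condition = cond, vocabulary = icd_voc, code = code,
        provenance = if (icd_voc == "ICD9CM") "quan_icd9" else "quan_icd10")
    }
    add_label <- function(cond, code, vocabulary, side, category, adjudication) {
      labels[[length(labels) + 1L]] <<- data.frame(
        condition = cond, code = normalize_code(code), vocabulary = vocabulary,
        side = side, category = category, adjudication = adjudication)
    }
    add_role <- function(cond, code, vocabulary, role, sid) {
      roles[[length(roles) + 1L]] <<- data.frame(
        condition = cond, code = code, vocabulary = vocabulary, role = role,
        snomed_id = sid)
    }
    add_adjud <- function(key, decision, note = "") {
      adjud[[length(adjud) + 1L]] <<- data.frame(
        key_type = "snomed_id", key = as.character(key), decision = decision,
        note = note)
    }
    expected_snomed <- list()
    add_expected <- function(cond, cid, curated = FALSE) {
      expected_snomed[[length(expected_snomed) + 1L]] <<- data.frame(
        condition = cond, vocabulary = "SNOMED", code = as.character(cid),
        provenance = if (curated) "curated_in" else "translated")
    }

    for (i in seq_len(nrow(spec$counts))) {
      row <- spec$counts[i, ]
      cond <- row$condition
      prev_clean_cid <- NA_integer_
      for (k in seq_len(row$n_clean)) {
        code <- icd_code()
        icd_cid <- add_concept(code, icd_voc, sprintf("%s clean %d", cond, k))
        s_cid <- snomed_row(sprintf("%s standard %d", cond, k))
        add_map(icd_cid, s_cid)
        add_quan(cond, code)
        add_role(cond, code, icd_voc, "clean", s_cid)
        add_expected(cond, s_cid)
        # a little hierarchy: chain clean standard concepts so descendant
        # expansion has something to traverse without changing any label
        if (!is.na(prev_clean_cid)) {
          ancestors[[length(ancestors) + 1L]] <- data.frame(
            ancestor_concept_id = prev_clean_cid,
            descendant_concept_id = s_cid, min_levels = 1L)
        }
        prev_clean_cid <- s_cid
      }
      for (k in seq_len(row$n_fanout_gain + row$n_fanout_noise)) {
        decision <- if (k <= row$n_fanout_gain) "information_gain" else "added_noise"
        in_code <- icd_code(); extra_code <- icd_code()
        in_cid <- add_concept(in_code, icd_voc, sprintf("%s fanout in %d", cond, k))
        extra_cid <- add_concept(extra_code, icd_voc,
                                 sprintf("%s fanout extra %d", cond, k))
        s_cid <- snomed_row(sprintf("%s fanout standard %d", cond, k))
        add_map(in_cid, s_cid); add_map(extra_cid, s_cid)
        add_quan(cond, in_code)
        add_adjud(s_cid, decision)
        add_label(cond, extra_code, icd_voc, "snomed_only",
                  "multiple_icd_to_one_snomed", decision)
        add_role(cond, in_code, icd_voc, "clean", s_cid)
        add_role(cond, extra_code, icd_voc, "fanout_extra", s_cid)
        add_expected(cond, s_cid, curated = TRUE)
      }
      for (k in seq_len(row$n_deprecated)) {
        code <- icd_code()
        add_concept(code, icd_voc, sprintf("%s deprecated %d", cond, k),
                    valid = FALSE)
        add_quan(cond, code)
        add_label(cond, code, icd_voc, "quan_only", "deprecated_unmapped",
                  "pending")
        add_role(cond, code, icd_voc, "deprecated", NA_integer_)
      }
      for (k in seq_len(row$n_specificity)) {
        in_code <- icd_code(); out_code <- icd_code()
        in_cid <- add_concept(in_code, icd_voc, sprintf("%s spec in %d", cond, k))
        out_cid <- add_concept(out_code, icd_voc,
                               sprintf("%s spec out-of-scope %d", cond, k))
        s_cid <- snomed_row(sprintf("%s overbroad standard %d", cond, k))
        add_map(in_cid, s_cid); add_map(out_cid, s_cid)
        add_quan(cond, in_code)
        add_adjud(s_cid, "exclude", "back-maps to out-of-scope codes")
        add_label(cond, in_code, icd_voc, "quan_only", "specificity", "pending")
        add_role(cond, in_code, icd_voc, "specificity", s_cid)
      }
    }

    if (isTRUE(spec$worked_examples)) {
      # hypertensive heart + chronic kidney disease: the in-set heart-failure
      # code shares its only standard target with a no-heart-failure code, so
      # the target is excluded and the in-set code is lost (specificity)
      hf_cid <- add_concept("I13.2", "ICD10CM", "hypertensive heart and CKD with heart failure, stage 5")
      nohf_cid <- add_concept("I13.1", "ICD10CM", "hypertensive heart and CKD without heart failure")
      broad_cid <- snomed_row("hypertensive heart and chronic kidney disease")
      add_map(hf_cid, broad_cid); add_map(nohf_cid, broad_cid)
      add_quan("chf", "I13.2")
      add_adjud(broad_cid, "exclude", "also captures no-heart-failure disease")
      add_label("chf", "I13.2", "ICD10CM", "quan_only", "specificity", "pending")
      add_role("chf", "I13.2", "ICD10CM", "specificity", broad_cid)

      # persistent migraine aura with cerebral infarction: extra codes pulled
      # in through the shared cerebral-infarction concept, clinically relevant
      ci_in <- add_concept("I63.4", "ICD10CM", "cerebral infarction due to embolism")
      mig_cid <- add_concept("G43.61", "ICD10CM", "persistent migraine aura with cerebral infarction")
      ci_s <- snomed_row("cerebral infarction")
      add_map(ci_in, ci_s); add_map(mig_cid, ci_s)
      add_quan("cvd", "I63.4")
      add_adjud(ci_s, "information_gain", "migraine with cerebral infarction is relevant CVD")
      add_label("cvd", "G43.61", "ICD10CM", "snomed_only",
                "multiple_icd_to_one_snomed", "information_gain")
      add_role("cvd", "I63.4", "ICD10CM", "clean", ci_s)
      add_role("cvd", "G43.61", "ICD10CM", "fanout_extra", ci_s)
      add_expected("cvd", ci_s, curated = TRUE)

      # disorder of kidney due to diabetes mellitus: fan-out also captures
      # secondary and drug-induced diabetes with renal manifestations (noise)
      dm_s <- snomed_row("disorder of kidney due to diabetes mellitus")
      dm9 <- add_concept("250.4", "ICD9CM", "diabetes with renal manifestations")
      sec9 <- add_concept("249.4", "ICD9CM", "secondary diabetes with renal manifestations")
      dm10 <- add_concept("E13.2", "ICD10CM", "other specified diabetes with kidney complications")
      drug10 <- add_concept("E09.2", "ICD10CM", "drug or chemical induced diabetes with kidney complications")
      for (cid in c(dm9, sec9, dm10, drug10)) add_map(cid, dm_s)
      quan[[length(quan) + 1L]] <- data.frame(
        condition = "diabetes_complicated", vocabulary = "ICD9CM",
        code = "250.4", provenance = "quan_icd9")
      quan[[length(quan) + 1L]] <- data.frame(
        condition = "diabetes_complicated", vocabulary = "ICD10CM",
        code = "E13.2", provenance = "quan_icd10")
      add_adjud(dm_s, "added_noise", "captures secondary/drug-induced diabetes")
      add_label("diabetes_complicated", "249.4", "ICD9CM", "snomed_only",
                "multiple_icd_to_one_snomed", "added_noise")
      add_label("diabetes_complicated", "E09.2", "ICD10CM", "snomed_only",
                "multiple_icd_to_one_snomed", "added_noise")
      add_role("diabetes_complicated", "250.4", "ICD9CM", "clean", dm_s)
      add_role("diabetes_complicated", "E13.2", "ICD10CM", "clean", dm_s)
      add_role("diabetes_complicated", "249.4", "ICD9CM", "fanout_extra", dm_s)
      add_role("diabetes_complicated", "E09.2", "ICD10CM", "fanout_extra", dm_s)
      add_expected("diabetes_complicated", dm_s, curated = TRUE)
    }

    store <- vocab_store(do.call(rbind, concepts),
                         if (length(mappings)) do.call(rbind, mappings),
                         if (length(ancestors)) do.call(rbind, ancestors))
    empty_labels <- data.frame(condition = character(), code = character(),
                               vocabulary = character(), side = character(),
                               category = character(), adjudication = character())
    quan_df <- do.call(rbind, quan)
    class(quan_df) <- c("cci_codeset", "data.frame")
    sn <- do.call(rbind, expected_snomed) %||%
      data.frame(condition = character(), vocabulary = character(),
                 code = character(), provenance = character())
    sn <- sn[order(sn$condition, as.integer(sn$code)), ]
    rownames(sn) <- NULL
    list(store = store,
         quan_codeset = quan_df,
         adjudication = do.call(rbind, adjud) %||%
           data.frame(key_type = character(), key = character(),
                      decision = character(), note = character()),
         labels = do.call(rbind, labels) %||% empty_labels,
         role_codes = do.call(rbind, roles),
         snomed_codeset = sn)
  })
}

#' Specification for a synthetic claims bundle
#'
#' Default per-condition prevalences follow the pattern of a large Medicaid
#' inpatient population (about a quarter of patients with heart failure,
#' vascular and cerebrovascular disease, half with chronic pulmonary
#' disease, rarer severe liver disease and HIV), which yields a mean
#' weighted score near 3.7; the mortality model defaults to
#' `logit p = -3 + 0.25 * CCI`.
#'
#' @param n_patients Number of patients.
#' @param calendar_year Index year (default 2018; ICD-10-CM era).
#' @param prevalence Named per-condition probabilities in `[0, 1]`.
#' @param disc_snomed_only,disc_quan_only Probability that a planted
#'   condition is recorded with a code visible to only the SNOMED / only the
#'   Quan algorithm (their sum must be <= 1).
#' @param mortality_intercept,mortality_slope Logistic model of one-year
#'   death on the true CCI.
#' @param eligible_fraction Fraction of patients given an observation period
#'   long enough to satisfy the 365-day lookback requirement.
#' @param underage_fraction Fraction of patients younger than 18 at index.
#' @param noise_code_rate Per-patient probability of an extra diagnosis
#'   matching no codeset.
#' @param seed Integer seed.
#' @return list of class `claims_spec`.
#' @export
claims_spec <- function(n_patients = 2000L, calendar_year = 2018L,
                        prevalence = NULL,
                        disc_snomed_only = 0, disc_quan_only = 0,
                        mortality_intercept = -3, mortality_slope = 0.25,
                        eligible_fraction = 0.9, underage_fraction = 0.02,
                        noise_code_rate = 0.3, seed = 1L) {
  default_prev <- c(
    mi = 0.128, chf = 0.254, pvd = 0.224, cvd = 0.253, dementia = 0.110,
    chronic_pulmonary = 0.509, rheumatic = 0.069, pud = 0.065,
    mild_liver = 0.151, diabetes_uncomplicated = 0.376,
    diabetes_complicated = 0.203, hemiplegia_paraplegia = 0.072,
    renal = 0.211, malignancy = 0.122, severe_liver = 0.022,
    metastatic_tumor = 0.038, hiv_aids = 0.017)
  prevalence <- prevalence %||% default_prev
  if (any(prevalence < 0 | prevalence > 1)) {
    abort_cci("prevalences must lie in [0, 1]", "snomedcci_spec_error")
  }
  if (n_patients < 1L) abort_cci("n_patients must be >= 1", "snomedcci_spec_error")
  if (disc_snomed_only < 0 || disc_quan_only < 0 ||
      disc_snomed_only + disc_quan_only > 1) {
    abort_cci("discordance rates must be non-negative and sum to <= 1",
              "snomedcci_spec_error")
  }
  structure(list(n_patients = as.integer(n_patients),
                 calendar_year = as.integer(calendar_year),
                 prevalence = prevalence,
                 disc_snomed_only = disc_snomed_only,
                 disc_quan_only = disc_quan_only,
                 mortality_intercept = mortality_intercept,
                 mortality_slope = mortality_slope,
                 eligible_fraction = eligible_fraction,
                 underage_fraction = underage_fraction,
                 noise_code_rate = noise_code_rate,
                 seed = as.integer(seed)),
            class = "claims_spec")
}

#' Generate a synthetic claims bundle with known ground truth
#'
#' Plants condition flags per patient from the spec prevalences and realizes
#' each planted condition as at least one condition occurrence inside the
#' 365-day lookback window, using codes from the synthetic vocabulary:
#' concordant plants emit an in-set ICD code plus its SNOMED standard
#' concept; SNOMED-only discordant plants emit a fan-out extra code (visible
#' only to the SNOMED algorithm); Quan-only discordant plants emit a
#' deprecated or specificity-lost code (visible only to the Quan
#' algorithm). Deaths are Bernoulli draws from
#' `plogis(intercept + slope * true_cci)` placed uniformly in the follow-up
#' year. Deterministic for a given spec.
#'
#' @param spec A [claims_spec()].
#' @param vocab Output of [gen_vocabulary()]; supplies codes per structural
#'   role.
#' @param definitions Condition table, default [cci_definitions()].
#' @return list with `bundle` (a [claims_bundle()]), `truth` (data.frame:
#'   `person_id`, one logical column per condition, `true_cci`, `died`,
#'   `eligible`), and `index_dates`.
#' @export
gen_claims <- function(spec, vocab, definitions = cci_definitions()) {
  if (!inherits(spec, "claims_spec")) {
    abort_cci("expected a claims_spec", "snomedcci_spec_error")
  }
  # flags span every defined condition; unspecified prevalences are zero
  conds <- definitions$condition
  prev <- stats::setNames(rep(0, length(conds)), conds)
  extra <- setdiff(names(spec$prevalence), conds)
  if (length(extra)) {
    abort_cci(sprintf("prevalence names unknown condition(s): %s",
                      paste(extra, collapse = ", ")),
              "snomedcci_spec_error")
  }
  prev[names(spec$prevalence)] <- spec$prevalence
  # claims of a given era carry the era's ICD dialect: ICD-9-CM before the
  # 2015 transition, ICD-10-CM after
  era_voc <- if (spec$calendar_year < 2015L) "ICD9CM" else "ICD10CM"
  roles <- vocab$role_codes[vocab$role_codes$vocabulary == era_voc, , drop = FALSE]
  missing <- setdiff(conds[prev > 0], unique(roles$condition))
  if (length(missing)) {
    abort_cci(sprintf("vocabulary lacks %s codes for condition(s): %s",
                      era_voc, paste(missing, collapse = ", ")),
              "snomedcci_spec_error")
  }
  with_seed(spec$seed, {
    n <- spec$n_patients
    year <- spec$calendar_year
    person_id <- seq_len(n)
    year_start <- as.Date(sprintf("%d-01-01", year))
    index_date <- year_start + sample.int(365L, n, replace = TRUE) - 1L

    underage <- stats::runif(n) < spec$underage_fraction
    age <- ifelse(underage, sample(1:17, n, replace = TRUE),
                  sample(18:90, n, replace = TRUE))
    persons <- data.frame(person_id = person_id,
                          year_of_birth = year - age,
                          sex = sample(c("F", "M"), n, replace = TRUE))

    long_obs <- stats::runif(n) < spec$eligible_fraction
    obs_start <- index_date - ifelse(long_obs,
                                     365L + sample.int(400L, n, replace = TRUE),
                                     sample.int(300L, n, replace = TRUE) - 1L)
    observation_periods <- data.frame(person_id = person_id,
                                      start_date = obs_start,
                                      end_date = index_date + 400L)
    visits <- data.frame(person_id = person_id, visit_start = index_date,
                         visit_type = "IP", visit_id = person_id)

    flag_mat <- matrix(FALSE, n, length(conds), dimnames = list(NULL, conds))
    occ <- list()
    emit <- function(pid, code, vocabulary, date) {
      occ[[length(occ) + 1L]] <<- data.frame(
        person_id = pid, code = code, vocabulary = vocabulary,
        date = date, stringsAsFactors = FALSE)
    }
    for (cond in conds) {
      if (prev[[cond]] == 0) next
      flagged <- which(stats::runif(n) < prev[[cond]])
      if (!length(flagged)) next
      flag_mat[flagged, cond] <- TRUE
      r <- roles[roles$condition == cond, , drop = FALSE]
      clean <- r[r$role == "clean", , drop = FALSE]
      sn_only <- r[r$role == "fanout_extra", , drop = FALSE]
      q_only <- r[r$role %in% c("deprecated", "specificity"), , drop = FALSE]
      u <- stats::runif(length(flagged))
      kind <- ifelse(u < spec$disc_snomed_only & nrow(sn_only) > 0, "snomed",
                     ifelse(u < spec$disc_snomed_only + spec$disc_quan_only &
                              nrow(q_only) > 0, "quan", "concordant"))
      dates <- index_date[flagged] - sample.int(366L, length(flagged),
                                                replace = TRUE) + 1L
      pick <- function(df, k) df[sample.int(nrow(df), k, replace = TRUE), , drop = FALSE]
      for (kd in c("concordant", "snomed", "quan")) {
        sel <- kind == kd
        if (!any(sel)) next
        src <- switch(kd, concordant = clean, snomed = sn_only, quan = q_only)
        rows <- pick(src, sum(sel))
        emit(flagged[sel], rows$code, rows$vocabulary, dates[sel])
        # the standard-concept row a CDM extract would carry alongside the
        # source code; deprecated codes have none
        has_std <- !is.na(rows$snomed_id)
        if (any(has_std)) {
          std_code <- vocab$store$concepts[data.table::data.table(
            concept_id = rows$snomed_id[has_std]), on = "concept_id", code]
          emit(flagged[sel][has_std], std_code, "SNOMED", dates[sel][has_std])
        }
      }
    }
    noisy <- which(stats::runif(n) < spec$noise_code_rate)
    if (length(noisy)) {
      emit(noisy, "R99.9", "ICD10CM",
           index_date[noisy] - sample.int(366L, length(noisy), replace = TRUE) + 1L)
    }
    condition_occurrences <- do.call(rbind, occ) %||%
      data.frame(person_id = integer(), code = character(),
                 vocabulary = character(), date = as.Date(character()))

    true_cci <- apply(flag_mat, 1L, compute_cci, definitions = definitions,
                      apply_hierarchy = TRUE)
    p_death <- stats::plogis(spec$mortality_intercept +
                               spec$mortality_slope * true_cci)
    died <- stats::runif(n) < p_death
    deaths <- data.frame(
      person_id = person_id[died],
      death_date = index_date[died] +
        sample.int(366L, sum(died), replace = TRUE) - 1L)

    truth <- data.frame(person_id = person_id)
    truth <- cbind(truth, as.data.frame(flag_mat))
    truth$true_cci <- as.integer(true_cci)
    truth$died <- died
    truth$eligible <- long_obs & !underage
    bundle <- claims_bundle(persons, observation_periods, visits,
                            condition_occurrences, deaths)
    list(bundle = bundle, truth = truth, index_dates = index_date)
  })
}
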