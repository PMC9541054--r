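# Study cohort construction from claims-shaped tables: inpatient index
# selection, eligibility filters, attrition accounting, one-year mortality.

#' Assemble and validate a claims bundle
#'
#' A claims bundle is the minimal CDM-shaped input the toolkit consumes:
#' persons, observation periods, visits, condition occurrences and deaths.
#' Dates are parsed, identifiers checked for resolvability, and observation
#' periods checked for within-person non-overlap.
#'
#' @param persons data.frame `person_id`, `year_of_birth`, `sex`.
#' @param observation_periods data.frame `person_id`, `start_date`, `end_date`.
#' @param visits data.frame `person_id`, `visit_start`, `visit_type`
#'   (inpatient visits carry `visit_type = "IP"`); an optional `visit_id`
#'   breaks same-day ties.
#' @param condition_occurrences data.frame `person_id`, `code`, `vocabulary`,
#'   `date`.
#' @param deaths data.frame `person_id`, `death_date`.
#' @return list of validated data.frames, class `claims_bundle`.
#' @export
claims_bundle <- function(persons, observation_periods, visits,
                          condition_occurrences, deaths) {
  assert_cols(persons, c("person_id", "year_of_birth", "sex"), "persons")
  assert_cols(observation_periods, c("person_id", "start_date", "end_date"),
              "observation_periods")
  assert_cols(visits, c("person_id", "visit_start", "visit_type"), "visits")
  assert_cols(condition_occurrences, c("person_id", "code", "vocabulary", "date"),
              "condition_occurrences")
  assert_cols(deaths, c("person_id", "death_date"), "deaths")
  if (anyDuplicated(persons$person_id)) {
    abort_cci("duplicate person_id in persons", "snomedcci_integrity_error")
  }
  observation_periods$start_date <- as_date_safe(observation_periods$start_date,
                                                 "observation start_date")
  observation_periods$end_date <- as_date_safe(observation_periods$end_date,
                                               "observation end_date")
  visits$visit_start <- as_date_safe(visits$visit_start, "visit_start")
  deaths$death_date <- as_date_safe(deaths$death_date, "death_date")
  known <- persons$person_id
  for (nm in c("observation_periods", "visits", "condition_occurrences", "deaths")) {
    tbl <- get(nm)
    stray <- setdiff(unique(tbl$person_id), known)
    if (length(stray)) {
      abort_cci(sprintf("%s references unknown person_id(s): %s", nm,
                        paste(utils::head(stray, 5), collapse = ", ")),
                "snomedcci_integrity_error")
    }
  }
  op <- observation_periods[order(observation_periods$person_id,
                                  observation_periods$start_date), ]
  same <- which(diff(match(op$person_id, unique(op$person_id))) == 0L)
  if (length(same) && any(op$start_date[same + 1L] <= op$end_date[same])) {
    abort_cci("overlapping observation periods within a person",
              "snomedcci_integrity_error")
  }
  structure(list(persons = persons, observation_periods = observation_periods,
                 visits = visits,
                 condition_occurrences = condition_occurrences,
                 deaths = deaths),
            class = "claims_bundle")
}

#' Build the inpatient index cohort for one calendar year
#'
#' Index is the earliest inpatient visit (`visit_type == "IP"`) in the
#' calendar year; same-day ties are broken by lowest `visit_id` when
#' present. Eligibility requires age >= 18 years at index (age computed as
#' `calendar_year - year_of_birth`; claims carry year of birth only) and a
#' single continuous observation period spanning `[index - 365, index]`.
#' Exclusions are counted per filter in an attrition table attached as
#' `attr(, "attrition")`; input persons = eligible + sum of exclusions.
#'
#' @param bundle A [claims_bundle()].
#' @param calendar_year Integer year.
#' @param min_age Minimum age at index (default 18).
#' @param min_observation_days Required prior continuous observation
#'   (default 365).
#' @return data.frame `person_id`, `index_date`, `age_at_index`, `sex`,
#'   ordered by `person_id`, with the attrition table as an attribute.
#' @export
build_cohort <- function(bundle, calendar_year, min_age = 18L,
                         min_observation_days = 365L) {
  if (!inherits(bundle, "claims_bundle")) {
    abort_cci("expected a claims_bundle", "snomedcci_contract_error")
  }
  calendar_year <- as.integer(calendar_year)
  persons <- data.table::as.data.table(bundle$persons)
  visits <- data.table::as.data.table(bundle$visits)
  if (!"visit_id" %in% names(visits)) visits[, visit_id := .I]
  n_total <- nrow(persons)

  year_start <- as.Date(sprintf("%d-01-01", calendar_year))
  year_end <- as.Date(sprintf("%d-12-31", calendar_year))
  ip <- visits[visit_type == "IP" & visit_start >= year_start &
                 visit_start <= year_end]
  data.table::setorder(ip, person_id, visit_start, visit_id)
  idx <- ip[, .SD[1L], by = person_id][, .(person_id, index_date = visit_start)]
  n_no_ip <- n_total - nrow(idx)

  idx <- persons[idx, on = "person_id"]
  idx[, age_at_index := calendar_year - as.integer(year_of_birth)]
  underage <- idx[age_at_index < min_age]
  idx <- idx[age_at_index >= min_age]
  n_underage <- nrow(underage)

  op <- data.table::as.data.table(bundle$observation_periods)
  cov <- op[idx, on = .(person_id, start_date <= index_date,
                        end_date >= index_date),
            .(person_id = i.person_id, index_date = i.index_date,
              op_start = x.start_date), nomatch = NULL]
  cov <- cov[op_start <= index_date - min_observation_days]
  eligible <- idx[cov[, .(person_id)], on = "person_id"]
  n_short_obs <- nrow(idx) - nrow(eligible)

  out <- eligible[, .(person_id, index_date, age_at_index, sex)]
  data.table::setorder(out, person_id)
  out <- as.data.frame(out)
  attr(out, "attrition") <- data.frame(
    step = c("input_persons", "no_inpatient_visit_in_year",
             "age_below_minimum", "insufficient_prior_observation",
             "eligible"),
    n = c(n_total, n_no_ip, n_underage, n_short_obs, nrow(out))
  )
  out
}

#' Attach the one-year mortality outcome
#'
#' `died_within_365` is `TRUE` when a death date `d` satisfies
#' `index_date <= d <= index_date + 365` (both ends inclusive). A death
#' recorded before a person's index is a data anomaly: the person is
#' excluded and the count reported via `message()` and the
#' `attr(, "n_death_before_index")` attribute.
#'
#' @param rows Cohort data.frame from [build_cohort()].
#' @param deaths data.frame `person_id`, `death_date`.
#' @param window_days Follow-up window length (default 365).
#' @return `rows` with a `died_within_365` column.
#' @export
attach_outcome <- function(rows, deaths, window_days = 365L) {
  assert_cols(rows, c("person_id", "index_date"), "cohort rows")
  assert_cols(deaths, c("person_id", "death_date"), "deaths")
  deaths$death_date <- as_date_safe(deaths$death_date, "death_date")
  first_death <- stats::aggregate(death_date ~ person_id, data = deaths, FUN = min)
  m <- merge(rows, first_death, by = "person_id", all.x = TRUE)
  pre_index <- !is.na(m$death_date) & m$death_date < m$index_date
  if (any(pre_index)) {
    message(sprintf("attach_outcome: excluded %d person(s) with death before index",
                    sum(pre_index)))
  }
  m <- m[!pre_index, , drop = FALSE]
  m$died_within_365 <- !is.na(m$death_date) &
    m$death_date >= m$index_date &
    m$death_date <= m$index_date + window_days
  m$death_date <- NULL
  m <- m[order(m$person_id), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "attrition") <- attr(rows, "attrition")
  attr(m, "n_death_before_index") <- sum(pre_index)
  m
}
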