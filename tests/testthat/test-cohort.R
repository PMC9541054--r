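make_bundle <- function(persons, op, visits, dx = NULL, deaths = NULL) {
  claims_bundle(
    persons,
    op,
    visits,
    dx %||% data.frame(person_id = integer(), code = character(),
                       vocabulary = character(), date = as.Date(character())),
    deaths %||% data.frame(person_id = integer(),
                           death_date = as.Date(character())))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("index is the earliest inpatient visit of the year", {
  persons <- data.frame(person_id = 1L, year_of_birth = 1960L, sex = "F")
  op <- data.frame(person_id = 1L, start_date = "2015-01-01",
                   end_date = "2019-12-31")
  visits <- data.frame(person_id = 1L,
                       visit_start = c("2018-07-09", "2018-03-03", "2017-11-01"),
                       visit_type = c("IP", "IP", "IP"))
  co <- build_cohort(make_bundle(persons, op, visits), 2018)
  expect_equal(co$index_date, as.Date("2018-03-03"))
  # outpatient visits never define index
  visits2 <- data.frame(person_id = 1L, visit_start = "2018-01-05",
                        visit_type = "OP")
  expect_equal(nrow(build_cohort(make_bundle(persons, op, visits2), 2018)), 0L)
})

test_that("eligibility filters and attrition accounting are conserved", {
  persons <- data.frame(person_id = 1:4,
                        year_of_birth = c(1960L, 2001L, 1970L, 1955L),
                        sex = c("F", "M", "F", "M"))
  op <- data.frame(
    person_id = 1:4,
    start_date = c("2015-01-01", "2015-01-01", "2018-03-01", "2015-01-01"),
    end_date = rep("2019-12-31", 4))  # person 3: only ~300 days before index
  visits <- data.frame(person_id = 1:4, visit_start = "2018-12-20",
                       visit_type = "IP")
  co <- build_cohort(make_bundle(persons, op, visits), 2018)
  expect_equal(co$person_id, c(1L, 4L))
  att <- attr(co, "attrition")
  n <- setNames(att$n, att$step)
  expect_equal(n[["input_persons"]],
               n[["no_inpatient_visit_in_year"]] + n[["age_below_minimum"]] +
                 n[["insufficient_prior_observation"]] + n[["eligible"]])
  expect_equal(n[["age_below_minimum"]], 1)
  expect_equal(n[["insufficient_prior_observation"]], 1)

  # exactly 365 days of prior observation qualifies (closed window)
  op365 <- data.frame(person_id = 1L, start_date = "2017-12-20",
                      end_date = "2019-12-31")
  co365 <- build_cohort(make_bundle(persons[1, ], op365, visits[1, ]), 2018)
  expect_equal(nrow(co365), 1L)
  # a gap inside the lookback disqualifies even if total coverage is long
  op_gap <- data.frame(person_id = c(1L, 1L),
                       start_date = c("2015-01-01", "2018-06-01"),
                       end_date = c("2018-05-01", "2019-12-31"))
  expect_equal(nrow(build_cohort(make_bundle(persons[1, ], op_gap, visits[1, ]),
                                 2018)), 0L)
})

test_that("one-year mortality uses a closed 365-day window", {
  persons <- data.frame(person_id = 1:4, year_of_birth = 1960L, sex = "F")
  op <- data.frame(person_id = 1:4, start_date = "2015-01-01",
                   end_date = "2019-12-31")
  visits <- data.frame(person_id = 1:4, visit_start = "2018-01-10",
                       visit_type = "IP")
  idx <- as.Date("2018-01-10")
  deaths <- data.frame(person_id = c(1L, 2L),
                       death_date = c(idx + 365, idx + 400))
  co <- build_cohort(make_bundle(persons, op, visits), 2018)
  co <- attach_outcome(co, deaths)
  expect_equal(co$died_within_365, c(TRUE, FALSE, FALSE, FALSE))

  # death before index is an anomaly: person excluded, count reported
  deaths2 <- data.frame(person_id = 3L, death_date = idx - 5)
  expect_message(co2 <- attach_outcome(build_cohort(make_bundle(persons, op, visits),
                                                    2018), deaths2),
                 "death before index")
  expect_false(3L %in% co2$person_id)
  expect_equal(attr(co2, "n_death_before_index"), 1L)
})

test_that("identical bundles yield identical cohorts", {
  v <- gen_vocabulary(vocab_spec(seed = 2))
  cl <- gen_claims(claims_spec(n_patients = 200, seed = 2), v)
  a <- attach_outcome(build_cohort(cl$bundle, 2018), cl$bundle$deaths)
  b <- attach_outcome(build_cohort(cl$bundle, 2018), cl$bundle$deaths)
  expect_identical(a, b)
})
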