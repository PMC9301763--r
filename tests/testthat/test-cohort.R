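test_that("index is the earliest antidepressant dispensing in accrual", {
  r <- recs(rec("p1", c(59, 0), "sertraline"),
            rec("p2", 10, "quetiapine"))
  idx <- find_index(r, FM)
  expect_equal(nrow(idx), 1L)
  expect_equal(idx$patient_id, "p1")
  expect_equal(idx$index_date, DAY0)

  # antidepressant before accrual start is not the index, but still counts
  # against the washout of the in-window index
  r2 <- recs(rec("p3", 0, "sertraline", origin = as.Date("2013-06-15")),
             rec("p3", 0, "sertraline", origin = as.Date("2013-08-01")))
  idx2 <- find_index(r2, FM)
  expect_equal(idx2$index_date, as.Date("2013-08-01"))
  wash <- apply_washout(r2, idx2, FM)
  expect_false(wash$included)
  expect_equal(wash$reason, "washout_antidepressant")
})

test_that("rolling washout excludes recent antidepressant users only", {
  idx_date <- as.Date("2015-06-01")
  idx <- data.frame(patient_id = "p", index_date = idx_date,
                    index_molecule = "sertraline", index_class = "SSRI",
                    stringsAsFactors = FALSE)
  mk <- function(months_before) {
    recs(rec("p", 0, "sertraline", origin = shift_months(idx_date,
                                                         -months_before)),
         rec("p", 0, "sertraline", origin = idx_date))
  }
  w13 <- apply_washout(mk(13), idx, FM)
  expect_true(w13$included)
  w11 <- apply_washout(mk(11), idx, FM)
  expect_false(w11$included)
  expect_equal(w11$reason, "washout_antidepressant")
})

test_that("antipsychotic prior to or on the index date excludes", {
  same <- recs(rec("p", 0, "sertraline"), rec("p", 0, "quetiapine"))
  w <- apply_washout(same, find_index(same, FM), FM)
  expect_equal(w$reason, "same_day_antipsychotic")

  # antipsychotic 14 months before index: outside the washout window but
  # still excluded, the pre-index rule has no time limit
  prior <- recs(rec("p", 0, "olanzapine",
                    origin = shift_months(DAY0 + 100, -14)),
                rec("p", 100, "sertraline"))
  w2 <- apply_washout(prior, find_index(prior, FM), FM)
  expect_equal(w2$reason, "prior_antipsychotic")

  # mood stabilisers never trigger exclusion
  ms <- recs(rec("p", -60, "lithium"), rec("p", 0, "sertraline"))
  w3 <- apply_washout(ms, find_index(ms, FM), FM)
  expect_true(w3$included)
})

test_that("fixed-window washout uses the shared clean period", {
  # violator dispensing 13+ months before a late index: clean under the
  # rolling reading, dirty under the fixed-window reading
  r <- recs(rec("p", 0, "sertraline", origin = as.Date("2013-06-20")),
            rec("p", 0, "sertraline", origin = as.Date("2014-08-01")))
  roll <- build_cohort(r, FM, cohort_config(washout_mode = "rolling"))
  expect_equal(nrow(roll$cohort), 1L)
  fixed <- build_cohort(r, FM, cohort_config(washout_mode = "fixed_window"))
  expect_equal(nrow(fixed$cohort), 0L)
  expect_equal(fixed$exclusions$reason, "washout_antidepressant")
})

test_that("age filter is year-precision with an inclusive 16 boundary", {
  expect_equal(age_at(1998L, as.Date("2014-06-01")), 16L)
  expect_equal(age_at(1950L, as.Date("2019-03-01")), 69L)
  r <- recs(rec("a16", 0, "sertraline", yob = 1998L),
            rec("a15", 0, "sertraline", yob = 1999L),
            rec("noyob", 0, "sertraline", yob = NA_integer_))
  co <- build_cohort(r, FM, cohort_config())
  expect_equal(co$cohort$patient_id, "a16")
  ex <- co$exclusions
  expect_equal(ex$reason[ex$patient_id == "a15"], "under_age")
  expect_equal(ex$reason[ex$patient_id == "noyob"],
               "missing_year_of_birth")
})

test_that("included patients have clean washout windows; cohort size is monotone", {
  sim <- simulate_dispensing(sim_config(n_patients = 150, seed = 11,
                                        p_prior_use = 0.3))
  co <- build_cohort(sim$records, FM, cohort_config())
  # no included patient has an AD/AP dispensing in (index - washout, index)
  cl <- classify(sim$records$molecule, FM)
  for (i in seq_len(nrow(co$cohort))) {
    p <- co$cohort$patient_id[i]
    idx <- co$cohort$index_date[i]
    sel <- sim$records$patient_id == p &
      cl$drug_group %in% c("antidepressant", "antipsychotic")
    d <- sim$records$dispense_date[sel]
    expect_false(any(d > shift_months(idx, -12L) & d < idx))
  }
  n_of <- function(cfg) nrow(build_cohort(sim$records, FM, cfg)$cohort)
  n6 <- n_of(cohort_config(washout_months = 6L,
                           data_start = as.Date("2012-07-01")))
  n12 <- n_of(cohort_config(washout_months = 12L))
  expect_true(n12 <= n6)
  n_a30 <- n_of(cohort_config(min_age_years = 30L))
  expect_true(n_a30 <= n_of(cohort_config(min_age_years = 16L)))
})
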