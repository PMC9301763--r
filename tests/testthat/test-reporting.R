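test_that("class shares by line recover generator probabilities", {
  n <- 4000
  sim <- simulate_dispensing(quiet_sim_config(n, seed = 41))
  pl <- run_pipeline(sim$records, FM, cohort_config(),
                     episode_config(data_end = sim$config$study_end))
  tab <- class_share_by_line(pl$episodes)
  t1 <- tab[tab$treatment_number == 1L, ]
  expect_equal(sum(t1$percentage), 100, tolerance = 1e-9)
  expect_equal(sum(t1$count), nrow(pl$cohort$cohort))  # cross-table check
  p <- sim$config$class_init_probs
  for (cl in t1$drug_class) {
    se <- sqrt(p[[cl]] * (1 - p[[cl]]) / n)
    expect_lt(abs(t1$count[t1$drug_class == cl] / n - p[[cl]]), 3 * se + 1e-12)
  }
})

test_that("degenerate share tables are safe", {
  one <- fixture_episodes(rec("p", c(0, 30), "sertraline"),
                          episode_config(data_end = DAY0 + 400))
  tab <- class_share_by_line(one)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$percentage, 100)

  empty <- one$episodes[0, ]
  expect_equal(nrow(class_share_by_line(empty)), 0L)
  expect_equal(nrow(prescriber_share(rec("p", 0, "sertraline")[0, ], empty)),
               0L)
})

test_that("prescriber shares cross-tabulate the line-opening prescription", {
  r <- recs(rec("p1", c(0, 30), "sertraline", presc = "GP"),
            rec("p2", c(0, 30), "amitriptyline", presc = "GP"),
            rec("p3", c(0, 30), "sertraline", presc = "psychiatrist"))
  ep <- fixture_episodes(r, episode_config(data_end = DAY0 + 400))
  tab <- prescriber_share(r, ep)
  gp <- tab[tab$prescriber_type == "GP", ]
  expect_equal(sum(gp$percentage), 100, tolerance = 1e-9)
  expect_equal(gp$percentage[gp$drug_class == "SSRI"], 50)
  expect_equal(gp$percentage[gp$drug_class == "TCA"], 50)
  psy <- tab[tab$prescriber_type == "psychiatrist", ]
  expect_equal(psy$drug_class, "SSRI")
  expect_equal(psy$percentage, 100)
})

test_that("age groups are non-exclusive with inclusive upper bounds", {
  # born 1990: age 24 in 2014, 29 in 2019 -> two age groups
  r <- recs(rec("p", 0, "sertraline", yob = 1990L),
            rec("p", 0, "sertraline", yob = 1990L,
                origin = as.Date("2019-01-01")))
  tab <- age_group_share(r, FM)
  expect_setequal(tab$age_group, c("16-25", "26-45"))

  # bin-boundary age 25 falls in 16-25
  r25 <- rec("p", 0, "sertraline", yob = 1989L)  # 2014 - 1989 = 25
  expect_equal(age_group_share(r25, FM)$age_group, "16-25")

  # one-age fixture: a single group at 100%
  same <- recs(rec("a", 0, "sertraline", yob = 1980L),
               rec("b", 0, "amitriptyline", yob = 1980L))
  tab2 <- age_group_share(same, FM)
  expect_true(all(tab2$age_group == "26-45"))
  expect_equal(sum(tab2$percentage), 100, tolerance = 1e-9)
})

test_that("horizon rates are censoring-aware cumulative incidences", {
  # every patient switches at day 30 (~1 month): 100% at all horizons >= 1
  r <- recs(rec("p1", c(0, 30, 60), c("sertraline", "venlafaxine",
                                      "venlafaxine")),
            rec("p2", c(0, 30, 60), c("sertraline", "venlafaxine",
                                      "venlafaxine")))
  ep <- fixture_episodes(r, episode_config(data_end = DAY0 + 200))
  hr <- horizon_rates(ep, horizons = c(6, 12, 24))
  sw <- hr[hr$event == "switch", ]
  expect_equal(sw$percentage, rep(100, 3))

  # no planted events: 0% everywhere
  quiet <- fixture_episodes(rec("p", c(0, 30, 60), "sertraline"),
                            episode_config(data_end = DAY0 + 200))
  hr0 <- horizon_rates(quiet)
  expect_true(all(hr0$percentage == 0))
})

test_that("dose-increase incidence recovers the generator's planted events", {
  n <- 3000
  sim <- simulate_dispensing(sim_config(
    n_patients = n, seed = 42, p_dose_increase = 0.19,
    disc_hazard_per_month = flat_hazards(6),
    p_switch = 0, p_combination = 0, p_augmentation = 0, p_return = 0))
  pl <- run_pipeline(sim$records, FM, cohort_config(),
                     episode_config(data_end = sim$config$study_end))
  hr <- horizon_rates(pl$episodes, horizons = 12)
  est <- hr$percentage[hr$event == "dose_increase"]
  # truth incidence among patients with a full 12 months of potential
  # follow-up (the KM estimate handles the administratively censored rest)
  tp <- sim$truth$patients
  full <- tp$index_date <= shift_months(sim$config$study_end, -12L)
  planted <- 100 * mean(!is.na(tp$dose_date[full]) &
                          (tp$dose_date[full] - tp$index_date[full]) / 30.44
                        <= 12)
  expect_lt(abs(est - planted), 2)
})

test_that("tables regenerate identically from the same inputs", {
  sim <- simulate_dispensing(sim_config(n_patients = 100, seed = 43,
                                        p_switch = 0.2, p_return = 0.4))
  pl <- run_pipeline(sim$records, FM, cohort_config(),
                     episode_config(data_end = sim$config$study_end))
  expect_identical(class_share_by_line(pl$episodes),
                   class_share_by_line(pl$episodes))
  expect_identical(age_group_share(sim$records, FM),
                   age_group_share(sim$records, FM))
})
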