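test_that("discontinuation boundaries follow the 6-month gap rule", {
  cfg <- episode_config(data_end = DAY0 + 400)
  b <- detect_discontinuation(DAY0 + c(0, 30, 250), cfg)
  expect_equal(nrow(b$boundaries), 1L)
  expect_equal(b$boundaries$last_before, DAY0 + 30)
  expect_equal(b$boundaries$next_after, DAY0 + 250)

  none <- detect_discontinuation(DAY0 + seq(0, 360, by = 30), cfg)
  expect_equal(nrow(none$boundaries), 0L)

  single <- detect_discontinuation(DAY0, episode_config(data_end = DAY0 + 200))
  expect_equal(nrow(single$boundaries), 0L)
  expect_true(single$trailing)

  # boundary is strict: a gap of exactly 183 days does not discontinue
  expect_equal(nrow(detect_discontinuation(DAY0 + c(0, 183),
                                           cfg)$boundaries), 0L)
  expect_equal(nrow(detect_discontinuation(DAY0 + c(0, 184),
                                           cfg)$boundaries), 1L)
})

test_that("restart after a gap increments the line even for the same class", {
  r <- rec("p", c(0, 30, 60, 90, 120, 320 + 30), "sertraline")
  # 200-day gap between day 120 and day 350
  ep <- fixture_episodes(r, episode_config(data_end = DAY0 + 400))$episodes
  expect_equal(ep$treatment_number, c(1L, 2L))
  expect_equal(ep$end_reason[1], "discontinuation")
  expect_equal(ep$end_date[1], DAY0 + 150)  # last dispensing + one pack
  expect_equal(ep$start_date[2], DAY0 + 350)
  expect_equal(ep$classes, c("SSRI", "SSRI"))
  # the alternative convention ends the episode at the last dispensing
  ep2 <- fixture_episodes(r, episode_config(
    disc_end = "last_dispensing", data_end = DAY0 + 400))$episodes
  expect_equal(ep2$end_date[1], DAY0 + 120)
})

test_that("a class switch starts a new line at the new dispensing date", {
  r <- rec("p", c(0, 30, 60), c("sertraline", "sertraline", "venlafaxine"))
  ep <- fixture_episodes(r, episode_config(data_end = DAY0 + 200))$episodes
  expect_equal(ep$treatment_number, c(1L, 2L))
  expect_equal(ep$end_reason[1], "switch")
  expect_equal(ep$end_date[1], DAY0 + 60)
  expect_equal(ep$start_date[2], DAY0 + 60)
  expect_equal(ep$classes, c("SSRI", "SNRI"))
  expect_equal(ep$persistence_months[1], 60 / 30.44)
})

test_that("an added concurrent class is a combination, not a switch", {
  # old class keeps being dispensed inside the 30-day window after the new
  # class appears
  r <- rec("p", c(0, 30, 60, 74), c("sertraline", "sertraline",
                                    "mirtazapine", "sertraline"))
  ep <- fixture_episodes(r, episode_config(data_end = DAY0 + 200))$episodes
  expect_equal(ep$end_reason[1], "combination_added")
  expect_equal(ep$classes[2], "NaSSA;SSRI")
  expect_equal(ep$start_date[2], DAY0 + 60)
})

test_that("a concurrent antipsychotic is augmentation; a distant one is not", {
  r <- rec("p", c(0, 30, 60, 60), c("sertraline", "sertraline",
                                    "sertraline", "quetiapine"))
  ep <- fixture_episodes(r, episode_config(data_end = DAY0 + 200))$episodes
  expect_equal(ep$end_reason[1], "augmentation_added")
  expect_equal(ep$start_date[2], DAY0 + 60)
  expect_equal(ep$classes[2], "SSRI;antipsychotic")

  # antipsychotic 60 days after the last antidepressant dispensing: not
  # concurrent, no augmentation (and no new line)
  r2 <- recs(rec("p", c(0, 30), "sertraline"),
             rec("p", 90, "quetiapine"))
  ep2 <- fixture_episodes(r2, episode_config(data_end = DAY0 + 200))$episodes
  expect_equal(nrow(ep2), 1L)
  expect_equal(ep2$classes, "SSRI")
})

test_that("within-class molecule changes are logged but never increment", {
  r <- rec("p", c(0, 30, 60), c("sertraline", "escitalopram",
                                "escitalopram"))
  res <- fixture_episodes(r, episode_config(data_end = DAY0 + 200))
  expect_equal(nrow(res$episodes), 1L)
  expect_equal(res$episodes$classes, "SSRI")
  expect_equal(nrow(res$within_class_switches), 1L)
  expect_equal(res$within_class_switches$from, "sertraline")
  expect_equal(res$within_class_switches$to, "escitalopram")
})

test_that("two classes on the index date form one flagged multi-class line", {
  r <- rec("p", c(0, 0, 30, 30), c("sertraline", "mirtazapine",
                                   "sertraline", "mirtazapine"))
  ep <- fixture_episodes(r, episode_config(data_end = DAY0 + 200))$episodes
  expect_equal(nrow(ep), 1L)
  expect_true(ep$multi_class_start)
  expect_equal(ep$classes, "NaSSA;SSRI")
})

test_that("dose increases compare within molecule, first increase only", {
  r <- rec("p", c(0, 60), "citalopram", str = c(10, 40))
  ev <- fixture_episodes(r, episode_config(data_end = DAY0 + 200))$dose_events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$date, DAY0 + 60)
  expect_equal(ev$from_strength_mg, 10)
  expect_equal(ev$to_strength_mg, 40)

  dec <- rec("p", c(0, 60), "citalopram", str = c(40, 10))
  expect_equal(nrow(fixture_episodes(
    dec, episode_config(data_end = DAY0 + 200))$dose_events), 0L)

  two <- rec("p", c(0, 60, 120), "citalopram", str = c(10, 20, 40))
  ev2 <- fixture_episodes(two,
                          episode_config(data_end = DAY0 + 200))$dose_events
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$date, DAY0 + 60)
  expect_equal(ev2$to_strength_mg, 20)

  # a strength change across molecules is not a dose increase
  cross <- rec("p", c(0, 60), c("citalopram", "sertraline"),
               str = c(40, 50))
  expect_equal(nrow(fixture_episodes(
    cross, episode_config(data_end = DAY0 + 200))$dose_events), 0L)
})

test_that("episode construction is invariant to record order", {
  sim <- simulate_dispensing(sim_config(n_patients = 60, seed = 5,
                                        p_switch = 0.3, p_combination = 0.2,
                                        p_augmentation = 0.2,
                                        p_return = 0.5))
  ecfg <- episode_config(data_end = sim$config$study_end)
  co <- build_cohort(sim$records, FM, cohort_config())
  ref <- build_episodes(sim$records, co, FM, ecfg)$episodes
  set.seed(99)
  shuffled <- sim$records[sample(nrow(sim$records)), ]
  got <- build_episodes(shuffled, co, FM, ecfg)$episodes
  expect_equal(canon_eps(got), canon_eps(ref))
})

test_that("episodes partition follow-up with consecutive numbering", {
  sim <- simulate_dispensing(sim_config(n_patients = 100, seed = 9,
                                        p_switch = 0.3, p_combination = 0.2,
                                        p_augmentation = 0.2,
                                        p_return = 0.5, p_prior_use = 0.1))
  chk <- recovery_check(sim)
  ep <- chk$pipeline$episodes$episodes
  cl <- classify(sim$records$molecule, FM)
  for (p in unique(ep$patient_id)) {
    e <- ep[ep$patient_id == p, ]
    e <- e[order(e$treatment_number), ]
    expect_equal(e$treatment_number, seq_len(nrow(e)))
    expect_true(all(e$start_date <= e$end_date))
    if (nrow(e) > 1L) {
      expect_true(all(e$start_date[-1L] >= e$end_date[-nrow(e)]))
    }
    # every antidepressant dispensing lies in exactly one episode span
    d <- sim$records$dispense_date[sim$records$patient_id == p &
                                     cl$drug_group == "antidepressant"]
    bins <- findInterval(as.integer(d), as.integer(e$start_date))
    expect_true(all(bins >= 1L))
  }
})

test_that("widening the gap never creates more discontinuation episodes", {
  sim <- simulate_dispensing(sim_config(n_patients = 120, seed = 13,
                                        p_return = 0.6))
  co <- build_cohort(sim$records, FM, cohort_config())
  n_disc <- function(gap) {
    ep <- build_episodes(sim$records, co, FM, episode_config(
      discontinuation_gap_days = gap,
      data_end = sim$config$study_end))$episodes
    sum(ep$end_reason == "discontinuation")
  }
  counts <- vapply(c(120L, 183L, 240L, 360L), n_disc, integer(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("pairwise concurrency detection honours the 30-day window", {
  cfg <- episode_config(data_end = DAY0 + 300)
  comb <- detect_concurrency(rec("p", c(0, 14), c("sertraline",
                                                  "mirtazapine")), FM, cfg)
  expect_equal(comb$type, "combination")
  expect_equal(comb$date, DAY0 + 14)

  wc <- detect_concurrency(rec("p", c(0, 14), c("sertraline",
                                                "escitalopram")), FM, cfg)
  expect_equal(wc$type, "within_class")

  far <- detect_concurrency(recs(rec("p", 0, "sertraline"),
                                 rec("p", 90, "quetiapine")), FM, cfg)
  expect_equal(nrow(far), 0L)

  aug <- detect_concurrency(recs(rec("p", c(0, 28), "sertraline"),
                                 rec("p", 40, "quetiapine")), FM, cfg)
  expect_equal(aug$type, "augmentation")
})
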