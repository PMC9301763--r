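# Fixture builders shared across the suite. All fixtures are constructed
# in code; the day origin for hand-traced patients is 2014-01-01, safely
# inside the default accrual window.

DAY0 <- as.Date("2014-01-01")

rec <- function(pid, day, mol, str = 50, presc = "GP", yob = 1980L,
                sex = "F", region = "NSW", origin = DAY0) {
  data.frame(patient_id = pid, year_of_birth = yob, sex = sex,
             region = region, dispense_date = origin + day, molecule = mol,
             strength_mg = str, prescriber_type = presc,
             stringsAsFactors = FALSE)
}

recs <- function(...) do.call(rbind, list(...))

FM <- default_formulary()

ep_cfg <- function(...) episode_config(...)

# Build episodes for a small fixture, going through the real cohort stage.
fixture_episodes <- function(records, ecfg = episode_config()) {
  cohort <- build_cohort(records, FM, cohort_config())
  build_episodes(records, cohort, FM, ecfg)
}

# Canonical comparable form of an episode table / truth table.
canon_eps <- function(df) {
  df <- df[order(df$patient_id, df$treatment_number),
           c("patient_id", "treatment_number", "start_date", "end_date",
             "classes", "end_reason")]
  rownames(df) <- NULL
  df
}

# Zero hazards / all-off dynamics helpers for generator scenarios.
zero_hazards <- setNames(rep(0, length(AD_CLASSES)), AD_CLASSES)
flat_hazards <- function(median_months) {
  setNames(rep(log(2) / median_months, length(AD_CLASSES)), AD_CLASSES)
}

quiet_sim_config <- function(n, seed, ...) {
  sim_config(n_patients = n, seed = seed,
             disc_hazard_per_month = zero_hazards,
             p_switch = 0, p_combination = 0, p_augmentation = 0,
             p_dose_increase = 0, p_return = 0, p_prior_use = 0, ...)
}

# Run generator output through the pipeline and compare with ground truth.
recovery_check <- function(sim, ecfg = NULL) {
  if (is.null(ecfg)) {
    ecfg <- episode_config(data_end = sim$config$study_end)
  }
  pl <- run_pipeline(sim$records, sim$config$formulary, cohort_config(),
                     ecfg)
  got <- canon_eps(pl$episodes$episodes)
  want <- canon_eps(sim$truth$episodes)
  list(pipeline = pl, got = got, want = want,
       equal = isTRUE(all.equal(got, want, check.attributes = FALSE)))
}
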