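## Synthetic dispensing-data generator. Produces per-patient refill
## trajectories together with the ground-truth treatment-episode structure
## that a correct line-of-therapy algorithm must recover. Every planted
## event (discontinuation gap, class switch, combination, antipsychotic
## augmentation, strength step-up) is constructed to satisfy the episode
## rules by a safe margin, so recovery is exact, not approximate.

#' Configuration for the synthetic dispensing-data generator
#'
#' Defaults emulate an Australian subsidised-dispensing antidepressant
#' cohort: accrual July 2013 to June 2019 on top of a one-year clean
#' look-back, monthly pack refills, first-line class shares dominated by
#' SSRIs (52%) and TCAs (25%), and class-specific exponential
#' discontinuation hazards parameterised by median persistence (5.8 months
#' for SSRIs down to 0.9 months for TCAs).
#'
#' @param n_patients Number of patients to simulate.
#' @param study_start Accrual start date (index dispensings are drawn from
#'   `study_start` to `accrual_end`).
#' @param study_end End of the data window; dispensing stops and follow-up
#'   is censored here.
#' @param accrual_end Last possible index date (default `study_end`).
#' @param data_start Start of the loadable data window (default 12 months
#'   before `study_start`); pre-index dispensings of washout violators are
#'   placed after this date.
#' @param seed Integer seed; identical `(config, seed)` gives byte-identical
#'   output. The caller's RNG state is left untouched.
#' @param class_init_probs Named probabilities (summing to 1) that an
#'   episode started from scratch begins with each antidepressant class.
#' @param disc_hazard_per_month Named per-month exponential discontinuation
#'   hazards by class; `log(2) / median_months`. A zero hazard disables
#'   spontaneous discontinuation for that class.
#' @param p_switch,p_combination,p_augmentation Per-episode probabilities
#'   that a single-class episode ends in a class switch, an added
#'   antidepressant class, or an added antipsychotic (the planted event
#'   time is uniform on 1-12 months and competes with discontinuation).
#' @param p_dose_increase Probability that a patient's first episode
#'   contains a single step-up to the next available tablet strength.
#' @param p_return Probability that a discontinuing patient eventually
#'   restarts therapy.
#' @param return_delay_min_months,return_median_months Return times
#'   (months from the discontinuation date) are drawn as
#'   `min + Exponential` with the stated median; the minimum keeps every
#'   planted restart beyond the 6-month gap criterion.
#' @param p_prior_use Probability that a patient has a pre-accrual
#'   antidepressant dispensing inside the washout window (and so must be
#'   excluded by the cohort stage).
#' @param refill_interval_days Nominal days between refills (one pack).
#' @param refill_jitter_days Uniform integer jitter applied to each refill,
#'   at most +/- this many days; must stay well below the concurrency
#'   window for planted events to be unambiguous.
#' @param sex_probs,prescriber_probs,region_probs,age_range Demographics:
#'   named sampling probabilities and an inclusive integer age range at
#'   index.
#' @param max_treatments Cap on planted treatment numbers per patient.
#' @param gap_days,concurrency_window_days,pack_days,months_per_unit The
#'   episode-rule constants the generator plants against; they must match
#'   the [episode_config()] used downstream for ground truth to be
#'   recoverable.
#' @param formulary Formulary the generator draws molecules from.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_patients,
                       study_start = as.Date("2013-07-01"),
                       study_end = as.Date("2019-06-30"),
                       accrual_end = study_end,
                       data_start = shift_months(study_start, -12L),
                       seed = 1L,
                       class_init_probs = c(SSRI = 0.52, TCA = 0.25,
                                            SNRI = 0.13, NaSSA = 0.04,
                                            MAOI = 0.005, RIMA = 0.005,
                                            NRI = 0.01, TeCA = 0.01,
                                            melatonin_agonist = 0.01,
                                            serotonin_modulator = 0.02),
                       disc_hazard_per_month = log(2) /
                         c(SSRI = 5.8, SNRI = 5.0, TCA = 0.9, NaSSA = 3.5,
                           MAOI = 3.0, RIMA = 3.0, NRI = 2.5, TeCA = 2.5,
                           NDRI = 4.0, melatonin_agonist = 4.0,
                           serotonin_modulator = 4.5),
                       p_switch = 0.06,
                       p_combination = 0.01,
                       p_augmentation = 0.03,
                       p_dose_increase = 0.19,
                       p_return = 0.36,
                       return_delay_min_months = 5.2,
                       return_median_months = 12.8,
                       p_prior_use = 0,
                       refill_interval_days = 30L,
                       refill_jitter_days = 5L,
                       sex_probs = c(F = 0.56, M = 0.44),
                       prescriber_probs = c(GP = 0.746, psychiatrist = 0.029,
                                            intern = 0.097, other = 0.128),
                       region_probs = c(NSW = 0.32, VIC = 0.26, QLD = 0.20,
                                        WA = 0.10, SA = 0.07, TAS = 0.02,
                                        ACT = 0.02, NT = 0.01),
                       age_range = c(16L, 85L),
                       max_treatments = 6L,
                       gap_days = 183L,
                       concurrency_window_days = 30L,
                       pack_days = 30L,
                       months_per_unit = 30.44,
                       formulary = default_formulary()) {
  stopifnot(length(n_patients) == 1L, n_patients >= 1L)
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  accrual_end <- as.Date(accrual_end); data_start <- as.Date(data_start)
  if (!(study_start < study_end)) stop("study_start must precede study_end")
  if (accrual_end > study_end || accrual_end < study_start) {
    stop("accrual_end must lie within [study_start, study_end]")
  }
  for (p in c(p_switch, p_combination, p_augmentation, p_dose_increase,
              p_return, p_prior_use)) .assert_prob(p, "event probability")
  .assert_prob(class_init_probs, "class_init_probs")
  if (abs(sum(class_init_probs) - 1) > 1e-9) {
    stop("class_init_probs must sum to 1")
  }
  bad <- setdiff(names(class_init_probs), AD_CLASSES)
  if (length(bad)) stop("class_init_probs has unknown classes: ",
                        paste(bad, collapse = ", "))
  stopifnot(inherits(formulary, "formulary"))
  active <- names(class_init_probs)[class_init_probs > 0]
  have <- unique(formulary$drug_class)
  if (length(setdiff(active, have))) {
    stop("formulary has no molecules for class(es): ",
         paste(setdiff(active, have), collapse = ", "))
  }
  if (any(disc_hazard_per_month < 0)) stop("hazards must be non-negative")
  miss_h <- setdiff(active, names(disc_hazard_per_month))
  if (length(miss_h)) stop("disc_hazard_per_month missing class(es): ",
                           paste(miss_h, collapse = ", "))
  if (return_median_months <= return_delay_min_months) {
    stop("return_median_months must exceed return_delay_min_months")
  }
  min_gap <- pack_days + floor(return_delay_min_months * months_per_unit)
  if (min_gap <= gap_days) {
    stop("return_delay_min_months too small: planted restarts would not ",
         "clear the discontinuation gap")
  }
  stopifnot(refill_interval_days >= 1L, refill_jitter_days >= 0L,
            refill_jitter_days < refill_interval_days,
            gap_days > concurrency_window_days,
            concurrency_window_days > 0L,
            age_range[1L] <= age_range[2L], max_treatments >= 1L)
  cfg <- list(n_patients = as.integer(n_patients),
              study_start = study_start, study_end = study_end,
              accrual_end = accrual_end, data_start = data_start,
              seed = as.integer(seed),
              class_init_probs = class_init_probs,
              disc_hazard_per_month = disc_hazard_per_month,
              p_switch = p_switch, p_combination = p_combination,
              p_augmentation = p_augmentation,
              p_dose_increase = p_dose_increase,
              p_return = p_return,
              return_delay_min_months = return_delay_min_months,
              return_median_months = return_median_months,
              p_prior_use = p_prior_use,
              refill_interval_days = as.integer(refill_interval_days),
              refill_jitter_days = as.integer(refill_jitter_days),
              sex_probs = sex_probs, prescriber_probs = prescriber_probs,
              region_probs = region_probs,
              age_range = as.integer(age_range),
              max_treatments = as.integer(max_treatments),
              gap_days = as.integer(gap_days),
              concurrency_window_days = as.integer(concurrency_window_days),
              pack_days = as.integer(pack_days),
              months_per_unit = months_per_unit,
              formulary = formulary)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_patients, " patients, accrual ",
      format(x$study_start), " .. ", format(x$accrual_end),
      ", data end ", format(x$study_end), ", seed ", x$seed, "\n", sep = "")
  cat("  class shares:",
      paste(sprintf("%s %.3f", names(x$class_init_probs),
                    x$class_init_probs), collapse = ", "), "\n")
  cat(sprintf("  p_switch %.3f  p_combination %.3f  p_augmentation %.3f  p_dose %.3f  p_return %.3f\n",
              x$p_switch, x$p_combination, x$p_augmentation,
              x$p_dose_increase, x$p_return))
  invisible(x)
}

#' Simulate dispensing records with ground truth
#'
#' Generates one dispensing trajectory per patient under `config` and
#' returns both the records (the observable data) and the ground truth the
#' generator planted (the oracle). Each episode's refills follow the
#' nominal pack cadence with small jitter; planted discontinuation gaps
#' clear the 6-month criterion by a safe margin, planted combinations
#' force a continuing dispensing of the old class inside the concurrency
#' window, and planted augmentations co-dispense the antipsychotic with an
#' antidepressant refill, so episode recovery is exact by construction.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `disp_sim` with elements:
#'   * `records`: data frame of dispensing events, one row per dispensing,
#'     sorted by patient, date and molecule: `patient_id`,
#'     `year_of_birth`, `sex`, `region`, `dispense_date`, `molecule`,
#'     `strength_mg`, `prescriber_type`.
#'   * `truth`: list with `patients` (inclusion flag, exclusion reason,
#'     drawn first-episode discontinuation time, planted dose step and
#'     first return date), `episodes` (the true treatment lines) and
#'     `treatment_free` (true discontinuation/restart pairs).
#'   * `config`: the configuration used.
#' @export
simulate_dispensing <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  fm <- cfg$formulary
  classes <- names(cfg$class_init_probs)
  class_p <- as.numeric(cfg$class_init_probs)
  pool <- lapply(classes, function(cl) fm$molecule[fm$drug_class == cl])
  names(pool) <- classes
  ap_pool <- fm$molecule[fm$drug_group == "antipsychotic"]
  str_tab <- fm$strengths_mg
  names(str_tab) <- fm$molecule_key
  low_str <- vapply(str_tab, `[`, numeric(1L), 1L)
  n_str <- lengths(str_tab)

  day0 <- as.integer(cfg$study_start)
  acc_days <- as.integer(cfg$accrual_end) - day0
  data_end <- as.integer(cfg$study_end)
  acc_start <- day0
  interval <- cfg$refill_interval_days
  jd <- cfg$refill_jitter_days
  gap <- cfg$gap_days
  pack <- cfg$pack_days
  mpu <- cfg$months_per_unit
  r0 <- cfg$return_delay_min_months
  ret_rate <- log(2) / (cfg$return_median_months - r0)

  .with_seed(cfg$seed, {
    n <- cfg$n_patients
    rec <- vector("list", n)
    eps <- vector("list", n)
    tf <- vector("list", n)
    pat <- vector("list", n)

    jit <- function() if (jd > 0L) sample.int(2L * jd + 1L, 1L) - jd - 1L else 0L
    draw_class <- function() classes[sample.int(length(classes), 1L,
                                                prob = class_p)]
    draw_class_excl <- function(excl) {
      keep <- !(classes %in% excl)
      p <- class_p[keep]
      if (sum(p) <= 0) p <- rep(1, sum(keep))
      classes[keep][sample.int(sum(keep), 1L, prob = p)]
    }
    draw_mol <- function(cl) {
      v <- pool[[cl]]
      v[sample.int(length(v), 1L)]
    }
    draw_presc <- function() {
      nm <- names(cfg$prescriber_probs)
      nm[sample.int(length(nm), 1L, prob = cfg$prescriber_probs)]
    }

    for (i in seq_len(n)) {
      pid <- sprintf("P%06d", i)
      sex <- names(cfg$sex_probs)[sample.int(length(cfg$sex_probs), 1L,
                                             prob = cfg$sex_probs)]
      region <- names(cfg$region_probs)[sample.int(length(cfg$region_probs),
                                                   1L,
                                                   prob = cfg$region_probs)]
      age <- cfg$age_range[1L] +
        sample.int(cfg$age_range[2L] - cfg$age_range[1L] + 1L, 1L) - 1L
      prior <- cfg$p_prior_use > 0 && stats::runif(1L) < cfg$p_prior_use
      if (prior) {
        ## Index early in accrual, violator dispensing just before accrual:
        ## inside the rolling 12-month washout AND inside the fixed clean
        ## window, so the patient is excluded under either washout reading.
        index_day <- acc_start + sample.int(min(301L, acc_days + 1L), 1L) - 1L
        prior_day <- acc_start - 4L - sample.int(56L, 1L)
      } else {
        index_day <- day0 + if (acc_days > 0L) sample.int(acc_days + 1L, 1L) - 1L else 0L
        prior_day <- NA_integer_
      }
      yob <- .year_of(as.Date(index_day, origin = "1970-01-01")) - age

      ## --- per-patient accumulators -------------------------------------
      rd <- integer(0); rmol <- character(0); rstr <- numeric(0)
      rpre <- character(0)
      emit <- function(day, m, s, p) {
        rd[[length(rd) + 1L]] <<- day
        rmol[[length(rmol) + 1L]] <<- m
        rstr[[length(rstr) + 1L]] <<- s
        rpre[[length(rpre) + 1L]] <<- p
      }
      en <- integer(0); es <- integer(0); ee <- integer(0)
      ecl <- character(0); ers <- character(0)
      close_ep <- function(no, s, e, cls, reason) {
        k <- length(en) + 1L
        en[[k]] <<- no; es[[k]] <<- s; ee[[k]] <<- e
        ecl[[k]] <<- paste(sort(cls), collapse = ";")
        ers[[k]] <<- reason
      }
      tfd <- integer(0); tfr <- integer(0)
      true_t1 <- NA_real_
      dose_day <- NA_integer_; dose_mol <- NA_character_
      dose_from <- NA_real_; dose_to <- NA_real_
      str_now <- list()
      str_of <- function(m) {
        k <- tolower(m)
        if (is.null(str_now[[k]])) low_str[[k]] else str_now[[k]]
      }

      if (!is.na(prior_day)) {
        pcl <- draw_class(); pm <- draw_mol(pcl)
        emit(prior_day, pm, str_of(pm), draw_presc())
      }

      treat <- 1L
      cl1 <- draw_class(); m1 <- draw_mol(cl1)
      cls <- cl1
      mols <- stats::setNames(m1, cl1)
      presc <- draw_presc()
      plant_dose <- cfg$p_dose_increase > 0 &&
        stats::runif(1L) < cfg$p_dose_increase
      dose_target <- if (plant_dose) {
        index_day + as.integer(round(stats::runif(1L, 1, 6) * mpu))
      } else NA_integer_
      emit(index_day, m1, str_of(m1), presc)
      cur_start <- index_day
      last_ad <- index_day
      nxt <- stats::setNames(index_day + interval + jit(), m1)

      maybe_dose <- function(m, t) {
        ## First-episode single strength step-up, planted once per patient.
        if (treat == 1L && plant_dose && is.na(dose_day) &&
            !is.na(dose_target) && t >= dose_target) {
          key <- tolower(m)
          if (n_str[[key]] >= 2L) {
            dose_day <<- t
            dose_mol <<- m
            dose_from <<- str_of(m)
            dose_to <<- str_tab[[key]][2L]
            str_now[[key]] <<- dose_to
          } else {
            plant_dose <<- FALSE  # single-strength molecule: nothing to step
          }
        }
      }

      repeat {
        anchor <- cls[1L]
        multi <- length(cls) > 1L
        haz <- cfg$disc_hazard_per_month[[anchor]]
        td <- if (haz > 0) stats::rexp(1L, haz) else Inf
        if (treat == 1L) true_t1 <- td
        can <- !multi && treat < cfg$max_treatments
        tsw <- if (can && cfg$p_switch > 0 &&
                   stats::runif(1L) < cfg$p_switch) {
          stats::runif(1L, 1, 12)
        } else Inf
        tcb <- if (can && cfg$p_combination > 0 &&
                   stats::runif(1L) < cfg$p_combination) {
          stats::runif(1L, 1, 12)
        } else Inf
        tag <- if (can && cfg$p_augmentation > 0 &&
                   stats::runif(1L) < cfg$p_augmentation) {
          stats::runif(1L, 1, 12)
        } else Inf
        tt <- c(td, tsw, tcb, tag)
        k <- which.min(tt)
        type <- c("disc", "switch", "combination", "augmentation")[k]
        if (!is.finite(tt[k])) type <- "censor"
        target <- if (is.finite(tt[k])) {
          cur_start + as.integer(round(tt[k] * mpu))
        } else data_end + 1L
        if (type == "disc" && target > data_end) type <- "censor"

        if (type %in% c("switch", "combination", "augmentation")) {
          mcur <- mols[[1L]]
          event_day <- NA_integer_
          t <- nxt[[mcur]]
          while (t <= data_end) {
            if (t >= target) { event_day <- t; break }
            maybe_dose(mcur, t)
            emit(t, mcur, str_of(mcur), presc)
            last_ad <- t
            t <- t + interval + jit()
          }
          feasible <- !is.na(event_day) &&
            !(type == "combination" && event_day + 14L > data_end)
          if (!feasible) {
            while (t <= data_end) {
              maybe_dose(mcur, t)
              emit(t, mcur, str_of(mcur), presc)
              last_ad <- t
              t <- t + interval + jit()
            }
            close_ep(treat, cur_start, data_end, cls, "censored")
            break
          }
          if (type == "switch") {
            close_ep(treat, cur_start, event_day, cls, "switch")
            ncl <- draw_class_excl(cls)
            nm <- draw_mol(ncl)
            treat <- treat + 1L
            cur_start <- event_day
            cls <- ncl
            mols <- stats::setNames(nm, ncl)
            presc <- draw_presc()
            emit(event_day, nm, str_of(nm), presc)
            last_ad <- event_day
            nxt <- stats::setNames(event_day + interval + jit(), nm)
          } else if (type == "combination") {
            close_ep(treat, cur_start, event_day, cls, "combination_added")
            ncl <- draw_class_excl(cls)
            nm <- draw_mol(ncl)
            treat <- treat + 1L
            cur_start <- event_day
            presc <- draw_presc()
            emit(event_day, nm, str_of(nm), presc)
            ## old class keeps going inside the concurrency window, so the
            ## transition reads as an added class, not a switch
            emit(event_day + 14L, mcur, str_of(mcur), presc)
            last_ad <- event_day + 14L
            nxt <- c(stats::setNames(event_day + interval + jit(), nm),
                     stats::setNames(event_day + 14L + interval + jit(), mcur))
            cls <- c(cls, ncl)
            mols <- c(mols, stats::setNames(nm, ncl))
          } else { # augmentation
            apm <- ap_pool[sample.int(length(ap_pool), 1L)]
            close_ep(treat, cur_start, event_day, cls, "augmentation_added")
            treat <- treat + 1L
            cur_start <- event_day
            presc <- draw_presc()
            ## antipsychotic co-dispensed with an antidepressant refill
            emit(event_day, mcur, str_of(mcur), presc)
            last_ad <- event_day
            emit(event_day, apm, str_of(apm), presc)
            nxt <- c(stats::setNames(event_day + interval + jit(), mcur),
                     stats::setNames(event_day + interval + jit(), apm))
            cls <- c(cls, "antipsychotic")
            mols <- c(mols, stats::setNames(apm, "antipsychotic"))
          }
          next
        }

        ## disc or censor: refill every molecule up to the stop day
        stop_before <- if (type == "disc") target else data_end + 1L
        for (mi in seq_along(nxt)) {
          m <- names(nxt)[mi]
          is_ad <- names(mols)[match(m, mols)] != "antipsychotic"
          t <- nxt[[mi]]
          while (t < stop_before && t <= data_end) {
            if (is_ad) maybe_dose(m, t)
            emit(t, m, str_of(m), presc)
            if (is_ad) last_ad <- max(last_ad, t)
            t <- t + interval + jit()
          }
        }
        if (type == "censor") {
          close_ep(treat, cur_start, data_end, cls, "censored")
          break
        }
        ## discontinuation: decide whether the patient ever returns
        disc_end_day <- last_ad + pack
        restart_day <- NA_integer_
        if (treat < cfg$max_treatments && cfg$p_return > 0 &&
            stats::runif(1L) < cfg$p_return) {
          rm_ <- r0 + stats::rexp(1L, ret_rate)
          cand <- disc_end_day + as.integer(round(rm_ * mpu))
          if (cand <= data_end) restart_day <- cand
        }
        if (!is.na(restart_day)) {
          close_ep(treat, cur_start, disc_end_day, cls, "discontinuation")
          tfd[[length(tfd) + 1L]] <- disc_end_day
          tfr[[length(tfr) + 1L]] <- restart_day
          treat <- treat + 1L
          rcl <- draw_class()       # restart may be any class, incl. the same
          rmolc <- draw_mol(rcl)
          cls <- rcl
          mols <- stats::setNames(rmolc, rcl)
          presc <- draw_presc()
          cur_start <- restart_day
          emit(restart_day, rmolc, str_of(rmolc), presc)
          last_ad <- restart_day
          nxt <- stats::setNames(restart_day + interval + jit(), rmolc)
          next
        }
        if (data_end - last_ad > gap) {
          close_ep(treat, cur_start, disc_end_day, cls, "discontinuation")
          tfd[[length(tfd) + 1L]] <- disc_end_day
          tfr[[length(tfr) + 1L]] <- NA_integer_
        } else {
          close_ep(treat, cur_start, data_end, cls, "censored")
        }
        break
      }

      ord <- order(rd, rmol)
      rec[[i]] <- list(n = length(rd), pid = pid, yob = yob, sex = sex,
                       region = region, day = rd[ord], mol = rmol[ord],
                       str = rstr[ord], presc = rpre[ord])
      pat[[i]] <- list(pid = pid, included = is.na(prior_day),
                       reason = if (is.na(prior_day)) NA_character_
                                else "washout_antidepressant",
                       yob = yob, sex = sex, region = region,
                       index_day = index_day, true_t1 = true_t1,
                       dose_day = dose_day, dose_mol = dose_mol,
                       dose_from = dose_from, dose_to = dose_to,
                       return_day = if (length(tfr) && !is.na(tfr[1L]))
                         tfr[1L] else NA_integer_)
      if (is.na(prior_day)) {
        eps[[i]] <- list(pid = pid, no = en, s = es, e = ee, cl = ecl,
                         rs = ers)
        tf[[i]] <- list(pid = pid, d = tfd, r = tfr)
      }
    }

    nrec <- vapply(rec, `[[`, integer(1L), "n")
    records <- data.frame(
      patient_id = rep(vapply(rec, `[[`, character(1L), "pid"), nrec),
      year_of_birth = rep(vapply(rec, `[[`, integer(1L), "yob"), nrec),
      sex = rep(vapply(rec, `[[`, character(1L), "sex"), nrec),
      region = rep(vapply(rec, `[[`, character(1L), "region"), nrec),
      dispense_date = as.Date(unlist(lapply(rec, `[[`, "day")),
                              origin = "1970-01-01"),
      molecule = unlist(lapply(rec, `[[`, "mol")),
      strength_mg = unlist(lapply(rec, `[[`, "str")),
      prescriber_type = unlist(lapply(rec, `[[`, "presc")),
      stringsAsFactors = FALSE)

    eps <- eps[!vapply(eps, is.null, logical(1L))]
    nep <- vapply(eps, function(x) length(x$no), integer(1L))
    truth_eps <- data.frame(
      patient_id = rep(vapply(eps, `[[`, character(1L), "pid"), nep),
      treatment_number = unlist(lapply(eps, `[[`, "no")),
      start_date = as.Date(unlist(lapply(eps, `[[`, "s")),
                           origin = "1970-01-01"),
      end_date = as.Date(unlist(lapply(eps, `[[`, "e")),
                         origin = "1970-01-01"),
      classes = unlist(lapply(eps, `[[`, "cl")),
      end_reason = unlist(lapply(eps, `[[`, "rs")),
      stringsAsFactors = FALSE)

    tf <- tf[!vapply(tf, is.null, logical(1L))]
    ntf <- vapply(tf, function(x) length(x$d), integer(1L))
    truth_tf <- data.frame(
      patient_id = rep(vapply(tf, `[[`, character(1L), "pid"), ntf),
      disc_date = as.Date(unlist(lapply(tf, `[[`, "d")),
                          origin = "1970-01-01"),
      restart_date = as.Date(unlist(lapply(tf, `[[`, "r")),
                             origin = "1970-01-01"),
      stringsAsFactors = FALSE)

    truth_pat <- data.frame(
      patient_id = vapply(pat, `[[`, character(1L), "pid"),
      included = vapply(pat, `[[`, logical(1L), "included"),
      exclusion_reason = vapply(pat, `[[`, character(1L), "reason"),
      year_of_birth = vapply(pat, `[[`, integer(1L), "yob"),
      sex = vapply(pat, `[[`, character(1L), "sex"),
      region = vapply(pat, `[[`, character(1L), "region"),
      index_date = as.Date(vapply(pat, `[[`, integer(1L), "index_day"),
                           origin = "1970-01-01"),
      true_t1_disc_months = vapply(pat, `[[`, numeric(1L), "true_t1"),
      dose_date = as.Date(vapply(pat, `[[`, integer(1L), "dose_day"),
                          origin = "1970-01-01"),
      dose_molecule = vapply(pat, `[[`, character(1L), "dose_mol"),
      dose_from_mg = vapply(pat, `[[`, numeric(1L), "dose_from"),
      dose_to_mg = vapply(pat, `[[`, numeric(1L), "dose_to"),
      first_return_date = as.Date(vapply(pat, `[[`, integer(1L),
                                         "return_day"),
                                  origin = "1970-01-01"),
      stringsAsFactors = FALSE)

    out <- list(records = records,
                truth = list(patients = truth_pat, episodes = truth_eps,
                             treatment_free = truth_tf),
                config = cfg)
    class(out) <- "disp_sim"
    out
  })
}

#' @export
print.disp_sim <- function(x, ...) {
  cat("<disp_sim> ", nrow(x$records), " dispensings for ",
      x$config$n_patients, " patients (",
      sum(x$truth$patients$included), " cohort-eligible), seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write dispensing records to CSV
#'
#' Dates are written ISO-8601; the file round-trips bit-exactly through
#' [read_dispensing()] (write, read, write is a fixed point).
#'
#' @param records Data frame of dispensing records (as produced by
#'   [simulate_dispensing()] or [read_dispensing()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dispensing <- function(records, path) {
  out <- records
  out$dispense_date <- format(as.Date(out$dispense_date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read dispensing records from CSV
#'
#' @param path Path to a dispensing CSV with columns `patient_id`,
#'   `year_of_birth`, `sex`, `region`, `dispense_date` (ISO-8601),
#'   `molecule`, `strength_mg`, `prescriber_type`.
#' @return Data frame of dispensing records with `dispense_date` as `Date`.
#' @export
read_dispensing <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       year_of_birth = "integer",
                                       sex = "character",
                                       region = "character",
                                       dispense_date = "character",
                                       molecule = "character",
                                       strength_mg = "numeric",
                                       prescriber_type = "character"))
  need <- c("patient_id", "year_of_birth", "sex", "region", "dispense_date",
            "molecule", "strength_mg", "prescriber_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dispensing CSV is missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.na(df$strength_mg) & df$strength_mg <= 0)) {
    stop("strength_mg must be positive", call. = FALSE)
  }
  df$dispense_date <- as.Date(df$dispense_date)
  df[need]
}
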