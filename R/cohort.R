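## Cohort selection: index antidepressant dispensing inside the accrual
## window, washout clean period, antipsychotic pre-exclusion, age filter.
## Mood-stabiliser dispensings never trigger exclusion: they are excluded
## from the antidepressant definition, not from patients.

#' Cohort-selection configuration
#'
#' @param accrual_start,accrual_end Accrual window for the index
#'   dispensing (first antidepressant dispensing in this window).
#' @param washout_months Look-back that must be free of antidepressant or
#'   antipsychotic dispensing (default 12).
#' @param min_age_years Minimum age at index, inclusive (default 16).
#' @param data_start Start of the loadable data window; must extend at
#'   least `washout_months` before `accrual_start`.
#' @param washout_mode `"rolling"` measures the washout in calendar months
#'   back from each patient's index date; `"fixed_window"` instead uses the
#'   fixed clean period `[data_start, accrual_start)` shared by all
#'   patients. Both readings are supported because drug-utilisation studies
#'   phrase the clean period either way; the rolling form is the default.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(accrual_start = as.Date("2013-07-01"),
                          accrual_end = as.Date("2019-06-30"),
                          washout_months = 12L,
                          min_age_years = 16L,
                          data_start = shift_months(as.Date(accrual_start),
                                                    -washout_months),
                          washout_mode = c("rolling", "fixed_window")) {
  accrual_start <- as.Date(accrual_start)
  accrual_end <- as.Date(accrual_end)
  data_start <- as.Date(data_start)
  washout_mode <- match.arg(washout_mode)
  stopifnot(accrual_start <= accrual_end, washout_months >= 0L,
            min_age_years >= 0L)
  if (data_start > shift_months(accrual_start, -washout_months)) {
    stop("data_start must extend at least washout_months before ",
         "accrual_start", call. = FALSE)
  }
  structure(list(accrual_start = accrual_start, accrual_end = accrual_end,
                 washout_months = as.integer(washout_months),
                 min_age_years = as.integer(min_age_years),
                 data_start = data_start, washout_mode = washout_mode),
            class = "cohort_config")
}

#' Find each patient's index dispensing
#'
#' The index is the earliest antidepressant dispensing inside the accrual
#' window. Patients with no antidepressant dispensing in the window are
#' omitted from the result. Input does not need to be sorted.
#'
#' @param records Dispensing records data frame.
#' @param formulary A `formulary` object.
#' @param config A [cohort_config()] object.
#' @return Data frame with one row per indexed patient: `patient_id`,
#'   `index_date`, `index_molecule`, `index_class`.
#' @export
find_index <- function(records, formulary, config = cohort_config()) {
  cl <- classify(records$molecule, formulary)
  ad <- cl$drug_group == "antidepressant" &
    records$dispense_date >= config$accrual_start &
    records$dispense_date <= config$accrual_end
  r <- records[ad, , drop = FALSE]
  if (!nrow(r)) {
    return(data.frame(patient_id = character(0),
                      index_date = as.Date(character(0)),
                      index_molecule = character(0),
                      index_class = character(0),
                      stringsAsFactors = FALSE))
  }
  rc <- cl[ad, , drop = FALSE]
  o <- order(r$patient_id, r$dispense_date, r$molecule)
  first <- !duplicated(r$patient_id[o])
  i <- o[first]
  data.frame(patient_id = r$patient_id[i], index_date = r$dispense_date[i],
             index_molecule = r$molecule[i], index_class = rc$drug_class[i],
             stringsAsFactors = FALSE)
}

#' Apply washout and antipsychotic pre-exclusion
#'
#' A patient is excluded if any antidepressant or antipsychotic dispensing
#' falls in the washout period before index (rolling or fixed-window per
#' the configuration), or if an antipsychotic was dispensed prior to or on
#' the same day as the index antidepressant dispensing, regardless of how
#' long before. Mood stabilisers never trigger exclusion.
#'
#' @param records Dispensing records data frame.
#' @param index Index table from [find_index()].
#' @param formulary A `formulary` object.
#' @param config A [cohort_config()] object.
#' @return Data frame with `patient_id`, `included` (logical) and `reason`
#'   (`NA` when included; otherwise `same_day_antipsychotic`,
#'   `prior_antipsychotic` or `washout_antidepressant`).
#' @export
apply_washout <- function(records, index, formulary,
                          config = cohort_config()) {
  cl <- classify(records$molecule, formulary)
  ix <- match(records$patient_id, index$patient_id)
  keep <- !is.na(ix)
  r_date <- records$dispense_date[keep]
  r_grp <- cl$drug_group[keep]
  idx_date <- index$index_date[ix[keep]]
  pid <- records$patient_id[keep]

  if (config$washout_mode == "rolling") {
    w_start <- shift_months(idx_date, -config$washout_months)
    in_washout <- r_date > w_start & r_date < idx_date
  } else {
    in_washout <- r_date >= config$data_start & r_date < config$accrual_start
  }
  ad_washout <- in_washout & r_grp == "antidepressant"
  ap_same <- r_grp == "antipsychotic" & r_date == idx_date
  ap_prior <- r_grp == "antipsychotic" & r_date < idx_date

  flag <- function(mask) index$patient_id %in% unique(pid[mask])
  same_day <- flag(ap_same)
  prior_ap <- flag(ap_prior)
  washed <- flag(ad_washout)

  reason <- rep(NA_character_, nrow(index))
  reason[washed] <- "washout_antidepressant"
  reason[prior_ap] <- "prior_antipsychotic"
  reason[same_day] <- "same_day_antipsychotic"
  data.frame(patient_id = index$patient_id, included = is.na(reason),
             reason = reason, stringsAsFactors = FALSE)
}

#' Select the analysis cohort
#'
#' Composes [find_index()], [apply_washout()] and the age filter
#' ([age_at()]; age is dispensing year minus year of birth, and patients
#' younger than `min_age_years` at index, or with a missing year of birth,
#' are excluded).
#'
#' @param records Dispensing records data frame.
#' @param formulary A `formulary` object.
#' @param config A [cohort_config()] object.
#' @return An `ad_cohort` object: list with `cohort` (one row per included
#'   patient: id, index date/molecule/class, demographics, age at index),
#'   `exclusions` (id + reason for every indexed-but-excluded patient) and
#'   the `config`.
#' @export
build_cohort <- function(records, formulary, config = cohort_config()) {
  idx <- find_index(records, formulary, config)
  if (!nrow(idx)) {
    cohort <- data.frame(patient_id = character(0),
                         index_date = as.Date(character(0)),
                         index_molecule = character(0),
                         index_class = character(0),
                         year_of_birth = integer(0), sex = character(0),
                         region = character(0), age_at_index = integer(0),
                         stringsAsFactors = FALSE)
    return(structure(list(cohort = cohort,
                          exclusions = data.frame(patient_id = character(0),
                                                  reason = character(0),
                                                  stringsAsFactors = FALSE),
                          config = config),
                     class = "ad_cohort"))
  }
  wash <- apply_washout(records, idx, formulary, config)

  first_row <- records[match(idx$patient_id, records$patient_id), ,
                       drop = FALSE]
  yob <- first_row$year_of_birth
  age <- age_at(yob, idx$index_date)
  reason <- wash$reason
  no_yob <- is.na(reason) & is.na(yob)
  reason[no_yob] <- "missing_year_of_birth"
  under <- is.na(reason) & age < config$min_age_years
  reason[under] <- "under_age"

  inc <- is.na(reason)
  cohort <- data.frame(patient_id = idx$patient_id[inc],
                       index_date = idx$index_date[inc],
                       index_molecule = idx$index_molecule[inc],
                       index_class = idx$index_class[inc],
                       year_of_birth = yob[inc],
                       sex = first_row$sex[inc],
                       region = first_row$region[inc],
                       age_at_index = age[inc],
                       stringsAsFactors = FALSE)
  exclusions <- data.frame(patient_id = idx$patient_id[!inc],
                           reason = reason[!inc], stringsAsFactors = FALSE)
  structure(list(cohort = cohort, exclusions = exclusions, config = config),
            class = "ad_cohort")
}

#' @export
print.ad_cohort <- function(x, ...) {
  cat("<ad_cohort> ", nrow(x$cohort), " included, ", nrow(x$exclusions),
      " excluded (accrual ", format(x$config$accrual_start), " .. ",
      format(x$config$accrual_end), ", washout ", x$config$washout_months,
      " months ", x$config$washout_mode, ", min age ",
      x$config$min_age_years, ")\n", sep = "")
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$reason)
    cat("  exclusions:",
        paste(sprintf("%s %d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.ad_cohort <- function(object, ...) {
  co <- object$cohort
  list(n_included = nrow(co), n_excluded = nrow(object$exclusions),
       exclusion_reasons = table(object$exclusions$reason),
       sex = table(co$sex),
       age = if (nrow(co)) summary(co$age_at_index) else NULL,
       index_class = table(co$index_class))
}
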