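## Treatment-free episodes: the interval after a confirmed discontinuation
## with no antidepressant dispensing, ending at restart or censored at the
## end of the data window.

#' Extract treatment-free episodes
#'
#' One treatment-free episode per discontinuation in the episode table.
#' The clock starts at the episode's discontinuation date (by default the
#' last dispensing plus one pack, per the episode configuration) and stops
#' at the next treatment episode's start (restart) or at the end of the
#' data window (censored). Patients who never discontinue contribute no
#' treatment-free episodes; all of a patient's discontinuations are
#' retained, with the patient id kept for optional first-episode-only
#' filtering.
#'
#' @param episodes An `ad_episodes` object from [build_episodes()].
#' @return Data frame `patient_id`, `disc_date`, `restart_date` (`NA` when
#'   censored), `duration_months`, `returned`.
#' @export
treatment_free_episodes <- function(episodes) {
  stopifnot(inherits(episodes, "ad_episodes"))
  ep <- episodes$episodes
  cfg <- episodes$config
  o <- order(ep$patient_id, ep$treatment_number)
  ep <- ep[o, , drop = FALSE]
  n <- nrow(ep)
  disc <- which(ep$end_reason == "discontinuation")
  if (!length(disc)) {
    return(data.frame(patient_id = character(0),
                      disc_date = as.Date(character(0)),
                      restart_date = as.Date(character(0)),
                      duration_months = numeric(0), returned = logical(0),
                      stringsAsFactors = FALSE))
  }
  nxt <- disc + 1L
  has_next <- nxt <= n & ep$patient_id[pmin(nxt, n)] == ep$patient_id[disc]
  restart <- as.Date(rep(NA_integer_, length(disc)), origin = "1970-01-01")
  restart[has_next] <- ep$start_date[nxt[has_next]]
  end <- restart
  end[!has_next] <- cfg$data_end
  dur <- as.numeric(end - ep$end_date[disc]) / cfg$months_per_unit
  data.frame(patient_id = ep$patient_id[disc],
             disc_date = ep$end_date[disc], restart_date = restart,
             duration_months = dur, returned = has_next,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier analysis of time to return to treatment
#'
#' Fits the product-limit estimator on time from discontinuation to
#' restart (event = restart, censored at data end) and reports the
#' cumulative return proportion at a horizon together with two medians:
#' the unconditional KM median and the headline conditional median, the
#' empirical median time to return among episodes that actually returned.
#'
#' @param tf Treatment-free episode table from
#'   [treatment_free_episodes()].
#' @param horizon Months at which to report the cumulative return
#'   proportion (default 70).
#' @return A `return_km` object: list with `fit` (`km_curve`),
#'   `return_proportion` (at `horizon`, on 0-1 scale),
#'   `median_conditional` (months, `NA` when nobody returned),
#'   `median_unconditional`, `horizon`, `n`, `n_returned`.
#' @export
return_km <- function(tf, horizon = 70) {
  if (!nrow(tf)) stop("no treatment-free episodes", call. = FALSE)
  fit <- km_fit(tf$duration_months, tf$returned)
  prop <- 1 - km_surv_at(fit, horizon)
  med_c <- if (any(tf$returned)) {
    stats::median(tf$duration_months[tf$returned])
  } else NA_real_
  structure(list(fit = fit, return_proportion = prop,
                 median_conditional = med_c,
                 median_unconditional = km_median(fit),
                 horizon = horizon, n = nrow(tf),
                 n_returned = sum(tf$returned)),
            class = "return_km")
}

#' @export
print.return_km <- function(x, ...) {
  cat("<return_km> ", x$n, " treatment-free episodes, ", x$n_returned,
      " returned\n", sep = "")
  cat(sprintf("  cumulative return at %g months: %.1f%%\n", x$horizon,
              100 * x$return_proportion))
  cat(sprintf("  median time to return (among returners): %s months\n",
              if (is.na(x$median_conditional)) "undefined"
              else format(round(x$median_conditional, 1))))
  invisible(x)
}
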