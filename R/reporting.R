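## Prescribing-pattern summary tables: class shares by treatment line,
## prescriber-type patterns, age-group patterns, and censoring-aware event
## rates at fixed horizons. Percentages are kept at full precision
## internally; print methods round to one decimal.

.share_table <- function(df, denominators) {
  attr(df, "denominators") <- denominators
  class(df) <- c("share_table", "data.frame")
  df
}

#' @export
print.share_table <- function(x, ...) {
  y <- as.data.frame(x)
  if ("percentage" %in% names(y)) y$percentage <- round(y$percentage, 1)
  print(y, row.names = FALSE)
  den <- attr(x, "denominators")
  if (!is.null(den) && length(den)) {
    cat("denominators:",
        paste(sprintf("%s = %d", names(den), as.integer(den)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Class share of episode starts by treatment line
#'
#' For each treatment number, the share of patients whose episode at that
#' line starts with each antidepressant class (the class of the dispensing
#' that opened the line). The denominator for each line is the number of
#' patients reaching it, so percentages within a line sum to 100.
#'
#' @param episodes An `ad_episodes` object or its `episodes` data frame.
#' @return A `share_table` with `treatment_number`, `drug_class`, `count`,
#'   `percentage`.
#' @export
class_share_by_line <- function(episodes) {
  ep <- if (inherits(episodes, "ad_episodes")) episodes$episodes else episodes
  if (!nrow(ep)) {
    return(.share_table(data.frame(treatment_number = integer(0),
                                   drug_class = character(0),
                                   count = integer(0),
                                   percentage = numeric(0),
                                   stringsAsFactors = FALSE), integer(0)))
  }
  tab <- table(ep$treatment_number, ep$start_class)
  den <- rowSums(tab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("treatment_number", "drug_class", "count")
  out$treatment_number <- as.integer(out$treatment_number)
  out <- out[out$count > 0L, , drop = FALSE]
  out$percentage <- 100 * out$count /
    den[as.character(out$treatment_number)]
  out <- out[order(out$treatment_number, -out$count), , drop = FALSE]
  rownames(out) <- NULL
  .share_table(out, stats::setNames(as.integer(den), names(den)))
}

#' Class share of line initiations by prescriber type
#'
#' Cross-tabulates the class of each line-opening prescription by the
#' prescriber type of the dispensing that opened the line. Percentages are
#' within (treatment line, prescriber) cells, so each prescriber's class
#' mix at a line sums to 100.
#'
#' @param records Dispensing records data frame.
#' @param episodes An `ad_episodes` object.
#' @return A `share_table` with `treatment_number`, `prescriber_type`,
#'   `drug_class`, `count`, `percentage`.
#' @export
prescriber_share <- function(records, episodes) {
  ep <- if (inherits(episodes, "ad_episodes")) episodes$episodes else episodes
  if (!nrow(ep)) {
    return(.share_table(data.frame(treatment_number = integer(0),
                                   prescriber_type = character(0),
                                   drug_class = character(0),
                                   count = integer(0),
                                   percentage = numeric(0),
                                   stringsAsFactors = FALSE), integer(0)))
  }
  o <- order(records$patient_id, records$dispense_date, records$molecule)
  r <- records[o, , drop = FALSE]
  key_r <- paste(r$patient_id, r$dispense_date)
  key_e <- paste(ep$patient_id, ep$start_date)
  presc <- r$prescriber_type[match(key_e, key_r)]
  cell <- paste(ep$treatment_number, presc, sep = "\r")
  tab <- table(cell, ep$start_class)
  den <- rowSums(tab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("cell", "drug_class", "count")
  parts <- strsplit(out$cell, "\r", fixed = TRUE)
  out$treatment_number <- as.integer(vapply(parts, `[`, character(1L), 1L))
  out$prescriber_type <- vapply(parts, `[`, character(1L), 2L)
  out$percentage <- 100 * out$count / den[out$cell]
  out <- out[out$count > 0L,
             c("treatment_number", "prescriber_type", "drug_class",
               "count", "percentage"), drop = FALSE]
  out <- out[order(out$treatment_number, out$prescriber_type, -out$count), ,
             drop = FALSE]
  rownames(out) <- NULL
  den_names <- gsub("\r", "/", names(den), fixed = TRUE)
  .share_table(out, stats::setNames(as.integer(den), den_names))
}

#' Class share by age group
#'
#' Age is computed at each dispensing (dispensing year minus year of
#' birth), so a patient followed across a bin boundary contributes to more
#' than one age group; groups are deliberately non-exclusive. Within each
#' age group a patient is classified by the class of their first
#' antidepressant dispensing while in that group, so percentages within a
#' group sum to 100. Bins are 16-25, 26-45, 46-65 and >65, with inclusive
#' upper bounds (a patient dispensed at age 25 falls in 16-25).
#'
#' @param records Dispensing records data frame.
#' @param formulary A `formulary` object.
#' @param breaks Upper bounds of the first three bins (default
#'   `c(25, 45, 65)`).
#' @return A `share_table` with `age_group`, `drug_class`, `count`,
#'   `percentage`.
#' @export
age_group_share <- function(records, formulary, breaks = c(25, 45, 65)) {
  cl <- classify(records$molecule, formulary)
  keep <- cl$drug_group == "antidepressant" & !is.na(records$year_of_birth)
  r <- records[keep, , drop = FALSE]
  k <- cl$drug_class[keep]
  if (!nrow(r)) {
    return(.share_table(data.frame(age_group = character(0),
                                   drug_class = character(0),
                                   count = integer(0),
                                   percentage = numeric(0),
                                   stringsAsFactors = FALSE), integer(0)))
  }
  age <- age_at(r$year_of_birth, r$dispense_date)
  labs <- c(paste0("16-", breaks[1L]),
            paste0(breaks[1L] + 1L, "-", breaks[2L]),
            paste0(breaks[2L] + 1L, "-", breaks[3L]),
            paste0(">", breaks[3L]))
  grp <- cut(age, breaks = c(-Inf, breaks, Inf), labels = labs)
  o <- order(r$patient_id, r$dispense_date, r$molecule)
  pid <- r$patient_id[o]; grp <- grp[o]; k <- k[o]
  first <- !duplicated(paste(pid, grp))
  tab <- table(grp[first], k[first])
  den <- rowSums(tab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("age_group", "drug_class", "count")
  out <- out[out$count > 0L, , drop = FALSE]
  out$percentage <- 100 * out$count / den[out$age_group]
  out <- out[order(match(out$age_group, labs), -out$count), , drop = FALSE]
  rownames(out) <- NULL
  .share_table(out, stats::setNames(as.integer(den), names(den)))
}

#' Censoring-aware event rates at fixed horizons
#'
#' Cumulative incidence (1 - Kaplan-Meier survival, so censoring-aware
#' rather than a naive fraction) of each treatment-modification event by
#' fixed horizons from each patient's first treatment start: first class
#' switch, first added antidepressant class (combination), first added
#' antipsychotic (augmentation), first dose increase. Patients without the
#' event are censored at the end of the data window.
#'
#' @param episodes An `ad_episodes` object.
#' @param horizons Months (default `c(6, 12, 24)`).
#' @return A `share_table` with `event`, `horizon_months`, `percentage`,
#'   plus the underlying `km_curve`s in attribute `fits`.
#' @export
horizon_rates <- function(episodes, horizons = c(6, 12, 24)) {
  stopifnot(inherits(episodes, "ad_episodes"))
  ep <- episodes$episodes
  cfg <- episodes$config
  pids <- unique(ep$patient_id)
  t1 <- ep$start_date[ep$treatment_number == 1L]
  names(t1) <- ep$patient_id[ep$treatment_number == 1L]
  t1 <- t1[pids]

  first_event_time <- function(reason_dates, reason_pids) {
    o <- order(reason_pids, reason_dates)
    first <- !duplicated(reason_pids[o])
    stats::setNames(reason_dates[o][first], reason_pids[o][first])
  }
  mk_input <- function(ev_dates) {
    ev <- ev_dates[pids]
    has <- !is.na(ev)
    end <- as.Date(ifelse(has, ev, cfg$data_end), origin = "1970-01-01")
    dur <- as.numeric(end - t1) / cfg$months_per_unit
    list(dur = pmax(dur, 0), ev = has)
  }

  evs <- list(
    switch = with(ep[ep$end_reason == "switch", ],
                  first_event_time(end_date, patient_id)),
    combination = with(ep[ep$end_reason == "combination_added", ],
                       first_event_time(end_date, patient_id)),
    augmentation = with(ep[ep$end_reason == "augmentation_added", ],
                        first_event_time(end_date, patient_id)),
    dose_increase = with(episodes$dose_events,
                         first_event_time(date, patient_id)))

  rows <- list()
  fits <- list()
  for (nm in names(evs)) {
    dates <- rep(as.Date(NA), length(pids))
    names(dates) <- pids
    hit <- evs[[nm]][names(evs[[nm]]) %in% pids]
    dates[names(hit)] <- hit
    inp <- mk_input(dates)
    if (!length(inp$dur)) next
    fit <- km_fit(inp$dur, inp$ev)
    fits[[nm]] <- fit
    for (h in horizons) {
      rows[[length(rows) + 1L]] <-
        data.frame(event = nm, horizon_months = h,
                   percentage = 100 * (1 - km_surv_at(fit, h)),
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(event = character(0), horizon_months = numeric(0),
               percentage = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  res <- .share_table(out, stats::setNames(length(pids), "patients"))
  attr(res, "fits") <- fits
  res
}
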