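## Treatment-line construction. The sweep walks each cohort patient's
## classified dispensings in time order and increments the treatment
## number on: (a) any antidepressant start after a discontinuation gap
## (including a restart of the initial class), (b) a class switch, (c) an
## added concurrent antidepressant class, (d) an added concurrent
## antipsychotic. The change date is always the date the new prescription
## was dispensed.

#' Episode-construction configuration
#'
#' @param discontinuation_gap_days Dispensing-free interval taken to mean
#'   therapy stopped (default 183 days, i.e. 6 months).
#' @param concurrency_window_days Two prescriptions are considered
#'   concurrent when dispensed within this many days of each other
#'   (default 30, one nominal pack). Claims data carry no days-supplied
#'   field, so concurrency has to be operationalised from dispensing dates
#'   alone; this window is the single most consequential tuning constant.
#' @param pack_days Nominal days of supply in one pack (default 30).
#' @param disc_end Convention for the end date of a discontinued episode:
#'   `"last_plus_pack"` (default) ends it one pack after the last
#'   dispensing, `"last_dispensing"` ends it at the last dispensing date
#'   (retained for sensitivity analysis; it pushes short-persistence
#'   classes below one month).
#' @param months_per_unit Days per month for duration reporting (30.44).
#' @param data_end End of the data window used for trailing
#'   discontinuation checks and censoring.
#' @return An `episode_config` object.
#' @export
episode_config <- function(discontinuation_gap_days = 183L,
                           concurrency_window_days = 30L,
                           pack_days = 30L,
                           disc_end = c("last_plus_pack", "last_dispensing"),
                           months_per_unit = 30.44,
                           data_end = as.Date("2019-06-30")) {
  disc_end <- match.arg(disc_end)
  stopifnot(discontinuation_gap_days > concurrency_window_days,
            concurrency_window_days > 0L, pack_days > 0L,
            months_per_unit > 0)
  structure(list(discontinuation_gap_days = as.integer(discontinuation_gap_days),
                 concurrency_window_days = as.integer(concurrency_window_days),
                 pack_days = as.integer(pack_days), disc_end = disc_end,
                 months_per_unit = months_per_unit,
                 data_end = as.Date(data_end)),
            class = "episode_config")
}

#' Detect discontinuation gaps in one patient's antidepressant dispensings
#'
#' A boundary falls between each pair of consecutive antidepressant
#' dispensings more than the gap apart; a trailing discontinuation is
#' flagged when the last dispensing lies more than the gap before the end
#' of the data window.
#'
#' @param dates `Date` vector of one patient's antidepressant dispensing
#'   dates (sorted internally).
#' @param config An [episode_config()] object.
#' @return List with `boundaries` (data frame of `last_before`,
#'   `next_after`, `gap_days`) and `trailing` (logical).
#' @export
detect_discontinuation <- function(dates, config = episode_config()) {
  d <- sort(as.Date(dates))
  gaps <- as.integer(diff(d))
  hit <- which(gaps > config$discontinuation_gap_days)
  list(boundaries = data.frame(last_before = d[hit],
                               next_after = d[hit + 1L],
                               gap_days = gaps[hit]),
       trailing = length(d) > 0L &&
         as.integer(config$data_end - d[length(d)]) >
           config$discontinuation_gap_days)
}

#' Detect concurrent-prescription events
#'
#' Two dispensings are concurrent when their dates differ by at most the
#' concurrency window and the molecules differ. Emits, per patient, the
#' onset dates (the later dispensing of each first qualifying pair) of
#' between-class antidepressant combinations, antidepressant +
#' antipsychotic augmentations, and within-class molecule combinations
#' (which never increment the treatment number).
#'
#' @param records Dispensing records data frame (any number of patients).
#' @param formulary A `formulary` object.
#' @param config An [episode_config()] object.
#' @return Data frame `patient_id`, `date`, `type` (`combination`,
#'   `augmentation`, `within_class`), `molecules`.
#' @export
detect_concurrency <- function(records, formulary,
                               config = episode_config()) {
  cl <- classify(records$molecule, formulary)
  keep <- cl$drug_group != "mood_stabiliser"
  r <- records[keep, , drop = FALSE]
  rc <- cl[keep, , drop = FALSE]
  out <- list()
  w <- config$concurrency_window_days
  for (p in unique(r$patient_id)) {
    sel <- r$patient_id == p
    d <- as.integer(r$dispense_date[sel])
    m <- r$molecule[sel]
    k <- rc$drug_class[sel]
    g <- rc$drug_group[sel]
    n <- length(d)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (abs(d[j] - d[i]) > w || m[i] == m[j]) next
        type <- if (g[i] == "antidepressant" && g[j] == "antidepressant") {
          if (k[i] == k[j]) "within_class" else "combination"
        } else "augmentation"
        out[[length(out) + 1L]] <-
          data.frame(patient_id = p,
                     date = as.Date(max(d[i], d[j]), origin = "1970-01-01"),
                     type = type,
                     molecules = paste(sort(c(m[i], m[j])), collapse = ";"),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(0),
                      date = as.Date(character(0)), type = character(0),
                      molecules = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[c("patient_id", "type", "molecules")]), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[order(res$patient_id, res$date), , drop = FALSE]
}

#' Detect first dose-strength increase per patient
#'
#' Scanning each molecule's dispensings in time order, a dose increase is
#' inferred when the dispensed tablet strength strictly exceeds the
#' immediately previous strength of the same molecule (a proxy used when
#' prescribed dose is unavailable). Only the first increase per patient is
#' reported; strengths are never compared across molecules.
#'
#' @param records Dispensing records data frame.
#' @param formulary A `formulary` object.
#' @return Data frame `patient_id`, `date`, `molecule`, `from_strength_mg`,
#'   `to_strength_mg` (at most one row per patient).
#' @export
detect_dose_increase <- function(records, formulary) {
  cl <- classify(records$molecule, formulary)
  keep <- cl$drug_group == "antidepressant"
  r <- records[keep, , drop = FALSE]
  if (!nrow(r)) {
    return(data.frame(patient_id = character(0),
                      date = as.Date(character(0)), molecule = character(0),
                      from_strength_mg = numeric(0),
                      to_strength_mg = numeric(0), stringsAsFactors = FALSE))
  }
  o <- order(r$patient_id, r$molecule, r$dispense_date)
  pid <- r$patient_id[o]; mol <- r$molecule[o]
  day <- as.integer(r$dispense_date[o]); str <- r$strength_mg[o]
  n <- length(pid)
  same <- pid[-1L] == pid[-n] & mol[-1L] == mol[-n]
  up <- same & str[-1L] > str[-n]
  cand <- data.frame(patient_id = pid[-1L][up],
                     date = as.Date(day[-1L][up], origin = "1970-01-01"),
                     molecule = mol[-1L][up],
                     from_strength_mg = str[-n][up],
                     to_strength_mg = str[-1L][up], stringsAsFactors = FALSE)
  if (!nrow(cand)) return(cand)
  cand <- cand[order(cand$patient_id, cand$date, cand$molecule), ,
               drop = FALSE]
  cand <- cand[!duplicated(cand$patient_id), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

## Core per-patient sweep. Vectors are one patient's classified records,
## sorted by (day, antidepressants before antipsychotics, molecule).
## Returns parallel vectors describing the patient's episodes.
.episodes_one <- function(day, klass, group, gap, window, pack, use_pack,
                          data_end) {
  ad <- group == "antidepressant"
  d_ad <- day[ad]
  c_ad <- klass[ad]
  n_ad <- length(d_ad)
  if (!n_ad) return(NULL)
  blk <- cumsum(c(TRUE, diff(d_ad) > gap))
  nblk <- blk[n_ad]

  ## assign each antipsychotic dispensing to the block of its nearest
  ## concurrent antidepressant dispensing (if any)
  d_ap <- day[!ad]
  ap_blk <- integer(0)
  ap_day <- integer(0)
  if (length(d_ap)) {
    for (a in d_ap) {
      j <- which.min(abs(d_ad - a))
      if (abs(d_ad[j] - a) <= window) {
        ap_day[[length(ap_day) + 1L]] <- a
        ap_blk[[length(ap_blk) + 1L]] <- blk[j]
      }
    }
  }

  e_no <- integer(0); e_start <- integer(0); e_end <- integer(0)
  e_cls <- character(0); e_rsn <- character(0); e_scl <- character(0)
  e_multi <- logical(0)
  treat <- 0L
  push <- function(no, s, e, cls, rsn, scl, multi) {
    k <- length(e_no) + 1L
    e_no[[k]] <<- no; e_start[[k]] <<- s; e_end[[k]] <<- e
    e_cls[[k]] <<- paste(sort(unique(cls)), collapse = ";")
    e_rsn[[k]] <<- rsn; e_scl[[k]] <<- scl; e_multi[[k]] <<- multi
  }

  for (b in seq_len(nblk)) {
    sel <- blk == b
    bd <- d_ad[sel]; bc <- c_ad[sel]
    bap <- sort(ap_day[ap_blk == b])
    ## merged event stream: AD records then AP records on date ties
    ev_day <- c(bd, bap)
    ev_ap <- c(rep(FALSE, length(bd)), rep(TRUE, length(bap)))
    ev_cls <- c(bc, rep("antipsychotic", length(bap)))
    o <- order(ev_day, ev_ap)
    ev_day <- ev_day[o]; ev_ap <- ev_ap[o]; ev_cls <- ev_cls[o]

    treat <- treat + 1L
    ep_start <- bd[1L]
    cs <- unique(bc[bd == bd[1L]])
    multi <- length(cs) > 1L
    start_cl <- bc[1L]

    for (ii in seq_along(ev_day)) {
      t <- ev_day[ii]
      cc <- ev_cls[ii]
      if (ev_ap[ii]) {
        if ("antipsychotic" %in% cs) next
        if (t <= ep_start) { cs <- c(cs, "antipsychotic"); next }
        push(treat, ep_start, t, cs, "augmentation_added", start_cl, multi)
        treat <- treat + 1L
        ep_start <- t
        cs <- c(cs, "antipsychotic")
        multi <- FALSE
      } else {
        if (cc %in% cs) next
        if (t == ep_start) { cs <- c(cs, cc); multi <- TRUE; next }
        old_ad <- cs[cs != "antipsychotic"]
        comb <- any(bd >= t & bd <= t + window & bc %in% old_ad)
        push(treat, ep_start, t, cs,
             if (comb) "combination_added" else "switch", start_cl, multi)
        treat <- treat + 1L
        ep_start <- t
        cs <- if (comb) c(cs, cc) else cc
        start_cl <- cc
        multi <- FALSE
      }
    }

    last_ad <- bd[length(bd)]
    disc_day <- last_ad + (if (use_pack) pack else 0L)
    if (b < nblk) {
      push(treat, ep_start, disc_day, cs, "discontinuation", start_cl, multi)
    } else if (data_end - last_ad > gap) {
      push(treat, ep_start, disc_day, cs, "discontinuation", start_cl, multi)
    } else {
      push(treat, ep_start, data_end, cs, "censored", start_cl, multi)
    }
  }
  list(no = e_no, start = e_start, end = e_end, cls = e_cls, rsn = e_rsn,
       scl = e_scl, multi = e_multi)
}

#' Construct numbered treatment episodes for a cohort
#'
#' Runs the line-of-therapy sweep over every included patient and also
#' extracts dose-increase events and within-class molecule switches. The
#' treatment number increments on restart after a discontinuation gap, on
#' a class switch (the previous class has no dispensing inside the
#' concurrency window after the new class's first dispensing), on an added
#' concurrent antidepressant class, and on an added concurrent
#' antipsychotic; a within-class molecule change never increments. Two
#' classes dispensed on the episode start date form a single multi-class
#' episode, flagged in the output. The result is invariant to the row
#' order of `records`.
#'
#' @param records Dispensing records data frame.
#' @param cohort An `ad_cohort` object from [build_cohort()].
#' @param formulary A `formulary` object.
#' @param config An [episode_config()] object.
#' @return An `ad_episodes` object: list with `episodes` (patient_id,
#'   treatment_number, start_date, end_date, classes (semicolon list),
#'   start_class, end_reason, persistence_months, multi_class_start),
#'   `dose_events`, `within_class_switches` and the `config`.
#' @export
build_episodes <- function(records, cohort, formulary,
                           config = episode_config()) {
  stopifnot(inherits(cohort, "ad_cohort"))
  cl <- classify(records$molecule, formulary)
  keep <- cl$drug_group != "mood_stabiliser" &
    records$patient_id %in% cohort$cohort$patient_id &
    records$dispense_date <= config$data_end
  r <- records[keep, , drop = FALSE]
  rc <- cl[keep, , drop = FALSE]
  day <- as.integer(r$dispense_date)
  o <- order(r$patient_id, day, rc$drug_group != "antidepressant",
             r$molecule)
  pid <- r$patient_id[o]; day <- day[o]
  kls <- rc$drug_class[o]; grp <- rc$drug_group[o]

  idx <- split(seq_along(pid), pid)
  use_pack <- config$disc_end == "last_plus_pack"
  dend <- as.integer(config$data_end)
  res <- vector("list", length(idx))
  for (q in seq_along(idx)) {
    ii <- idx[[q]]
    res[[q]] <- .episodes_one(day[ii], kls[ii], grp[ii],
                              config$discontinuation_gap_days,
                              config$concurrency_window_days,
                              config$pack_days, use_pack, dend)
  }
  pids <- names(idx)
  nv <- vapply(res, function(x) length(x$no), integer(1L))
  episodes <- data.frame(
    patient_id = rep(pids, nv),
    treatment_number = unlist(lapply(res, `[[`, "no")),
    start_date = as.Date(unlist(lapply(res, `[[`, "start")),
                         origin = "1970-01-01"),
    end_date = as.Date(unlist(lapply(res, `[[`, "end")),
                       origin = "1970-01-01"),
    classes = unlist(lapply(res, `[[`, "cls")),
    start_class = unlist(lapply(res, `[[`, "scl")),
    end_reason = unlist(lapply(res, `[[`, "rsn")),
    multi_class_start = unlist(lapply(res, `[[`, "multi")),
    stringsAsFactors = FALSE)
  if (!nrow(episodes)) {
    episodes$persistence_months <- numeric(0)
  } else {
    episodes$persistence_months <-
      as.numeric(episodes$end_date - episodes$start_date) /
      config$months_per_unit
  }

  dose <- detect_dose_increase(r, formulary)

  ## within-class molecule switches: consecutive dispensings of the same
  ## class with a different molecule (logged, never a line increment)
  wcs <- local({
    adm <- grp == "antidepressant"
    p <- pid[adm]; d <- day[adm]; k <- kls[adm]
    m <- r$molecule[o][adm]
    oo <- order(p, k, d, m)
    p <- p[oo]; d <- d[oo]; k <- k[oo]; m <- m[oo]
    n <- length(p)
    if (n < 2L) {
      return(data.frame(patient_id = character(0),
                        date = as.Date(character(0)),
                        drug_class = character(0), from = character(0),
                        to = character(0), stringsAsFactors = FALSE))
    }
    hit <- p[-1L] == p[-n] & k[-1L] == k[-n] & m[-1L] != m[-n]
    data.frame(patient_id = p[-1L][hit],
               date = as.Date(d[-1L][hit], origin = "1970-01-01"),
               drug_class = k[-1L][hit], from = m[-n][hit], to = m[-1L][hit],
               stringsAsFactors = FALSE)
  })

  structure(list(episodes = episodes, dose_events = dose,
                 within_class_switches = wcs, config = config),
            class = "ad_episodes")
}

#' @export
print.ad_episodes <- function(x, ...) {
  ep <- x$episodes
  cat("<ad_episodes> ", nrow(ep), " episodes for ",
      length(unique(ep$patient_id)), " patients; ",
      nrow(x$dose_events), " dose increases\n", sep = "")
  if (nrow(ep)) {
    cat("  treatment numbers:",
        paste(sprintf("%s:%d", names(table(ep$treatment_number)),
                      as.integer(table(ep$treatment_number))),
              collapse = " "), "\n")
    cat("  end reasons:",
        paste(sprintf("%s %d", names(table(ep$end_reason)),
                      as.integer(table(ep$end_reason))), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Export the episode table to CSV
#'
#' Columns: patient_id, treatment_number, start_date, end_date, classes
#' (semicolon list), end_reason, persistence_months.
#'
#' @param episodes An `ad_episodes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  ep <- episodes$episodes
  out <- data.frame(patient_id = ep$patient_id,
                    treatment_number = ep$treatment_number,
                    start_date = format(ep$start_date, "%Y-%m-%d"),
                    end_date = format(ep$end_date, "%Y-%m-%d"),
                    classes = ep$classes, end_reason = ep$end_reason,
                    persistence_months = ep$persistence_months,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
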