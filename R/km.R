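## Self-contained survival machinery: Kaplan-Meier product-limit estimate
## with Greenwood variance, median survival, two-group log-rank test, and
## relative risk at a fixed horizon. Written directly from the estimators'
## definitions; the survival package is used in the test suite as an
## independent cross-check only.

#' Kaplan-Meier product-limit estimate
#'
#' Computes S(t) = prod over event times t_i <= t of (1 - d_i / n_i),
#' with the Greenwood variance accumulated alongside. Ties between an
#' event and a censoring at the same time follow the standard convention:
#' censored observations are still at risk at that time (events first).
#'
#' @param time Non-negative durations (months, by package convention).
#' @param event Logical (or 0/1): `TRUE` when the endpoint was observed,
#'   `FALSE` when censored.
#' @return A `km_curve` object: list with `time` (increasing observed
#'   event times), `surv`, `n_risk`, `n_event`, `greenwood_var` (variance
#'   of S at each event time), plus `n` and `n_events`.
#' @examples
#' fit <- km_fit(c(6, 7, 10, 15, 19, 25),
#'               c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
#' km_median(fit)
#' @export
km_fit <- function(time, event) {
  time <- as.numeric(time)
  event <- as.logical(event)
  if (length(time) == 0L) stop("empty survival input", call. = FALSE)
  if (length(time) != length(event)) stop("time/event length mismatch",
                                          call. = FALSE)
  if (anyNA(time) || anyNA(event)) stop("missing values in survival input",
                                        call. = FALSE)
  if (any(time < 0)) stop("durations must be non-negative", call. = FALSE)
  n <- length(time)
  ut <- sort(unique(time))
  tot <- tabulate(match(time, ut), nbins = length(ut))
  dd <- tabulate(match(time[event], ut), nbins = length(ut))
  n_risk_all <- n - c(0L, cumsum(tot))[seq_along(ut)]
  has_ev <- dd > 0L
  t_ev <- ut[has_ev]
  d <- dd[has_ev]
  r <- n_risk_all[has_ev]
  surv <- cumprod(1 - d / r)
  gw <- cumsum(ifelse(r > d, d / (r * (r - d)), Inf))
  var_s <- ifelse(is.finite(gw), surv^2 * gw, NA_real_)
  structure(list(time = t_ev, surv = surv, n_risk = r, n_event = d,
                 greenwood_var = var_s, n = n, n_events = sum(d)),
            class = "km_curve")
}

#' Survival probability at a time point
#'
#' Step-function lookup of the product-limit estimate: S(t) is 1 before
#' the first event time and right-continuous thereafter.
#'
#' @param fit A `km_curve` object.
#' @param t Time point(s).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_curve"))
  idx <- findInterval(t, fit$time)
  ifelse(idx == 0L, 1, fit$surv[pmax(idx, 1L)])
}

.km_var_at <- function(fit, t) {
  idx <- findInterval(t, fit$time)
  ifelse(idx == 0L, 0, fit$greenwood_var[pmax(idx, 1L)])
}

#' Median survival time
#'
#' The smallest observed event time at which the survival estimate drops
#' to 0.5 or below; `NA` ("not reached") when the curve never does.
#'
#' @param fit A `km_curve` object.
#' @return A single number, or `NA` if the median is not reached.
#' @export
km_median <- function(fit) {
  stopifnot(inherits(fit, "km_curve"))
  hit <- which(fit$surv <= 0.5)
  if (!length(hit)) NA_real_ else fit$time[hit[1L]]
}

#' @export
print.km_curve <- function(x, ...) {
  med <- km_median(x)
  cat("<km_curve> n = ", x$n, ", events = ", x$n_events, ", median = ",
      if (is.na(med)) "not reached" else format(round(med, 2)),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.km_curve <- function(object, ...) {
  data.frame(time = object$time, n_risk = object$n_risk,
             n_event = object$n_event, surv = object$surv,
             std_err = sqrt(object$greenwood_var))
}

#' @export
plot.km_curve <- function(x, xlab = "Months", ylab = "Survival",
                          main = NULL, ...) {
  tt <- c(0, x$time)
  ss <- c(1, x$surv)
  graphics::plot(tt, ss, type = "s", ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, main = main, ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank: at each pooled event time the observed
#' minus expected events in the first group are summed, with the
#' hypergeometric variance, and the squared standardised sum is referred
#' to a chi-squared distribution on one degree of freedom. The statistic
#' is invariant to swapping the group labels.
#'
#' @param time Durations for both groups combined.
#' @param event Event indicator.
#' @param group Two-level grouping vector.
#' @return A `logrank_test` object with `chi_square`, `p_value`,
#'   `observed` and `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  time <- as.numeric(time); event <- as.logical(event)
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  if (!sum(event)) stop("no events in pooled data", call. = FALSE)
  g1 <- group == lev[1L]
  t_ev <- sort(unique(time[event]))
  J <- length(t_ev)

  st1 <- sort(time[g1])
  st <- sort(time)
  n1 <- length(st1) - findInterval(t_ev, st1, left.open = TRUE)
  nn <- length(st) - findInterval(t_ev, st, left.open = TRUE)
  d1 <- tabulate(match(time[event & g1], t_ev), nbins = J)
  dd <- tabulate(match(time[event], t_ev), nbins = J)

  e1 <- dd * n1 / nn
  v <- ifelse(nn > 1L,
              dd * (n1 / nn) * (1 - n1 / nn) * (nn - dd) / (nn - 1L), 0)
  o_minus_e <- sum(d1 - e1)
  V <- sum(v)
  chi <- if (V > 0) o_minus_e^2 / V else NA_real_
  p <- if (is.na(chi)) NA_real_ else stats::pchisq(chi, df = 1L,
                                                   lower.tail = FALSE)
  structure(list(chi_square = chi, p_value = p,
                 groups = lev,
                 observed = c(sum(d1), sum(dd) - sum(d1)),
                 expected = c(sum(e1), sum(dd) - sum(e1)),
                 variance = V),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test: ", x$groups[1L], " vs ", x$groups[2L], "\n", sep = "")
  cat(sprintf("  observed %g / %g, expected %.2f / %.2f\n",
              x$observed[1L], x$observed[2L], x$expected[1L],
              x$expected[2L]))
  cat(sprintf("  chi-square = %.4g on 1 df, p = %.3g\n", x$chi_square,
              x$p_value))
  invisible(x)
}

#' Relative risk of the endpoint at a fixed horizon
#'
#' Compares two Kaplan-Meier curves at horizon `t` as a risk ratio
#' `RR = (1 - S_A(t)) / (1 - S_B(t))` (default, `type = "risk"`): the risk
#' of treatment change by `t` in the comparator over the reference, so a
#' group with worse persistence gets RR > 1. `type = "survival"` instead
#' reports the survival ratio `S_A(t) / S_B(t)`. The confidence interval
#' is a log-transformed Wald interval with the Greenwood variances
#' propagated by the delta method.
#'
#' @param fit_a Comparator `km_curve`.
#' @param fit_b Reference `km_curve`.
#' @param t Horizon (months; default 12).
#' @param conf_level Confidence level (default 0.95).
#' @param type `"risk"` (default) or `"survival"`.
#' @return An `rr_estimate` object with `rr`, `ci_low`, `ci_high`,
#'   `p_value` (Wald test of RR = 1) and the two survival estimates.
#' @export
rr_at <- function(fit_a, fit_b, t = 12, conf_level = 0.95,
                  type = c("risk", "survival")) {
  stopifnot(inherits(fit_a, "km_curve"), inherits(fit_b, "km_curve"))
  type <- match.arg(type)
  sa <- km_surv_at(fit_a, t)
  sb <- km_surv_at(fit_b, t)
  va <- .km_var_at(fit_a, t)
  vb <- .km_var_at(fit_b, t)
  ## Greenwood variance is degenerate once the curve reaches zero: the
  ## in-sample risk is exactly 1 and contributes no variance term
  if (is.na(va) && sa == 0) va <- 0
  if (is.na(vb) && sb == 0) vb <- 0
  if (type == "risk") {
    if (sb >= 1) stop("reference risk at horizon is zero; RR undefined",
                      call. = FALSE)
    rr <- (1 - sa) / (1 - sb)
    if (sa >= 1) {
      warning("comparator risk at horizon is zero; RR = 0 with no CI")
      return(structure(list(rr = 0, ci_low = NA_real_, ci_high = NA_real_,
                            p_value = NA_real_, surv_a = sa, surv_b = sb,
                            t = t, type = type), class = "rr_estimate"))
    }
    se_log <- sqrt(va / (1 - sa)^2 + vb / (1 - sb)^2)
  } else {
    if (sa <= 0 || sb <= 0) stop("survival ratio undefined at horizon",
                                 call. = FALSE)
    rr <- sa / sb
    se_log <- sqrt(va / sa^2 + vb / sb^2)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(rr) + c(-1, 1) * z * se_log)
  p <- 2 * stats::pnorm(-abs(log(rr)) / se_log)
  structure(list(rr = rr, ci_low = ci[1L], ci_high = ci[2L], p_value = p,
                 surv_a = sa, surv_b = sb, t = t, type = type),
            class = "rr_estimate")
}

#' @export
print.rr_estimate <- function(x, ...) {
  lab <- if (x$type == "risk") "risk ratio" else "survival ratio"
  cat(sprintf("%s at %g months: %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              lab, x$t, x$rr, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  S_comparator(%g) = %.4f, S_reference(%g) = %.4f\n",
              x$t, x$surv_a, x$t, x$surv_b))
  invisible(x)
}

#' Kaplan-Meier persistence curves for treatment episodes
#'
#' Convenience wrapper: builds survival input from an episode table
#' (duration = `persistence_months`, event = any end reason other than
#' censoring) and fits one curve per stratum.
#'
#' @param episodes An `ad_episodes` object or its `episodes` data frame.
#' @param by `"none"` (one pooled curve), `"class"` (stratify by the
#'   episode's starting class) or `"treatment_number"`.
#' @return A named list of `km_curve` objects.
#' @export
persistence_km <- function(episodes, by = c("none", "class",
                                            "treatment_number")) {
  by <- match.arg(by)
  ep <- if (inherits(episodes, "ad_episodes")) episodes$episodes else episodes
  evt <- ep$end_reason != "censored"
  if (by == "none") {
    return(list(overall = km_fit(ep$persistence_months, evt)))
  }
  key <- if (by == "class") ep$start_class else ep$treatment_number
  out <- lapply(split(seq_len(nrow(ep)), key), function(i) {
    km_fit(ep$persistence_months[i], evt[i])
  })
  out
}
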