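# Kaplan-Meier and k-group log-rank utilities used by every downstream stage.
# Estimation is delegated to the survival package; these wrappers fix the
# conventions (tie handling, group dropping, chi-square reference) and the
# return shapes the rest of the pipeline relies on.

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival curve with risk/event counts, overall
#' or per group. Ties are handled by simultaneous decrement; subjects censored
#' exactly at an event time remain in the risk set for that time. `S(0) = 1`
#' and the curve is non-increasing.
#'
#' @param time follow-up times (days, >= 0, finite).
#' @param event event indicator (TRUE/1 = TE observed).
#' @param group optional group labels; when given, one curve per group.
#' @return A data frame with columns `group` (if requested), `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, suitable for CSV export.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  check_surv_input(time, event)
  event <- as.integer(as.logical(event))
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                             conf.type = "none")
    return(data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv))
  }
  group <- as.character(group)
  out <- lapply(split(seq_along(time), group), function(idx) {
    km <- kaplan_meier(time[idx], event[idx])
    cbind(group = group[idx[1]], km)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kaplan-Meier survival probability at a time point
#'
#' @param time,event as in [kaplan_meier()].
#' @param at evaluation time; returns `S(at)` from the step function.
#' @return Survival probability in \[0, 1\].
#' @export
km_survival_at <- function(time, event, at) {
  km <- kaplan_meier(time, event)
  steps <- km[km$n_event > 0 & km$time <= at, , drop = FALSE]
  if (nrow(steps) == 0L) return(1)
  steps$surv[nrow(steps)]
}

check_surv_input <- function(time, event) {
  if (length(time) == 0L) stop("at least one sample is required")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time))) stop("times must be finite")
  if (any(time < 0)) stop("negative survival times are not allowed")
  invisible(TRUE)
}

#' K-group log-rank test
#'
#' Standard log-rank test: at each distinct event time the observed group
#' event counts are compared with their hypergeometric expectations given the
#' risk sets, and the accumulated observed-minus-expected vector is referred
#' to a chi-square distribution with (groups - 1) degrees of freedom, with the
#' usual tie-corrected hypergeometric variance. Empty groups (unused factor
#' levels) are dropped with a warning and the degrees of freedom adjusted;
#' fewer than two remaining groups is an error. The result is invariant to
#' permutations of the group labels and to strictly monotone transforms of
#' time.
#'
#' @param time follow-up times (days, >= 0, finite).
#' @param event event indicator (TRUE/1 = TE observed).
#' @param group group labels (>= 2 non-empty groups).
#' @return An object of class `pv_logrank`: list with `chi2`, `df`, `p`,
#'   `n_groups`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv_input(time, event)
  if (length(group) != length(time)) stop("group and time lengths differ")
  g <- if (is.factor(group)) group else factor(group)
  if (nlevels(g) != nlevels(droplevels(g))) {
    warning("dropping empty group level(s); degrees of freedom adjusted")
  }
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2L) stop("log-rank test needs at least two non-empty groups")
  event <- as.integer(as.logical(event))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  chi2 <- unname(sd$chisq)
  df <- k - 1L
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 n_groups = k),
            class = "pv_logrank")
}

#' @export
print.pv_logrank <- function(x, ...) {
  cat(sprintf("log-rank: chi2 = %.4g on %d df, p = %.3g (%d groups)\n",
              x$chi2, x$df, x$p, x$n_groups))
  invisible(x)
}
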