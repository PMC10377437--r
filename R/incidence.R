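# Period construction, annualized TE incidence, and propensity matching.

#' Build analysis periods for one patient
#'
#' Constructs the half-open per-patient intervals used for period-aligned
#' incidence: `pre_index = [index - 365, index)`; for switchers,
#' `post_index = [index, rux_first)` and `switch = [rux_first, rux_last)`;
#' for non-switchers, `post_index = [index, index + median_hu_time)` and
#' `no_switch = [index + median_hu_time, index + median_hu_time +
#' median_rux_time)`, where the medians are the switch cohort's median HU and
#' ruxolitinib treatment times (days). All periods are truncated at
#' `record_end`; a record too short for the full pre-index window drops the
#' patient from that period's denominator (the period is omitted and listed in
#' attribute `"dropped"`).
#'
#' @param patient one-row [pv_cohort].
#' @param median_hu_time,median_rux_time reference treatment durations (days).
#' @param switcher is this patient in the HU-to-ruxolitinib group? Defaults to
#'   the presence of a first ruxolitinib date.
#' @return Data frame with columns `period`, `start`, `end` (day offsets,
#'   half-open).
#' @export
build_periods <- function(patient, median_hu_time, median_rux_time,
                          switcher = !is.na(patient$rux_first)) {
  stopifnot(nrow(patient) == 1L)
  if (is.na(patient$index_date)) stop("index_date is required")
  idx <- patient$index_date
  rend <- patient$record_end
  if (switcher && (is.na(patient$rux_first) || is.na(patient$rux_last))) {
    stop("switcher without ruxolitinib dates: ", patient$patient_id)
  }
  if (switcher) {
    per <- data.frame(
      period = c("pre_index", "post_index", "switch"),
      start = c(idx - 365, idx, patient$rux_first),
      end = c(idx, patient$rux_first, patient$rux_last))
  } else {
    per <- data.frame(
      period = c("pre_index", "post_index", "no_switch"),
      start = c(idx - 365, idx, idx + median_hu_time),
      end = c(idx, idx + median_hu_time,
              idx + median_hu_time + median_rux_time))
  }
  dropped <- character(0)
  if (per$start[per$period == "pre_index"] < patient$record_start) {
    dropped <- "pre_index"
    per <- per[per$period != "pre_index", , drop = FALSE]
  }
  per$end <- pmin(per$end, rend)
  per$start <- pmin(per$start, rend)
  empty <- per$end <= per$start
  per <- per[!empty, , drop = FALSE]
  rownames(per) <- NULL
  attr(per, "dropped") <- dropped
  per
}

#' Build periods for a whole cohort
#'
#' Applies [build_periods()] to each patient. When the reference treatment
#' times are not supplied they are computed from the cohort's switchers:
#' median time from index to first ruxolitinib prescription (HU time) and
#' median ruxolitinib course length.
#'
#' @param cohort a [pv_cohort].
#' @param median_hu_time,median_rux_time reference durations (days); computed
#'   from the cohort's switchers when `NULL`.
#' @return Data frame with columns `patient_id`, `period`, `start`, `end`.
#' @export
cohort_periods <- function(cohort, median_hu_time = NULL,
                           median_rux_time = NULL) {
  sw <- !is.na(cohort$rux_first)
  if (is.null(median_hu_time)) {
    if (!any(sw)) stop("no switchers to derive median_hu_time from")
    median_hu_time <- stats::median(cohort$rux_first[sw] -
                                      cohort$index_date[sw])
  }
  if (is.null(median_rux_time)) {
    if (!any(sw)) stop("no switchers to derive median_rux_time from")
    median_rux_time <- stats::median(cohort$rux_last[sw] -
                                       cohort$rux_first[sw])
  }
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    p <- build_periods(cohort[i, , drop = FALSE], median_hu_time,
                       median_rux_time)
    if (nrow(p) == 0L) return(NULL)
    cbind(patient_id = cohort$patient_id[i], p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annualized TE incidence rate per 100 patient-years
#'
#' Counts TE events falling in each patient's labelled interval and divides by
#' the summed interval person-time: `ir_per_100 = 100 * events /
#' person_years`, with person-years = days / 365.25. By default all events are
#' counted (recurrent TEs included); `first_event_only = TRUE` counts at most
#' one event per patient-period.
#'
#' @param cohort a [pv_cohort].
#' @param periods per-patient periods from [cohort_periods()].
#' @param period_label which period to summarize (e.g. `"pre_index"`).
#' @param first_event_only count at most one TE per patient in the period.
#' @return An object of class `pv_incidence`: list with `cohort`, `period`,
#'   `n_patients`, `events`, `person_years`, `ir_per_100` (`NA` with a warning
#'   when person-time is zero).
#' @export
annualized_ir <- function(cohort, periods, period_label,
                          first_event_only = FALSE) {
  per <- periods[periods$period == period_label, , drop = FALSE]
  idx <- match(per$patient_id, cohort$patient_id)
  if (anyNA(idx)) stop("periods reference patients absent from the cohort")
  ev <- vapply(seq_len(nrow(per)), function(i) {
    tt <- cohort$te_times[[idx[i]]]
    k <- sum(tt >= per$start[i] & tt < per$end[i])
    if (first_event_only) min(k, 1L) else k
  }, numeric(1))
  person_years <- sum(per$end - per$start) / DAYS_PER_YEAR
  events <- sum(ev)
  ir <- if (person_years > 0) {
    100 * events / person_years
  } else {
    warning("zero person-years in period '", period_label,
            "'; incidence rate undefined")
    NA_real_
  }
  structure(list(cohort = cohort_label(cohort), period = period_label,
                 n_patients = nrow(per), events = events,
                 person_years = person_years, ir_per_100 = ir),
            class = "pv_incidence")
}

#' @export
print.pv_incidence <- function(x, ...) {
  cat(sprintf("%s / %s: %d patients, %d events over %.1f person-years; IR = %s per 100 patient-years\n",
              x$cohort, x$period, x$n_patients, x$events, x$person_years,
              ifelse(is.na(x$ir_per_100), "NA",
                     sprintf("%.2f", x$ir_per_100))))
  invisible(x)
}

#' 1:1 propensity-score matching
#'
#' Fits a logistic propensity model for treatment on the given covariates,
#' then matches each treated patient to at most one control by greedy
#' nearest-neighbour on the logit of the propensity score, without
#' replacement, within a caliper of `caliper_sd` pooled standard deviations of
#' the logit. The procedure is deterministic: treated patients are processed
#' in `patient_id` order and ties go to the control with the smaller
#' `patient_id`. Absolute standardized mean differences (SMD) per covariate
#' are reported before and after matching (categorical covariates are expanded
#' to indicators).
#'
#' @param treated,controls [pv_cohort]s (covariates must be non-missing).
#' @param covariates covariate column names (e.g. total treatment time,
#'   gender, race, age at index, region).
#' @param caliper_sd caliper width in pooled SDs of the logit (0.2 by
#'   convention; `Inf` disables).
#' @return An object of class `pv_match`: list with `pairs` (data frame
#'   `treated_id`, `control_id`, `distance`), `model` (propensity
#'   coefficients), `balance` (SMD per covariate pre/post), `caliper`.
#' @export
propensity_match <- function(treated, controls, covariates,
                             caliper_sd = 0.2) {
  empty <- function() {
    structure(list(pairs = data.frame(treated_id = character(0),
                                      control_id = character(0),
                                      distance = numeric(0)),
                   model = NULL, balance = NULL, caliper = NA_real_),
              class = "pv_match")
  }
  if (nrow(treated) == 0L) return(empty())
  dat <- rbind(
    data.frame(patient_id = treated$patient_id, treat = 1L,
               treated[, covariates, drop = FALSE]),
    data.frame(patient_id = controls$patient_id, treat = 0L,
               controls[, covariates, drop = FALSE]))
  if (anyNA(dat[, covariates])) {
    stop("covariates must be non-missing for all patients")
  }
  sep <- FALSE
  fml <- stats::as.formula(paste("treat ~", paste(covariates, collapse = "+")))
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  mu <- stats::fitted(fit)
  if (sep || all(abs(mu - dat$treat) < 1e-6)) {
    stop("propensity model separates treated from controls perfectly; ",
         "review the covariate set")
  }
  logit <- stats::predict(fit, type = "link")
  caliper <- caliper_sd * stats::sd(logit)
  pairs <- greedy_nn_match(logit[dat$treat == 1L], logit[dat$treat == 0L],
                           dat$patient_id[dat$treat == 1L],
                           dat$patient_id[dat$treat == 0L], caliper)
  mm <- stats::model.matrix(stats::as.formula(
    paste("~", paste(covariates, collapse = "+"))), data = dat)[, -1, drop = FALSE]
  pre <- smd_table(mm, dat$treat == 1L, dat$treat == 0L)
  ti <- dat$patient_id %in% pairs$treated_id & dat$treat == 1L
  ci <- dat$patient_id %in% pairs$control_id & dat$treat == 0L
  post <- if (nrow(pairs) > 0) smd_table(mm, ti, ci) else rep(NA_real_, ncol(mm))
  structure(list(pairs = pairs, model = stats::coef(fit),
                 balance = data.frame(covariate = colnames(mm),
                                      smd_pre = pre, smd_post = post,
                                      row.names = NULL),
                 caliper = caliper),
            class = "pv_match")
}

# deterministic greedy 1:1 nearest-neighbour matching on a scalar score:
# treated processed in id order, each taking the closest unused control
# within the caliper; distance ties go to the control with the smaller id
greedy_nn_match <- function(score_t, score_c, id_t, id_c, caliper = Inf) {
  ord_t <- order(id_t)
  ord_c <- order(id_c)
  score_t <- score_t[ord_t]; id_t <- id_t[ord_t]
  score_c <- score_c[ord_c]; id_c <- id_c[ord_c]
  used <- rep(FALSE, length(score_c))
  pairs <- vector("list", length(score_t))
  for (i in seq_along(score_t)) {
    d <- abs(score_c - score_t[i])
    d[used] <- Inf
    if (length(d) == 0L) break
    j <- which.min(d)
    if (!is.finite(d[j]) || d[j] > caliper) next
    used[j] <- TRUE
    pairs[[i]] <- data.frame(treated_id = id_t[i], control_id = id_c[j],
                             distance = d[j])
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    pairs <- data.frame(treated_id = character(0), control_id = character(0),
                        distance = numeric(0))
  }
  rownames(pairs) <- NULL
  pairs
}

# absolute standardized mean differences
smd_table <- function(mm, is_t, is_c) {
  vapply(seq_len(ncol(mm)), function(j) {
    x <- mm[, j]
    s <- sqrt((stats::var(x[is_t]) + stats::var(x[is_c])) / 2)
    d <- abs(mean(x[is_t]) - mean(x[is_c]))
    if (!is.finite(s) || s == 0) {
      if (d == 0) 0 else NA_real_
    } else {
      d / s
    }
  }, numeric(1))
}

#' @export
print.pv_match <- function(x, ...) {
  cat(sprintf("<pv_match: %d pairs, caliper %.3f>\n", nrow(x$pairs),
              x$caliper))
  invisible(x)
}
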