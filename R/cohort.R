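# Cohort data model: one row per patient, day offsets from an arbitrary epoch.

pv_mandatory_cols <- function() {
  c("patient_id", "age_at_index", "sex", "race", "region", "te_history",
    "n_phlebotomy", "anticoag_antiplatelet", "smoking", "alcohol",
    pv_lab_vars, pv_obs_vars,
    "index_date", "hu_first", "hu_last", "rux_first", "rux_last",
    "record_start", "record_end", "te_times")
}

#' Construct a patient cohort
#'
#' A cohort is a data frame with one row per patient. Dates are integer day
#' offsets from an arbitrary epoch; `te_times` is a list column of sorted TE
#' event day offsets (possibly empty). Laboratory and observation medians may
#' be missing (`NA`), which is meaningful in itself and never collapsed to
#' zero. Row-level invariants are checked and violating rows are dropped with
#' a warning naming the patients:
#' \itemize{
#'   \item `record_start <= index_date <= record_end`
#'   \item `hu_first == index_date` when present (index is the first HU
#'     prescription date)
#'   \item `te_times` strictly increasing, all within
#'     `[record_start, record_end]`
#'   \item laboratory/observation medians strictly positive when present
#' }
#'
#' @param data data frame holding at least the mandatory patient columns.
#' @param label provenance label (e.g. `"HU-alone"`, `"validation"`).
#' @return An object of class `pv_cohort` (a data frame).
#' @export
pv_cohort <- function(data, label = "cohort") {
  miss <- setdiff(pv_mandatory_cols(), names(data))
  if (length(miss) > 0L) {
    stop("cohort is missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.list(data$te_times)) {
    data$te_times <- parse_te_times(as.character(data$te_times))
  }
  if (anyDuplicated(data$patient_id)) {
    stop("patient_id must be unique within a cohort")
  }
  bad <- cohort_row_problems(data)
  if (length(bad) > 0L) {
    keep <- !(data$patient_id %in% names(bad))
    warning(sprintf("dropped %d invalid row(s): %s", length(bad),
                    paste(sprintf("%s (%s)", names(bad), unlist(bad)),
                          collapse = "; ")))
    data <- data[keep, , drop = FALSE]
  }
  rownames(data) <- NULL
  structure(data, label = label, class = c("pv_cohort", "data.frame"))
}

# per-row invariant checks; returns named list patient_id -> first problem
cohort_row_problems <- function(data) {
  probs <- list()
  num_pos <- c(pv_lab_vars, pv_obs_vars)
  for (i in seq_len(nrow(data))) {
    r <- data[i, ]
    id <- as.character(r$patient_id)
    msg <- NULL
    if (is.na(r$record_start) || is.na(r$record_end) || is.na(r$index_date)) {
      msg <- "missing record_start/index_date/record_end"
    } else if (!(r$record_start <= r$index_date && r$index_date <= r$record_end)) {
      msg <- "index_date outside record interval"
    } else if (!is.na(r$hu_first) && r$hu_first != r$index_date) {
      msg <- "hu_first differs from index_date"
    } else {
      tt <- data$te_times[[i]]
      if (length(tt) > 0) {
        if (any(is.na(tt)) || is.unsorted(tt, strictly = TRUE)) {
          msg <- "te_times not strictly increasing"
        } else if (min(tt) < r$record_start || max(tt) > r$record_end) {
          msg <- "te_time outside record interval"
        }
      }
      if (is.null(msg)) {
        vals <- unlist(r[num_pos], use.names = FALSE)
        if (any(!is.na(vals) & vals <= 0)) {
          msg <- "non-positive lab/observation value"
        }
      }
    }
    if (!is.null(msg)) probs[[id]] <- msg
  }
  probs
}

parse_te_times <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

format_te_times <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = ";"), character(1))
}

#' Cohort provenance label
#' @param cohort a `pv_cohort`.
#' @return The provenance label string.
#' @export
cohort_label <- function(cohort) {
  lab <- attr(cohort, "label")
  if (is.null(lab)) "cohort" else lab
}

#' @export
print.pv_cohort <- function(x, ...) {
  cat(sprintf("<pv_cohort '%s': %d patients, %d TE events>\n",
              cohort_label(x), nrow(x), sum(lengths(x$te_times))))
  invisible(x)
}

#' Read / write a cohort CSV
#'
#' One row per patient; missing values are empty cells; `te_times` is a
#' semicolon-separated list of day offsets. `read_cohort` enforces the cohort
#' invariants, rejecting violating rows with row-level diagnostics, and errors
#' if a mandatory column is absent. Unparsable numbers in a row reject that
#' row (naming the patient) rather than the whole file. `write_cohort` is the
#' inverse; the pair round-trips valid cohorts field for field.
#'
#' @param path CSV file path.
#' @param label provenance label for the cohort.
#' @return `read_cohort`: a [pv_cohort]. `write_cohort`: `path`, invisibly.
#' @export
read_cohort <- function(path, label = "cohort") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character")
  miss <- setdiff(pv_mandatory_cols(), names(raw))
  if (length(miss) > 0L) {
    stop("cohort file is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning("cohort file has a header but no rows; returning an empty cohort")
  }
  num_cols <- c("age_at_index", "n_phlebotomy", pv_lab_vars, pv_obs_vars,
                "index_date", "hu_first", "hu_last", "rux_first", "rux_last",
                "record_start", "record_end")
  lgl_cols <- c("te_history", "anticoag_antiplatelet", "smoking", "alcohol")
  opt_cols <- intersect(c("has_mf_et", "has_other_cytoreductive",
                          "n_hu_prescriptions", "n_rux_prescriptions"),
                        names(raw))
  bad_rows <- rep(FALSE, nrow(raw))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad_rows <- bad_rows | (!is.na(raw[[cl]]) & is.na(v))
    raw[[cl]] <- v
  }
  for (cl in lgl_cols) {
    v <- as.logical(raw[[cl]])
    bad_rows <- bad_rows | (!is.na(raw[[cl]]) & is.na(v))
    raw[[cl]] <- v
  }
  for (cl in opt_cols) {
    raw[[cl]] <- if (startsWith(cl, "n_")) {
      suppressWarnings(as.numeric(raw[[cl]]))
    } else {
      as.logical(raw[[cl]])
    }
  }
  if (any(bad_rows)) {
    warning(sprintf("rejected %d row(s) with unparsable values: %s",
                    sum(bad_rows),
                    paste(raw$patient_id[bad_rows], collapse = ", ")))
    raw <- raw[!bad_rows, , drop = FALSE]
  }
  raw$te_times <- parse_te_times(raw$te_times)
  pv_cohort(raw, label = label)
}

#' @param cohort a [pv_cohort] to serialize.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$te_times <- format_te_times(cohort$te_times)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Cohort eligibility criteria
#'
#' Encodes the cohort-selection rules: adult patients with at least two HU (or,
#' for switchers, ruxolitinib) prescriptions, no myelofibrosis/essential
#' thrombocythemia, no other cytoreductive treatment; optionally, for the risk
#' model, at least `min_hu_months` of HU treatment, `min_followup_months` of
#' follow-up, and at least one laboratory value and one clinical observation
#' from the post-index feature window. Months are converted to days at
#' 30.4375 days/month; the feature window defaults to 3--6 months post-index,
#' i.e. day offsets `[91, 183)`.
#'
#' @param min_age minimum age at index (years).
#' @param min_hu_prescriptions minimum prescription count.
#' @param exclude_mf_et drop patients with myelofibrosis/ET.
#' @param exclude_other_cytoreductives drop patients on other cytoreductives.
#' @param min_hu_months minimum HU treatment duration (months; 0 disables).
#' @param min_followup_months minimum post-index follow-up (months; 0 disables).
#' @param require_lab_and_obs_in_window require >= 1 lab and >= 1 observation
#'   median to be present.
#' @param feature_window c(start, end) months post-index for the feature
#'   medians.
#' @return An object of class `pv_eligibility`.
#' @export
eligibility_criteria <- function(min_age = 18,
                                 min_hu_prescriptions = 2,
                                 exclude_mf_et = TRUE,
                                 exclude_other_cytoreductives = TRUE,
                                 min_hu_months = 0,
                                 min_followup_months = 0,
                                 require_lab_and_obs_in_window = FALSE,
                                 feature_window = c(3, 6)) {
  stopifnot(length(feature_window) == 2L, feature_window[1] < feature_window[2],
            min_age >= 0, min_hu_prescriptions >= 0, min_hu_months >= 0,
            min_followup_months >= 0)
  structure(list(min_age = min_age,
                 min_hu_prescriptions = min_hu_prescriptions,
                 exclude_mf_et = exclude_mf_et,
                 exclude_other_cytoreductives = exclude_other_cytoreductives,
                 min_hu_months = min_hu_months,
                 min_followup_months = min_followup_months,
                 require_lab_and_obs_in_window = require_lab_and_obs_in_window,
                 feature_window = feature_window),
            class = "pv_eligibility")
}

#' @rdname eligibility_criteria
#' @details `rsf_eligibility_criteria()` is the stricter preset used for risk
#'   modelling: >= 6 months of HU treatment, >= 18 months of follow-up, and at
#'   least one lab and one observation median present.
#' @export
rsf_eligibility_criteria <- function() {
  eligibility_criteria(min_hu_months = 6, min_followup_months = 18,
                       require_lab_and_obs_in_window = TRUE)
}

#' Apply eligibility criteria to a cohort
#'
#' Filters a cohort by the rules in an [eligibility_criteria] object. The
#' per-patient flags (`has_mf_et`, `has_other_cytoreductive`,
#' `n_hu_prescriptions`, `n_rux_prescriptions`) are taken from `flags` (a data
#' frame keyed by `patient_id`) or, when `flags` is `NULL`, from columns of the
#' cohort itself; a patient without flags is an error. The operation is
#' idempotent and monotone: adding a criterion never adds patients.
#'
#' @param cohort a [pv_cohort].
#' @param criteria an [eligibility_criteria] object.
#' @param flags optional data frame with `patient_id` plus flag columns.
#' @return The filtered [pv_cohort].
#' @export
apply_eligibility <- function(cohort, criteria = eligibility_criteria(),
                              flags = NULL) {
  stopifnot(inherits(criteria, "pv_eligibility"))
  if (nrow(cohort) == 0L) return(cohort)
  flag_cols <- c("has_mf_et", "has_other_cytoreductive",
                 "n_hu_prescriptions", "n_rux_prescriptions")
  if (is.null(flags)) {
    miss <- setdiff(flag_cols, names(cohort))
    if (length(miss) > 0L) {
      stop("eligibility flags absent from cohort and no `flags` given: ",
           paste(miss, collapse = ", "))
    }
    fl <- cohort[, c("patient_id", flag_cols)]
  } else {
    miss <- setdiff(c("patient_id", flag_cols), names(flags))
    if (length(miss) > 0L) {
      stop("`flags` is missing column(s): ", paste(miss, collapse = ", "))
    }
    fl <- flags[match(cohort$patient_id, flags$patient_id), ]
    if (anyNA(fl$patient_id)) {
      stop("no eligibility flags for patient(s): ",
           paste(cohort$patient_id[is.na(fl$patient_id)], collapse = ", "))
    }
  }
  switcher <- !is.na(cohort$rux_first)
  keep <- cohort$age_at_index >= criteria$min_age
  n_rx <- ifelse(switcher,
                 pmax(fl$n_hu_prescriptions, fl$n_rux_prescriptions),
                 fl$n_hu_prescriptions)
  keep <- keep & (n_rx >= criteria$min_hu_prescriptions)
  if (criteria$exclude_mf_et) keep <- keep & !fl$has_mf_et
  if (criteria$exclude_other_cytoreductives) {
    keep <- keep & !fl$has_other_cytoreductive
  }
  if (criteria$min_hu_months > 0) {
    hu_days <- cohort$hu_last - cohort$hu_first
    keep <- keep & !is.na(hu_days) &
      hu_days >= criteria$min_hu_months * DAYS_PER_MONTH
  }
  if (criteria$min_followup_months > 0) {
    keep <- keep & (cohort$record_end - cohort$index_date >=
                      criteria$min_followup_months * DAYS_PER_MONTH)
  }
  if (criteria$require_lab_and_obs_in_window) {
    has_lab <- rowSums(!is.na(cohort[, pv_lab_vars, drop = FALSE])) > 0
    has_obs <- rowSums(!is.na(cohort[, pv_obs_vars, drop = FALSE])) > 0
    keep <- keep & has_lab & has_obs
  }
  keep[is.na(keep)] <- FALSE
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label = cohort_label(cohort),
            class = c("pv_cohort", "data.frame"))
}

#' Restrict a cohort to a TE-history stratum
#'
#' @param cohort a [pv_cohort].
#' @param stratum `"all"`, `"with_te"` (history of TE) or `"without_te"`.
#' @return The filtered [pv_cohort].
#' @export
filter_stratum <- function(cohort, stratum = c("all", "without_te", "with_te")) {
  stratum <- match.arg(stratum)
  keep <- switch(stratum,
                 all = rep(TRUE, nrow(cohort)),
                 with_te = cohort$te_history %in% TRUE,
                 without_te = cohort$te_history %in% FALSE)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label = cohort_label(cohort),
            class = c("pv_cohort", "data.frame"))
}
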