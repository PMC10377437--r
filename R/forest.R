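# Random survival forest risk model, drop-column importance, windowed AUC.
# Tree growing is delegated to ranger (log-rank splitting); the outcome
# construction, out-of-bag risk scoring, windowed AUC and drop-column
# importance are defined here.

#' Default feature set for the risk model
#'
#' History flags, demographics and the summarized laboratory/observation
#' medians.
#'
#' @return Character vector of cohort column names.
#' @export
default_rsf_features <- function() {
  c("te_history", "anticoag_antiplatelet", "age_at_index", "smoking",
    "n_phlebotomy", pv_lab_vars, pv_obs_vars)
}

#' Random survival forest configuration
#'
#' Conventional settings for an EHR cohort of a few thousand patients:
#' 500 trees, `mtry = ceiling(sqrt(k))`, terminal nodes of at least 10
#' subjects, unlimited depth, 0.632 subsampling without replacement. Splits
#' maximize the log-rank statistic among the candidate features.
#'
#' @param n_trees number of trees.
#' @param mtry candidate features per split (`NULL` = `ceiling(sqrt(k))`).
#' @param min_node_size minimal terminal-node size (subjects).
#' @param max_depth maximal tree depth (0 = unlimited).
#' @param bootstrap_fraction subsample fraction per tree, drawn without
#'   replacement.
#' @param seed integer seed; the fit is deterministic for a fixed seed.
#' @param features feature column names.
#' @return An object of class `pv_rsf_config`.
#' @export
rsf_config <- function(n_trees = 500, mtry = NULL, min_node_size = 10,
                       max_depth = 0, bootstrap_fraction = 0.632, seed = 1,
                       features = default_rsf_features()) {
  stopifnot(n_trees >= 1, bootstrap_fraction > 0, bootstrap_fraction <= 1,
            length(features) >= 1)
  if (!is.null(mtry) && (mtry < 1 || mtry > length(features))) {
    stop("mtry must lie in [1, number of features]")
  }
  structure(list(n_trees = n_trees, mtry = mtry,
                 min_node_size = min_node_size, max_depth = max_depth,
                 bootstrap_fraction = bootstrap_fraction, seed = seed,
                 features = features),
            class = "pv_rsf_config")
}

#' Windowed time-to-TE outcome
#'
#' Builds the survival outcome for the risk model: time (days) from the end of
#' the post-index feature window (`origin_days` after index, default 183 days
#' = 6 months) to the first TE within the following `horizon_days` (default
#' 365 days, i.e. the 6--18-month post-index window), censored at the horizon
#' or at the record end. Patients whose record ends on or before the origin
#' are excluded. The binary window label used for ROC evaluation is 1 for an
#' observed TE, 0 for follow-up covering the whole window without TE, and `NA`
#' for patients censored inside the window before any TE (excluded from the
#' label set).
#'
#' @param cohort a [pv_cohort].
#' @param origin_days window origin, days after index.
#' @param horizon_days window length in days.
#' @return Data frame `patient_id`, `time`, `event`, `label`.
#' @export
te_outcome <- function(cohort, origin_days = 183, horizon_days = 365) {
  origin <- cohort$index_date + origin_days
  end <- origin + horizon_days
  first_te <- vapply(seq_len(nrow(cohort)), function(i) {
    tt <- cohort$te_times[[i]]
    tt <- tt[tt >= origin[i] & tt < end[i]]
    if (length(tt) == 0L) NA_real_ else tt[1]
  }, numeric(1))
  cens <- pmin(cohort$record_end, end)
  event <- !is.na(first_te) & first_te <= cens
  time <- ifelse(event, first_te, cens) - origin
  label <- ifelse(event, 1L, ifelse(cens >= end, 0L, NA_integer_))
  out <- data.frame(patient_id = cohort$patient_id, time = time,
                    event = as.integer(event), label = label,
                    stringsAsFactors = FALSE)
  out[out$time > 0, , drop = FALSE]
}

#' Fit the random survival forest risk model
#'
#' Fits a survival forest with log-rank splitting on the windowed time-to-TE
#' outcome of [te_outcome()]. Each tree is grown on a subsample drawn without
#' replacement; out-of-bag (OOB) ensemble predictions are retained for
#' unbiased evaluation. Logical features are coded 0/1; missing feature
#' values are imputed with the training-cohort median (the imputation values
#' are stored and reused at prediction time). The fit is deterministic for a
#' fixed configuration seed.
#'
#' @param cohort an eligible [pv_cohort] (see [rsf_eligibility_criteria()]).
#' @param config an [rsf_config()].
#' @param origin_days,horizon_days outcome window, see [te_outcome()].
#' @return An object of class `pv_rsf`.
#' @export
fit_rsf <- function(cohort, config = rsf_config(), origin_days = 183,
                    horizon_days = 365) {
  stopifnot(inherits(config, "pv_rsf_config"))
  out <- te_outcome(cohort, origin_days, horizon_days)
  if (sum(out$event) == 0L) stop("no TE events in the training window")
  idx <- match(out$patient_id, cohort$patient_id)
  feats <- config$features
  miss <- setdiff(feats, names(cohort))
  if (length(miss) > 0L) stop("unknown feature(s): ", paste(miss, collapse = ", "))
  x <- as.data.frame(cohort)[idx, feats, drop = FALSE]
  for (v in feats) if (is.logical(x[[v]])) x[[v]] <- as.numeric(x[[v]])
  medians <- vapply(x, function(col) stats::median(col, na.rm = TRUE),
                    numeric(1))
  if (anyNA(medians)) {
    stop("feature(s) with no observed values: ",
         paste(feats[is.na(medians)], collapse = ", "))
  }
  for (v in feats) x[[v]][is.na(x[[v]])] <- medians[[v]]
  dat <- cbind(x, .time = out$time, .event = out$event)
  mtry <- if (is.null(config$mtry)) ceiling(sqrt(length(feats))) else config$mtry
  fit <- ranger::ranger(
    formula = survival::Surv(.time, .event) ~ .,
    data = dat,
    num.trees = config$n_trees,
    mtry = min(mtry, length(feats)),
    min.node.size = config$min_node_size,
    max.depth = if (config$max_depth > 0) config$max_depth else NULL,
    sample.fraction = config$bootstrap_fraction,
    replace = FALSE,
    splitrule = "logrank",
    seed = config$seed,
    num.threads = 1,
    oob.error = TRUE)
  structure(list(fit = fit, features = feats, medians = medians,
                 outcome = out, config = config, origin_days = origin_days,
                 horizon_days = horizon_days,
                 risk_time = 365),
            class = "pv_rsf")
}

#' @export
print.pv_rsf <- function(x, ...) {
  cat(sprintf("<pv_rsf: %d trees, %d features, %d patients (%d events)>\n",
              x$config$n_trees, length(x$features), nrow(x$outcome),
              sum(x$outcome$event)))
  invisible(x)
}

# column of the ensemble CHF matrix closest to (but not after) the risk
# evaluation time
chf_column <- function(fit, at) {
  ti <- fit$unique.death.times
  k <- which(ti <= at)
  if (length(k) == 0L) 1L else max(k)
}

#' Predict TE risk scores
#'
#' The risk score of a patient is the ensemble cumulative hazard (Nelson-Aalen
#' within each terminal node, averaged over trees) evaluated 12 months after
#' the feature-window end; higher scores mean earlier expected TE. With
#' `newdata = NULL` the out-of-bag scores of the training patients are
#' returned (each patient scored only by trees whose subsample excluded them).
#'
#' @param object a fitted `pv_rsf`.
#' @param newdata optional [pv_cohort] or data frame with the feature columns.
#' @return Named numeric vector of risk scores (names = patient ids for OOB
#'   scores).
#' @export
predict_risk <- function(object, newdata = NULL) {
  if (!inherits(object, "pv_rsf")) stop("predict_risk needs a fitted pv_rsf")
  k <- chf_column(object$fit, object$risk_time)
  if (is.null(newdata)) {
    sc <- object$fit$chf[, k]
    names(sc) <- object$outcome$patient_id
    return(sc)
  }
  x <- as.data.frame(newdata)[, object$features, drop = FALSE]
  for (v in object$features) {
    if (is.logical(x[[v]])) x[[v]] <- as.numeric(x[[v]])
    x[[v]][is.na(x[[v]])] <- object$medians[[v]]
  }
  pr <- stats::predict(object$fit, data = x, num.threads = 1)
  pr$chf[, chf_column(pr, object$risk_time)]
}

#' Mann-Whitney ROC-AUC
#'
#' Rank-based AUC of a score against a binary label; equals the probability
#' that a randomly chosen positive outranks a randomly chosen negative, with
#' ties counted half.
#'
#' @param score numeric scores.
#' @param label binary labels (0/1).
#' @return AUC in \[0, 1\], or `NA` if only one class is present.
#' @export
mann_whitney_auc <- function(score, label) {
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]; label <- as.integer(label[keep])
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Out-of-bag windowed ROC-AUC of the risk model
#'
#' Mann-Whitney AUC of the out-of-bag risk scores against the binary label
#' "at least one TE in the outcome window", computed among patients whose
#' follow-up covers the window or who had an event (see [te_outcome()]).
#'
#' @param object a fitted `pv_rsf`.
#' @return AUC in \[0, 1\] (`NA` with a warning if the label set has a single
#'   class).
#' @export
windowed_auc <- function(object) {
  sc <- predict_risk(object)
  auc <- mann_whitney_auc(sc, object$outcome$label)
  if (is.na(auc)) warning("window label set has a single class; AUC undefined")
  auc
}

#' Drop-column variable importance
#'
#' Scores each feature by the degradation of the model's out-of-bag windowed
#' AUC when the feature is removed and the forest refit with the same seed:
#' `score(v) = AUC_full - AUC_without_v`. Features are ranked by descending
#' score, ties broken alphabetically. A permutation mode is provided for
#' comparison: the fitted forest is kept and each feature column is permuted
#' (deterministically, from the configuration seed) before re-scoring.
#'
#' @param cohort an eligible [pv_cohort].
#' @param config an [rsf_config()].
#' @param method `"drop"` (refit without the column) or `"permutation"`.
#' @param origin_days,horizon_days outcome window, see [te_outcome()].
#' @return Data frame `variable`, `score`, `rank` (class `pv_importance`),
#'   with the full-model AUC as attribute `"auc_full"`.
#' @export
drop_variable_importance <- function(cohort, config = rsf_config(),
                                     method = c("drop", "permutation"),
                                     origin_days = 183, horizon_days = 365) {
  method <- match.arg(method)
  feats <- config$features
  if (length(feats) < 2L) stop("importance needs at least two features")
  full <- fit_rsf(cohort, config, origin_days, horizon_days)
  auc_full <- windowed_auc(full)
  score <- if (method == "drop") {
    vapply(feats, function(v) {
      cfg <- config
      cfg$features <- setdiff(feats, v)
      auc_full - windowed_auc(fit_rsf(cohort, cfg, origin_days, horizon_days))
    }, numeric(1))
  } else {
    idx <- match(full$outcome$patient_id, cohort$patient_id)
    x <- as.data.frame(cohort)[idx, feats, drop = FALSE]
    set.seed(config$seed)
    vapply(feats, function(v) {
      xp <- x
      xp[[v]] <- xp[[v]][sample.int(nrow(xp))]
      auc_full - mann_whitney_auc(predict_risk(full, xp), full$outcome$label)
    }, numeric(1))
  }
  ord <- order(-score, feats)
  out <- data.frame(variable = feats[ord], score = unname(score[ord]),
                    rank = seq_along(feats), row.names = NULL)
  structure(out, auc_full = auc_full,
            class = c("pv_importance", "data.frame"))
}
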