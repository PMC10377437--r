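# Multi-threshold two-variable split search ("risk landscape"), optimal
# threshold extraction, decision trees and fixed-threshold validation.

#' Default candidate threshold grid
#'
#' Percentiles 5 to 95 in steps of 2.5 of the observed values, so the search
#' adapts to each variable's scale and never strands a quadrant at an extreme.
#'
#' @param x numeric values (missing allowed).
#' @return Strictly increasing threshold candidates.
#' @export
threshold_grid <- function(x) {
  g <- stats::quantile(x, probs = seq(0.05, 0.95, by = 0.025), na.rm = TRUE,
                       names = FALSE, type = 7)
  sort(unique(g))
}

#' Log-rank p-value matrix over a threshold grid
#'
#' For every pair of candidate thresholds `(t1, t2)` the cohort is cut into
#' the four quadrants of `(direction1 at t1) x (direction2 at t2)` on the
#' windowed time-to-TE outcome, and a log-rank p-value is recorded:
#' `mode = "risk_vs_rest"` (default) tests the designated risk quadrant
#' (both risk directions satisfied) against all other patients pooled;
#' `mode = "four_group"` runs the k-group test over all quadrants. Cells whose
#' groups fall below `min_quadrant_size` are absent (`NA`). Apply any
#' TE-history stratum filter (see [filter_stratum()]) before calling; the
#' computation itself is deterministic, so landscapes are reproducible
#' bit-for-bit for a fixed cohort.
#'
#' @param cohort a [pv_cohort] (already restricted to the stratum of
#'   interest).
#' @param var1,var2 numeric cohort columns.
#' @param grid1,grid2 candidate thresholds (default [threshold_grid()] of the
#'   observed values).
#' @param mode `"risk_vs_rest"` or `"four_group"`.
#' @param direction1,direction2 risk directions, `">="` or `"<"` (e.g. NEP
#'   `">="`, RDW `"<"`).
#' @param min_quadrant_size minimum group size for a cell to be evaluated.
#' @param origin_days,horizon_days outcome window, see [te_outcome()];
#'   the default horizon targets TE within 12 months of the feature-window
#'   end.
#' @return An object of class `pv_landscape`: grids, the p-value matrix `p`
#'   (`length(grid1)` x `length(grid2)`), the risk-quadrant size matrix
#'   `n_risk`, and the survival data used.
#' @export
pvalue_matrix <- function(cohort, var1, var2, grid1 = NULL, grid2 = NULL,
                          mode = c("risk_vs_rest", "four_group"),
                          direction1 = ">=", direction2 = "<",
                          min_quadrant_size = 10,
                          origin_days = 183, horizon_days = 365) {
  mode <- match.arg(mode)
  out <- te_outcome(cohort, origin_days, horizon_days)
  idx <- match(out$patient_id, cohort$patient_id)
  v1 <- as.numeric(cohort[[var1]][idx])
  v2 <- as.numeric(cohort[[var2]][idx])
  ok <- !is.na(v1) & !is.na(v2)
  v1 <- v1[ok]; v2 <- v2[ok]
  time <- out$time[ok]; event <- out$event[ok]
  if (is.null(grid1)) grid1 <- threshold_grid(v1)
  if (is.null(grid2)) grid2 <- threshold_grid(v2)
  if (length(grid1) == 0L || length(grid2) == 0L) stop("empty threshold grid")
  rng_warn <- FALSE
  if (min(grid1) < min(v1) || max(grid1) > max(v1) ||
      min(grid2) < min(v2) || max(grid2) > max(v2)) {
    warning("grid extends beyond the observed variable range; ",
            "affected cells will be absent")
  }
  surv <- survival::Surv(time, event)
  p <- matrix(NA_real_, length(grid1), length(grid2))
  n_risk <- matrix(NA_integer_, length(grid1), length(grid2))
  for (i in seq_along(grid1)) {
    in1 <- apply_direction(v1, grid1[i], direction1)
    for (j in seq_along(grid2)) {
      in2 <- apply_direction(v2, grid2[j], direction2)
      risk <- in1 & in2
      n_risk[i, j] <- sum(risk)
      if (mode == "risk_vs_rest") {
        if (sum(risk) < min_quadrant_size ||
            sum(!risk) < min_quadrant_size) next
        g <- risk
      } else {
        counts <- table(in1, in2)
        if (length(counts) < 4L || any(counts < min_quadrant_size)) next
        g <- interaction(in1, in2, drop = TRUE)
      }
      if (sum(event) == 0) next
      sd <- survival::survdiff(surv ~ g)
      df <- length(unique(g)) - 1L
      p[i, j] <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
    }
  }
  structure(list(var1 = var1, var2 = var2, grid1 = grid1, grid2 = grid2,
                 p = p, n_risk = n_risk, mode = mode,
                 direction1 = direction1, direction2 = direction2,
                 min_quadrant_size = min_quadrant_size,
                 data = data.frame(v1 = v1, v2 = v2, time = time,
                                   event = event),
                 horizon_days = horizon_days),
            class = "pv_landscape")
}

#' @export
print.pv_landscape <- function(x, ...) {
  cat(sprintf("<pv_landscape %s x %s (%s): %d x %d grid, %d evaluable cells, min p = %.3g>\n",
              x$var1, x$var2, x$mode, length(x$grid1), length(x$grid2),
              sum(!is.na(x$p)),
              if (all(is.na(x$p))) NA else min(x$p, na.rm = TRUE)))
  invisible(x)
}

#' Long-format export of a p-value matrix
#'
#' @param landscape a `pv_landscape`.
#' @return Data frame `t1`, `t2`, `p`, `n_risk` (one row per cell).
#' @export
landscape_table <- function(landscape) {
  data.frame(t1 = rep(landscape$grid1, times = length(landscape$grid2)),
             t2 = rep(landscape$grid2, each = length(landscape$grid1)),
             p = as.vector(landscape$p),
             n_risk = as.vector(landscape$n_risk))
}

#' Most significant threshold pair of a landscape
#'
#' Returns the cell with the minimum log-rank p-value. Ties are broken by the
#' larger risk-quadrant size, then the lower first and second thresholds. In
#' `risk_vs_rest` mode the risk directions are the ones the landscape was
#' built with; in `four_group` mode the risk quadrant is the one with the
#' worst Kaplan-Meier survival 12 months after the window origin.
#'
#' @param landscape a `pv_landscape` with at least one evaluable cell.
#' @return An object of class `pv_threshold_pair`: `var1`, `threshold1`,
#'   `direction1`, `var2`, `threshold2`, `direction2`, `p`, `n_risk`.
#' @export
optimal_thresholds <- function(landscape) {
  p <- landscape$p
  if (all(is.na(p))) stop("no evaluable cells in the landscape")
  pmin_val <- min(p, na.rm = TRUE)
  cand <- which(p == pmin_val, arr.ind = TRUE)
  if (nrow(cand) > 1L) {
    nr <- landscape$n_risk[cand]
    ord <- order(-nr, landscape$grid1[cand[, 1]], landscape$grid2[cand[, 2]])
    cand <- cand[ord, , drop = FALSE]
  }
  i <- cand[1, 1]; j <- cand[1, 2]
  d1 <- landscape$direction1; d2 <- landscape$direction2
  if (landscape$mode == "four_group") {
    dirs <- worst_quadrant_directions(landscape, landscape$grid1[i],
                                      landscape$grid2[j])
    d1 <- dirs[1]; d2 <- dirs[2]
  }
  structure(list(var1 = landscape$var1, threshold1 = landscape$grid1[i],
                 direction1 = d1,
                 var2 = landscape$var2, threshold2 = landscape$grid2[j],
                 direction2 = d2,
                 p = p[i, j], n_risk = landscape$n_risk[i, j]),
            class = "pv_threshold_pair")
}

# pick the quadrant with the worst KM survival at 12 months as the risk group
worst_quadrant_directions <- function(landscape, t1, t2) {
  d <- landscape$data
  best <- NULL; best_s <- Inf
  for (d1 in c(">=", "<")) {
    for (d2 in c(">=", "<")) {
      inq <- apply_direction(d$v1, t1, d1) & apply_direction(d$v2, t2, d2)
      if (sum(inq) < landscape$min_quadrant_size) next
      s <- km_survival_at(d$time[inq], d$event[inq],
                          min(365, landscape$horizon_days))
      if (s < best_s) {
        best_s <- s
        best <- c(d1, d2)
      }
    }
  }
  if (is.null(best)) c(landscape$direction1, landscape$direction2) else best
}

#' @export
print.pv_threshold_pair <- function(x, ...) {
  cat(sprintf("risk group: %s %s %.4g & %s %s %.4g (p = %.3g, n = %d)\n",
              x$var1, x$direction1, x$threshold1,
              x$var2, x$direction2, x$threshold2, x$p, x$n_risk))
  invisible(x)
}

#' Build a two-level clinical decision tree
#'
#' Turns a threshold pair into a two-level decision tree labelling a patient
#' "high risk" exactly when both risk-direction conditions hold, and
#' "low risk" otherwise (boundary convention: `<` excludes the threshold
#' value, `>=` includes it). Either pass a `pv_threshold_pair` or the explicit
#' rule components.
#'
#' @param pair a `pv_threshold_pair` from [optimal_thresholds()], or `NULL`.
#' @param var1,threshold1,direction1,var2,threshold2,direction2 explicit rule
#'   components (used when `pair` is `NULL`).
#' @return An object of class `pv_dtree`.
#' @export
build_decision_tree <- function(pair = NULL, var1, threshold1, direction1,
                                var2, threshold2, direction2) {
  if (!is.null(pair)) {
    stopifnot(inherits(pair, "pv_threshold_pair"))
    var1 <- pair$var1; threshold1 <- pair$threshold1
    direction1 <- pair$direction1
    var2 <- pair$var2; threshold2 <- pair$threshold2
    direction2 <- pair$direction2
  }
  stopifnot(direction1 %in% c(">=", "<", ">", "<="),
            direction2 %in% c(">=", "<", ">", "<="))
  structure(list(var1 = var1, threshold1 = threshold1,
                 direction1 = direction1,
                 var2 = var2, threshold2 = threshold2,
                 direction2 = direction2),
            class = "pv_dtree")
}

#' @export
print.pv_dtree <- function(x, ...) {
  cat(sprintf("decision tree: high risk iff %s %s %.4g and %s %s %.4g\n",
              x$var1, x$direction1, x$threshold1,
              x$var2, x$direction2, x$threshold2))
  invisible(x)
}

#' Apply a decision tree to patients
#'
#' A pure function of the patient's two variable values: `"high risk"` when
#' both conditions hold, `"low risk"` otherwise, `NA` when a required value is
#' missing.
#'
#' @param object a `pv_dtree`.
#' @param newdata a [pv_cohort] or data frame with the tree's variables.
#' @param ... unused.
#' @return Character vector of `"high risk"` / `"low risk"` labels.
#' @export
predict.pv_dtree <- function(object, newdata, ...) {
  v1 <- as.numeric(newdata[[object$var1]])
  v2 <- as.numeric(newdata[[object$var2]])
  high <- apply_direction(v1, object$threshold1, object$direction1) &
    apply_direction(v2, object$threshold2, object$direction2)
  ifelse(high, "high risk", "low risk")
}

#' Validate fixed thresholds on an independent cohort
#'
#' Labels the patients of an independent cohort with a fixed decision tree
#' and tests thrombosis-free survival between the high- and low-risk leaves
#' with a two-group log-rank test, returning the Kaplan-Meier curves per
#' leaf. The TE-history stratum filter (default: patients without TE history)
#' is applied first; patients missing a tree variable are excluded.
#'
#' @param tree a `pv_dtree`.
#' @param cohort the validation [pv_cohort].
#' @param stratum TE-history stratum to validate in.
#' @param origin_days,horizon_days outcome window, see [te_outcome()].
#' @return An object of class `pv_validation`: list with `logrank`
#'   ([logrank_test()] result), `km` (per-leaf curves), `n_high`, `n_low`.
#' @export
validate_fixed_thresholds <- function(tree, cohort,
                                      stratum = c("without_te", "all",
                                                  "with_te"),
                                      origin_days = 183, horizon_days = 365) {
  stopifnot(inherits(tree, "pv_dtree"))
  stratum <- match.arg(stratum)
  sub <- filter_stratum(cohort, stratum)
  out <- te_outcome(sub, origin_days, horizon_days)
  idx <- match(out$patient_id, sub$patient_id)
  lab <- predict(tree, sub[idx, , drop = FALSE])
  ok <- !is.na(lab)
  lab <- lab[ok]; time <- out$time[ok]; event <- out$event[ok]
  n_high <- sum(lab == "high risk"); n_low <- sum(lab == "low risk")
  if (n_high == 0L || n_low == 0L) {
    stop(sprintf("empty decision-tree leaf (high: %d, low: %d); %s",
                 n_high, n_low, "log-rank comparison impossible"))
  }
  lr <- logrank_test(time, event, lab)
  km <- kaplan_meier(time, event, lab)
  structure(list(logrank = lr, km = km, n_high = n_high, n_low = n_low,
                 stratum = stratum),
            class = "pv_validation")
}

#' @export
print.pv_validation <- function(x, ...) {
  cat(sprintf("fixed-threshold validation (%s): high %d vs low %d, ",
              x$stratum, x$n_high, x$n_low))
  print(x$logrank)
  invisible(x)
}

#' Permutation-adjusted minimum p-value of a landscape
#'
#' The minimum cell p-value of a threshold search is optimistic because it is
#' selected over the whole grid. This helper permutes the event labels
#' (keeping times fixed), rebuilds the landscape each time and reports the
#' fraction of permutations whose minimum p-value is at least as small as the
#' observed one -- a selection-adjusted p-value that the underlying single
#' tests do not provide.
#'
#' @param landscape a `pv_landscape`.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return List with `p_min` (observed) and `p_adjusted`.
#' @export
landscape_permutation_p <- function(landscape, n_perm = 500, seed = 1) {
  d <- landscape$data
  p_min <- min(landscape$p, na.rm = TRUE)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(d))
    ls_b <- pvalue_matrix_from_data(d$v1, d$v2, d$time[perm], d$event[perm],
                                    landscape)
    m <- suppressWarnings(min(ls_b, na.rm = TRUE))
    if (is.finite(m) && m <= p_min) hits <- hits + 1L
  }
  list(p_min = p_min, p_adjusted = (hits + 1) / (n_perm + 1))
}

# p-matrix recomputation on permuted outcomes, reusing a landscape's grids
pvalue_matrix_from_data <- function(v1, v2, time, event, landscape) {
  surv <- survival::Surv(time, event)
  p <- matrix(NA_real_, length(landscape$grid1), length(landscape$grid2))
  for (i in seq_along(landscape$grid1)) {
    in1 <- apply_direction(v1, landscape$grid1[i], landscape$direction1)
    for (j in seq_along(landscape$grid2)) {
      in2 <- apply_direction(v2, landscape$grid2[j], landscape$direction2)
      risk <- in1 & in2
      if (sum(risk) < landscape$min_quadrant_size ||
          sum(!risk) < landscape$min_quadrant_size) next
      sd <- survival::survdiff(surv ~ risk)
      p[i, j] <- stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
    }
  }
  p
}
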