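# Pairwise synergy screen: expected vs observed log-rank significance of
# two-variable splits.

#' Synergy score of a variable pair
#'
#' The synergy score contrasts what two variables achieve jointly with what
#' their separate effects predict: `expected_p` is the product of the two
#' individual log-rank p-values, `observed_p` the p-value of the joint
#' (four-quadrant) model, and the score is `expected_p / observed_p`. Scores
#' well above 1 flag pairs that are more predictive together than the product
#' of their parts.
#'
#' @param expected_p,observed_p p-values in (0, 1\].
#' @return `expected_p / observed_p` (vectorized).
#' @export
synergy_score <- function(expected_p, observed_p) {
  if (any(expected_p <= 0 | expected_p > 1) ||
      any(observed_p <= 0 | observed_p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  expected_p / observed_p
}

# two survival groups from one variable: median split for numeric variables
# (>= median is "high"), the value itself for logical flags
split_high <- function(x) {
  if (is.logical(x)) return(x)
  x >= stats::median(x)
}

#' Two-variable interaction record
#'
#' Assesses one variable pair in one TE-history stratum. Individual p-values
#' `p1`, `p2` come from two-group log-rank tests at each variable's
#' stratum-median split (logical flags split on their value); the observed
#' p-value comes from the k-group log-rank over the four quadrants formed by
#' crossing the two splits. Quadrants below `min_quadrant_size` are dropped
#' with a warning; a record with fewer than two usable groups, a degenerate
#' pair (`var1 == var2`) or too few complete cases is flagged invalid.
#'
#' @param cohort a [pv_cohort].
#' @param var1,var2 cohort column names.
#' @param stratum `"all"`, `"without_te"` or `"with_te"`.
#' @param min_quadrant_size minimum subjects per quadrant (and minimum
#'   complete-case count per group).
#' @param origin_days,horizon_days outcome window, see [te_outcome()].
#' @return One-row data frame: `var1`, `var2`, `stratum`, `n`, `p1`, `p2`,
#'   `expected_p`, `observed_p`, `score`, `valid`.
#' @export
pair_interaction <- function(cohort, var1, var2,
                             stratum = c("all", "without_te", "with_te"),
                             min_quadrant_size = 10,
                             origin_days = 183, horizon_days = 365) {
  stratum <- match.arg(stratum)
  invalid <- function() {
    data.frame(var1 = var1, var2 = var2, stratum = stratum, n = NA_integer_,
               p1 = NA_real_, p2 = NA_real_, expected_p = NA_real_,
               observed_p = NA_real_, score = NA_real_, valid = FALSE,
               stringsAsFactors = FALSE)
  }
  if (identical(var1, var2)) {
    warning("degenerate pair: var1 == var2")
    return(invalid())
  }
  sub <- filter_stratum(cohort, stratum)
  out <- te_outcome(sub, origin_days, horizon_days)
  idx <- match(out$patient_id, sub$patient_id)
  v1 <- to_numeric_feature(sub[[var1]][idx])
  v2 <- to_numeric_feature(sub[[var2]][idx])
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 2 * min_quadrant_size || sum(out$event[ok]) == 0) {
    return(invalid())
  }
  v1 <- v1[ok]; v2 <- v2[ok]
  time <- out$time[ok]; event <- out$event[ok]
  hi1 <- split_high(v1); hi2 <- split_high(v2)
  p_single <- function(hi) {
    if (length(unique(hi)) < 2L) return(NA_real_)
    logrank_test(time, event, hi)$p
  }
  p1 <- p_single(hi1)
  p2 <- p_single(hi2)
  quad <- interaction(hi1, hi2, drop = TRUE)
  small <- names(which(table(quad) < min_quadrant_size))
  if (length(small) > 0L) {
    warning(sprintf("dropping %d quadrant(s) below minimum size", length(small)))
    keep <- !(quad %in% small)
    quad <- droplevels(quad[keep]); time <- time[keep]; event <- event[keep]
  }
  if (is.na(p1) || is.na(p2) || nlevels(quad) < 2L || sum(event) == 0) {
    return(invalid())
  }
  observed_p <- logrank_test(time, event, quad)$p
  expected_p <- p1 * p2
  data.frame(var1 = var1, var2 = var2, stratum = stratum, n = sum(ok),
             p1 = p1, p2 = p2, expected_p = expected_p,
             observed_p = observed_p,
             score = synergy_score(expected_p, observed_p), valid = TRUE,
             stringsAsFactors = FALSE)
}

to_numeric_feature <- function(x) {
  if (is.logical(x)) x else as.numeric(x)
}

#' Screen all variable pairs for synergy
#'
#' Evaluates every unordered pair of the given variables in every requested
#' TE-history stratum with [pair_interaction()] and ranks the records by
#' descending synergy score (invalid records last). Raw p-values are reported
#' as such; a Bonferroni-adjusted observed p-value over the number of
#' evaluated records is included for reference only.
#'
#' @param cohort a [pv_cohort].
#' @param variables two or more cohort column names.
#' @param strata strata to evaluate.
#' @param ... passed to [pair_interaction()].
#' @return Data frame of ranked synergy records with an added
#'   `observed_p_bonferroni` column.
#' @export
screen_all_pairs <- function(cohort, variables,
                             strata = c("all", "without_te", "with_te"),
                             ...) {
  if (length(variables) < 2L) stop("need at least two variables to screen")
  pairs <- utils::combn(sort(variables), 2)
  recs <- list()
  for (s in strata) {
    for (j in seq_len(ncol(pairs))) {
      recs[[length(recs) + 1L]] <-
        pair_interaction(cohort, pairs[1, j], pairs[2, j], stratum = s, ...)
    }
  }
  out <- do.call(rbind, recs)
  out$observed_p_bonferroni <- pmin(1, out$observed_p * nrow(out))
  ord <- order(!out$valid, -out$score, out$var1, out$var2)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
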